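test_that("2x2 reconstruction from frequencies matches hand-derived cells", {
  tab <- load_fmd_table()
  cnts <- build_table(tab, "NFE", "AFR", scale = "counts")
  r <- cnts[tab$pos == 17553211, ]
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 152, b = 113618, c = 2, d = 16254))
  # zero frequency gives a = 0, b = AN
  r0 <- cnts[tab$pos == 17641065, ]
  expect_equal(r0$a, 0)
  expect_equal(r0$b, 113770)
  # cohort side uses cohort_ac / cohort_an
  coh_side <- build_table(tab, "COHORT", "NFE", scale = "counts")
  r5 <- coh_side[tab$pos == 17557227, ]
  expect_equal(c(r5$a, r5$b), c(5, 195))
  expect_error(two_by_two(5, 0, 1, 10), class = "varburden_validation_error")
  expect_error(two_by_two(11, 10, 1, 10), class = "varburden_validation_error")
})

test_that("sample OR obeys identity, antisymmetry, scale invariance and zero policies", {
  expect_equal(sample_or(3, 7, 3, 7), 1)
  expect_equal(sample_or(1, 1, 1, 1), 1)
  expect_equal(sample_or(1, 1, 1, 1, zero_policy = "haldane"), 1)
  # antisymmetry and invariance over random all-positive tables
  set.seed(401)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    or12 <- sample_or(cells[1], cells[2], cells[3], cells[4])
    or21 <- sample_or(cells[3], cells[4], cells[1], cells[2])
    expect_equal(or12 * or21, 1, tolerance = 1e-12)
    k <- sample(2:9, 1)
    expect_equal(sample_or(k * cells[1], k * cells[2], k * cells[3],
                           k * cells[4]), or12, tolerance = 1e-12)
  }
  expect_equal(sample_or(0, 10, 5, 5), 0)
  expect_equal(sample_or(5, 5, 0, 10), Inf)
  expect_true(is.na(sample_or(0, 10, 0, 10)))
  expect_equal(sample_or(2, 8, 0, 10, zero_policy = "haldane"),
               (2.5 * 10.5) / (8.5 * 0.5))
})

test_that("Woolf interval matches a direct log-OR variance computation and brackets the OR", {
  a <- 152; b <- 113618; c <- 2; d <- 16254
  ci <- or_ci(a, b, c, d, level = 0.95, method = "woolf")
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  expect_equal(ci$ci_low, exp(lor - qnorm(0.975) * se))
  expect_equal(ci$ci_high, exp(lor + qnorm(0.975) * se))
  expect_lt(ci$ci_low, 9.07)
  expect_gt(ci$ci_high, 9.07)
  # all-equal cells: symmetric about 1 on the log scale
  ci1 <- or_ci(20, 20, 20, 20)
  expect_equal(log(ci1$ci_low), -log(ci1$ci_high), tolerance = 1e-12)
  # exact method at c = 0: finite lower bound, infinite upper bound
  ci0 <- or_ci(5, 95, 0, 100, method = "exact")
  expect_true(is.finite(ci0$ci_low))
  expect_equal(ci0$ci_high, Inf)
  # degenerate table flagged, not erred
  cid <- or_ci(0, 10, 0, 10)
  expect_true(is.na(cid$ci_low) && is.na(cid$ci_high))
})

test_that("exact p equals the enumeration oracle for small tables", {
  # the complete sweep to total 40 runs with the acceptance checks
  for (n in 2:20) {
    for (r1 in 1:(n - 1)) {
      r2 <- n - r1
      for (k in 1:(n - 1)) {
        xs <- max(0, k - r2):min(k, r1)
        for (a in xs) {
          b <- r1 - a; c <- k - a; d <- r2 - c
          expect_equal(fisher_exact_p(a, b, c, d),
                       fisher_enum_oracle(a, b, c, d),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("exact p matches fisher.test and behaves at the null", {
  set.seed(402)
  for (i in 1:25) {
    cells <- sample(0:60, 4, replace = TRUE)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    ft <- fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(fisher_exact_p(cells[1], cells[2], cells[3], cells[4]),
                 ft$p.value, tolerance = 1e-9)
  }
  expect_gt(fisher_exact_p(500, 500, 500, 500), 0.9)
})

test_that("enrichment classification applies OR >= 1 and p < alpha with strict boundaries", {
  res <- tibble::tibble(or_point = c(9.07, 0.71, 1.0, 0.2),
                        p_value = c(4.26e-3, 7.50e-2, 1.0, 1e-4))
  out <- classify_enrichment(res, alpha = 0.05)
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$depleted, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_enrichment(res, alpha = 1),
               class = "varburden_validation_error")
})

test_that("per-variant enrichment over the cohort table flags the expected populations", {
  coh <- filter_rare_missense(load_fmd_table())
  enr <- enrich_variants(coh, pop1 = "NFE")
  expect_setequal(unique(enr$pop2), c("AFR", "EAS", "SAS", "AMR"))
  # the NFE-enriched comparisons from the frequency tables
  r <- enr[enr$variant_id == "NC_000011.10:g.17553211G>A" & enr$pop2 == "AFR", ]
  expect_true(r$enriched)
  expect_lt(r$p_value, 0.05)
  # NFE vs AMR for the AMR-overrepresented variant is depleted, not enriched
  r2 <- enr[enr$variant_id == "NC_000011.10:g.17557227G>A" & enr$pop2 == "AMR", ]
  expect_false(r2$enriched)
  expect_true(r2$depleted)
  g <- glance(enr)
  expect_equal(g$n_comparisons, 52)
  expect_equal(g$n_variants, 13)
})

test_that("Woolf 95% intervals cover a known OR at close to nominal rate", {
  set.seed(403)
  n_rep <- 2000
  an1 <- 20000; an2 <- 20000
  true_or <- exp(runif(n_rep, log(0.25), log(4)))
  p2 <- runif(n_rep, 0.05, 0.3)
  odds1 <- true_or * p2 / (1 - p2)
  p1 <- odds1 / (1 + odds1)
  a <- rbinom(n_rep, an1, p1)
  c <- rbinom(n_rep, an2, p2)
  ci <- or_ci(a, an1 - a, c, an2 - c, level = 0.95, method = "woolf")
  coverage <- mean(ci$ci_low <= true_or & true_or <= ci$ci_high)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})
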