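toy_variants <- function(cds_pos, ac = 1L) {
  tibble::tibble(
    contig = "chrS", pos = 1000L + cds_pos, ref = "A", alt = "G",
    consequence = "missense", cds_pos = cds_pos,
    AF_NFE = ac / 1000, AC_NFE = ac, AN_NFE = 1000L
  )
}

test_that("window densities match direct counts, including edge clipping", {
  prof <- density_profile(toy_variants(500L), cds_length = 1000,
                          population = "NFE")
  expect_equal(nrow(prof), 1000)
  expect_equal(unique(prof$density[prof$cds_pos %in% 400:600]), 1 / 201)
  expect_equal(unique(prof$density[prof$cds_pos < 400 | prof$cds_pos > 600]), 0)
  # a variant at position 1: clipped window of 101 bp
  p1 <- density_profile(toy_variants(1L), cds_length = 1000,
                        population = "NFE")
  expect_equal(p1$density[1], 1 / 101)
  # no variants: identically zero
  p0 <- density_profile(toy_variants(integer(0)), cds_length = 500)
  expect_true(all(p0$density == 0))
  # the same site twice counts once; AC = 0 sites are invisible
  dup <- dplyr::bind_rows(toy_variants(500L), toy_variants(500L),
                          toy_variants(700L, ac = 0L))
  pd <- density_profile(dup, cds_length = 1000, population = "NFE")
  expect_equal(pd$density[500], 1 / 201)
  expect_equal(pd$density[700], 0)
  # a record without cds_pos is reported by id
  bad <- toy_variants(500L)
  bad$cds_pos <- NA_integer_
  expect_error(density_profile(bad, 1000), "g.1500",
               class = "varburden_validation_error")
})

test_that("window mass is conserved for interior variants", {
  set.seed(406)
  h <- 100
  pos <- sample(200:800, 25)
  prof <- density_profile(toy_variants(as.integer(pos)), cds_length = 1000,
                          population = "NFE", halfwidth = h)
  lo <- pmax(1, prof$cds_pos - h)
  hi <- pmin(1000, prof$cds_pos + h)
  expect_equal(sum(prof$density * (hi - lo + 1)),
               (2 * h + 1) * length(unique(pos)))
})

test_that("population thresholds are the scaled expected count per bp", {
  expect_equal(population_threshold(400, 8778, scale = 0.5), 200 / 8778)
  expect_equal(population_threshold(400, 8778, scale = 1), 400 / 8778)
  expect_error(population_threshold(0, 8778),
               class = "varburden_validation_error")
  panel <- gnomad_panel()
  s <- population_scales(panel)
  expect_equal(unname(s["GLOBAL"]), 1)
  expect_equal(unname(s["NFE"]), 113770 / 251496)
  coh <- filter_rare_missense(load_fmd_table())
  s2 <- population_scales(panel, method = "count_share", variants = coh)
  expect_equal(unname(s2["GLOBAL"]), 1)
  expect_equal(unname(s2["EAS"]), 5 / 13)  # 5 of the 13 sites have EAS AC > 0
})

test_that("region calling partitions the CDS and matches the per-position oracle", {
  set.seed(407)
  for (i in 1:20) {
    L <- sample(50:400, 1)
    pos <- unique(sample.int(L, sample(1:30, 1), replace = TRUE))
    prof <- density_profile(toy_variants(as.integer(pos)), cds_length = L,
                            population = "NFE", halfwidth = sample(2:20, 1))
    thr <- runif(1, 0, max(prof$density) + 0.01)
    reg <- call_regions(prof, thr)
    orc <- regions_oracle(prof$density, thr)
    expect_equal(data.frame(start = reg$start, end = reg$end,
                            label = reg$label, stringsAsFactors = FALSE),
                 orc)
    # partition of [0, L) with alternating labels
    expect_equal(reg$start[1], 0L)
    expect_equal(reg$end[nrow(reg)], L)
    if (nrow(reg) > 1) {
      expect_equal(reg$start[-1], reg$end[-nrow(reg)])
      expect_true(all(reg$label[-1] != reg$label[-nrow(reg)]))
    }
  }
})

test_that("raising the threshold never shrinks the total LDR length", {
  set.seed(408)
  pos <- unique(sample.int(2000, 150, replace = TRUE))
  prof <- density_profile(toy_variants(as.integer(pos)), cds_length = 2000,
                          population = "NFE")
  ldr_len <- vapply(seq(0, 0.03, length.out = 12), function(t) {
    r <- call_regions(prof, t)
    sum(r$end[r$label == "LDR"] - r$start[r$label == "LDR"])
  }, numeric(1))
  expect_true(all(diff(ldr_len) >= 0))
})

test_that("a uniformly sub-threshold profile is one single LDR", {
  prof <- density_profile(toy_variants(500L), 1000, population = "NFE")
  reg <- call_regions(prof, threshold = 1)  # everything below
  expect_equal(nrow(reg), 1)
  expect_equal(unlist(reg[c("start", "end")]), c(start = 0, end = 1000))
  expect_equal(reg$label, "LDR")
  expect_equal(annotate_variant_region(reg, 123), "LDR")
})

test_that("variant region annotation follows the half-open region layout", {
  reg <- make_regions(c(0, 500), c(500, 1000), c("LDR", "HDR"), 1000)
  expect_equal(annotate_variant_region(reg, c(1, 500, 501, 1000)),
               c("LDR", "LDR", "HDR", "HDR"))
  expect_error(annotate_variant_region(reg, 1001),
               class = "varburden_validation_error")
})

test_that("profile similarity equals hand-computed agreement percentages", {
  a <- make_regions(c(0, 500), c(500, 1000), c("LDR", "HDR"), 1000)
  b <- make_regions(c(0, 250), c(250, 1000), c("LDR", "HDR"), 1000)
  expect_equal(profile_similarity(a, b), 75)
  expect_equal(profile_similarity(b, a), 75)  # symmetric
  expect_equal(profile_similarity(a, a), 100)
  comp <- make_regions(c(0, 500), c(500, 1000), c("HDR", "LDR"), 1000)
  expect_equal(profile_similarity(a, comp), 0)
  short <- make_regions(0, 500, "LDR", 500)
  expect_error(profile_similarity(a, short),
               class = "varburden_validation_error")
})

test_that("a planted low-density segment is recovered by the region caller", {
  # scaled-down version of the recovery experiment (more seeds in the
  # acceptance suite)
  jac <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 500 + s, n_variants = 2000,
                      ldr_segments = tibble::tibble(start = 3001, end = 4500,
                                                    multiplier = 0.1))
    sim <- simulate_frequency_table(cfg)
    prof <- density_profile(sim$variants, cfg$cds_length, population = "NFE")
    n_obs <- sum(sim$variants$AC_NFE > 0)
    reg <- call_regions(prof, population_threshold(n_obs, cfg$cds_length))
    best_ldr_jaccard(reg, 3000, 4500)
  }, numeric(1))
  expect_gte(median(jac), 0.8)
})
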