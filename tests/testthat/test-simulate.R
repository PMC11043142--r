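test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- sim_config(seed = 42, n_variants = 150)
  a <- simulate_frequency_table(cfg)
  b <- simulate_frequency_table(cfg)
  expect_identical(a, b)
  expect_identical(simulate_cohort(cfg, a$variants),
                   simulate_cohort(cfg, b$variants))
  expect_identical(simulate_control_panel(cfg), simulate_control_panel(cfg))
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  # a different seed changes the draw
  expect_false(identical(
    a$variants, simulate_frequency_table(sim_config(seed = 43,
                                                    n_variants = 150))$variants
  ))
})

test_that("global allele counts are the sums over populations", {
  sim <- simulate_frequency_table(sim_config(seed = 44, n_variants = 200))
  v <- sim$variants
  pops <- setdiff(table_populations(v), "GLOBAL")
  expect_equal(v$AC_GLOBAL,
               rowSums(as.matrix(v[paste0("AC_", pops)])))
  expect_equal(unique(v$AN_GLOBAL),
               sum(vapply(paste0("AN_", pops), function(cn) v[[cn]][1],
                          numeric(1))))
  # simulated tables pass the package's own validation
  panel <- population_panel(c(pops, "GLOBAL"),
                            c(gnomad_panel()$n_individuals[1:5],
                              sum(gnomad_panel()$n_individuals[1:5])))
  expect_silent(validate_variant_table(v, panel))
})

test_that("planted odds-scale enrichment is recovered by the sample OR", {
  # plant OR 9 in the smaller population against a shared baseline
  nv <- 500
  cfg <- sim_config(seed = 45,
                    panel = population_panel(c("NFE", "AFR"), c(56885, 8128)),
                    cds_length = 50000, n_variants = nv,
                    af_range = c(1.5e-4, 1.5e-4),
                    enrichments = tibble::tibble(variant = seq_len(nv),
                                                 pop = "AFR", or = 9))
  sim <- simulate_frequency_table(cfg)
  expect_gt(nrow(sim$variants), 450)
  enr <- enrich_variants(sim$variants, pop1 = "AFR", pop2 = "NFE")
  expect_equal(mean(enr$or_point), 9, tolerance = 0.1)
  # null case: no enrichment, ORs concentrate at 1
  cfg0 <- sim_config(seed = 46,
                     panel = population_panel(c("NFE", "AFR"),
                                              c(500000, 500000)),
                     cds_length = 50000, n_variants = nv,
                     af_range = c(5e-3, 5e-3))
  sim0 <- simulate_frequency_table(cfg0)
  enr0 <- enrich_variants(sim0$variants, pop1 = "AFR", pop2 = "NFE")
  expect_lt(median(abs(enr0$or_point - 1)), 0.05)
})

test_that("enrichment that crosses the rarity threshold is refused", {
  cfg <- sim_config(seed = 47, n_variants = 50,
                    af_range = c(5e-3, 9e-3),
                    enrichments = tibble::tibble(variant = 1, pop = "NFE",
                                                 or = 50))
  expect_error(simulate_frequency_table(cfg), "smaller baseline",
               class = "varburden_validation_error")
})

test_that("density segments thin variant placement as configured", {
  # multiplier 0 over the whole CDS: nothing survives
  cfg <- sim_config(seed = 48, n_variants = 300,
                    ldr_segments = tibble::tibble(start = 1, end = 8778,
                                                  multiplier = 0))
  expect_equal(nrow(simulate_frequency_table(cfg)$variants), 0)
  # truth records the segment in 0-based half-open coordinates
  cfg2 <- sim_config(seed = 49, n_variants = 300,
                     ldr_segments = tibble::tibble(start = 1001, end = 2000,
                                                   multiplier = 0))
  sim2 <- simulate_frequency_table(cfg2)
  expect_equal(sim2$truth$ldr_segments$start, 1000L)
  expect_equal(sim2$truth$ldr_segments$end, 2000L)
  expect_false(any(sim2$variants$cds_pos %in% 1001:2000))
})

test_that("cohort simulation honours planted counts and degenerate inputs", {
  cfg <- sim_config(seed = 50, n_variants = 100,
                    cohort_planted = tibble::tibble(variant = 1, ac = 5))
  sim <- simulate_frequency_table(cfg)
  coh <- simulate_cohort(cfg, sim$variants)
  expect_equal(coh$cohort_ac[1], 5L)
  expect_equal(coh$cohort_ac[1] / coh$cohort_an[1], 0.025)
  expect_equal(unique(coh$cohort_an), 200L)
  # zero probands refused
  expect_error(simulate_cohort(sim_config(seed = 50, n_probands = 0),
                               sim$variants),
               class = "varburden_validation_error")
  # planted count beyond the allele number refused
  cfg_bad <- sim_config(seed = 50, n_variants = 100,
                        cohort_planted = tibble::tibble(variant = 1, ac = 201))
  expect_error(simulate_cohort(cfg_bad, sim$variants),
               class = "varburden_validation_error")
  # reference frequencies all zero give an all-zero cohort
  z <- sim$variants
  z$AF_NFE <- 0
  cohz <- simulate_cohort(cfg, z)
  expect_true(all(cohz$cohort_ac[-1] == 0))
})

test_that("control panels stay inside the length band with Poisson counts", {
  cfg <- sim_config(seed = 51)
  ctl <- simulate_control_panel(cfg)
  expect_equal(nrow(ctl), 64)
  expect_true(all(ctl$cds_length >= 8778 - 439 & ctl$cds_length <= 8778 + 439))
  # rate 0: all counts zero, and a focal gene with one variant tops the panel
  ctl0 <- simulate_control_panel(sim_config(seed = 52, control_rate = 0))
  expect_true(all(ctl0$count_GLOBAL == 0))
  expect_gt(percentile_rank(ctl0$count_GLOBAL, 1)$percentile, 98)
  # Poisson mean check at scale: global counts track rate x length
  big <- simulate_control_panel(sim_config(seed = 53, n_control_genes = 10000,
                                           control_rate = 0.02))
  expected <- 0.02 * mean(big$cds_length)
  se <- sqrt(expected / 10000)
  expect_lt(abs(mean(big$count_GLOBAL) - expected), 3 * se)
})
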