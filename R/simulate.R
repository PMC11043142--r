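# Synthetic gnomAD-style data with known ground truth. One global seed;
# each stage draws from a fixed-offset substream so stages are reproducible
# independently of which other stages run.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study conditions of the reference analysis: the gnomAD v2.1 exome
#' population panel (NFE/AFR/EAS/SAS/AMR with the global totals formed by
#' summation), an 8778-bp CDS, rare baseline frequencies below the 0.01
#' rarity threshold, and a 100-proband cohort typed at 200 alleles.
#'
#' @param seed Integer master seed; fully determines all outputs.
#' @param panel Population panel *without* a global row (the generator sums
#'   populations into `GLOBAL`). Default: [gnomad_panel()] minus `GLOBAL`.
#' @param cds_length CDS length in bp (default 8778).
#' @param gene_symbol,contig,genomic_offset Cosmetic coordinates for the
#'   generated records.
#' @param n_variants Number of candidate variant sites placed along the CDS
#'   before density thinning (default 400, a typical rare-missense site
#'   count for a CDS of this size in a gnomAD-scale panel).
#' @param af_range Log-uniform range for baseline true allele frequencies,
#'   within (0, 0.01).
#' @param af_threshold Rarity bound; planting an enrichment that pushes a
#'   true AF to or above it is an error.
#' @param enrichments Tibble/data frame with columns `variant` (site index),
#'   `pop` and `or`: the population's true odds are `or` times the baseline
#'   odds shared by all other populations.
#' @param ldr_segments Tibble with `start`, `end` (1-based, inclusive) and
#'   `multiplier` in \[0, 1): placement intensity inside the segment is
#'   multiplied, creating plantable low-density regions.
#' @param n_probands Cohort size (diploid); cohort AN is `2 * n_probands`.
#' @param reference Reference population for cohort sampling and rarity.
#' @param cohort_planted Tibble with `variant`, `ac`: fixed cohort allele
#'   counts for chosen sites.
#' @param cohort_odds_multiplier Multiplier on the reference-population odds
#'   used when drawing un-planted cohort counts; 3 plants a threefold
#'   aggregated burden (default 1, no burden).
#' @param n_control_genes,control_length_spread Control panel size (default
#'   64) and CDS-length half-range in bp (default 439).
#' @param control_rate Expected rare-missense sites per CDS bp in the global
#'   population; per-population rates are scaled by allele-number share.
#' @param n_geno_individuals Individuals in the genotype matrix (default
#'   500).
#' @param geno_mafs Minor allele frequencies of the genotype-matrix variants.
#' @param ld_pairs Tibble with `v1`, `v2` (variant indices into
#'   `geno_mafs`, each index in at most one pair) and `r2` targets in
#'   \[0, 1\].
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       panel = NULL,
                       cds_length = 8778L,
                       gene_symbol = "GENE_SYN",
                       contig = "chrS",
                       genomic_offset = 1000000L,
                       n_variants = 400L,
                       af_range = c(1e-5, 1e-3),
                       af_threshold = 0.01,
                       enrichments = NULL,
                       ldr_segments = NULL,
                       n_probands = 100L,
                       reference = "NFE",
                       cohort_planted = NULL,
                       cohort_odds_multiplier = 1,
                       n_control_genes = 64L,
                       control_length_spread = 439L,
                       control_rate = 0.045,
                       n_geno_individuals = 500L,
                       geno_mafs = c(0.3, 0.3, 0.2),
                       ld_pairs = NULL) {
  if (is.null(panel)) {
    panel <- gnomad_panel()
    panel <- panel[panel$code != "GLOBAL", , drop = FALSE]
  }
  if (!is_count(seed)) {
    abort_varburden("`seed` must be a non-negative integer",
                    class = "varburden_validation_error")
  }
  if (af_range[1] <= 0 || af_range[2] >= af_threshold ||
      af_range[1] > af_range[2]) {
    abort_varburden("`af_range` must lie inside (0, af_threshold)",
                    class = "varburden_validation_error")
  }
  if (!is.null(enrichments) && any(enrichments$or <= 0)) {
    abort_varburden("target odds ratios must be > 0",
                    class = "varburden_validation_error")
  }
  if (!is.null(ldr_segments) &&
      (any(ldr_segments$multiplier < 0) || any(ldr_segments$multiplier >= 1))) {
    abort_varburden("density multipliers must lie in [0, 1)",
                    class = "varburden_validation_error")
  }
  if (!is.null(ld_pairs)) {
    if (any(ld_pairs$r2 < 0 | ld_pairs$r2 > 1)) {
      abort_varburden("target r2 must lie in [0, 1]",
                      class = "varburden_validation_error")
    }
    idx <- c(ld_pairs$v1, ld_pairs$v2)
    if (anyDuplicated(idx) || any(idx > length(geno_mafs)) || any(idx < 1)) {
      abort_varburden("ld_pairs indices must be distinct and within geno_mafs",
                      class = "varburden_validation_error")
    }
  }
  structure(list(
    seed = as.integer(seed), panel = panel, cds_length = as.integer(cds_length),
    gene_symbol = gene_symbol, contig = contig,
    genomic_offset = as.integer(genomic_offset),
    n_variants = as.integer(n_variants), af_range = af_range,
    af_threshold = af_threshold,
    enrichments = enrichments, ldr_segments = ldr_segments,
    n_probands = as.integer(n_probands), reference = reference,
    cohort_planted = cohort_planted,
    cohort_odds_multiplier = cohort_odds_multiplier,
    n_control_genes = as.integer(n_control_genes),
    control_length_spread = as.integer(control_length_spread),
    control_rate = control_rate,
    n_geno_individuals = as.integer(n_geno_individuals),
    geno_mafs = geno_mafs, ld_pairs = ld_pairs
  ), class = "sim_config")
}

odds_scale <- function(p, mult) {
  o <- mult * p / (1 - p)
  o / (1 + o)
}

#' Simulate a multi-population variant frequency table
#'
#' Places candidate sites uniformly along the CDS, thins them inside planted
#' low-density segments by each segment's intensity multiplier, draws a
#' baseline true allele frequency per site (log-uniform), applies planted
#' enrichments on the odds scale (so the target odds ratio is the estimand),
#' and samples per-population allele counts `AC ~ Binomial(AN, true AF)`.
#' Global AC/AN are the sums over populations. Reported AF columns are the
#' observed `AC/AN` (as a frequency database would print them); true
#' frequencies live in the returned truth object.
#'
#' @param config A [sim_config()].
#' @return List with `variants` (a variant table tibble) and `truth` (true
#'   per-population AFs, planted low-density segments in 0-based half-open
#'   coordinates, enrichment list).
#' @export
simulate_frequency_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, 11L), {
    L <- config$cds_length
    pos <- sort(unique(sample.int(L, config$n_variants, replace = TRUE)))
    if (!is.null(config$ldr_segments)) {
      keep <- rep(TRUE, length(pos))
      u <- stats::runif(length(pos))
      for (k in seq_len(nrow(config$ldr_segments))) {
        seg <- config$ldr_segments[k, ]
        inside <- pos >= seg$start & pos <= seg$end
        keep[inside] <- keep[inside] & (u[inside] < seg$multiplier)
      }
      pos <- pos[keep]
    }
    nv <- length(pos)
    pops <- config$panel$code
    base <- exp(stats::runif(nv, log(config$af_range[1]),
                             log(config$af_range[2])))
    af_true <- matrix(base, nrow = nv, ncol = length(pops),
                      dimnames = list(NULL, pops))
    if (!is.null(config$enrichments) && nv > 0) {
      for (k in seq_len(nrow(config$enrichments))) {
        e <- config$enrichments[k, ]
        if (e$variant > nv) next
        p <- odds_scale(base[e$variant], e$or)
        if (p >= config$af_threshold) {
          abort_varburden(sprintf(
            "planted enrichment pushes AF to %.3g >= threshold %.3g; use a smaller baseline",
            p, config$af_threshold
          ), class = "varburden_validation_error")
        }
        af_true[e$variant, e$pop] <- p
      }
    }
    an <- config$panel$an
    ac <- matrix(0L, nrow = nv, ncol = length(pops),
                 dimnames = list(NULL, pops))
    for (j in seq_along(pops)) {
      ac[, j] <- stats::rbinom(nv, an[j], af_true[, j])
    }
    cds_vec <- pos
    out <- tibble::tibble(
      contig = config$contig,
      pos = config$genomic_offset + cds_vec,
      ref = "A", alt = "G",
      rsid = NA_character_,
      consequence = "missense",
      cds_pos = cds_vec
    )
    for (j in seq_along(pops)) {
      out[[paste0("AF_", pops[j])]] <- ac[, j] / an[j]
      out[[paste0("AC_", pops[j])]] <- ac[, j]
      out[[paste0("AN_", pops[j])]] <- an[j]
    }
    out$AF_GLOBAL <- rowSums(ac) / sum(an)
    out$AC_GLOBAL <- as.integer(rowSums(ac))
    out$AN_GLOBAL <- sum(an)
    ldr_truth <- if (is.null(config$ldr_segments)) {
      tibble::tibble(start = integer(0), end = integer(0),
                     multiplier = numeric(0))
    } else {
      tibble::tibble(start = as.integer(config$ldr_segments$start - 1L),
                     end = as.integer(config$ldr_segments$end),
                     multiplier = config$ldr_segments$multiplier)
    }
    list(
      variants = out,
      truth = list(af = af_true, ldr_segments = ldr_truth,
                   enrichments = config$enrichments)
    )
  })
}

#' Simulate cohort allele counts onto a variant table
#'
#' Sets `cohort_ac`/`cohort_an` on the records: planted counts where
#' specified, otherwise `Binomial(2 n_probands, q)` with `q` the
#' reference-population frequency rescaled on the odds scale by
#' `cohort_odds_multiplier` (1 leaves the cohort exchangeable with the
#' reference population).
#'
#' @param config A [sim_config()].
#' @param variants Variant table from [simulate_frequency_table()].
#' @return A `cohort_table` with cohort columns filled.
#' @export
simulate_cohort <- function(config, variants) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_probands <= 0) {
    abort_varburden("`n_probands` must be positive",
                    class = "varburden_validation_error")
  }
  an <- 2L * config$n_probands
  with_seed(stage_seed(config$seed, 23L), {
    p_ref <- variants[[paste0("AF_", config$reference)]]
    if (is.null(p_ref)) {
      abort_varburden(sprintf("reference population %s absent",
                              config$reference),
                      class = "varburden_validation_error")
    }
    q <- odds_scale(p_ref, config$cohort_odds_multiplier)
    ac <- stats::rbinom(nrow(variants), an, q)
    if (!is.null(config$cohort_planted)) {
      if (any(config$cohort_planted$ac > an)) {
        abort_varburden(sprintf("planted cohort AC exceeds %d alleles", an),
                        class = "varburden_validation_error")
      }
      ok <- config$cohort_planted$variant <= nrow(variants)
      ac[config$cohort_planted$variant[ok]] <- config$cohort_planted$ac[ok]
    }
    out <- variants
    out$cohort_ac <- as.integer(ac)
    out$cohort_an <- an
    new_cohort_table(out, config$reference, config$af_threshold,
                     config$n_probands)
  })
}

#' Simulate a CDS-length-matched control-gene panel
#'
#' Control CDS lengths are drawn uniformly within
#' `focal length +/- control_length_spread`; per-population rare-missense
#' counts are Poisson with mean `cds_length * rate`, where the global rate
#' is split across populations by allele-number share.
#'
#' @param config A [sim_config()].
#' @return Tibble with `gene_symbol`, `transcript_id`, `cds_length` and one
#'   `count_<POP>` column per panel population plus `count_GLOBAL`.
#' @export
simulate_control_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_control_genes < 1) {
    abort_varburden("`n_control_genes` must be >= 1",
                    class = "varburden_validation_error")
  }
  with_seed(stage_seed(config$seed, 37L), {
    n <- config$n_control_genes
    len <- config$cds_length +
      sample.int(2L * config$control_length_spread + 1L, n, replace = TRUE) -
      config$control_length_spread - 1L
    out <- tibble::tibble(
      gene_symbol = sprintf("CTRL%03d", seq_len(n)),
      transcript_id = sprintf("TSYN%03d.1", seq_len(n)),
      cds_length = as.integer(len)
    )
    share <- config$panel$an / sum(config$panel$an)
    for (j in seq_along(config$panel$code)) {
      rate <- config$control_rate * share[j]
      out[[paste0("count_", config$panel$code[j])]] <-
        stats::rpois(n, len * rate)
    }
    out$count_GLOBAL <- stats::rpois(n, len * config$control_rate)
    out
  })
}

#' Simulate genotypes with planted pairwise LD
#'
#' For each planted pair, builds the four-haplotype frequency table that
#' achieves the target r2 at the pair's allele frequencies (with D > 0:
#' `p_AB = p1 p2 + sqrt(r2 p1 q1 p2 q2)`), then samples two haplotypes per
#' individual independently. Unpaired variants are sampled at linkage
#' equilibrium. Infeasible targets (r2 above the bound
#' `min(p1 q2 / (q1 p2), q1 p2 / (p1 q2))`) raise an error stating the
#' feasible maximum.
#'
#' @param config A [sim_config()].
#' @return List with `dosages` (individuals x variants, 0/1/2), `phased`
#'   (2n x variants binary haplotypes) and `truth` (planted r2 table).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- length(config$geno_mafs)
  n <- config$n_geno_individuals
  nh <- 2L * n
  with_seed(stage_seed(config$seed, 53L), {
    haps <- matrix(0L, nrow = nh, ncol = m,
                   dimnames = list(NULL, paste0("v", seq_len(m))))
    done <- rep(FALSE, m)
    if (!is.null(config$ld_pairs)) {
      for (k in seq_len(nrow(config$ld_pairs))) {
        pr <- config$ld_pairs[k, ]
        p1 <- config$geno_mafs[pr$v1]; p2 <- config$geno_mafs[pr$v2]
        r2max <- r2_max_feasible(p1, p2)
        if (pr$r2 > r2max + 1e-12) {
          abort_varburden(sprintf(
            "target r2 %.3f infeasible for AFs %.3f/%.3f (maximum %.3f)",
            pr$r2, p1, p2, r2max
          ), class = "varburden_validation_error")
        }
        d <- sqrt(pr$r2 * p1 * (1 - p1) * p2 * (1 - p2))
        f <- c(p1 * p2 + d,              # AB
               p1 * (1 - p2) - d,        # Ab
               (1 - p1) * p2 - d,        # aB
               (1 - p1) * (1 - p2) + d)  # ab
        f <- pmax(f, 0); f <- f / sum(f)
        cat_draw <- sample.int(4L, nh, replace = TRUE, prob = f)
        haps[, pr$v1] <- as.integer(cat_draw %in% c(1L, 2L))
        haps[, pr$v2] <- as.integer(cat_draw %in% c(1L, 3L))
        done[c(pr$v1, pr$v2)] <- TRUE
      }
    }
    for (j in which(!done)) {
      haps[, j] <- stats::rbinom(nh, 1L, config$geno_mafs[j])
    }
    dosages <- haps[seq(1, nh, by = 2), , drop = FALSE] +
      haps[seq(2, nh, by = 2), , drop = FALSE]
    rownames(dosages) <- sprintf("ind%04d", seq_len(n))
    list(
      dosages = dosages,
      phased = haps,
      truth = list(ld_pairs = config$ld_pairs, mafs = config$geno_mafs)
    )
  })
}
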