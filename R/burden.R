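#' Aggregate allele frequency over a gene's variants
#'
#' Collapses a gene's rare variants at the allele level: the aggregated
#' allele count is the sum of per-variant alt counts, against the single
#' population allele number as denominator (when per-site ANs vary, the
#' largest — the cohort-wide AN — is used).
#'
#' @param variants A variant table holding one gene's variants (an error is
#'   raised if a `gene_symbol` column is present with more than one value).
#' @param population Population code, or `"COHORT"` for the cohort columns.
#' @return One-row tibble with `agg_ac`, `agg_an`, `agg_af`.
#' @examples
#' tab <- read_variant_table(system.file("extdata", "otog_fmd_variants.tsv",
#'                                       package = "varburden"))
#' aggregate_af(filter_rare_missense(tab), "COHORT") # 22 / 200
#' @export
aggregate_af <- function(variants, population) {
  if ("gene_symbol" %in% names(variants) &&
      dplyr::n_distinct(variants$gene_symbol) > 1) {
    abort_varburden("variants span more than one gene; aggregate per gene",
                    class = "varburden_validation_error")
  }
  if (identical(population, "COHORT")) {
    ac <- variants$cohort_ac
    an <- variants$cohort_an
  } else {
    ac <- variants[[paste0("AC_", population)]]
    an <- variants[[paste0("AN_", population)]]
  }
  if (is.null(ac)) {
    abort_varburden(sprintf("population %s absent from the variant table",
                            population),
                    class = "varburden_validation_error")
  }
  agg_an <- if (length(an) == 0) NA_integer_ else max(an, na.rm = TRUE)
  tibble::tibble(
    agg_ac = sum(ac, na.rm = TRUE),
    agg_an = agg_an,
    agg_af = if (length(ac) == 0) 0 else sum(ac, na.rm = TRUE) / agg_an
  )
}

#' Gene-level burden odds ratio against reference populations
#'
#' Contrasts the cohort's aggregated allele frequency for a gene against the
#' aggregated frequency in each reference population, as a 2x2 allele-count
#' odds ratio with confidence interval and Fisher exact p. As for per-variant
#' enrichment, the point OR is computed on the frequency scale (the odds
#' ratio of the aggregated frequencies) while the exact test uses
#' nearest-integer counts. Benjamini-Hochberg q-values are computed across
#' the populations tested.
#'
#' @param cohort A `cohort_table` (see [filter_rare_missense()]) carrying
#'   both the cohort counts and the per-population columns.
#' @param populations Population codes to test against; default all
#'   populations on the table.
#' @param ci_method,level,zero_policy Passed to [or_ci()] / [sample_or()].
#' @return A `gene_burden` tibble: one row per population with
#'   `cohort_agg_ac`, `cohort_an`, `pop_agg_af`, `or_point`, `ci_low`,
#'   `ci_high`, `p_value`, `q_value`.
#' @examples
#' tab <- read_variant_table(system.file("extdata", "otog_fmd_variants.tsv",
#'                                       package = "varburden"))
#' gene_burden(filter_rare_missense(tab), populations = c("NFE", "GLOBAL"))
#' @export
gene_burden <- function(cohort, populations = NULL,
                        ci_method = c("woolf", "exact"), level = 0.95,
                        zero_policy = c("none", "haldane")) {
  ci_method <- match.arg(ci_method)
  zero_policy <- match.arg(zero_policy)
  if (is.null(populations)) populations <- table_populations(cohort)
  if (!all(c("cohort_ac", "cohort_an") %in% names(cohort))) {
    abort_varburden("cohort table lacks cohort_ac/cohort_an columns",
                    class = "varburden_validation_error")
  }
  coh <- aggregate_af(cohort, "COHORT")
  rows <- purrr::map(populations, function(pop) {
    ref <- aggregate_af(cohort, pop)
    # frequency-scale cells for the point OR
    fa <- coh$agg_ac; fb <- coh$agg_an - coh$agg_ac
    fc <- ref$agg_af * ref$agg_an; fd <- ref$agg_an - fc
    # integer cells for the exact test
    ia <- round(coh$agg_ac); ic <- round(fc)
    ci <- or_ci(ia, coh$agg_an - ia, ic, ref$agg_an - ic,
                level = level, method = ci_method)
    tibble::tibble(
      gene_symbol = if ("gene_symbol" %in% names(cohort) && nrow(cohort) > 0)
        cohort$gene_symbol[1] else NA_character_,
      population = pop,
      cohort_agg_ac = coh$agg_ac,
      cohort_an = coh$agg_an,
      pop_agg_af = ref$agg_af,
      or_point = sample_or(fa, fb, fc, fd, zero_policy = zero_policy),
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      p_value = fisher_exact_p(ia, coh$agg_an - ia, ic, ref$agg_an - ic)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- fdr_adjust(out$p_value)
  structure(out, class = c("gene_burden", class(tibble::tibble())))
}

#' Select CDS-length-matched control genes
#'
#' Keeps candidate genes whose CDS length is within `tolerance` bp of the
#' focal gene's, sorted by absolute length difference and then by symbol.
#'
#' @param candidates Tibble of candidate genes with `gene_symbol` and
#'   `cds_length` columns (see [read_control_table()]).
#' @param focal_length Focal gene CDS length in bp.
#' @param tolerance Maximum absolute CDS-length difference in bp
#'   (default 439, about a five-percent band around an 8778-bp CDS).
#' @return The filtered, sorted candidate tibble.
#' @export
select_controls <- function(candidates, focal_length, tolerance = 439) {
  if (tolerance < 0) {
    abort_varburden("`tolerance` must be >= 0",
                    class = "varburden_validation_error")
  }
  d <- abs(candidates$cds_length - focal_length)
  out <- candidates[d <= tolerance, , drop = FALSE]
  out[order(abs(out$cds_length - focal_length), out$gene_symbol), ,
      drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests
#' (a thin wrapper over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort_varburden("p-values must be in [0, 1]",
                    class = "varburden_validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Percentile rank of a focal gene's variant count in a control panel
#'
#' Midrank percentile of the focal count among the panel plus the focal gene
#' itself: `100 * (n_below + 0.5 * n_ties) / (n_panel + 1)`, where ties are
#' counted among the panel genes.
#'
#' @param controls Control-gene tibble with `count_<POP>` columns, or a bare
#'   numeric vector of counts (then `population` is only a label).
#' @param focal_count Focal gene's rare missense variant count (a single
#'   number, or a named vector/list keyed by population).
#' @param populations Population codes to rank in; default every `count_`
#'   column present (ignored for a bare numeric panel).
#' @return Tibble with `population`, `variant_count`, `percentile`.
#' @examples
#' percentile_rank(1:64, 15)  # about the 22nd percentile
#' @export
percentile_rank <- function(controls, focal_count, populations = NULL) {
  rank_one <- function(counts, focal, pop) {
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0) {
      abort_varburden("control panel is empty",
                      class = "varburden_validation_error")
    }
    tibble::tibble(
      population = pop,
      variant_count = as.integer(focal),
      percentile = 100 * (sum(counts < focal) + 0.5 * sum(counts == focal)) /
        (length(counts) + 1)
    )
  }
  if (is.numeric(controls) && is.null(dim(controls))) {
    return(rank_one(controls, focal_count, populations %||% NA_character_))
  }
  if (is.null(populations)) {
    populations <- sub("^count_", "", grep("^count_", names(controls),
                                           value = TRUE))
  }
  focal <- if (length(focal_count) == 1 && is.null(names(focal_count))) {
    stats::setNames(rep(focal_count, length(populations)), populations)
  } else unlist(focal_count)
  dplyr::bind_rows(purrr::map(populations, function(p) {
    rank_one(controls[[paste0("count_", p)]], focal[[p]], p)
  }))
}
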