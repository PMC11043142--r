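#' Allele-count 2x2 table
#'
#' Builds the contingency table contrasting alternate-allele counts in two
#' groups: `a` alt and `b` ref alleles in group 1, `c` alt and `d` ref in
#' group 2.
#'
#' @param ac1,an1 Alt allele count and allele number in group 1.
#' @param ac2,an2 Alt allele count and allele number in group 2.
#' @return A tibble with columns `a`, `b`, `c`, `d` (vectorised over inputs).
#' @examples
#' two_by_two(152, 113770, 2, 16256)
#' @export
two_by_two <- function(ac1, an1, ac2, an2) {
  if (any(an1 <= 0) || any(an2 <= 0)) {
    abort_varburden("allele numbers must be > 0",
                    class = "varburden_validation_error")
  }
  if (any(ac1 < 0) || any(ac2 < 0) || any(ac1 > an1) || any(ac2 > an2)) {
    abort_varburden("allele counts must satisfy 0 <= AC <= AN",
                    class = "varburden_validation_error")
  }
  tibble::tibble(a = ac1, b = an1 - ac1, c = ac2, d = an2 - ac2)
}

#' Per-variant 2x2 tables between two populations
#'
#' For each variant, contrasts alt/ref allele counts in `pop1` against
#' `pop2`. With `scale = "counts"` the cells are nearest-integer allele
#' counts (`round(AF * AN)` when only a frequency is known) — the form the
#' exact test needs. With `scale = "frequency"` the cells are the unrounded
#' `AF * AN`, which leaves the cross-product odds ratio equal to the odds
#' ratio of the frequencies themselves; this is the default for point
#' estimation because printed gnomAD frequencies are rounded to three
#' significant digits and rounding the counts first can distort the OR badly
#' at small counts.
#'
#' @param variants A variant table.
#' @param pop1,pop2 Population codes; `"COHORT"` uses `cohort_ac`/`cohort_an`.
#' @param scale `"frequency"` (default) or `"counts"`.
#' @return Tibble with `variant_id`, `a`, `b`, `c`, `d`.
#' @export
build_table <- function(variants, pop1, pop2,
                        scale = c("frequency", "counts")) {
  scale <- match.arg(scale)
  side <- function(pop) {
    if (identical(pop, "COHORT")) {
      list(ac = variants$cohort_ac, an = variants$cohort_an,
           af = variants$cohort_ac / variants$cohort_an)
    } else {
      list(ac = variants[[paste0("AC_", pop)]],
           an = variants[[paste0("AN_", pop)]],
           af = variants[[paste0("AF_", pop)]])
    }
  }
  s1 <- side(pop1); s2 <- side(pop2)
  if (is.null(s1$ac) || is.null(s2$ac)) {
    abort_varburden(sprintf("population(s) %s absent from the variant table",
                            paste(setdiff(c(pop1, pop2),
                                          table_populations(variants)),
                                  collapse = ", ")),
                    class = "varburden_validation_error")
  }
  cells <- if (scale == "counts") {
    two_by_two(s1$ac, s1$an, s2$ac, s2$an)
  } else {
    two_by_two(s1$af * s1$an, s1$an, s2$af * s2$an, s2$an)
  }
  dplyr::bind_cols(tibble::tibble(variant_id = variant_ids(variants)), cells)
}

variant_ids <- function(variants) {
  sprintf("%s:g.%d%s>%s", variants$contig, as.integer(variants$pos),
          variants$ref, variants$alt)
}

#' Sample (cross-product) odds ratio
#'
#' `(a d) / (b c)`. With `zero_policy = "none"` a zero `c` gives `Inf` and a
#' zero `a` gives 0 (both zero gives `NA`); with `"haldane"` 0.5 is added to
#' every cell of tables containing a zero before the cross-product.
#'
#' @param a,b,c,d Table cells (vectorised; non-negative, need not be integer).
#' @param zero_policy `"none"` (default) or `"haldane"`.
#' @return Numeric vector of odds ratios.
#' @examples
#' sample_or(40, 60, 10, 90) # 6
#' @export
sample_or <- function(a, b, c, d, zero_policy = c("none", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  if (zero_policy == "haldane") {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  num <- a * d
  den <- b * c
  out <- num / den
  out[num == 0 & den == 0] <- NA_real_
  out[num > 0 & den == 0] <- Inf
  out[num == 0 & den > 0] <- 0
  out
}

#' Confidence interval for an odds ratio
#'
#' `method = "woolf"`: the log-OR normal interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, computed on the
#' Haldane-corrected table whenever a cell is zero. `method = "exact"`: the
#' conditional (noncentral hypergeometric) interval that inverts the exact
#' test, via [stats::fisher.test()]; cells must be integers. A degenerate
#' table (an empty alt or ref margin) yields an `NA` interval rather than an
#' error.
#'
#' @inheritParams sample_or
#' @param level Confidence level in (0, 1), default 0.95.
#' @param method `"woolf"` or `"exact"`.
#' @return Tibble with columns `ci_low`, `ci_high` (vectorised over rows).
#' @export
or_ci <- function(a, b, c, d, level = 0.95, method = c("woolf", "exact")) {
  method <- match.arg(method)
  check_fraction(level, "level", closed_one = FALSE)
  degen <- (a + c) == 0 | (b + d) == 0
  if (method == "woolf") {
    z0 <- a == 0 | b == 0 | c == 0 | d == 0
    aa <- a + 0.5 * z0; bb <- b + 0.5 * z0; cc <- c + 0.5 * z0; dd <- d + 0.5 * z0
    zq <- stats::qnorm(1 - (1 - level) / 2)
    lor <- log(aa * dd / (bb * cc))
    se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
    out <- tibble::tibble(ci_low = exp(lor - zq * se),
                          ci_high = exp(lor + zq * se))
  } else {
    ints <- cbind(a, b, c, d)
    if (any(ints != round(ints))) {
      abort_varburden("exact CI requires integer cells",
                      class = "varburden_validation_error")
    }
    ci <- t(vapply(seq_along(a), function(i) {
      if (degen[i]) return(c(NA_real_, NA_real_))
      ft <- stats::fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2,
                                      byrow = TRUE), conf.level = level)
      ft$conf.int
    }, numeric(2)))
    out <- tibble::tibble(ci_low = ci[, 1], ci_high = ci[, 2])
  }
  out$ci_low[degen] <- NA_real_
  out$ci_high[degen] <- NA_real_
  out
}

#' Two-sided Fisher exact p-value
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables no more likely than the observed one (the minimum-likelihood rule,
#' the same convention as [stats::fisher.test()]).
#'
#' @inheritParams sample_or
#' @return Numeric vector of p-values in \[0, 1\] (vectorised over rows).
#' @examples
#' fisher_exact_p(5, 195, 2, 198)
#' @export
fisher_exact_p <- function(a, b, c, d) {
  ints <- cbind(a, b, c, d)
  if (any(ints < 0) || any(ints != round(ints))) {
    abort_varburden("exact test requires non-negative integer cells",
                    class = "varburden_validation_error")
  }
  vapply(seq_along(a), function(i) {
    m <- a[i] + b[i]          # group-1 margin
    n <- c[i] + d[i]          # group-2 margin
    k <- a[i] + c[i]          # alt-allele margin
    if (m == 0 || n == 0) return(1)
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    p_obs <- stats::dhyper(a[i], m, n, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Flag enrichment and depletion
#'
#' A comparison is enriched in population 1 when `or_point >= 1` and
#' `p_value < alpha`; symmetrically depleted when `or_point < 1` and
#' `p_value < alpha`.
#'
#' @param results Tibble with columns `or_point` and `p_value`.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return `results` with logical columns `enriched` and `depleted` set.
#' @export
classify_enrichment <- function(results, alpha = 0.05) {
  check_fraction(alpha, "alpha", closed_one = FALSE)
  dplyr::mutate(
    results,
    enriched = !is.na(.data$or_point) & !is.na(.data$p_value) &
      .data$or_point >= 1 & .data$p_value < alpha,
    depleted = !is.na(.data$or_point) & !is.na(.data$p_value) &
      .data$or_point < 1 & .data$p_value < alpha
  )
}

#' Per-variant cross-population enrichment
#'
#' For every variant and every `pop1` vs `pop2` comparison, reconstructs the
#' allele-count 2x2 table, computes the sample odds ratio (on the frequency
#' scale by default, see [build_table()]), a confidence interval, the
#' two-sided Fisher exact p-value (always on integer counts), and flags
#' enrichment/depletion. The odds ratio is always oriented as population-1
#' odds over population-2 odds.
#'
#' @param variants A variant table (or `cohort_table`).
#' @param pop1 Population code(s) for the numerator side, default `"NFE"`.
#' @param pop2 Population code(s) for the denominator side; default all other
#'   populations on the table (excluding `GLOBAL`).
#' @param alpha Significance level for the enrichment call.
#' @param ci_method `"woolf"` (default) or `"exact"`.
#' @param level Confidence level, default 0.95.
#' @param zero_policy Zero-cell policy for the point OR, see [sample_or()].
#' @param or_scale `"frequency"` (default) or `"counts"`, see [build_table()].
#' @param adjust If `TRUE`, adds Benjamini-Hochberg `q_value` across all
#'   comparisons. Raw p-values are reported either way.
#' @return An `enrich_result` tibble, one row per variant x comparison, with
#'   columns `variant_id`, `pop1`, `pop2`, `af1`, `af2`, `a`:`d`, `or_point`,
#'   `ci_low`, `ci_high`, `p_value`, `method_ci`, `enriched`, `depleted`.
#' @examples
#' tab <- read_variant_table(system.file("extdata", "otog_fmd_variants.tsv",
#'                                       package = "varburden"))
#' enr <- enrich_variants(tab, pop1 = "NFE", pop2 = c("AFR", "SAS"))
#' dplyr::filter(enr, enriched)
#' @export
enrich_variants <- function(variants, pop1 = "NFE", pop2 = NULL,
                            alpha = 0.05, ci_method = c("woolf", "exact"),
                            level = 0.95,
                            zero_policy = c("none", "haldane"),
                            or_scale = c("frequency", "counts"),
                            adjust = FALSE) {
  ci_method <- match.arg(ci_method)
  zero_policy <- match.arg(zero_policy)
  or_scale <- match.arg(or_scale)
  pops <- table_populations(variants)
  if (is.null(pop2)) pop2 <- setdiff(pops, c(pop1, "GLOBAL"))
  pairs <- tidyr::expand_grid(pop1 = pop1, pop2 = pop2)
  pairs <- pairs[pairs$pop1 != pairs$pop2, , drop = FALSE]
  res <- purrr::pmap(pairs, function(pop1, pop2) {
    freq <- build_table(variants, pop1, pop2, scale = or_scale)
    cnts <- build_table(variants, pop1, pop2, scale = "counts")
    ci <- or_ci(cnts$a, cnts$b, cnts$c, cnts$d, level = level,
                method = ci_method)
    tibble::tibble(
      variant_id = freq$variant_id,
      pop1 = pop1, pop2 = pop2,
      af1 = freq$a / (freq$a + freq$b),
      af2 = freq$c / (freq$c + freq$d),
      a = cnts$a, b = cnts$b, c = cnts$c, d = cnts$d,
      or_point = sample_or(freq$a, freq$b, freq$c, freq$d,
                           zero_policy = zero_policy),
      ci_low = ci$ci_low, ci_high = ci$ci_high,
      p_value = fisher_exact_p(cnts$a, cnts$b, cnts$c, cnts$d),
      method_ci = ci_method
    )
  })
  out <- classify_enrichment(dplyr::bind_rows(res), alpha = alpha)
  if (adjust) out$q_value <- fdr_adjust(out$p_value)
  structure(out, class = c("enrich_result", class(out)),
            alpha = alpha)
}

#' Summarise an enrichment result set
#'
#' @param x An `enrich_result` tibble from [enrich_variants()].
#' @param ... Unused.
#' @return One-row tibble: comparisons, variants, enriched and depleted
#'   counts, and the number of distinct variants enriched in population 1 in
#'   at least one comparison.
#' @export
glance.enrich_result <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x),
    n_variants = dplyr::n_distinct(x$variant_id),
    n_enriched = sum(x$enriched, na.rm = TRUE),
    n_depleted = sum(x$depleted, na.rm = TRUE),
    n_variants_enriched = dplyr::n_distinct(x$variant_id[x$enriched])
  )
}
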