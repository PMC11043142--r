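#' Sliding-window variant density along a CDS
#'
#' For every evaluated CDS position `i`, counts the distinct variant sites
#' with a non-zero allele count in the chosen population inside the window
#' `[i - halfwidth, i + halfwidth]` (201 bp at the default halfwidth of 100),
#' clipped to `[1, cds_length]`, and divides by the clipped window length.
#' Clipping keeps densities at the CDS termini comparable with interior
#' positions instead of spuriously low. Each distinct site counts once
#' regardless of its frequency.
#'
#' @param variants Variant table with a `cds_pos` column (1-based position in
#'   concatenated CDS space; introns are invisible to the window).
#' @param cds_length CDS length in bp.
#' @param population Population code: only sites with `AC_<population> > 0`
#'   are counted. `NULL` counts every row.
#' @param halfwidth Window half-width in bp (default 100, i.e. 201-bp
#'   windows).
#' @param step Step between evaluated positions in bp (default 1).
#' @return A `density_profile`: tibble with `cds_pos` and `density`
#'   (variants/bp) and attributes `population`, `cds_length`, `halfwidth`,
#'   `step`, `threshold` (NA until set).
#' @seealso [population_threshold()], [call_regions()]
#' @export
density_profile <- function(variants, cds_length, population = NULL,
                            halfwidth = 100, step = 1) {
  if (halfwidth < 1 || step < 1) {
    abort_varburden("`halfwidth` and `step` must be >= 1",
                    class = "varburden_validation_error")
  }
  if (nrow(variants) > 0) {
    no_pos <- is.na(variants$cds_pos %||% rep(NA, nrow(variants)))
    if (any(no_pos)) {
      abort_varburden(sprintf(
        "variant(s) lacking cds_pos: %s",
        paste(variant_ids(variants[no_pos, , drop = FALSE]), collapse = ", ")
      ), class = "varburden_validation_error")
    }
  }
  pos <- variants$cds_pos
  if (!is.null(population) && nrow(variants) > 0) {
    ac <- variants[[paste0("AC_", population)]]
    if (is.null(ac)) {
      abort_varburden(sprintf("population %s absent from the variant table",
                              population),
                      class = "varburden_validation_error")
    }
    pos <- pos[!is.na(ac) & ac > 0]
  }
  pos <- unique(pos)
  if (length(pos) > 0 && (any(pos < 1) || any(pos > cds_length))) {
    abort_varburden("cds_pos outside [1, cds_length]",
                    class = "varburden_validation_error")
  }
  i <- seq.int(1L, cds_length, by = step)
  counts <- cumsum(tabulate(pos, nbins = cds_length))
  lo <- pmax(1L, i - halfwidth)
  hi <- pmin(cds_length, i + halfwidth)
  n_in <- counts[hi] - c(0L, counts)[lo]
  len <- hi - lo + 1L
  structure(
    tibble::tibble(cds_pos = i, density = n_in / len),
    class = c("density_profile", class(tibble::tibble())),
    population = population %||% NA_character_,
    cds_length = as.integer(cds_length),
    halfwidth = as.integer(halfwidth),
    step = as.integer(step),
    threshold = NA_real_
  )
}

#' Population-scaled expected-density threshold
#'
#' The density threshold separating low- from high-density windows:
#' the gene's expected missense-variant count scaled to the population, per
#' CDS base pair — `expected_total * scale / cds_length`.
#'
#' @param expected_total Expected missense variant count for the whole gene
#'   in the overall (global) population; must be positive.
#' @param cds_length CDS length in bp.
#' @param scale Population scale in (0, 1]; 1 for the global population. See
#'   [population_scales()].
#' @return Threshold in variants/bp.
#' @examples
#' population_threshold(400, 8778, scale = 0.5)  # 200/8778
#' @export
population_threshold <- function(expected_total, cds_length, scale = 1) {
  if (!is.numeric(expected_total) || expected_total <= 0) {
    abort_varburden("`expected_total` must be > 0",
                    class = "varburden_validation_error")
  }
  check_fraction(scale, "scale")
  expected_total * scale / cds_length
}

#' Per-population expected-count scales
#'
#' How much of the overall expected variant count to attribute to each
#' population, as a direct proportion. Two readings are offered:
#' `"an_share"` (default) scales by the population's share of the total
#' allele number, `"count_share"` by its share of distinct observed variant
#' sites (which then needs `variants`). The global population always gets
#' scale 1.
#'
#' @param panel Population panel.
#' @param method `"an_share"` or `"count_share"`.
#' @param variants Variant table, required for `"count_share"`.
#' @param global Code of the all-population label (default `"GLOBAL"`).
#' @return Named numeric vector of scales in (0, 1], one per panel code.
#' @export
population_scales <- function(panel, method = c("an_share", "count_share"),
                              variants = NULL, global = "GLOBAL") {
  method <- match.arg(method)
  if (method == "an_share") {
    tot <- if (global %in% panel$code) panel$an[panel$code == global] else
      sum(panel$an)
    s <- panel$an / tot
  } else {
    if (is.null(variants)) {
      abort_varburden("`variants` required for count_share scales",
                      class = "varburden_validation_error")
    }
    n_sites <- vapply(panel$code, function(p) {
      ac <- variants[[paste0("AC_", p)]]
      if (is.null(ac)) return(NA_real_)
      length(unique(variants$cds_pos[!is.na(ac) & ac > 0]))
    }, numeric(1))
    tot <- if (global %in% panel$code) n_sites[panel$code == global] else
      max(n_sites, na.rm = TRUE)
    s <- n_sites / tot
  }
  s[panel$code == global] <- 1
  stats::setNames(pmin(s, 1), panel$code)
}

#' Call low- and high-density regions
#'
#' Labels every profiled position LDR (density strictly below the threshold;
#' the constrained state) or HDR, then merges identical consecutive labels
#' into maximal runs. The returned regions partition `[0, cds_length)` in
#' BED-style 0-based half-open coordinates, with adjacent regions always
#' differing in label.
#'
#' @param profile A `density_profile` with `step = 1`.
#' @param threshold Density threshold in variants/bp (see
#'   [population_threshold()]).
#' @return A `region_set`: tibble with `start`, `end`, `label` and
#'   `mean_density`, plus `population` and `cds_length` attributes.
#' @export
call_regions <- function(profile, threshold) {
  if (attr(profile, "step") != 1L) {
    abort_varburden("region calling requires a step-1 profile",
                    class = "varburden_validation_error")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort_varburden("`threshold` must be a single finite number",
                    class = "varburden_validation_error")
  }
  lab <- ifelse(profile$density < threshold, "LDR", "HDR")
  r <- rle(lab)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  mean_d <- vapply(seq_along(start), function(k) {
    mean(profile$density[(start[k] + 1L):end[k]])
  }, numeric(1))
  structure(
    tibble::tibble(start = as.integer(start), end = as.integer(end),
                   label = r$values, mean_density = mean_d),
    class = c("region_set", class(tibble::tibble())),
    population = attr(profile, "population"),
    cds_length = attr(profile, "cds_length"),
    threshold = threshold
  )
}

#' Label variants by the density region containing them
#'
#' @param regions A `region_set` from [call_regions()].
#' @param cds_pos 1-based CDS position(s) of the variant(s).
#' @return Character vector of `"LDR"`/`"HDR"` labels.
#' @export
annotate_variant_region <- function(regions, cds_pos) {
  L <- attr(regions, "cds_length")
  if (any(cds_pos < 1 | cds_pos > L)) {
    abort_varburden(sprintf("cds_pos outside the CDS [1, %d]", L),
                    class = "varburden_validation_error")
  }
  # position p (1-based) falls in the region with start < p <= end
  idx <- findInterval(cds_pos - 1L, regions$start)
  regions$label[idx]
}

#' Position-wise similarity of two region labelings
#'
#' The percentage of CDS positions whose LDR/HDR label agrees between two
#' region sets over the same CDS. Symmetric; 100 on self.
#'
#' @param a,b `region_set` objects with equal `cds_length`.
#' @return Similarity percentage in \[0, 100\].
#' @export
profile_similarity <- function(a, b) {
  La <- attr(a, "cds_length"); Lb <- attr(b, "cds_length")
  if (!identical(La, Lb)) {
    abort_varburden("region sets cover CDSs of different lengths",
                    class = "varburden_validation_error")
  }
  expand <- function(r) rep(r$label, r$end - r$start)
  100 * mean(expand(a) == expand(b))
}

#' Set the threshold and labels on a density profile
#'
#' Convenience: stores the threshold and adds a per-position `label` column
#' (`LDR` where density < threshold).
#'
#' @param profile A `density_profile`.
#' @param threshold Density threshold in variants/bp.
#' @return The profile with a `label` column and its `threshold` attribute
#'   set.
#' @export
set_threshold <- function(profile, threshold) {
  out <- dplyr::mutate(profile,
                       label = ifelse(.data$density < threshold, "LDR", "HDR"))
  attrs <- attributes(profile)
  for (nm in c("population", "cds_length", "halfwidth", "step")) {
    attr(out, nm) <- attrs[[nm]]
  }
  attr(out, "threshold") <- threshold
  class(out) <- class(profile)
  out
}

#' Summarise a density profile
#'
#' @param x A `density_profile`.
#' @param ... Unused.
#' @return One-row tibble: population, CDS length, window width, threshold
#'   (if set), mean density, and the LDR fraction of positions (if a
#'   threshold is set).
#' @export
glance.density_profile <- function(x, ...) {
  thr <- attr(x, "threshold")
  tibble::tibble(
    population = attr(x, "population"),
    cds_length = attr(x, "cds_length"),
    window = 2L * attr(x, "halfwidth") + 1L,
    threshold = thr,
    mean_density = mean(x$density),
    ldr_fraction = if (is.na(thr)) NA_real_ else mean(x$density < thr)
  )
}

#' Regions of a thresholded density profile
#'
#' @param x A `density_profile` whose threshold has been set (see
#'   [set_threshold()]), or any profile with `threshold` supplied.
#' @param threshold Optional threshold override.
#' @param ... Unused.
#' @return The `region_set` tibble from [call_regions()].
#' @export
tidy.density_profile <- function(x, threshold = NULL, ...) {
  thr <- threshold %||% attr(x, "threshold")
  if (is.null(thr) || is.na(thr)) {
    abort_varburden("no threshold set on this profile",
                    class = "varburden_validation_error")
  }
  call_regions(x, thr)
}
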