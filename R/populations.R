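#' Define a population panel
#'
#' A population panel records, for each population, its label and diploid
#' sample size. The allele number (AN) used to reconstruct allele counts from
#' frequencies is `2 * n_individuals` unless a per-site AN override is carried
#' on the variant table.
#'
#' @param code Character vector of population codes (e.g. `"NFE"`, `"AFR"`).
#'   Codes must be unique.
#' @param n_individuals Positive integer vector of diploid sample sizes,
#'   recycled against `code`.
#' @return A tibble with columns `code`, `n_individuals`, `an`.
#' @examples
#' population_panel(c("NFE", "AFR"), c(56885, 8128))
#' @export
population_panel <- function(code, n_individuals) {
  if (anyDuplicated(code)) {
    abort_varburden("population codes must be unique",
                    class = "varburden_validation_error")
  }
  if (any(!is.finite(n_individuals)) || any(n_individuals <= 0) ||
      any(n_individuals != round(n_individuals))) {
    abort_varburden("`n_individuals` must be positive integers",
                    class = "varburden_validation_error")
  }
  tibble::tibble(
    code = as.character(code),
    n_individuals = as.integer(n_individuals),
    an = 2L * as.integer(n_individuals)
  )
}

#' gnomAD v2.1 exome population panel
#'
#' The default reference panel: non-Finnish European (NFE), African/African
#' American (AFR), East Asian (EAS), South Asian (SAS), Latino/Admixed
#' American (AMR) and the global (all-population) totals, with the gnomAD
#' v2.1 exome diploid sample sizes.
#'
#' @return A tibble as produced by [population_panel()].
#' @examples
#' gnomad_panel()
#' @export
gnomad_panel <- function() {
  population_panel(
    code = c("NFE", "AFR", "EAS", "SAS", "AMR", "GLOBAL"),
    n_individuals = c(56885L, 8128L, 9197L, 15308L, 17296L, 125748L)
  )
}

panel_an <- function(panel, pop) {
  i <- match(pop, panel$code)
  if (anyNA(i)) {
    abort_varburden(sprintf(
      "unknown population code(s) %s; known codes: %s",
      paste(unique(pop[is.na(i)]), collapse = ", "),
      paste(panel$code, collapse = ", ")
    ), class = "varburden_validation_error")
  }
  panel$an[i]
}
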