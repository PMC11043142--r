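#' Pairwise r-squared from phased haplotypes
#'
#' With haplotype frequencies `p_AB` and allele frequencies `p_A`, `p_B`,
#' `D = p_AB - p_A p_B` and `r2 = D^2 / (p_A q_A p_B q_B)`. A site that is
#' monomorphic in the sample makes r2 undefined; `NA` is returned (never 0).
#'
#' @param h1,h2 Binary haplotype vectors (one entry per haplotype, >= 2).
#' @return r-squared in \[0, 1\], or `NA` for a monomorphic site.
#' @examples
#' r2_phased(rep(c(1, 0), 50), rep(c(1, 0), 50))  # 1
#' @export
r2_phased <- function(h1, h2) {
  stopifnot(length(h1) == length(h2), length(h1) >= 2)
  pa <- mean(h1)
  pb <- mean(h2)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(h1 * h2) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Pairwise r-squared from unphased genotypes via EM
#'
#' Resolves the phase ambiguity of double heterozygotes by
#' expectation-maximisation over the four haplotype frequencies,
#' initialised at linkage equilibrium, then plugs the converged frequencies
#' into the phased r2 formula. When the sample contains no double
#' heterozygotes the phase is unambiguous and the estimate equals
#' [r2_phased()] on the implied haplotypes.
#'
#' @param g1,g2 Diploid dosage vectors in `{0, 1, 2}`, no missing values.
#' @param tol Convergence threshold on the largest haplotype-frequency
#'   change per iteration (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return r-squared in \[0, 1\], or `NA` for a monomorphic site.
#' @export
r2_unphased_em <- function(g1, g2, tol = 1e-10, max_iter = 1000) {
  stopifnot(length(g1) == length(g2))
  if (anyNA(g1) || anyNA(g2)) {
    abort_varburden("missing dosages are not supported",
                    class = "varburden_validation_error")
  }
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    abort_varburden("dosages must be 0, 1 or 2",
                    class = "varburden_validation_error")
  }
  n <- length(g1)
  pa <- mean(g1) / 2
  pb <- mean(g2) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  # phase-known haplotype counts; (1,1) individuals are ambiguous
  cnt <- function(cond1, cond2) sum(cond1 & cond2)
  dh <- sum(g1 == 1 & g2 == 1)
  k11 <- 2 * cnt(g1 == 2, g2 == 2) + cnt(g1 == 2, g2 == 1) +
    cnt(g1 == 1, g2 == 2)
  k10 <- 2 * cnt(g1 == 2, g2 == 0) + cnt(g1 == 2, g2 == 1) +
    cnt(g1 == 1, g2 == 0)
  k01 <- 2 * cnt(g1 == 0, g2 == 2) + cnt(g1 == 0, g2 == 1) +
    cnt(g1 == 1, g2 == 2)
  k00 <- 2 * cnt(g1 == 0, g2 == 0) + cnt(g1 == 0, g2 == 1) +
    cnt(g1 == 1, g2 == 0)
  tot <- 2 * n
  f <- c(p11 = pa * pb, p10 = pa * (1 - pb), p01 = (1 - pa) * pb,
         p00 = (1 - pa) * (1 - pb))
  converged <- FALSE
  delta <- NA_real_
  for (it in seq_len(max_iter)) {
    cis <- f[["p11"]] * f[["p00"]]       # coupling: AB/ab
    trans <- f[["p10"]] * f[["p01"]]     # repulsion: Ab/aB
    w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    new <- c(p11 = (k11 + dh * w) / tot,
             p10 = (k10 + dh * (1 - w)) / tot,
             p01 = (k01 + dh * (1 - w)) / tot,
             p00 = (k00 + dh * w) / tot)
    delta <- max(abs(new - f))
    f <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort_varburden(sprintf(
      "EM did not converge in %d iterations (last delta %.3g)",
      max_iter, delta
    ), class = "varburden_convergence_error")
  }
  d <- f[["p11"]] - pa * pb
  unname(d^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Pairwise LD matrix for a genotype set
#'
#' Computes r2 for every variant pair, from phased haplotypes when present
#' and otherwise by EM from the dosages. Pairs involving a monomorphic site
#' are `NA`. The result is symmetric with a unit diagonal.
#'
#' @param genotypes Either a dosage matrix/data frame (individuals x
#'   variants, entries 0/1/2, column names = variant ids) or a list with
#'   elements `dosages` and optionally `phased` (a `2n x variants` binary
#'   haplotype matrix), as produced by [simulate_genotypes()].
#' @param ... Passed to [r2_unphased_em()].
#' @return An `ld_matrix`: list with `r2` (named square matrix), `variants`
#'   and `n` (individuals).
#' @export
ld_matrix <- function(genotypes, ...) {
  phased <- NULL
  if (is.list(genotypes) && !is.data.frame(genotypes) &&
      "dosages" %in% names(genotypes)) {
    phased <- genotypes$phased
    genotypes <- genotypes$dosages
  }
  g <- as.matrix(genotypes)
  if (ncol(g) < 1) {
    abort_varburden("at least one variant required",
                    class = "varburden_validation_error")
  }
  ids <- colnames(g) %||% paste0("v", seq_len(ncol(g)))
  m <- ncol(g)
  r2 <- diag(1, m)
  dimnames(r2) <- list(ids, ids)
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        val <- if (!is.null(phased)) {
          r2_phased(phased[, i], phased[, j])
        } else {
          r2_unphased_em(g[, i], g[, j], ...)
        }
        r2[i, j] <- r2[j, i] <- val
      }
    }
  }
  # a monomorphic site has no defined r2 even with itself
  mono <- apply(g, 2, function(col) length(unique(col)) == 1 &&
                  col[1] %in% c(0, 2))
  diag(r2)[mono] <- NA_real_
  structure(list(r2 = r2, variants = ids, n = nrow(g)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("# ld_matrix: %d variants, %d individuals\n",
              length(x$variants), x$n))
  print(round(x$r2, 4))
  invisible(x)
}

#' Long-format pairs of an LD matrix
#'
#' @param x An `ld_matrix`.
#' @param ... Unused.
#' @return Tibble with `variant1`, `variant2`, `r2` for each unordered pair.
#' @export
tidy.ld_matrix <- function(x, ...) {
  m <- x$r2
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    variant1 = rownames(m)[idx[, 1]],
    variant2 = colnames(m)[idx[, 2]],
    r2 = m[idx]
  )
}

#' Summarise an LD matrix
#'
#' @param x An `ld_matrix`.
#' @param ... Unused.
#' @return One-row tibble: variant and individual counts, mean and maximum
#'   off-diagonal r2, and the number of pairs with r2 >= 0.2 (linked pairs).
#' @export
glance.ld_matrix <- function(x, ...) {
  pairs <- tidy.ld_matrix(x)
  tibble::tibble(
    n_variants = length(x$variants),
    n_individuals = x$n,
    mean_r2 = mean(pairs$r2, na.rm = TRUE),
    max_r2 = if (all(is.na(pairs$r2))) NA_real_ else max(pairs$r2, na.rm = TRUE),
    n_linked = sum(pairs$r2 >= 0.2, na.rm = TRUE)
  )
}

# Largest r2 achievable (with D > 0) for allele frequencies p1, p2.
r2_max_feasible <- function(p1, p2) {
  q1 <- 1 - p1; q2 <- 1 - p2
  min(p1 * q2 / (q1 * p2), q1 * p2 / (p1 * q2))
}
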