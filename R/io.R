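#' Read a per-population variant frequency table
#'
#' Reads variant records either from a tab-separated table or from a
#' sites-only VCF carrying per-population `AF_<POP>` / `AC_<POP>` / `AN_<POP>`
#' INFO keys. One row per biallelic ALT allele is returned; multi-allelic VCF
#' sites are split into biallelic records (`Number=A` fields are expanded).
#'
#' The TSV layout is: `contig`, `pos` (1-based), `ref`, `alt`, `rsid`,
#' `consequence`, `cds_pos`, then `AF_<POP>`, `AC_<POP>`, `AN_<POP>` per
#' population, then `cohort_ac`, `cohort_an`; `"."` marks absent optional
#' values. Missing pieces are back-filled: AC as `round(AF * AN)` (gnomAD
#' frequencies are printed rounded, so the nearest integer is the unique
#' consistent count), AF as `AC / AN`, AN as the panel default `2 * N`.
#' A population in which a variant is absent is stored as AC = 0 with the
#' population AN, not as missing.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param panel Population panel (see [population_panel()]); population codes
#'   found in the file must all be declared here.
#' @return A tibble of variant records, one row per biallelic ALT.
#' @seealso [write_variant_table()], [filter_rare_missense()]
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf"),
                               panel = gnomad_panel()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_varburden(sprintf("file not found: %s", path),
                    class = "varburden_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  x <- switch(format,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  validate_variant_table(x, panel)
}

read_variant_tsv <- function(path) {
  x <- readr::read_tsv(path, na = c("", ".", "NA"), show_col_types = FALSE,
                       progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort_varburden(sprintf(
      "malformed row(s) in %s at line(s) %s",
      path, paste(unique(probs$row + 1L), collapse = ", ")
    ), class = "varburden_io_error")
  }
  required <- c("contig", "pos", "ref", "alt", "consequence")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort_varburden(sprintf("variant table lacks column(s): %s",
                            paste(missing, collapse = ", ")),
                    class = "varburden_io_error")
  }
  bad <- which(is.na(x$pos) | is.na(x$ref) | is.na(x$alt))
  if (length(bad) > 0) {
    abort_varburden(sprintf("malformed row(s): missing pos/ref/alt at line(s) %s",
                            paste(bad + 1L, collapse = ", ")),
                    class = "varburden_io_error")
  }
  tibble::as_tibble(x)
}

read_variant_vcf <- function(path) {
  for (pkg in c("VariantAnnotation", "SummarizedExperiment", "GenomeInfoDb",
                "BiocGenerics")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      abort_varburden(sprintf("package '%s' is required to read VCF", pkg),
                      class = "varburden_io_error")
    }
  }
  vcf <- VariantAnnotation::readVcf(path)
  ids0 <- names(SummarizedExperiment::rowRanges(vcf))
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  vcf <- VariantAnnotation::expand(vcf)  # split multi-allelics (Number=A)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ids <- if (is.null(ids0)) rep(NA_character_, length(rr)) else
    rep(ids0, n_alt)
  ids[!is.na(ids) & (ids == "." | grepl(":", ids))] <- NA_character_
  out <- tibble::tibble(
    contig = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    rsid = ids,
    consequence = if ("CSQ" %in% names(info)) as.character(info$CSQ) else NA_character_,
    cds_pos = if ("CDS_POS" %in% names(info)) as.integer(info$CDS_POS) else NA_integer_
  )
  pops <- unique(sub("^AF_", "", grep("^AF_", names(info), value = TRUE)))
  for (p in pops) {
    af <- info[[paste0("AF_", p)]]
    ac <- info[[paste0("AC_", p)]]
    an <- info[[paste0("AN_", p)]]
    out[[paste0("AF_", p)]] <- if (is.null(af)) NA_real_ else as.numeric(af)
    out[[paste0("AC_", p)]] <- if (is.null(ac)) NA_integer_ else as.integer(ac)
    out[[paste0("AN_", p)]] <- if (is.null(an)) NA_integer_ else as.integer(an)
  }
  if ("COHORT_AC" %in% names(info)) out$cohort_ac <- as.integer(info$COHORT_AC)
  if ("COHORT_AN" %in% names(info)) out$cohort_an <- as.integer(info$COHORT_AN)
  out
}

#' Population codes present on a variant table
#' @param variants A variant table (tibble).
#' @return Character vector of population codes with `AF_`/`AC_` columns.
#' @export
table_populations <- function(variants) {
  unique(sub("^A[FC]_", "", grep("^A[FC]_", names(variants), value = TRUE)))
}

#' Validate and back-fill a variant table
#'
#' Checks positions, allele strings and per-population AF/AC/AN consistency
#' (`AC <= AN`; `|AF - AC/AN|` within the rounding tolerance of a printed
#' frequency), and back-fills whichever of AF/AC/AN is absent. Absence of a
#' variant in a population is stored as AC = 0 at the population AN.
#'
#' @inheritParams read_variant_table
#' @param variants A variant table.
#' @return The validated, back-filled tibble.
#' @export
validate_variant_table <- function(variants, panel = gnomad_panel()) {
  x <- tibble::as_tibble(variants)
  if (nrow(x) == 0) return(x)
  if (any(x$pos <= 0 | x$pos != round(x$pos))) {
    abort_varburden("`pos` must be strictly positive integers",
                    class = "varburden_validation_error")
  }
  if (any(!nzchar(x$ref)) || any(!nzchar(x$alt))) {
    abort_varburden("ref/alt alleles must be non-empty",
                    class = "varburden_validation_error")
  }
  pops <- table_populations(x)
  unknown <- setdiff(pops, panel$code)
  if (length(unknown) > 0) {
    abort_varburden(sprintf(
      "unknown population code(s) %s; known codes: %s",
      paste(unknown, collapse = ", "), paste(panel$code, collapse = ", ")
    ), class = "varburden_validation_error")
  }
  for (p in pops) {
    af_c <- paste0("AF_", p); ac_c <- paste0("AC_", p); an_c <- paste0("AN_", p)
    if (!an_c %in% names(x)) x[[an_c]] <- NA_integer_
    x[[an_c]] <- ifelse(is.na(x[[an_c]]), panel_an(panel, p), x[[an_c]])
    if (any(x[[an_c]] <= 0)) {
      abort_varburden(sprintf("AN_%s must be > 0", p),
                      class = "varburden_validation_error")
    }
    if (!af_c %in% names(x)) x[[af_c]] <- NA_real_
    if (!ac_c %in% names(x)) x[[ac_c]] <- NA_integer_
    # absence in a population means frequency zero, not missing
    both_na <- is.na(x[[af_c]]) & is.na(x[[ac_c]])
    x[[ac_c]][both_na] <- 0L
    x[[ac_c]] <- ifelse(is.na(x[[ac_c]]),
                        as.integer(round(x[[af_c]] * x[[an_c]])), x[[ac_c]])
    x[[af_c]] <- ifelse(is.na(x[[af_c]]), x[[ac_c]] / x[[an_c]], x[[af_c]])
    bad_ac <- which(x[[ac_c]] > x[[an_c]] | x[[ac_c]] < 0)
    if (length(bad_ac) > 0) {
      abort_varburden(sprintf("AC_%s > AN_%s (or negative) at row(s) %s", p, p,
                              paste(bad_ac, collapse = ", ")),
                      class = "varburden_validation_error")
    }
    # tolerance: counting resolution or the half-ulp of a 3-significant-digit
    # printed frequency, whichever is larger
    tol <- pmax(0.5 / x[[an_c]],
                ifelse(x[[af_c]] > 0, 0.5 * 10^(floor(log10(x[[af_c]])) - 2), 0))
    off <- which(abs(x[[af_c]] - x[[ac_c]] / x[[an_c]]) > tol + 1e-12)
    if (length(off) > 0) {
      abort_varburden(sprintf("AF_%s inconsistent with AC_%s/AN_%s at row(s) %s",
                              p, p, p, paste(off, collapse = ", ")),
                      class = "varburden_validation_error")
    }
  }
  if ("cohort_ac" %in% names(x) && "cohort_an" %in% names(x)) {
    bad <- which(!is.na(x$cohort_ac) & !is.na(x$cohort_an) &
                   x$cohort_ac > x$cohort_an)
    if (length(bad) > 0) {
      abort_varburden(sprintf("cohort_ac > cohort_an at row(s) %s",
                              paste(bad, collapse = ", ")),
                      class = "varburden_validation_error")
    }
  }
  x
}

#' Write a variant table to TSV
#'
#' Deterministic tab-separated output using the same column layout
#' [read_variant_table()] consumes; `"."` encodes absent optional values, so
#' a write/read round trip reproduces the table exactly.
#'
#' @param variants A variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Filter to rare missense variants
#'
#' Keeps records whose `consequence` is `"missense"` and whose allele
#' frequency in the reference population is strictly below `af_threshold`
#' (an absent reference frequency counts as zero). Row order is preserved
#' and the operation is idempotent. The result is a cohort table: when
#' `cohort_an` columns are present the proband count is inferred as
#' `cohort_an / 2` (cohort allele number is fixed at two alleles per proband).
#'
#' @param variants A variant table.
#' @param reference Reference population code for the rarity filter
#'   (default `"NFE"`).
#' @param af_threshold Strict upper bound on the reference AF, in (0, 1].
#' @return A `cohort_table`: the filtered tibble with attributes
#'   `reference`, `af_threshold` and `n_probands`.
#' @examples
#' tab <- read_variant_table(system.file("extdata", "otog_fmd_variants.tsv",
#'                                       package = "varburden"))
#' nrow(filter_rare_missense(tab))  # 13
#' @export
filter_rare_missense <- function(variants, reference = "NFE",
                                 af_threshold = 0.01) {
  check_fraction(af_threshold, "af_threshold")
  af_col <- paste0("AF_", reference)
  af <- if (af_col %in% names(variants)) variants[[af_col]] else
    rep(0, nrow(variants))
  af[is.na(af)] <- 0
  keep <- !is.na(variants$consequence) & variants$consequence == "missense" &
    af < af_threshold
  out <- variants[keep, , drop = FALSE]
  n_probands <- if ("cohort_an" %in% names(out) && nrow(out) > 0 &&
                    any(!is.na(out$cohort_an))) {
    as.integer(max(out$cohort_an, na.rm = TRUE) / 2)
  } else NA_integer_
  new_cohort_table(out, reference, af_threshold, n_probands)
}

new_cohort_table <- function(x, reference, af_threshold, n_probands) {
  structure(tibble::as_tibble(x),
            class = c("cohort_table", class(tibble::tibble())),
            reference = reference, af_threshold = af_threshold,
            n_probands = n_probands)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("# cohort_table: %d variants (reference %s, AF < %g%s)\n",
              nrow(x), attr(x, "reference"), attr(x, "af_threshold"),
              if (!is.na(attr(x, "n_probands") %||% NA))
                sprintf(", %d probands", attr(x, "n_probands")) else ""))
  NextMethod()
}

#' Export called density regions as BED6
#'
#' Regions are written 0-based half-open per the BED standard (variant
#' positions elsewhere in the package are 1-based). The score column is the
#' region's mean window density times 1000, clamped to an integer in
#' [0, 1000].
#'
#' @param regions A `region_set` (see [call_regions()]).
#' @param path Output path.
#' @param chrom Chromosome/sequence name for column 1 (default the CDS label).
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path, chrom = "CDS") {
  score <- if ("mean_density" %in% names(regions)) {
    pmin(1000L, pmax(0L, as.integer(round(regions$mean_density * 1000))))
  } else 0L
  bed <- tibble::tibble(
    chrom = chrom,
    start = regions$start,
    end = regions$end,
    name = regions$label,
    score = score,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a control-gene table
#'
#' TSV with columns `gene_symbol`, `transcript_id`, `cds_length`, then one
#' `count_<POP>` column per population holding the gene's rare missense
#' variant count.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_control_table <- function(path) {
  x <- readr::read_tsv(path, na = c("", "."), show_col_types = FALSE,
                       progress = FALSE)
  required <- c("gene_symbol", "cds_length")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort_varburden(sprintf("control table lacks column(s): %s",
                            paste(missing, collapse = ", ")),
                    class = "varburden_io_error")
  }
  cnt <- grep("^count_", names(x), value = TRUE)
  if (any(unlist(x[cnt]) < 0, na.rm = TRUE)) {
    abort_varburden("control counts must be non-negative",
                    class = "varburden_validation_error")
  }
  x
}

#' Write pipeline result tables
#'
#' Writes whichever result tables are supplied as deterministic TSV (and BED
#' for region sets) under `out_dir`, and returns a manifest. Identical inputs
#' produce byte-identical files. Recognised names: `variants`, `cohort`,
#' `enrichment`, `burden`, `density`, `regions`, `ld`, `controls`.
#'
#' @param results Named list of result objects.
#' @param out_dir Output directory (created if absent).
#' @return A tibble manifest with columns `name`, `path`, `md5`.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort_varburden(sprintf("cannot create output directory %s", out_dir),
                      class = "varburden_io_error")
    }
  }
  paths <- character(0)
  put_tsv <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_tsv(tibble::as_tibble(df), p, na = ".", progress = FALSE)
    p
  }
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (is.null(obj)) next
    p <- switch(nm,
      regions = {
        pb <- file.path(out_dir, "regions.bed")
        regions_to_bed(obj, pb)
        pb
      },
      ld = {
        pl <- file.path(out_dir, "ld_matrix.tsv")
        m <- as.data.frame(obj$r2)
        m <- cbind(variant = rownames(obj$r2), m)
        readr::write_tsv(tibble::as_tibble(m), pl, na = "NA", progress = FALSE)
        pl
      },
      put_tsv(obj, paste0(nm, ".tsv"))
    )
    paths[nm] <- p
  }
  tibble::tibble(
    name = names(paths),
    path = unname(paths),
    md5 = unname(tools::md5sum(paths))
  )
}
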