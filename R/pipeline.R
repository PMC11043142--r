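#' Assemble a pipeline configuration
#'
#' Validates a configuration list (or YAML file) for [run_pipeline()].
#' Recognised top-level keys: `seed`, `out_dir`, `stages` (subset of
#' `simulate`, `filter`, `enrich`, `burden`, `density`, `ld`), `inputs`
#' (paths for `variants`, `cohort`, `controls`, `genotypes` when the
#' simulate stage is off), `sim` (arguments for [sim_config()]), `filter`
#' (`reference`, `af_threshold`), `enrich` (`pop1`, `alpha`, `ci_method`,
#' `zero_policy`), `burden` (`populations`, `tolerance`, `focal_length`),
#' `density` (`halfwidth`, `expected_total`, `scale_method`, `populations`),
#' `ld` (`tol`, `max_iter`). Unknown keys are rejected.
#'
#' @param config A named list, or the path of a YAML file encoding one.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "out_dir", "stages", "inputs", "sim", "filter",
             "enrich", "burden", "density", "ld")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort_varburden(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")),
                    class = "varburden_validation_error")
  }
  defaults <- list(
    seed = 1L,
    out_dir = "varburden_run",
    stages = c("simulate", "filter", "enrich", "burden", "density", "ld"),
    inputs = list(),
    sim = list(),
    filter = list(reference = "NFE", af_threshold = 0.01),
    enrich = list(pop1 = "NFE", alpha = 0.05, ci_method = "woolf",
                  zero_policy = "none"),
    burden = list(populations = NULL, tolerance = 439, focal_length = NULL),
    density = list(halfwidth = 100, expected_total = NULL,
                   scale_method = "an_share", populations = NULL),
    ld = list(tol = 1e-10, max_iter = 1000)
  )
  out <- utils::modifyList(defaults, config)
  bad <- setdiff(out$stages, defaults$stages)
  if (length(bad) > 0) {
    abort_varburden(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
                    class = "varburden_validation_error")
  }
  structure(out, class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order — simulate, filter, enrich,
#' burden, density, ld — consuming and producing files under
#' `config$out_dir`, and writes a manifest (parameters, per-stage output
#' paths and md5 checksums). Reruns with an identical configuration are
#' byte-identical. A stage failure aborts the run with the failing stage
#' named, after removing that stage's partial outputs.
#'
#' @param config A [pipeline_config()] (or a list / YAML path coercible to
#'   one).
#' @return The manifest as a list (also serialised to
#'   `out_dir/manifest.json`), with elements `config`, `stages` (per-stage
#'   output files and checksums) and `summary`.
#' @seealso [pipeline_report()]
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(config = unclass(cfg), stages = list(), summary = list())
  paths <- list()

  run_stage <- function(name, files, fn) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    message(sprintf("[varburden] stage %s", name))
    res <- tryCatch(fn(), error = function(e) {
      existing <- files[file.exists(files)]
      if (length(existing) > 0) unlink(existing)
      abort_varburden(sprintf("stage '%s' failed: %s", name,
                              conditionMessage(e)),
                      class = "varburden_pipeline_error")
    })
    manifest$stages[[name]] <<- list(
      outputs = as.list(files),
      md5 = as.list(unname(tools::md5sum(files[file.exists(files)])))
    )
    res
  }

  p <- function(f) file.path(out_dir, f)
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))

  sim_out <- run_stage("simulate",
    c(p("variants.tsv"), p("controls.tsv"), p("genotypes.tsv"),
      p("truth.json")),
    function() {
      ft <- simulate_frequency_table(scfg)
      coh <- simulate_cohort(scfg, ft$variants)
      ctl <- simulate_control_panel(scfg)
      gen <- simulate_genotypes(scfg)
      write_variant_table(coh, p("variants.tsv"))
      readr::write_tsv(ctl, p("controls.tsv"), progress = FALSE)
      geno_df <- tibble::as_tibble(as.data.frame(gen$dosages),
                                   .name_repair = "minimal")
      readr::write_tsv(geno_df, p("genotypes.tsv"), progress = FALSE)
      truth <- ft$truth
      truth$af <- as.data.frame(truth$af)
      truth$ld <- gen$truth
      jsonlite::write_json(truth, p("truth.json"), digits = NA,
                           dataframe = "columns", auto_unbox = TRUE)
      list(genotypes = gen)
    })

  variants_path <- if ("simulate" %in% cfg$stages) p("variants.tsv") else
    cfg$inputs$variants
  cohort <- NULL
  cohort <- run_stage("filter", p("cohort.tsv"), function() {
    vars <- read_variant_table(variants_path,
                               panel = rbind(scfg$panel,
                                             tibble::tibble(code = "GLOBAL",
                                                            n_individuals = sum(scfg$panel$n_individuals),
                                                            an = sum(scfg$panel$an))))
    coh <- filter_rare_missense(vars, reference = cfg$filter$reference,
                                af_threshold = cfg$filter$af_threshold)
    write_variant_table(coh, p("cohort.tsv"))
    manifest$summary$n_variants <<- nrow(coh)
    coh
  })

  load_cohort <- function() {
    if (!is.null(cohort)) return(cohort)
    path <- if (file.exists(p("cohort.tsv"))) p("cohort.tsv") else
      cfg$inputs$cohort %||% variants_path
    tab <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                           progress = FALSE)
    new_cohort_table(tab, cfg$filter$reference, cfg$filter$af_threshold,
                     if ("cohort_an" %in% names(tab))
                       as.integer(max(tab$cohort_an, na.rm = TRUE) / 2)
                     else NA_integer_)
  }

  run_stage("enrich", p("enrichment.tsv"), function() {
    coh <- load_cohort()
    enr <- enrich_variants(coh, pop1 = cfg$enrich$pop1,
                           alpha = cfg$enrich$alpha,
                           ci_method = cfg$enrich$ci_method,
                           zero_policy = cfg$enrich$zero_policy)
    readr::write_tsv(enr, p("enrichment.tsv"), na = ".", progress = FALSE)
    manifest$summary$enriched <<- unname(sum(enr$enriched, na.rm = TRUE))
    invisible(enr)
  })

  run_stage("burden", c(p("burden.tsv"), p("percentile.tsv")), function() {
    coh <- load_cohort()
    bur <- gene_burden(coh)
    readr::write_tsv(bur, p("burden.tsv"), na = ".", progress = FALSE)
    ctl_path <- if (file.exists(p("controls.tsv"))) p("controls.tsv") else
      cfg$inputs$controls
    if (!is.null(ctl_path)) {
      ctl <- read_control_table(ctl_path)
      focal_length <- cfg$burden$focal_length %||% scfg$cds_length
      sel <- select_controls(ctl, focal_length, cfg$burden$tolerance)
      pops <- intersect(sub("^count_", "", grep("^count_", names(sel),
                                                value = TRUE)),
                        table_populations(coh))
      focal_counts <- vapply(pops, function(pp) {
        ac <- coh[[paste0("AC_", pp)]]
        sum(!is.na(ac) & ac > 0)
      }, numeric(1))
      pct <- percentile_rank(sel, as.list(focal_counts), populations = pops)
      readr::write_tsv(pct, p("percentile.tsv"), progress = FALSE)
    }
    manifest$summary$burden_or <<-
      unname(bur$or_point[match(cfg$filter$reference, bur$population)])
    invisible(bur)
  })

  run_stage("density", c(p("density.tsv"), p("regions.bed")), function() {
    coh <- load_cohort()
    L <- scfg$cds_length
    panel_all <- rbind(scfg$panel,
                       tibble::tibble(code = "GLOBAL",
                                      n_individuals = sum(scfg$panel$n_individuals),
                                      an = sum(scfg$panel$an)))
    pops <- cfg$density$populations %||%
      setdiff(table_populations(coh), "GLOBAL")
    expected <- cfg$density$expected_total %||%
      length(unique(coh$cds_pos[rowSums(
        as.matrix(coh[paste0("AC_", pops)]), na.rm = TRUE) > 0]))
    scales <- population_scales(panel_all, method = cfg$density$scale_method,
                                variants = coh)
    prof_all <- list()
    reg_ref <- NULL
    for (pp in pops) {
      prof <- density_profile(coh, L, population = pp,
                              halfwidth = cfg$density$halfwidth)
      thr <- population_threshold(expected, L, scales[[pp]])
      prof <- set_threshold(prof, thr)
      prof_all[[pp]] <- dplyr::mutate(tibble::as_tibble(prof),
                                      population = pp, threshold = thr)
      if (pp == cfg$filter$reference || is.null(reg_ref)) {
        reg_ref <- call_regions(prof, thr)
      }
    }
    readr::write_tsv(dplyr::bind_rows(prof_all), p("density.tsv"),
                     progress = FALSE)
    regions_to_bed(reg_ref, p("regions.bed"))
    manifest$summary$ldr_fraction <<-
      unname(sum(reg_ref$end[reg_ref$label == "LDR"] -
                   reg_ref$start[reg_ref$label == "LDR"]) / L)
    invisible(reg_ref)
  })

  run_stage("ld", p("ld_matrix.tsv"), function() {
    geno <- if (!is.null(sim_out$genotypes)) sim_out$genotypes$dosages else {
      path <- if (file.exists(p("genotypes.tsv"))) p("genotypes.tsv") else
        cfg$inputs$genotypes
      as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                progress = FALSE))
    }
    lm <- ld_matrix(geno, tol = cfg$ld$tol, max_iter = cfg$ld$max_iter)
    m <- as.data.frame(lm$r2)
    readr::write_tsv(tibble::as_tibble(cbind(variant = rownames(lm$r2), m)),
                     p("ld_matrix.tsv"), progress = FALSE)
    top <- tidy.ld_matrix(lm)
    top <- top[order(-top$r2), , drop = FALSE]
    manifest$summary$top_ld <<- if (nrow(top) > 0) {
      sprintf("%s-%s r2=%.3f", top$variant1[1], top$variant2[1], top$r2[1])
    } else NA_character_
    invisible(lm)
  })

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Human-readable run report
#'
#' Renders a per-stage markdown summary of a pipeline run: variant counts,
#' enriched comparisons, burden OR, LDR fraction of the CDS and the top LD
#' pair. Stages without output are marked absent rather than failing.
#'
#' @param manifest A manifest list from [run_pipeline()], or the path of a
#'   run directory containing `manifest.json`.
#' @param path Optional output file for the report text.
#' @return The report, invisibly, as a character vector of lines.
#' @export
pipeline_report <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    mf <- file.path(manifest, "manifest.json")
    if (!file.exists(mf)) mf <- manifest
    manifest <- jsonlite::read_json(mf)
  }
  s <- manifest$summary
  lines <- c(
    "# varburden run report",
    "",
    sprintf("- seed: %s", manifest$config$seed),
    sprintf("- stages run: %s",
            paste(names(manifest$stages), collapse = ", ")),
    ""
  )
  add <- function(stage, txt) {
    if (is.null(manifest$stages[[stage]])) {
      c(sprintf("## %s", stage), "", "section absent (stage not run)", "")
    } else {
      c(sprintf("## %s", stage), "", txt, "")
    }
  }
  lines <- c(lines,
    add("filter", sprintf("%s rare missense variants retained",
                          s$n_variants %||% "unknown")),
    add("enrich", sprintf("%s enriched variant-population comparisons",
                          s$enriched %||% 0)),
    add("burden", sprintf("burden OR vs reference population: %s",
                          if (is.null(s$burden_or)) "not computed" else
                            format(round(as.numeric(s$burden_or), 3)))),
    add("density", sprintf("LDR fraction of CDS: %s",
                           if (is.null(s$ldr_fraction)) "not computed" else
                             format(round(as.numeric(s$ldr_fraction), 3)))),
    add("ld", sprintf("top LD pair: %s", s$top_ld %||% "none"))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
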