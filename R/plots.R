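#' Plot a variant density profile
#'
#' Line plot of window density along the CDS, with the population-scaled
#' expected-density threshold as a dashed line and HDR stretches shaded when
#' the threshold has been set.
#'
#' @param object A `density_profile`.
#' @param threshold Optional threshold override (variants/bp).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, threshold = NULL, ...) {
  thr <- threshold %||% attr(object, "threshold")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cds_pos,
                                            y = .data$density))
  if (!is.null(thr) && !is.na(thr)) {
    reg <- call_regions(object, thr)
    hdr <- reg[reg$label == "HDR", , drop = FALSE]
    if (nrow(hdr) > 0) {
      p <- p + ggplot2::geom_rect(
        data = hdr,
        ggplot2::aes(xmin = .data$start + 0.5, xmax = .data$end + 0.5),
        ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE
      )
    }
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                                 colour = "red")
  }
  pop <- attr(object, "population")
  p +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "CDS position (bp)", y = "variant density (variants/bp)",
      title = if (is.na(pop)) "Variant density profile" else
        sprintf("Variant density profile (%s)", pop)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise LD matrix
#'
#' @param object An `ld_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ld_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(variant1 = object$variants,
                           variant2 = object$variants)
  df$r2 <- as.vector(object$r2[cbind(match(df$variant1, object$variants),
                                     match(df$variant2, object$variants))])
  df$variant1 <- factor(df$variant1, levels = object$variants)
  df$variant2 <- factor(df$variant2, levels = rev(object$variants))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant1, y = .data$variant2,
                                   fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey70") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Forest plot of per-variant enrichment odds ratios
#'
#' Points and confidence intervals on a log scale, one facet per population
#' comparison; enriched comparisons are highlighted. Non-finite ORs
#' (variants absent from one side) are dropped from the plot.
#'
#' @param object An `enrich_result` from [enrich_variants()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrich_result <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      is.finite(.data$or_point), .data$or_point > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_point, y = .data$variant_id,
                                   colour = .data$enriched)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(. ~ paste(.data$pop1, "vs", .data$pop2)) +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  colour = "enriched") +
    ggplot2::theme_minimal()
}

#' Percentile bar plot for a control panel
#'
#' Bar plot of control-gene rare-missense counts with the focal gene's count
#' marked, mirroring a percentile-ranking display.
#'
#' @param controls Control tibble with a `count_<population>` column.
#' @param focal_count Focal gene's count.
#' @param population Population code to display.
#' @param focal_label Label for the focal gene (default `"focal"`).
#' @return A ggplot object.
#' @export
plot_percentile <- function(controls, focal_count, population,
                            focal_label = "focal") {
  cnt <- controls[[paste0("count_", population)]]
  df <- tibble::tibble(
    gene = c(controls$gene_symbol, focal_label),
    count = c(cnt, focal_count),
    focal = c(rep(FALSE, length(cnt)), TRUE)
  )
  df$gene <- factor(df$gene, levels = df$gene[order(df$count)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$count,
                                   fill = .data$focal)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "rare missense variants",
                  title = sprintf("Variant count rank (%s)", population)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
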