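#' Hierarchical-clustering leaf orders for a contrast matrix
#'
#' Rows (patients) and columns (feature combinations) are clustered with the
#' Euclidean distance metric and complete linkage; the returned leaf orders
#' drive the heatmap layout. An axis with a single element is returned
#' unclustered (and a message logged).
#'
#' @param cm a `cc_contrast` or numeric matrix.
#' @param cluster_rows,cluster_cols toggle clustering per axis.
#' @return a list with `rows` and `cols` (character leaf orders) and the
#'   underlying `hclust` objects (`row_hclust`, `col_hclust`, possibly
#'   `NULL`).
#' @export
contrast_leaf_orders <- function(cm, cluster_rows = TRUE, cluster_cols = TRUE) {
  m <- if (inherits(cm, "cc_contrast")) contrast_values(cm) else as.matrix(cm)
  cluster_axis <- function(x, on) {
    if (!on) return(NULL)
    if (nrow(x) < 2L) {
      message("axis has a single element; clustering skipped")
      return(NULL)
    }
    stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
  }
  hr <- cluster_axis(m, cluster_rows)
  hc <- cluster_axis(t(m), cluster_cols)
  list(
    rows = if (is.null(hr)) rownames(m) else rownames(m)[hr$order],
    cols = if (is.null(hc)) colnames(m) else colnames(m)[hc$order],
    row_hclust = hr, col_hclust = hc
  )
}

#' Class-contrastive heatmap
#'
#' Rows are test patients, columns are feature combinations, and the fill is
#' the change in predicted death probability when the combination is forced
#' from all-0 to all-1. Axes are ordered by complete-linkage clustering on
#' Euclidean distances; the diverging colour scale is symmetric about zero
#' (limits +/- max |delta p|) so red always means increased and blue
#' decreased predicted mortality.
#'
#' @param cm a `cc_contrast`.
#' @param cluster_rows,cluster_cols toggle clustering per axis.
#' @return a ggplot object.
#' @export
plot_contrast_heatmap <- function(cm, cluster_rows = TRUE, cluster_cols = TRUE) {
  stopifnot(inherits(cm, "cc_contrast"))
  orders <- contrast_leaf_orders(cm, cluster_rows, cluster_cols)
  long <- tidyr::pivot_longer(cm$deltas, -"patient_id",
                              names_to = "combination", values_to = "delta_p")
  long$patient_id <- factor(long$patient_id, levels = orders$rows)
  long$combination <- factor(long$combination, levels = orders$cols)
  lim <- max(abs(long$delta_p), 1e-12)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$combination, y = .data$patient_id,
                                     fill = .data$delta_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  name = expression(Delta * p)) +
    ggplot2::labs(x = "feature combination set to 1 vs 0", y = "patient",
                  title = sprintf("Class-contrastive heatmap (order %d, %s model)",
                                  cm$order, cm$model_kind)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Write a class-contrastive heatmap to file
#'
#' @param cm a `cc_contrast`.
#' @param path output path ending in `.png` or `.svg`.
#' @param cluster_rows,cluster_cols toggle clustering per axis.
#' @param width,height device size in inches.
#' @return the leaf orders (as from [contrast_leaf_orders()]), invisibly.
#' @export
render_heatmap <- function(cm, path, cluster_rows = TRUE, cluster_cols = TRUE,
                           width = 8, height = 6) {
  p <- plot_contrast_heatmap(cm, cluster_rows, cluster_cols)
  save_plot(p, path, width, height)
  invisible(contrast_leaf_orders(cm, cluster_rows, cluster_cols))
}

# png or svg by extension, via the base cairo devices.
save_plot <- function(p, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in", res = 150)
  } else {
    stop("unsupported figure format: .", ext, " (use png or svg)", call. = FALSE)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}

#' Forest plot of odds ratios
#'
#' One marker per model term at its odds ratio with 95\% confidence-interval
#' whiskers on a log-scaled axis, a reference line at odds ratio 1, and the
#' conventional significance glyphs: filled circles for p < 0.05, open
#' circles otherwise. Terms with non-finite interval bounds (separation) are
#' drawn without whiskers and reported by message.
#'
#' @param odds an odds table as produced by [fit_logistic()] /
#'   [tidy()]; the intercept row is dropped from display.
#' @return a ggplot object.
#' @export
plot_forest <- function(odds) {
  stopifnot(nrow(odds) > 0)
  d <- odds[odds$term != "(Intercept)", , drop = FALSE]
  if (nrow(d) == 0L) d <- odds
  bad <- !is.finite(d$conf_low) | !is.finite(d$conf_high)
  if (any(bad)) {
    message("non-finite confidence bounds for: ",
            paste(d$term[bad], collapse = ", "),
            " (possible separation); whiskers omitted")
    d$conf_low[bad] <- NA_real_
    d$conf_high[bad] <- NA_real_
  }
  d$significant <- ifelse(is.na(d$significant), FALSE, d$significant)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2.5,
                        fill = "black") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "p < 0.05",
                                           `FALSE` = "not significant"),
                                name = NULL) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL,
                  title = "Odds ratios with 95% confidence intervals") +
    ggplot2::theme_minimal(base_size = 10)
}

#' @rdname plot_forest
#' @param path output path ending in `.png` or `.svg`.
#' @param width,height device size in inches.
#' @return `render_forest_plot()` returns `path` invisibly.
#' @export
render_forest_plot <- function(odds, path, width = 6, height = 5) {
  p <- plot_forest(odds)
  save_plot(p, path, width, height)
  invisible(path)
}
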