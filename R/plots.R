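#' Volcano plot of a differential contrast
#'
#' @param res Contrast tibble (after [call_features()]; uncalled results
#'   are drawn in grey).
#' @param lfc_min,fdr_max Guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(res, lfc_min = 1, fdr_max = 0.05) {
  res <- filter(res, !is.na(.data$p))
  if (!"call" %in% names(res)) res$call <- "ns"
  ggplot(res, aes(x = .data$log2FC, y = -log10(.data$p), colour = .data$call)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed", linewidth = 0.3) +
    scale_colour_manual(values = c(up = "#B2182B", down = "#2166AC", ns = "grey70")) +
    labs(x = "log2 fold-change", y = "-log10 p", colour = NULL) +
    theme_minimal()
}

#' Module profile plot for a fuzzy c-means fit
#'
#' One line per feature, coloured by membership score, facetted by module;
#' the classic soft-clustering profile view.
#'
#' @param object A `mempar_fcm`.
#' @param X The matrix the fit was computed on (features x groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mempar_fcm <- function(object, X, ...) {
  df <- as_tibble(X, .name_repair = "minimal") |>
    mutate(feature_id = object$feature_id,
           module = factor(object$hard_label),
           membership = object$membership_score) |>
    tidyr::pivot_longer(-c("feature_id", "module", "membership"),
                        names_to = "group", values_to = "z")
  df$group <- factor(df$group, levels = colnames(X))
  ggplot(df, aes(x = .data$group, y = .data$z, group = .data$feature_id,
                 colour = .data$membership)) +
    geom_line(alpha = 0.4, linewidth = 0.3) +
    facet_wrap(~ module) +
    scale_colour_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = "z-scored expression", colour = "membership") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' Tri-wise (barycentric) projection plot
#'
#' @param e 3-column matrix of group log-expression (see
#'   [triwise_project()]).
#' @param labels Axis labels (defaults to column names).
#' @return A ggplot object.
#' @export
plot_triwise <- function(e, labels = colnames(e)) {
  pts <- triwise_project(e)
  ang <- c(90, 210, 330) * pi / 180
  r <- max(1, max(sqrt(pts$x^2 + pts$y^2)))
  axes <- tibble(x = 0, y = 0, xend = r * cos(ang), yend = r * sin(ang),
                 label = labels %||% paste0("group", 1:3))
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = axes, aes(x = .data$x, y = .data$y,
                                  xend = .data$xend, yend = .data$yend),
                 inherit.aes = FALSE, colour = "grey50") +
    geom_text(data = axes, aes(x = 1.1 * .data$xend, y = 1.1 * .data$yend,
                               label = .data$label), inherit.aes = FALSE) +
    geom_point(size = 0.8, alpha = 0.7) +
    coord_equal() +
    theme_void()
}

#' Bar plot of PAR category counts
#'
#' @param par_counts Output of [par_category_counts()].
#' @return A ggplot object.
#' @export
plot_par_counts <- function(par_counts) {
  ggplot(par_counts, aes(x = .data$par, y = .data$n, fill = .data$par)) +
    geom_col() +
    facet_wrap(~ subset) +
    labs(x = NULL, y = "peaks") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1), legend.position = "none")
}

#' Bar plot of SCENITH metrics by group
#'
#' @param scenith Output of [scenith_metrics()].
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_scenith <- function(scenith, metric = "mito_dependence") {
  ggplot(scenith, aes(x = .data$group, y = .data[[metric]])) +
    stat_summary(fun = mean, geom = "col", fill = "grey75") +
    geom_point(size = 1, alpha = 0.8, position = position_jitter(width = 0.1)) +
    labs(x = NULL, y = gsub("_", " ", metric)) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
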