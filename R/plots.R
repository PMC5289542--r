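#' Scatter of eigenscores with group convex hulls
#'
#' @param model An `eigenshape_model` whose scores carry a `group` column,
#'   or an `analysis_report`.
#' @param axes Integer pair of eigenshape axes to plot (default ES1, ES2).
#' @return A ggplot object.
#' @export
plot_scores <- function(model, axes = c(1, 2)) {
  if (inherits(model, "analysis_report")) model <- model$eigenshape
  stopifnot(inherits(model, "eigenshape_model"),
            "group" %in% names(model$scores))
  xs <- paste0("ES", axes[1])
  ys <- paste0("ES", axes[2])
  df <- model$scores
  hull <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::slice(grDevices::chull(.data[[xs]], .data[[ys]])) |>
    dplyr::ungroup()
  vf <- model$variance_fractions
  ggplot2::ggplot(df, ggplot2::aes(.data[[xs]], .data[[ys]], colour = .data$group)) +
    ggplot2::geom_polygon(data = hull,
                          ggplot2::aes(fill = .data$group), alpha = 0.15,
                          show.legend = FALSE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%% of variance)", xs, 100 * vf[axes[1]]),
      y = sprintf("%s (%.1f%% of variance)", ys, 100 * vf[axes[2]]),
      colour = "group") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of eigenscores per group
#'
#' @param model An `eigenshape_model` (with a `group` column) or
#'   `analysis_report`.
#' @param axes Eigenshape axes to show.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(model, axes = c(1, 2)) {
  if (inherits(model, "analysis_report")) model <- model$eigenshape
  stopifnot(inherits(model, "eigenshape_model"))
  cols <- paste0("ES", axes)
  df <- tidyr::pivot_longer(model$scores, dplyr::all_of(cols),
                            names_to = "axis", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$score, fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "eigenscore") +
    ggplot2::theme_minimal()
}

#' Ternary plot of the first three eigenshapes
#'
#' The per-specimen proportions are the normalized squared scores on ES1-ES3
#' (an interpretation of signed scores as a composition; the decomposition
#' itself is signed, so this is a reading aid, not part of the model).
#'
#' @param model An `eigenshape_model` (with groups) or `analysis_report`.
#' @return A ggplot object.
#' @export
plot_ternary <- function(model) {
  if (inherits(model, "analysis_report")) model <- model$eigenshape
  stopifnot(inherits(model, "eigenshape_model"),
            ncol(model$eigenshapes) >= 3)
  sc <- as.matrix(model$scores[, paste0("ES", 1:3)])^2
  prop <- sc / rowSums(sc)
  # simplex -> 2D: ES1 bottom-left, ES2 bottom-right, ES3 top
  df <- tibble::tibble(
    x = prop[, 2] + 0.5 * prop[, 3],
    y = sqrt(3) / 2 * prop[, 3],
    group = model$scores$group
  )
  tri <- tibble::tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$group)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                      label = c("ES1", "ES2", "ES3"), size = 3.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "group")
}

#' Mean shape and shape models along an eigenshape axis
#'
#' Draws the reconstructed outline at the mean and at +/- `score` along one
#' axis, the standard way of visualizing what a morphospace direction means.
#'
#' @param model An `eigenshape_model` or `analysis_report`.
#' @param axis Axis number.
#' @param score Displacement; default two standard deviations of the axis.
#' @param segment Optional segment name for per-segment models.
#' @return A ggplot object.
#' @export
plot_shape_axis <- function(model, axis = 1, score = NULL, segment = NULL) {
  if (inherits(model, "analysis_report")) model <- model$eigenshape
  stopifnot(inherits(model, "eigenshape_model"))
  if (is.null(score)) score <- 2 * sqrt(model$eigenvalues[axis])
  shapes <- dplyr::bind_rows(
    dplyr::mutate(shape_model(model, axis, -score, segment = segment), which = sprintf("-%.2g", score)),
    dplyr::mutate(shape_model(model, axis, 0, segment = segment), which = "mean"),
    dplyr::mutate(shape_model(model, axis, score, segment = segment), which = sprintf("+%.2g", score))
  )
  ggplot2::ggplot(shapes, ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = sprintf("ES%d score", axis)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_scores `autoplot` method: score scatter on ES1/ES2.
#' @param object,... Passed through.
#' @export
autoplot.eigenshape_model <- function(object, axes = c(1, 2), ...) {
  if ("group" %in% names(object$scores)) {
    plot_scores(object, axes)
  } else {
    tb <- tidy(object)
    ggplot2::ggplot(tb, ggplot2::aes(.data$axis, .data$variance_fraction)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "eigenshape", y = "variance fraction") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn plot_scores `autoplot` method for a whole-outline report.
#' @export
autoplot.analysis_report <- function(object, axes = c(1, 2), ...) {
  plot_scores(object$eigenshape, axes)
}
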