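# ggplot2 autoplot methods for the main result types.

#' Plot a salinity series
#'
#' @param object A `salinity_series`.
#' @param ... Unused.
#' @return A ggplot: salinity against transfer index, with the stationary mean
#'   as a dashed line.
#' @export
autoplot.salinity_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$transfer, y = .data$salinity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mu"), linetype = "dashed") +
    ggplot2::labs(x = "Transfer", y = "Salinity (M NaCl)",
                  title = sprintf("AR1 salinity regime (target rho = %.2f, realized %.2f)",
                                  attr(object, "rho"),
                                  attr(object, "realized_rho"))) +
    ggplot2::theme_minimal()
}

#' Plot a variation partitioning
#'
#' @param object An `rda_partition`.
#' @param ... Unused.
#' @return A ggplot: each term's share of total variation (R2), residual
#'   included.
#' @export
autoplot.rda_partition <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$term != "Total") |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2, y = .data$term)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = expression(R^2 ~ "(share of total variation)"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hierarchical bootstrap
#'
#' @param object A `plasticity_boot`.
#' @param ... Unused.
#' @return A ggplot: per-line distances against predictability with the
#'   observed regression line and the bootstrap replicate lines in grey.
#' @export
autoplot.plasticity_boot <- function(object, ...) {
  reps <- tibble::tibble(slope = object$slopes, intercept = object$intercepts)
  show <- reps[seq_len(min(nrow(reps), 200)), ]
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$predictability, y = .data$distance)) +
    ggplot2::geom_abline(data = show,
                         ggplot2::aes(slope = .data$slope, intercept = .data$intercept),
                         colour = "grey80", alpha = 0.3) +
    ggplot2::geom_abline(slope = object$slope_obs, intercept = object$intercept_obs,
                         colour = "red", linewidth = 1) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$distance - .data$se,
                                          ymax = .data$distance + .data$se)) +
    ggplot2::labs(x = expression(rho^2 ~ "(environmental predictability)"),
                  y = "Degree of plasticity (Euclidean distance)") +
    ggplot2::theme_minimal()
}

#' Plot a per-day slope profile
#'
#' @param object A `slope_profile`.
#' @param ... Unused.
#' @return A ggplot: mean bootstrap slope per day with 95% bootstrap interval.
#' @export
autoplot.slope_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$day, y = .data$slope_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$slope_lo, ymax = .data$slope_hi),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Day after transfer",
                  y = expression("Slope of plasticity vs" ~ rho^2)) +
    ggplot2::theme_minimal()
}

#' Plot day-ordered centroid trajectories in morphospace
#'
#' @param centroids A treatment-level [condition_centroids()] tibble.
#' @return A ggplot of the PC1-PC2 trajectories, one path per treatment and
#'   salinity, points ordered by day.
#' @export
plot_centroid_trajectories <- function(centroids) {
  assert_columns(centroids, c("salinity_M", "day", "PC1", "PC2"))
  grp <- if ("treatment" %in% names(centroids)) "treatment" else "line_id"
  ggplot2::ggplot(centroids,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$salinity_M),
                               group = interaction(.data[[grp]], .data$salinity_M))) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"),
                                              type = "closed")) +
    ggplot2::geom_point(ggplot2::aes(size = .data$day)) +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(colour = "Assay salinity (M)", size = "Day") +
    ggplot2::theme_minimal()
}
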