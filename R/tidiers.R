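# broom-style tidiers for the package's fitted objects.

#' Tidy a plasticity regression
#'
#' @param x A `plasticity_fit` from [regress_on_predictability()].
#' @param ... Unused.
#' @return A tibble with one row per model term (`estimate`, `std.error`,
#'   `statistic`, `p.value`).
#' @export
tidy.plasticity_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "predictability"),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.plasticity_fit
#' @export
glance.plasticity_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, slope = x$slope, intercept = x$intercept,
                 nobs = nrow(x$data), constant_mean = x$constant_mean)
}

#' Tidy a hierarchical bootstrap
#'
#' @param x A `plasticity_boot` from [hierarchical_bootstrap()].
#' @param ... Unused.
#' @return `tidy()`: the per-line tibble of observed distances with bootstrap
#'   standard errors. `glance()`: a one-row summary (observed slope, replicate
#'   mean slope, one-sided p in both conventions, B).
#' @export
tidy.plasticity_boot <- function(x, ...) x$distances

#' @rdname tidy.plasticity_boot
#' @export
glance.plasticity_boot <- function(x, ...) {
  tibble::tibble(slope = x$slope_obs, intercept = x$intercept_obs,
                 r.squared = x$r2_obs,
                 slope_boot_mean = mean(x$slopes),
                 p_slope_le_0 = x$p_one_sided,
                 p_slope_gt_0 = 1 - x$p_one_sided,
                 B = x$B, n_cells = x$n_cells)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A one-row tibble with the observed difference, group means,
#'   bootstrap SE and two-sided p.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(difference = x$diff_obs, mean_a = x$mean_a, mean_b = x$mean_b,
                 std.error = sd(x$diffs), p.value = x$p_two_sided, B = x$B)
}

#' Summaries of a salinity series
#'
#' @param x A `salinity_series` from [simulate_salinity()].
#' @param ... Unused.
#' @return A one-row tibble: target and realized autocorrelation,
#'   predictability, sample mean and SD.
#' @export
glance.salinity_series <- function(x, ...) {
  tibble::tibble(rho_target = attr(x, "rho"),
                 realized_rho = attr(x, "realized_rho"),
                 predictability = attr(x, "predictability"),
                 mean = mean(x$salinity), sd = sd(x$salinity),
                 n_transfers = nrow(x))
}
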