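#' Euclidean degree of plasticity between two salinities
#'
#' The degree of plasticity of a line is the Euclidean (L2) distance between
#' its multivariate morphology means measured at low (0.8 M) vs. high (4.0 M)
#' salinity, computed on the bead-corrected log-scale channels (not PCA
#' scores, not standardised). The distance is invariant to any common shift of
#' both salinities' cells -- so bead correction, which shifts each salinity's
#' cells by a constant, matters -- and scales linearly under a common channel
#' scaling.
#'
#' @param low_cells,high_cells Data frames (or matrices) of cells at the low
#'   and high salinity; columns `channels`.
#' @param channels Channel columns (default the bead-corrected triplet).
#' @return The distance (log-scale channel units), a non-negative scalar.
#' @examples
#' a <- data.frame(fsc_c = 0, ssc_c = 0, red_b_c = 0)
#' b <- data.frame(fsc_c = 3, ssc_c = 4, red_b_c = 0)
#' plasticity_distance(a, b) # 5
#' @export
plasticity_distance <- function(low_cells, high_cells,
                                channels = corrected_channels()) {
  lo <- as.matrix(as.data.frame(low_cells)[channels])
  hi <- as.matrix(as.data.frame(high_cells)[channels])
  if (nrow(lo) == 0 || nrow(hi) == 0) {
    stop("both salinities need at least one cell", call. = FALSE)
  }
  sqrt(sum((colMeans(hi) - colMeans(lo))^2))
}

#' Per-line, per-day plasticity distances
#'
#' Tidy wrapper computing [plasticity_distance()] for every line and day
#' present in a corrected-cell table.
#'
#' @param cells Corrected cells with columns `line_id`, `salinity_M`, `day`
#'   and the channels.
#' @param low,high The two assay salinities compared (defaults 0.8 and 4.0).
#' @param channels Channel columns.
#' @return A tibble with columns `line_id`, `day`, `distance`, `n_low`,
#'   `n_high`. Line-days lacking one of the two salinities are dropped.
#' @export
plasticity_distances <- function(cells, low = 0.8, high = 4.0,
                                 channels = corrected_channels()) {
  assert_columns(cells, c("line_id", "salinity_M", "day", channels))
  cells |>
    dplyr::filter(.data$salinity_M %in% c(low, high)) |>
    dplyr::group_by(.data$line_id, .data$day) |>
    dplyr::group_modify(function(d, key) {
      lo <- d[d$salinity_M == low, ]
      hi <- d[d$salinity_M == high, ]
      if (nrow(lo) == 0 || nrow(hi) == 0) return(tibble::tibble())
      tibble::tibble(distance = plasticity_distance(lo, hi, channels),
                     n_low = nrow(lo), n_high = nrow(hi))
    }) |>
    dplyr::ungroup()
}

#' Regress the degree of plasticity on environmental predictability
#'
#' Ordinary least squares of each fluctuating line's plasticity distance on
#' its realized predictability rho^2. Constant-regime lines have no defined
#' rho^2 and never enter the fit; they are reported separately as a group
#' mean.
#'
#' @param records A tibble with `line_id` and `distance` (one row per line,
#'   e.g. [plasticity_distances()] filtered to one day).
#' @param design Design tibble with `line_id`, `regime`, `predictability`.
#' @return An object of class `plasticity_fit` wrapping the `lm`, with
#'   `slope`, `intercept`, `r2` and the per-line data; supports [tidy()] and
#'   [glance()].
#' @export
regress_on_predictability <- function(records, design) {
  assert_columns(records, c("line_id", "distance"))
  assert_columns(design, c("line_id", "regime", "predictability"), "design")
  d <- dplyr::inner_join(records, design, by = "line_id")
  fl <- d[d$regime == "fluctuating", ]
  if (nrow(fl) < 3) stop("need at least 3 fluctuating lines", call. = FALSE)
  if (sd(fl$predictability) == 0) {
    stop("zero variance in predictability across lines", call. = FALSE)
  }
  fit <- lm(distance ~ predictability, data = fl)
  const <- d[d$regime == "constant", ]
  structure(list(
    fit = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    data = fl,
    constant_mean = if (nrow(const)) mean(const$distance) else NA_real_,
    n_constant = nrow(const)
  ), class = "plasticity_fit")
}

#' @export
print.plasticity_fit <- function(x, ...) {
  cat(sprintf("Degree of plasticity ~ predictability (rho^2), %d lines\n",
              nrow(x$data)))
  cat(sprintf("  slope %.4f  intercept %.4f  R2 %.3f\n",
              x$slope, x$intercept, x$r2))
  if (!is.na(x$constant_mean)) {
    cat(sprintf("  constant-regime mean distance %.4f (%d lines, not in fit)\n",
                x$constant_mean, x$n_constant))
  }
  invisible(x)
}

# ---- hierarchical bootstrap ------------------------------------------------

# Split cells into per-line x per-salinity channel matrices.
cell_matrices <- function(cells, lines, low, high, channels) {
  out <- list()
  for (s in c(low, high)) {
    key <- if (s == low) "low" else "high"
    out[[key]] <- lapply(setNames(lines, lines), function(l) {
      m <- as.matrix(cells[cells$line_id == l & cells$salinity_M == s,
                           channels, drop = FALSE])
      if (nrow(m) == 0) {
        stop(sprintf("line %s has no cells at salinity %s", l, s), call. = FALSE)
      }
      m
    })
  }
  out
}

# For a vector of line assignments (slot -> line index), draw an independent
# n_cells-with-replacement mean vector per slot from the line's cell matrix.
# Fully vectorised via rowsum over slots grouped by line.
slot_means <- function(mats, slot_line, n_cells) {
  n_slots <- length(slot_line)
  out <- matrix(NA_real_, n_slots, ncol(mats[[1]]))
  for (li in unique(slot_line)) {
    slots <- which(slot_line == li)
    M <- mats[[li]]
    idx <- sample.int(nrow(M), n_cells * length(slots), replace = TRUE)
    grp <- rep(seq_along(slots), each = n_cells)
    out[slots, ] <- rowsum(M[idx, , drop = FALSE], grp) / n_cells
  }
  out
}

ols_slopes <- function(X, D) {
  # row-wise OLS slope of D on X (replicates x slots matrices)
  mx <- rowMeans(X); md <- rowMeans(D)
  sxy <- rowMeans(X * D) - mx * md
  sxx <- rowMeans(X * X) - mx^2
  list(slope = sxy / sxx, intercept = md - (sxy / sxx) * mx)
}

#' Hierarchical nonparametric bootstrap of the plasticity-predictability slope
#'
#' Resampling mirrors the data's nesting. Each replicate (i) draws the
#' fluctuating lines with replacement (32 among 32 in the full design); (ii)
#' for each drawn line and each salinity draws `n_cells` (default 150) cells
#' with replacement -- a line observed with fewer cells is still resampled to
#' `n_cells`, which the fixed-n scheme forces; (iii) recomputes every drawn
#' line's Euclidean plasticity distance and the OLS slope of distance on
#' rho^2. After `B` replicates the slope distribution yields per-line distance
#' standard errors and the one-sided significance level.
#'
#' The reported `p_one_sided` is the proportion of replicate slopes less than
#' or equal to zero, so a small value supports a positive
#' plasticity-predictability relationship; its complement (the proportion of
#' slopes greater than zero) is the same evidence stated the other way around.
#'
#' @param cells Corrected cells (`line_id`, `salinity_M`, `day` optional,
#'   channels).
#' @param design Design tibble (`line_id`, `regime`, `predictability`); only
#'   fluctuating lines enter.
#' @param day Optional single day to filter `cells` to.
#' @param B Number of bootstrap replicates (default 1000).
#' @param n_cells Cells resampled per line and salinity (default 150).
#' @param seed Optional seed.
#' @param low,high Assay salinities compared.
#' @param channels Channel columns.
#' @return An object of class `plasticity_boot`: observed slope / intercept /
#'   r2, the `B` replicate slopes, `p_one_sided`, and a per-line tibble of
#'   observed distances with bootstrap SEs. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
hierarchical_bootstrap <- function(cells, design, day = NULL, B = 1000,
                                   n_cells = 150, seed = NULL,
                                   low = 0.8, high = 4.0,
                                   channels = corrected_channels()) {
  assert_columns(cells, c("line_id", "salinity_M", channels))
  assert_columns(design, c("line_id", "regime", "predictability"), "design")
  if (!is.null(day)) {
    assert_columns(cells, "day")
    cells <- cells[cells$day == day, , drop = FALSE]
  }
  fl <- design[design$regime == "fluctuating", ]
  lines <- fl$line_id
  rho2 <- setNames(fl$predictability, fl$line_id)
  n_lines <- length(lines)
  if (n_lines < 3) stop("need at least 3 fluctuating lines", call. = FALSE)
  cells <- cells[cells$line_id %in% lines, , drop = FALSE]
  mats <- cell_matrices(cells, lines, low, high, channels)

  # observed statistic
  dist_obs <- vapply(lines, function(l) {
    sqrt(sum((colMeans(mats$high[[l]]) - colMeans(mats$low[[l]]))^2))
  }, 0)
  fit_obs <- lm(dist_obs ~ rho2[lines])
  slope_obs <- unname(coef(fit_obs)[2])
  intercept_obs <- unname(coef(fit_obs)[1])
  r2_obs <- summary(fit_obs)$r.squared

  res <- with_seed_or_not(seed, {
    line_draw <- matrix(sample.int(n_lines, B * n_lines, replace = TRUE),
                        nrow = B)
    lo_means <- slot_means(mats$low, as.vector(line_draw), n_cells)
    hi_means <- slot_means(mats$high, as.vector(line_draw), n_cells)
    D <- matrix(sqrt(rowSums((hi_means - lo_means)^2)), nrow = B)
    X <- matrix(rho2[lines][as.vector(line_draw)], nrow = B)
    fitb <- ols_slopes(X, D)
    # per-line distance SE from the replicate distances of slots drawn as
    # that line
    se <- vapply(seq_len(n_lines), function(li) {
      v <- D[line_draw == li]
      if (length(v) > 1) sd(v) else NA_real_
    }, 0)
    list(slopes = fitb$slope, intercepts = fitb$intercept, se = se)
  })

  finite <- is.finite(res$slopes)
  if (!all(finite)) {
    # a replicate that redraws a single line has no rho^2 spread; its slope is
    # undefined and is excluded from the summaries (rare unless very few lines)
    warning(sprintf("%d replicate(s) with undefined slope excluded",
                    sum(!finite)), call. = FALSE)
  }
  degenerate <- isTRUE(sd(res$slopes[finite]) == 0)
  if (degenerate) {
    warning("all bootstrap slopes identical: degenerate resampling distribution",
            call. = FALSE)
  }
  structure(list(
    slope_obs = slope_obs, intercept_obs = intercept_obs, r2_obs = r2_obs,
    slopes = res$slopes, intercepts = res$intercepts,
    p_one_sided = mean(res$slopes[finite] <= 0),
    B = B, n_cells = n_cells, seed = seed, day = day,
    degenerate = degenerate,
    distances = tibble::tibble(line_id = lines,
                               predictability = unname(rho2[lines]),
                               distance = unname(dist_obs), se = res$se)
  ), class = "plasticity_boot")
}

#' @export
print.plasticity_boot <- function(x, ...) {
  cat(sprintf("Hierarchical bootstrap (%d replicates, %d cells/line/salinity%s)\n",
              x$B, x$n_cells,
              if (!is.null(x$day)) sprintf(", day %s", x$day) else ""))
  cat(sprintf("  observed slope %.4f (R2 %.3f)\n", x$slope_obs, x$r2_obs))
  cat(sprintf("  P(slope <= 0) = %.4g  [P(slope > 0) = %.4g]\n",
              x$p_one_sided, 1 - x$p_one_sided))
  invisible(x)
}

#' Per-day slope profile of the evolution of plasticity
#'
#' Applies [hierarchical_bootstrap()] independently to each assay day,
#' producing the day profile of the plasticity-predictability slope (mean
#' replicate slope, bootstrap quantiles and one-sided significance per day).
#'
#' @inheritParams hierarchical_bootstrap
#' @param days Days to profile (default 1:10).
#' @return A tibble of class `slope_profile`: `day`, `slope_obs`,
#'   `slope_mean`, `slope_lo`, `slope_hi` (2.5%/97.5% bootstrap quantiles),
#'   `p_one_sided`, `B`. Supports [autoplot()].
#' @export
slope_profile_by_day <- function(cells, design, days = 1:10, B = 1000,
                                 n_cells = 150, seed = NULL,
                                 low = 0.8, high = 4.0,
                                 channels = corrected_channels()) {
  out <- purrr::map_dfr(seq_along(days), function(i) {
    bt <- hierarchical_bootstrap(cells, design, day = days[i], B = B,
                                 n_cells = n_cells,
                                 seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                                 low = low, high = high, channels = channels)
    sl <- bt$slopes[is.finite(bt$slopes)]
    tibble::tibble(day = days[i], slope_obs = bt$slope_obs,
                   slope_mean = mean(sl),
                   slope_lo = unname(quantile(sl, 0.025)),
                   slope_hi = unname(quantile(sl, 0.975)),
                   p_one_sided = bt$p_one_sided, B = bt$B)
  })
  class(out) <- c("slope_profile", class(out))
  out
}

#' Bootstrap comparison of plasticity between two line groups
#'
#' Tests whether two sets of lines (for instance the constant-regime controls
#' vs. lines evolved under high predictability, or the -0.5 vs. +0.5
#' autocorrelation treatments) differ in mean degree of plasticity. Each
#' replicate resamples lines with replacement within each group, then cells
#' within each drawn line and salinity, exactly as in
#' [hierarchical_bootstrap()], and recomputes the difference in group mean
#' distance (A minus B). The two-sided p-value is twice the smaller tail
#' probability of the replicate differences around zero (capped at 1).
#'
#' @inheritParams hierarchical_bootstrap
#' @param group_a,group_b Character vectors of `line_id`s.
#' @return An object of class `group_comparison`: `diff_obs`, replicate
#'   `diffs`, `p_two_sided`, group summaries.
#' @export
compare_groups <- function(cells, design, group_a, group_b, day = NULL,
                           B = 1000, n_cells = 150, seed = NULL,
                           low = 0.8, high = 4.0,
                           channels = corrected_channels()) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (!is.null(day)) {
    assert_columns(cells, "day")
    cells <- cells[cells$day == day, , drop = FALSE]
  }
  lines <- unique(c(group_a, group_b))
  mats <- cell_matrices(cells[cells$line_id %in% lines, , drop = FALSE],
                        lines, low, high, channels)
  dist_of <- function(lo, hi) sqrt(rowSums((hi - lo)^2))
  obs <- vapply(lines, function(l) {
    sqrt(sum((colMeans(mats$high[[l]]) - colMeans(mats$low[[l]]))^2))
  }, 0)
  names(obs) <- lines
  diff_obs <- mean(obs[group_a]) - mean(obs[group_b])

  group_mean_reps <- function(group) {
    gi <- match(group, lines)
    draw <- matrix(sample(gi, B * length(gi), replace = TRUE), nrow = B)
    lo <- slot_means(mats$low, as.vector(draw), n_cells)
    hi <- slot_means(mats$high, as.vector(draw), n_cells)
    rowMeans(matrix(dist_of(lo, hi), nrow = B))
  }
  diffs <- with_seed_or_not(seed, group_mean_reps(group_a) - group_mean_reps(group_b))
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  structure(list(diff_obs = diff_obs, diffs = diffs, p_two_sided = p,
                 mean_a = mean(obs[group_a]), mean_b = mean(obs[group_b]),
                 n_a = length(group_a), n_b = length(group_b), B = B),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group plasticity comparison (%d vs %d lines, %d replicates)\n",
              x$n_a, x$n_b, x$B))
  cat(sprintf("  mean distance %.4f vs %.4f, difference %.4f, two-sided p = %.3g\n",
              x$mean_a, x$mean_b, x$diff_obs, x$p_two_sided))
  invisible(x)
}
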