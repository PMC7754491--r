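#' Simulate an AR1 salinity regime
#'
#' Generates one line's salinity trajectory across serial transfers as a
#' stationary first-order autoregressive (AR1) process
#' \deqn{S_{t+1} = \mu + \rho (S_t - \mu) + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \sigma^2 (1 - \rho^2)),}
#' so that every autocorrelation treatment shares the same stationary mean
#' \eqn{\mu} and stationary standard deviation \eqn{\sigma}. The first value is
#' drawn from the stationary distribution \eqn{N(\mu, \sigma^2)}, which keeps
#' realized moments unbiased at finite length. The series is returned
#' unclipped: physical feasibility of a transfer (given finite-salinity stock
#' media and partial retention of the previous culture) is the business of
#' [transfer_recipe()], so statistical targets are not distorted by truncation.
#'
#' @param n_transfers Number of transfers (series length), at least 2.
#' @param rho Lag-1 autocorrelation, in (-1, 1). The study's treatments target
#'   long-run autocorrelations -0.5, 0, 0.5 and 0.9.
#' @param mu Stationary mean salinity in M NaCl (default 2.4).
#' @param sigma Stationary standard deviation in M NaCl (default 1).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param treatment_label Optional label stored on the result (e.g. "p09").
#'
#' @return A tibble of class `salinity_series` with columns `transfer`
#'   (1-based index) and `salinity` (M NaCl), and attributes `mu`, `sigma`,
#'   `rho`, `realized_rho`, `predictability` (the squared realized
#'   autocorrelation), `degenerate` (TRUE when `sigma == 0`) and
#'   `treatment_label`.
#'
#' @examples
#' s <- simulate_salinity(139, rho = 0.9, seed = 1)
#' attr(s, "realized_rho")
#' @seealso [realized_autocorrelation()], [predictability()], [series_recipes()]
#' @export
simulate_salinity <- function(n_transfers, rho, mu = 2.4, sigma = 1,
                              seed = NULL, treatment_label = NULL) {
  assert_scalar_number(n_transfers, "n_transfers", lower = 2)
  assert_scalar_number(rho, "rho")
  if (rho <= -1 || rho >= 1) stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma, "sigma", lower = 0)
  n <- as.integer(n_transfers)

  values <- with_seed_or_not(seed, {
    x0 <- rnorm(1, mu, sigma)
    if (n == 1L) {
      x0
    } else {
      eps <- rnorm(n - 1L, 0, sigma * sqrt(1 - rho^2))
      dev <- as.numeric(stats::filter(eps, rho, method = "recursive",
                                      init = x0 - mu))
      c(x0, mu + dev)
    }
  })

  degenerate <- sigma == 0
  r <- if (degenerate) NA_real_ else realized_autocorrelation(values)
  out <- tibble::tibble(transfer = seq_len(n), salinity = values)
  class(out) <- c("salinity_series", class(out))
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "rho") <- rho
  attr(out, "seed") <- seed
  attr(out, "treatment_label") <- treatment_label
  attr(out, "degenerate") <- degenerate
  attr(out, "realized_rho") <- r
  attr(out, "predictability") <- if (is.na(r)) NA_real_ else r^2
  out
}

#' Realized lag-1 autocorrelation of a salinity series
#'
#' The Pearson correlation between salinities at two subsequent transfers,
#' i.e. `cor(x[1:(T-1)], x[2:T])`. Because each line experiences a finite
#' random realization of its AR1 process, this realized autocorrelation (and
#' hence the realized predictability) varies around the treatment target,
#' spanning a continuum of values across lines.
#'
#' @param x A numeric vector of salinities, or a `salinity_series` tibble.
#' @return The realized lag-1 correlation (dimensionless).
#' @examples
#' realized_autocorrelation(c(0.8, 4.0, 0.8, 4.0, 0.8, 4.0)) # exactly -1
#' @export
realized_autocorrelation <- function(x) {
  if (is.data.frame(x)) {
    assert_columns(x, "salinity")
    x <- x$salinity
  }
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 values for a lag-1 correlation", call. = FALSE)
  a <- x[-length(x)]
  b <- x[-1]
  if (sd(a) == 0 || sd(b) == 0) {
    stop("degenerate series: zero variance in a lagged subseries", call. = FALSE)
  }
  cor(a, b)
}

#' Environmental predictability from autocorrelation
#'
#' Predictability is quantified as \eqn{\rho^2}, the proportion of the temporal
#' variance in the environment explained by its previous value. Treatments with
#' autocorrelation -0.5 and +0.5 therefore share the same predictability
#' (0.25) despite producing very different magnitudes of change per transfer.
#'
#' @param rho Lag-1 autocorrelation in \[-1, 1\] (vectorised).
#' @return `rho^2`.
#' @examples
#' predictability(c(-0.5, 0, 0.9))
#' @export
predictability <- function(rho) {
  if (!is.numeric(rho)) stop("`rho` must be numeric", call. = FALSE)
  if (any(abs(rho) > 1, na.rm = TRUE)) {
    stop("`rho` must lie in [-1, 1]", call. = FALSE)
  }
  rho^2
}

#' Transfer recipe: volumes of stock media realising a target salinity
#'
#' At each serial transfer a fraction of the pre-transfer culture is retained
#' (default 20%) and diluted into fresh medium (default 800 ul) mixed from
#' hypo-saline (0 M) and hyper-saline (4.8 M) stocks. Mass balance gives the
#' required fresh-medium salinity
#' \deqn{m = (s_{target} - f \, s_{pre}) / (1 - f)}
#' with retained fraction \eqn{f}. When the required `m` falls outside the
#' achievable \[0, 4.8\] M range it is clamped to the nearest bound, the
#' achieved salinity is recomputed, and the recipe is flagged infeasible.
#'
#' @param s_pre Pre-transfer salinity (M NaCl), non-negative. Vectorised.
#' @param s_target Target post-transfer salinity (M NaCl). Vectorised.
#' @param retained_fraction Fraction of final volume carried over (default 0.2).
#' @param fresh_volume Fresh-medium volume in ul (default 800).
#' @param stock_salinities Salinities of the two stock media (M NaCl).
#'
#' @return A tibble with columns `s_pre`, `s_target`, `medium_salinity`,
#'   `v_hypo`, `v_hyper` (ul), `achieved_salinity` and `feasible`.
#' @examples
#' transfer_recipe(2.4, 2.4) # 400 ul of each stock
#' @export
transfer_recipe <- function(s_pre, s_target, retained_fraction = 0.2,
                            fresh_volume = 800,
                            stock_salinities = c(0, 4.8)) {
  if (any(!is.finite(s_pre)) || any(s_pre < 0)) {
    stop("`s_pre` must be non-negative and finite", call. = FALSE)
  }
  assert_scalar_number(retained_fraction, "retained_fraction")
  if (retained_fraction <= 0 || retained_fraction >= 1) {
    stop("`retained_fraction` must lie strictly inside (0, 1)", call. = FALSE)
  }
  assert_scalar_number(fresh_volume, "fresh_volume", lower = 0)
  lo <- min(stock_salinities)
  hi <- max(stock_salinities)
  f <- retained_fraction

  medium_needed <- (s_target - f * s_pre) / (1 - f)
  feasible <- medium_needed >= lo & medium_needed <= hi
  medium <- pmin(pmax(medium_needed, lo), hi)
  achieved <- f * s_pre + (1 - f) * medium
  v_hyper <- fresh_volume * (medium - lo) / (hi - lo)
  tibble::tibble(
    s_pre = s_pre,
    s_target = s_target,
    medium_salinity = medium,
    v_hypo = fresh_volume - v_hyper,
    v_hyper = v_hyper,
    achieved_salinity = achieved,
    feasible = feasible
  )
}

#' Transfer recipes for a whole salinity series
#'
#' Applies [transfer_recipe()] to every consecutive pair of a series,
#' producing the bench-ready table of stock volumes per transfer. For a series
#' whose steps are all physically achievable, following the recipes reproduces
#' the series exactly.
#'
#' @param series A `salinity_series` tibble (or data frame with columns
#'   `transfer` and `salinity`).
#' @inheritParams transfer_recipe
#' @return A tibble with columns `transfer_index`, `salinity_M` (the target),
#'   `v_hypo_ul`, `v_hyper_ul`, `achieved_M`, `feasible`. Row `t` describes the
#'   transfer from salinity `t` to salinity `t + 1`.
#' @export
series_recipes <- function(series, retained_fraction = 0.2, fresh_volume = 800,
                           stock_salinities = c(0, 4.8)) {
  assert_columns(series, c("transfer", "salinity"))
  x <- series$salinity
  if (length(x) < 2) stop("series must contain at least 2 transfers", call. = FALSE)
  rec <- transfer_recipe(head(x, -1), tail(x, -1),
                         retained_fraction = retained_fraction,
                         fresh_volume = fresh_volume,
                         stock_salinities = stock_salinities)
  tibble::tibble(
    transfer_index = seq_len(nrow(rec)),
    salinity_M = rec$s_target,
    v_hypo_ul = rec$v_hypo,
    v_hyper_ul = rec$v_hyper,
    achieved_M = rec$achieved_salinity,
    feasible = rec$feasible
  )
}
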