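#' Per-capita daily growth rates
#'
#' The discrete per-capita growth rate between consecutive days,
#' \deqn{r_t = (N_t - N_{t-1}) / N_{t-1},}
#' where `N` is population density (cells/ml). The first density is the
#' inoculation density. A zero previous density leaves that day's rate
#' undefined (`NA`, with a warning).
#'
#' @param densities Numeric vector of densities ordered by day (day 0 first).
#' @return Numeric vector of rates, one per day after the first.
#' @examples
#' per_capita_growth(c(2e4, 4e4, 2e4)) # doubling then halving
#' @export
per_capita_growth <- function(densities) {
  if (!is.numeric(densities) || length(densities) < 2) {
    stop("`densities` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(densities < 0)) stop("densities must be non-negative", call. = FALSE)
  prev <- head(densities, -1)
  rates <- (tail(densities, -1) - prev) / prev
  if (any(prev == 0)) {
    warning("zero density: growth rate undefined for some day(s)", call. = FALSE)
    rates[prev == 0] <- NA_real_
  }
  rates
}

#' Label growth phases from daily rates
#'
#' The exponential phase is the maximal contiguous block of days whose rate is
#' at least a fraction `f` (default 0.8) of the maximum rate, containing the
#' day of maximum rate (earliest day on ties). Days before the block are the
#' lag phase; days after are stationary. If no rate is positive, all days are
#' labelled stationary with a warning. The verbal definition -- highest-rate
#' days are exponential, slower positive growth before/after is lag/stationary
#' -- leaves the cut-off open; `f` makes it explicit and configurable.
#'
#' @param rates Numeric vector of per-day rates (length >= 3; `NA` allowed).
#' @param f Fraction of the maximum rate defining the exponential block.
#' @return Character vector of labels (`"lag"`, `"exponential"`,
#'   `"stationary"`), same length as `rates`.
#' @examples
#' classify_phases(c(0.1, 0.2, 1.0, 1.0, 0.2, 0.1))
#' @export
classify_phases <- function(rates, f = 0.8) {
  if (length(rates) < 3) stop("need at least 3 rates", call. = FALSE)
  assert_scalar_number(f, "f", lower = 0, upper = 1)
  ok <- !is.na(rates)
  if (!any(ok) || max(rates[ok]) <= 0) {
    warning("no positive growth: labelling all days stationary", call. = FALSE)
    return(rep("stationary", length(rates)))
  }
  m <- max(rates[ok])
  peak <- which(rates >= m)[1]
  thr <- f * m
  in_block <- !is.na(rates) & rates >= thr
  # expand contiguously around the peak
  lo <- peak
  while (lo > 1 && in_block[lo - 1]) lo <- lo - 1
  hi <- peak
  while (hi < length(rates) && in_block[hi + 1]) hi <- hi + 1
  labels <- rep("stationary", length(rates))
  if (lo > 1) labels[seq_len(lo - 1)] <- "lag"
  labels[lo:hi] <- "exponential"
  labels
}

#' Growth rates and phases for a density table
#'
#' Tidy wrapper: for each line x salinity, orders densities by day, computes
#' [per_capita_growth()] and labels phases with [classify_phases()].
#'
#' @param densities A tibble with columns `line_id`, `salinity_M`, `day`,
#'   `cells_per_ml` (day 0 = inoculation).
#' @param f Passed to [classify_phases()].
#' @return A tibble with one row per line x salinity x post-inoculation day,
#'   adding columns `r` and `phase`.
#' @export
growth_phases <- function(densities, f = 0.8) {
  assert_columns(densities, c("line_id", "salinity_M", "day", "cells_per_ml"))
  densities |>
    dplyr::group_by(.data$line_id, .data$salinity_M) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::reframe(
      day = .data$day[-1],
      r = per_capita_growth(.data$cells_per_ml),
      phase = classify_phases(per_capita_growth(.data$cells_per_ml), f = f)
    )
}
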