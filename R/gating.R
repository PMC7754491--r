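#' Gate alive cells on the Red-B / Yellow-B cytogram
#'
#' Non-algal particles and dead cells lack chlorophyll auto-fluorescence, so
#' live algae separate cleanly on red vs. yellow emission. The visual cytogram
#' gate is formalised as two log-scale thresholds: a minimum Red-B and a
#' minimum Red-B minus Yellow-B difference. An event is kept when
#' `red_b >= min_red` **and** `red_b - yellow_b >= min_diff`. The defaults are
#' calibrated against the synthetic generator's class separation; they are not
#' instrument constants and should be set per dataset.
#'
#' @param events An event tibble with columns `red_b`, `yellow_b`.
#' @param min_red Minimum Red-B (log units; default 3.2).
#' @param min_diff Minimum Red-B - Yellow-B (log units; default 0.5).
#' @return The retained events, with attribute `retained` giving the retention
#'   fraction. Empty input or an empty result triggers a warning.
#' @export
gate_alive <- function(events, min_red = 3.2, min_diff = 0.5) {
  assert_columns(events, c("red_b", "yellow_b"))
  if (nrow(events) == 0) {
    warning("empty event table: nothing to gate", call. = FALSE)
    return(structure(events, retained = NA_real_))
  }
  keep <- events$red_b >= min_red & (events$red_b - events$yellow_b) >= min_diff
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("live gate removed every event", call. = FALSE)
  attr(out, "retained") <- mean(keep)
  out
}

#' Exclude doublets by pulse width
#'
#' Two cells recorded as one event produce a wide electronic pulse; singlets
#' are retained as events with `fsc_w <= fsc_w_max`. The threshold is a single
#' configurable cut (default 2.75 log units, calibrated on the synthetic
#' generator).
#'
#' @param events An event tibble with column `fsc_w`.
#' @param fsc_w_max Maximum pulse width retained.
#' @return Retained events with attribute `retained`.
#' @export
remove_doublets <- function(events, fsc_w_max = 2.75) {
  assert_columns(events, "fsc_w")
  if (!is.finite(fsc_w_max)) {
    if (is.na(fsc_w_max)) stop("`fsc_w_max` must not be NA", call. = FALSE)
  }
  if (nrow(events) == 0) return(structure(events, retained = NA_real_))
  keep <- events$fsc_w <= fsc_w_max
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("doublet cut removed every event", call. = FALSE)
  attr(out, "retained") <- mean(keep)
  out
}

#' Bead-calibrate morphology channels
#'
#' The optical density of the medium biases the light signal, more so at high
#' salinity. Calibration beads acquired in medium at the same salinity carry
#' the same bias, so subtracting the per-salinity bead mean of each channel
#' from each cell measurement removes it. Adds bead-corrected columns
#' `fsc_c`, `ssc_c`, `red_b_c`.
#'
#' @param events Event tibble with columns `salinity_M`, `fsc`, `ssc`, `red_b`.
#' @param beads Bead tibble with columns `salinity_M`, `fsc`, `ssc`, `red_b`,
#'   covering every salinity present in `events`.
#' @return `events` with the three corrected columns appended.
#' @export
bead_correct <- function(events, beads) {
  assert_columns(events, c("salinity_M", raw_channels()))
  assert_columns(beads, c("salinity_M", raw_channels()), "beads")
  if (nrow(beads) == 0) stop("bead table is empty", call. = FALSE)
  missing_sal <- setdiff(unique(events$salinity_M), unique(beads$salinity_M))
  if (length(missing_sal)) {
    stop(sprintf("no beads for assay salinity %s",
                 paste(missing_sal, collapse = ", ")), call. = FALSE)
  }
  bead_means <- beads |>
    dplyr::group_by(.data$salinity_M) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(raw_channels()), mean),
                     .groups = "drop") |>
    dplyr::rename(bm_fsc = "fsc", bm_ssc = "ssc", bm_red_b = "red_b")
  events |>
    dplyr::left_join(bead_means, by = "salinity_M") |>
    dplyr::mutate(
      fsc_c = .data$fsc - .data$bm_fsc,
      ssc_c = .data$ssc - .data$bm_ssc,
      red_b_c = .data$red_b - .data$bm_red_b
    ) |>
    dplyr::select(-dplyr::starts_with("bm_"))
}

#' Subsample events to a balanced cap
#'
#' Low density just after transfer limits how many cells the cytometer can
#' see, so conditions are balanced by randomly selecting up to `cap` events
#' (without replacement) per condition. Grouping columns among `line_id`,
#' `salinity_M`, `day` that are present define a condition; with none present
#' the whole table is one condition.
#'
#' @param events Event tibble.
#' @param cap Maximum events retained per condition (default 150).
#' @param seed Optional seed (reproducible subsets).
#' @param by Condition-defining columns (defaults to those present).
#' @return The subsampled tibble.
#' @export
subsample_events <- function(events, cap = 150, seed = NULL,
                             by = intersect(c("line_id", "salinity_M", "day"),
                                            names(events))) {
  assert_scalar_number(cap, "cap", lower = 1)
  with_seed_or_not(seed, {
    if (length(by) == 0) {
      events[sample(nrow(events), min(cap, nrow(events))), , drop = FALSE]
    } else {
      events |>
        dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
        dplyr::slice_sample(n = cap) |>
        dplyr::ungroup()
    }
  })
}

#' Population density from an alive-event count
#'
#' Density is the ratio of events identified as alive cells to the acquisition
#' volume, converted to cells per ml. The default volume, 35.4 ul, corresponds
#' to 30 s of acquisition at 1.18 ul/s.
#'
#' @param n_alive Count of alive events (vectorised).
#' @param acquisition_volume_ul Acquisition volume in ul (> 0).
#' @return Density in cells/ml.
#' @examples
#' estimate_density(354, 35.4) # 1e4 cells/ml
#' @export
estimate_density <- function(n_alive, acquisition_volume_ul = 35.4) {
  if (any(acquisition_volume_ul <= 0)) {
    stop("`acquisition_volume_ul` must be positive", call. = FALSE)
  }
  if (any(n_alive < 0)) stop("`n_alive` must be non-negative", call. = FALSE)
  n_alive / acquisition_volume_ul * 1000
}
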