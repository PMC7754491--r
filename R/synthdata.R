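#' Parameters of the synthetic cytometry-study generator
#'
#' Collects every tunable of the synthetic data generator in one validated
#' list. The generator emulates the statistical structure the downstream
#' analysis assumes: a three-channel (FSC, SSC, Red-B) log-scale morphology
#' whose response to assay salinity acts along a fixed direction (high-salinity
#' cells smaller, with less chlorophyll), a plasticity magnitude that is linear
#' in a line's realized predictability rho^2 (`plasticity_intercept +
#' plasticity_slope * rho2`), a day-indexed loop-shaped ontogenic path, a
#' growth-phase-dependent gain on plasticity (low during exponential growth,
#' high during lag and stationary phases), contaminating debris / dead cells /
#' doublets, and salinity-dependent optical offsets cancelled by bead
#' calibration.
#'
#' Channel units are log-scale cytometer units throughout.
#'
#' @param baseline_mean Named 3-vector: mean (fsc, ssc, red_b) of alive
#'   singlets at the acclimation salinity.
#' @param salinity_effect 3-vector direction of the plastic response per unit
#'   plasticity magnitude; default `c(-0.6, 0, -0.8)` (unit norm) so the
#'   expected low-vs-high distance equals the plasticity magnitude itself.
#' @param plasticity_intercept,plasticity_slope Intercept `a` and slope `b` of
#'   the per-line plasticity magnitude `a + b * rho2` (log units).
#' @param constant_rho2 Effective rho^2 assigned to constant-regime lines
#'   (default 0.7), matching their observed similarity to lines evolved under
#'   high predictability.
#' @param line_noise_sd SD of a per-line random deviation of the plasticity
#'   magnitude around `a + b * rho2` (log units; default 0.1). Evolved lines
#'   are biological replicates, not deterministic functions of their
#'   environment history; this residual heterogeneity between lines is also
#'   what the hierarchical bootstrap's line-resampling level measures. Each
#'   line's deviation is a fixed, reproducible function of its id and
#'   `line_effect_seed`.
#' @param line_effect_seed Seed stream for the per-line deviations.
#' @param ontogeny_amplitude Radius of the loop-shaped day path (log units).
#' @param day_phases Character vector of length 11 mapping days 0..10 to
#'   `"lag"`, `"exponential"` or `"stationary"`.
#' @param phase_gain Named multiplier on plasticity per phase.
#' @param within_cell_sd Per-channel SD of alive singlets.
#' @param yellow_alive_mean,yellow_sd Yellow-B parameters for alive cells.
#' @param fsc_w_alive,fsc_w_doublet,fsc_w_sd Pulse-width (FSC-W) means for
#'   singlets and doublets, and their SD.
#' @param dead_mean,dead_yellow Dead-cell channel means (low Red-B relative to
#'   Yellow-B, so the live gate excludes them).
#' @param debris_mean,debris_yellow,debris_sd Debris channel parameters.
#' @param debris_fraction,dead_fraction,doublet_fraction Mixture fractions,
#'   each in \[0, 1) and summing to less than 1.
#' @param bead_offsets 3 x 3 matrix (rows named "0.8", "2.4", "4") of
#'   per-assay-salinity optical offsets added to (fsc, ssc, red_b).
#' @param bead_sd SD of bead channel values.
#' @param r_max,K,N0 Logistic growth parameters: intrinsic rate (per day),
#'   carrying capacity and inoculation density (cells/ml; default 2e4).
#' @param growth_noise_sd SD of multiplicative lognormal day-to-day noise on
#'   densities.
#' @param acquisition_volume_ul Acquisition volume per sample (default 35.4 ul,
#'   i.e. 30 s at 1.18 ul/s).
#' @param max_events,min_events Bounds on events acquired per condition (the
#'   cytometer stops at 5000 events; low-density early days yield few).
#'
#' @return A validated list of class `generator_params`.
#' @examples
#' p <- generator_params(plasticity_slope = 2)
#' p$phase_gain
#' @export
generator_params <- function(
    baseline_mean = c(fsc = 5.0, ssc = 4.5, red_b = 5.5),
    salinity_effect = c(fsc = -0.6, ssc = 0, red_b = -0.8),
    plasticity_intercept = 0.5,
    plasticity_slope = 2.0,
    constant_rho2 = 0.7,
    line_noise_sd = 0.1,
    line_effect_seed = 42,
    ontogeny_amplitude = 0.5,
    day_phases = c("lag", "lag", "lag", "exponential", "exponential",
                   rep("stationary", 6)),
    phase_gain = c(lag = 1, exponential = 0.25, stationary = 1),
    within_cell_sd = c(fsc = 0.3, ssc = 0.3, red_b = 0.3),
    yellow_alive_mean = 2.3, yellow_sd = 0.3,
    fsc_w_alive = 2.0, fsc_w_doublet = 3.5, fsc_w_sd = 0.2,
    dead_mean = c(fsc = 4.0, ssc = 3.5, red_b = 1.2), dead_yellow = 2.5,
    debris_mean = c(fsc = 2.5, ssc = 2.0, red_b = 0.8), debris_yellow = 1.5,
    debris_sd = 0.5,
    debris_fraction = 0.05, dead_fraction = 0.10, doublet_fraction = 0.05,
    bead_offsets = rbind(`0.8` = c(0.12, 0.08, 0.05),
                         `2.4` = c(0, 0, 0),
                         `4` = c(-0.10, -0.06, -0.04)),
    bead_sd = 0.05,
    r_max = 1.2, K = 2e6, N0 = 2e4, growth_noise_sd = 0.1,
    acquisition_volume_ul = 35.4,
    max_events = 5000, min_events = 160) {
  stopifnot(length(baseline_mean) == 3, length(salinity_effect) == 3,
            length(within_cell_sd) == 3, length(day_phases) == 11)
  if (!all(day_phases %in% c("lag", "exponential", "stationary"))) {
    stop("`day_phases` entries must be lag/exponential/stationary", call. = FALSE)
  }
  fr <- c(debris_fraction, dead_fraction, doublet_fraction)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1) {
    stop("mixture fractions must each lie in [0, 1) and sum to < 1", call. = FALSE)
  }
  if (any(phase_gain < 0)) stop("`phase_gain` must be non-negative", call. = FALSE)
  stopifnot(N0 > 0, K > 0)
  colnames(bead_offsets) <- c("fsc", "ssc", "red_b")
  p <- as.list(environment())
  class(p) <- "generator_params"
  p
}

# Loop-shaped ontogenic offset for one day (0..10): day-indexed positions on a
# closed path so the start and end morphologies sit near each other while
# mid-assay days are displaced, as observed along the batch-culture ontogeny.
ontogeny_offset <- function(day, params) {
  theta <- 2 * pi * day / 11
  r <- params$ontogeny_amplitude
  cbind(fsc = r * (cos(theta) - 1),
        ssc = r * sin(theta),
        red_b = 0.5 * r * sin(theta))
}

phase_of_day <- function(day, params) params$day_phases[day + 1L]

# Per-line plasticity deviation: a reproducible draw keyed on the line id, so
# one line expresses the same deviation in every condition and every call.
line_effect <- function(line_id, params) {
  if (params$line_noise_sd == 0) return(0)
  h <- sum(utf8ToInt(line_id) * seq_along(utf8ToInt(line_id)))
  withr::with_seed(derive_seed(params$line_effect_seed, h),
                   rnorm(1, 0, params$line_noise_sd))
}

#' Generate the experimental design of an evolution study
#'
#' Assigns lines evenly to the four autocorrelation treatments (targets -0.5,
#' 0, 0.5, 0.9) and to the two ancestral strains, plus constant-salinity
#' control lines. Each fluctuating line receives its own simulated AR1
#' salinity history, from which the realized autocorrelation and predictability
#' rho^2 are computed, so that realized predictability spans a continuum of
#' values around the treatment targets.
#'
#' @param n_fluct Number of fluctuating-regime lines (default 32), divisible by
#'   the number of treatments.
#' @param n_const Number of constant-regime control lines (default 4).
#' @param n_transfers Length of each simulated salinity history (default 139).
#' @param treatments Target autocorrelations (default `c(-0.5, 0, 0.5, 0.9)`).
#' @param mu,sigma Stationary mean and SD of the salinity process.
#' @param seed Root seed; per-line seeds are derived deterministically.
#'
#' @return A tibble (one row per line) with columns `line_id`, `strain`
#'   (`"A"`/`"B"`, standing for the two ancestral strains), `regime`,
#'   `rho_bar` (treatment target; `NA` for constant lines), `realized_rho` and
#'   `predictability` (`NA` for constant lines). The simulated salinity series
#'   are attached as the `"series"` attribute (a named list).
#' @examples
#' d <- generate_design(n_fluct = 8, n_const = 2, seed = 1)
#' table(d$regime, d$rho_bar, useNA = "ifany")
#' @export
generate_design <- function(n_fluct = 32, n_const = 4, n_transfers = 139,
                            treatments = c(-0.5, 0, 0.5, 0.9),
                            mu = 2.4, sigma = 1, seed = 1) {
  if (n_fluct %% length(treatments) != 0) {
    stop("`n_fluct` must be divisible by the number of treatments", call. = FALSE)
  }
  n <- n_fluct + n_const
  per <- n_fluct / length(treatments)
  rho_bar <- c(rep(treatments, each = per), rep(NA_real_, n_const))
  regime <- c(rep("fluctuating", n_fluct), rep("constant", n_const))
  line_id <- sprintf("L%02d", seq_len(n))
  strain <- rep(c("A", "B"), length.out = n)

  series <- vector("list", n)
  names(series) <- line_id
  realized <- rep(NA_real_, n)
  for (i in seq_len(n_fluct)) {
    s <- simulate_salinity(n_transfers, rho = rho_bar[i], mu = mu, sigma = sigma,
                           seed = derive_seed(seed, i))
    series[[i]] <- s
    realized[i] <- attr(s, "realized_rho")
  }
  out <- tibble::tibble(
    line_id = line_id, strain = strain, regime = regime, rho_bar = rho_bar,
    realized_rho = realized,
    predictability = ifelse(regime == "constant", NA_real_, realized^2)
  )
  attr(out, "series") <- series
  out
}

#' Logistic growth trajectory with day-to-day noise
#'
#' Closed-form logistic density
#' \deqn{N(t) = K N_0 e^{r t} / (K + N_0 (e^{r t} - 1))}
#' evaluated at the given days, with multiplicative lognormal noise applied to
#' post-inoculation days. `N(0)` is the inoculation density (default 2e4
#' cells/ml, the density at which populations are transferred into the assay
#' salinities).
#'
#' @param params A [generator_params()] list (uses `r_max`, `K`, `N0`,
#'   `growth_noise_sd`).
#' @param days Integer days (default 0:10).
#' @param seed Optional seed for the noise.
#' @return A tibble with columns `day` and `cells_per_ml`.
#' @export
generate_growth_curve <- function(params = generator_params(), days = 0:10,
                                  seed = NULL) {
  r <- params$r_max; K <- params$K; N0 <- params$N0
  det <- K * N0 * exp(r * days) / (K + N0 * (exp(r * days) - 1))
  dens <- with_seed_or_not(seed, {
    noise <- ifelse(days == 0 | params$growth_noise_sd == 0, 1,
                    exp(rnorm(length(days), 0, params$growth_noise_sd)))
    det * noise
  })
  tibble::tibble(day = days, cells_per_ml = dens)
}

#' Generate per-cell cytometry events for one assay condition
#'
#' Draws a mixture of alive singlets, dead cells, debris and doublets on the
#' five log-scale channels (FSC, SSC, Red-B, Yellow-B, FSC-W). Alive-singlet
#' morphology is
#' `baseline + ontogeny(day) + sign(salinity - 2.4) * d/2 * salinity_effect`
#' with plasticity magnitude
#' `d = (plasticity_intercept + plasticity_slope * rho2) * phase_gain[phase(day)]`,
#' so the expected Euclidean distance between the 0.8 M and 4.0 M alive-singlet
#' means is `d * ||salinity_effect||`. All events are then shifted by the
#' per-salinity `bead_offsets`, emulating medium-density optical effects that
#' bead calibration later removes.
#'
#' @param line One row of a [generate_design()] tibble (data frame or list with
#'   `line_id`, `regime`, `predictability`).
#' @param assay_salinity One of 0.8, 2.4 or 4.0 (M NaCl).
#' @param day Assay day, 0..10.
#' @param n_events Number of events to draw.
#' @param params A [generator_params()] list.
#' @param seed Optional seed.
#' @return An event tibble with columns `line_id`, `salinity_M`, `day`, `fsc`,
#'   `ssc`, `red_b`, `yellow_b`, `fsc_w` and the true class in `.class`
#'   (dropped by [write_events_csv()]; downstream gating never reads it).
#' @export
generate_events <- function(line, assay_salinity, day, n_events,
                            params = generator_params(), seed = NULL) {
  if (is.data.frame(line)) line <- as.list(line[1, ])
  stopifnot(n_events >= 1)
  key <- as.character(assay_salinity)
  if (!key %in% rownames(params$bead_offsets)) {
    stop(sprintf("unknown assay salinity %s: expected one of %s", key,
                 paste(rownames(params$bead_offsets), collapse = ", ")),
         call. = FALSE)
  }
  if (!day %in% 0:10) stop("`day` must be in 0..10", call. = FALSE)
  rho2 <- if (identical(line$regime, "constant")) params$constant_rho2 else line$predictability
  if (is.null(rho2) || is.na(rho2)) stop("line predictability is missing", call. = FALSE)

  s <- sign(assay_salinity - 2.4)
  gain <- params$phase_gain[[phase_of_day(day, params)]]
  magnitude <- (params$plasticity_intercept + params$plasticity_slope * rho2 +
                  line_effect(line$line_id %||% "L01", params)) * gain
  alive_mean <- params$baseline_mean + drop(ontogeny_offset(day, params)) +
    s * magnitude * params$salinity_effect / 2
  offs <- params$bead_offsets[key, ]

  with_seed_or_not(seed, {
    cls <- sample(c("alive", "dead", "debris", "doublet"), n_events, replace = TRUE,
                  prob = c(1 - params$debris_fraction - params$dead_fraction -
                             params$doublet_fraction,
                           params$dead_fraction, params$debris_fraction,
                           params$doublet_fraction))
    n <- n_events
    m <- matrix(NA_real_, n, 3, dimnames = list(NULL, raw_channels()))
    yellow <- numeric(n)
    fsc_w <- numeric(n)

    a <- cls %in% c("alive", "doublet")
    if (any(a)) {
      m[a, ] <- rep(alive_mean, each = sum(a)) +
        matrix(rnorm(sum(a) * 3), ncol = 3) %*% diag(params$within_cell_sd)
      # doublets: twice the signal, i.e. +log10(2) on each log channel
      dbl <- cls == "doublet"
      m[dbl, ] <- m[dbl, ] + log10(2)
      yellow[a] <- rnorm(sum(a), params$yellow_alive_mean, params$yellow_sd)
      fsc_w[a] <- rnorm(sum(a), ifelse(cls[a] == "doublet",
                                       params$fsc_w_doublet, params$fsc_w_alive),
                        params$fsc_w_sd)
    }
    d <- cls == "dead"
    if (any(d)) {
      m[d, ] <- rep(params$dead_mean, each = sum(d)) +
        matrix(rnorm(sum(d) * 3), ncol = 3) %*% diag(params$within_cell_sd)
      yellow[d] <- rnorm(sum(d), params$dead_yellow, params$yellow_sd)
      fsc_w[d] <- rnorm(sum(d), params$fsc_w_alive, params$fsc_w_sd)
    }
    de <- cls == "debris"
    if (any(de)) {
      m[de, ] <- rep(params$debris_mean, each = sum(de)) +
        matrix(rnorm(sum(de) * 3, 0, params$debris_sd), ncol = 3)
      yellow[de] <- rnorm(sum(de), params$debris_yellow, params$yellow_sd)
      fsc_w[de] <- rnorm(sum(de), params$fsc_w_alive, params$fsc_w_sd)
    }
    m <- m + rep(offs, each = n)

    tibble::tibble(
      line_id = line$line_id %||% "L01",
      salinity_M = assay_salinity,
      day = day,
      fsc = m[, "fsc"], ssc = m[, "ssc"], red_b = m[, "red_b"],
      yellow_b = yellow, fsc_w = fsc_w,
      .class = cls
    )
  })
}

#' Generate a calibration-bead table for one assay salinity
#'
#' Beads suspended in medium at the assay salinity pick up the same
#' medium-density optical offset as cells; their per-channel means are later
#' subtracted from cell measurements by [bead_correct()].
#'
#' @inheritParams generate_events
#' @param n_beads Number of beads (default 1000, the calibration-kit count).
#' @return A tibble with columns `salinity_M`, `fsc`, `ssc`, `red_b`.
#' @export
generate_beads <- function(assay_salinity, n_beads = 1000,
                           params = generator_params(), seed = NULL) {
  stopifnot(n_beads >= 2)
  key <- as.character(assay_salinity)
  if (!key %in% rownames(params$bead_offsets)) {
    stop("unknown assay salinity for beads", call. = FALSE)
  }
  offs <- params$bead_offsets[key, ]
  with_seed_or_not(seed, {
    tibble::tibble(
      salinity_M = assay_salinity,
      fsc = rnorm(n_beads, offs["fsc"], params$bead_sd),
      ssc = rnorm(n_beads, offs["ssc"], params$bead_sd),
      red_b = rnorm(n_beads, offs["red_b"], params$bead_sd)
    )
  })
}

#' Generate a complete synthetic study
#'
#' Ties the design, growth curves, event tables and bead tables together into
#' one reproducible bundle. Event counts per condition follow the
#' density-limited acquisition rule (count = density x acquisition volume,
#' bounded by `min_events` and the cytometer's `max_events` stop) unless a
#' fixed `n_events` is supplied.
#'
#' @param design A [generate_design()] tibble.
#' @param params A [generator_params()] list.
#' @param days Assay days (default 0:10).
#' @param salinities Assay salinities (default `c(0.8, 2.4, 4.0)`).
#' @param n_events Optional fixed event count per condition; `NULL` (default)
#'   uses the density-limited rule.
#' @param seed Root seed; per-condition seeds are derived deterministically.
#' @return A list of class `synthetic_study` with elements `design`,
#'   `densities` (line x salinity x day), `events`, `beads` and `params`.
#' @examples
#' st <- generate_study(generate_design(n_fluct = 4, n_const = 0, seed = 1),
#'                      days = c(0, 10), salinities = c(0.8, 4.0),
#'                      n_events = 50, seed = 1)
#' dplyr::count(st$events, salinity_M, day)
#' @export
generate_study <- function(design = generate_design(), params = generator_params(),
                           days = 0:10, salinities = c(0.8, 2.4, 4.0),
                           n_events = NULL, seed = 1) {
  conds <- tidyr::expand_grid(line_id = design$line_id, salinity_M = salinities)
  k <- 0L
  densities <- purrr::pmap_dfr(conds, function(line_id, salinity_M) {
    k <<- k + 1L
    g <- generate_growth_curve(params, days = days, seed = derive_seed(seed, 1000L + k))
    tibble::tibble(line_id = line_id, salinity_M = salinity_M,
                   day = g$day, cells_per_ml = g$cells_per_ml)
  })

  frac_alive <- 1 - params$debris_fraction - params$dead_fraction
  events <- purrr::pmap_dfr(densities, function(line_id, salinity_M, day, cells_per_ml) {
    k <<- k + 1L
    n <- if (is.null(n_events)) {
      alive_seen <- cells_per_ml * params$acquisition_volume_ul / 1000
      max(params$min_events, min(params$max_events, round(alive_seen / frac_alive)))
    } else n_events
    line <- design[design$line_id == line_id, ]
    generate_events(line, salinity_M, day, n, params,
                    seed = derive_seed(seed, 10000L + k))
  })

  beads <- purrr::map_dfr(seq_along(salinities), function(i) {
    generate_beads(salinities[i], params = params, seed = derive_seed(seed, 99L + i))
  })

  structure(list(design = design, densities = densities, events = events,
                 beads = beads, params = params),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic plasticity study\n")
  cat(sprintf("  lines: %d (%d fluctuating, %d constant)\n",
              nrow(x$design), sum(x$design$regime == "fluctuating"),
              sum(x$design$regime == "constant")))
  cat(sprintf("  events: %d across %d conditions\n", nrow(x$events),
              nrow(dplyr::distinct(x$events, .data$line_id, .data$salinity_M, .data$day))))
  invisible(x)
}

#' Write study tables to CSV
#'
#' Writes the standard event-table dialect
#' (`line_id,salinity_M,day,fsc,ssc,red_b,yellow_b,fsc_w`; the generator's
#' hidden truth column is dropped), the bead table
#' (`salinity_M,fsc,ssc,red_b`), the design table and the density table.
#'
#' @param study A `synthetic_study` list.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    beads = file.path(dir, "beads.csv"),
    design = file.path(dir, "design.csv"),
    densities = file.path(dir, "densities.csv")
  )
  write_events_csv(study$events, paths["events"])
  readr::write_csv(study$beads, paths["beads"])
  readr::write_csv(study$design, paths["design"])
  readr::write_csv(study$densities, paths["densities"])
  invisible(paths)
}

#' @rdname write_study_csv
#' @param events An event tibble.
#' @param path Output file.
#' @export
write_events_csv <- function(events, path) {
  keep <- intersect(c("line_id", "salinity_M", "day",
                      "fsc", "ssc", "red_b", "yellow_b", "fsc_w"), names(events))
  readr::write_csv(events[keep], path)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
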