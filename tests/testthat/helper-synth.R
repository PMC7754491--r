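# Shared fixture builders (all in-code; nothing on disk).

# Minimal design tibble with controlled predictability values.
manual_design <- function(rho2, regime = "fluctuating",
                          strain = rep(c("A", "B"), length.out = length(rho2))) {
  tibble::tibble(
    line_id = sprintf("L%02d", seq_along(rho2)),
    strain = strain,
    regime = regime,
    rho_bar = NA_real_,
    realized_rho = ifelse(is.na(rho2), NA_real_, sqrt(rho2)),
    predictability = rho2
  )
}

# Corrected-cell table with known per-line plasticity distances: low-salinity
# cells centred at the origin, high-salinity cells displaced by `distance`
# along a unit direction, Gaussian noise `sd` per channel.
synth_cells <- function(distances, n = 60, sd = 0.1, day = 10, seed = 1) {
  dirn <- c(0.6, 0, 0.8)
  withr::with_seed(seed, {
    purrr::imap_dfr(distances, function(d, i) {
      id <- sprintf("L%02d", i)
      purrr::map_dfr(c(0.8, 4.0), function(s) {
        mu <- if (s == 4.0) d * dirn else c(0, 0, 0)
        tibble::tibble(
          line_id = id, salinity_M = s, day = day,
          fsc_c = rnorm(n, mu[1], sd),
          ssc_c = rnorm(n, mu[2], sd),
          red_b_c = rnorm(n, mu[3], sd)
        )
      })
    })
  })
}

# End-to-end synthetic assay for one day: simulate events, gate, bead-correct.
assay_cells <- function(design, params, day = 10, n_events = 200, seed = 1,
                        salinities = c(0.8, 4.0)) {
  study <- generate_study(design, params = params, days = day,
                          salinities = salinities, n_events = n_events,
                          seed = seed)
  study$events |>
    gate_alive() |>
    remove_doublets() |>
    bead_correct(study$beads)
}

# Brute-force sequential multivariate SS oracle: per-column univariate
# ANOVA decompositions summed across response columns.
oracle_sequential_r2 <- function(Y, metadata, formula_rhs) {
  f <- stats::as.formula(paste("y ~", formula_rhs))
  ss <- sapply(seq_len(ncol(Y)), function(j) {
    d <- cbind(data.frame(y = Y[, j]), metadata)
    stats::anova(stats::lm(f, data = d))[, "Sum Sq"]
  })
  tot <- rowSums(as.matrix(ss))
  tot / sum(tot)
}
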