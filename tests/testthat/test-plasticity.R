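test_that("plasticity distance is the L2 norm between mean vectors", {
  a <- data.frame(fsc_c = rnorm(20), ssc_c = rnorm(20), red_b_c = rnorm(20))
  expect_equal(plasticity_distance(a, a), 0)

  lo <- data.frame(fsc_c = 0, ssc_c = 0, red_b_c = 0)
  hi <- data.frame(fsc_c = 3, ssc_c = 4, red_b_c = 0)
  expect_equal(plasticity_distance(lo, hi), 5)
  expect_error(plasticity_distance(lo[0, ], hi), "at least one cell")
})

test_that("distance is shift-invariant and scales linearly", {
  withr::with_seed(1, {
    lo <- data.frame(fsc_c = rnorm(50), ssc_c = rnorm(50), red_b_c = rnorm(50))
    hi <- data.frame(fsc_c = rnorm(50, 1), ssc_c = rnorm(50), red_b_c = rnorm(50, 2))
  })
  d0 <- plasticity_distance(lo, hi)
  shift <- function(df, v) as.data.frame(sweep(as.matrix(df), 2, -v))
  expect_equal(plasticity_distance(shift(lo, c(3, -1, 7)), shift(hi, c(3, -1, 7))),
               d0, tolerance = 1e-12)
  expect_equal(plasticity_distance(lo * 2.5, hi * 2.5), 2.5 * d0,
               tolerance = 1e-12)
})

test_that("distance recovers the generator's constructed mean shift", {
  # construction: shift (0.6, 0, 0.8) -> distance 1
  cells <- synth_cells(1, n = 1e4, sd = 0.3, seed = 2)
  d <- plasticity_distances(cells)
  se <- sqrt(2 * 3 * 0.3^2 / 1e4)
  expect_equal(d$distance, 1, tolerance = 3 * se)
})

test_that("regression on predictability excludes constant lines", {
  rho2 <- c(seq(0, 0.81, length.out = 8), NA, NA)
  des <- manual_design(rho2, regime = c(rep("fluctuating", 8), rep("constant", 2)))
  records <- tibble::tibble(line_id = des$line_id,
                            distance = ifelse(is.na(rho2), 5, 0.5 + 2 * rho2))
  fit <- suppressWarnings(regress_on_predictability(records, des))
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$constant_mean, 5)
  expect_equal(nrow(fit$data), 8) # constant lines never enter the fit

  flat <- dplyr::mutate(records, distance = 1)
  expect_equal(suppressWarnings(regress_on_predictability(flat, des))$slope, 0)
  expect_error(regress_on_predictability(records,
                                         dplyr::mutate(des, predictability = 0.4)),
               "zero variance")

  td <- suppressWarnings(tidy(fit)) # exact fixture data: summary warns
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(glance(fit)$slope, 2, tolerance = 1e-10)
})

test_that("hierarchical bootstrap is seeded, centred on the observed slope", {
  des <- manual_design(seq(0.05, 0.8, length.out = 8))
  cells <- synth_cells(0.5 + 2 * des$predictability, n = 120, sd = 0.2, seed = 3)
  b1 <- hierarchical_bootstrap(cells, des, day = 10, B = 300, n_cells = 100,
                               seed = 11)
  b2 <- hierarchical_bootstrap(cells, des, day = 10, B = 300, n_cells = 100,
                               seed = 11)
  expect_identical(b1$slopes, b2$slopes)
  expect_equal(length(b1$slopes), 300)
  # replicate slopes centre near the observed slope
  expect_lt(abs(mean(b1$slopes) - b1$slope_obs), 2 * sd(b1$slopes))
  expect_lt(b1$p_one_sided, 0.05)
  # per-line output is tidy-able
  expect_named(tidy(b1), c("line_id", "predictability", "distance", "se"))
  expect_true(all(tidy(b1)$se > 0))
  expect_equal(glance(b1)$p_slope_gt_0, 1 - b1$p_one_sided)
})

test_that("zero-variance cells give a degenerate flat bootstrap", {
  des <- manual_design(c(0.1, 0.3, 0.5, 0.8))
  cells <- synth_cells(c(1, 1, 1, 1), n = 30, sd = 0, seed = 4)
  w <- capture_warnings(
    b <- hierarchical_bootstrap(cells, des, day = 10, B = 50, n_cells = 20,
                                seed = 5))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(b$slopes[is.finite(b$slopes)] == 0))
  expect_equal(b$p_one_sided, 1) # slopes <= 0 convention
  expect_true(b$degenerate)
})

test_that("expected distance is non-decreasing in predictability when slope >= 0", {
  des <- manual_design(seq(0, 0.81, length.out = 12))
  p <- generator_params(plasticity_slope = 1.5)
  cells <- assay_cells(des, p, day = 10, n_events = 400, seed = 6)
  d <- plasticity_distances(cells)
  d <- d[match(des$line_id, d$line_id), ]
  fit <- lm(d$distance ~ des$predictability)
  expect_gt(coef(fit)[2], 0)
  # ranks broadly follow rho2
  expect_gt(cor(d$distance, des$predictability, method = "spearman"), 0.8)
})

test_that("per-day slope profile mirrors the phase-dependent construction", {
  des <- manual_design(seq(0.02, 0.8, length.out = 8))
  p <- generator_params(phase_gain = c(lag = 1, exponential = 0, stationary = 1))
  study <- generate_study(des, params = p, days = c(2, 3, 10),
                          salinities = c(0.8, 4.0), n_events = 250, seed = 7)
  cells <- study$events |> gate_alive() |> remove_doublets() |>
    bead_correct(study$beads)
  prof <- slope_profile_by_day(cells, des, days = c(2, 3, 10), B = 200,
                               n_cells = 150, seed = 8)
  expect_s3_class(prof, "slope_profile")
  # day 3 is exponential with zero gain: slope indistinguishable from zero
  d3 <- prof[prof$day == 3, ]
  expect_true(d3$slope_lo <= 0 && d3$slope_hi >= 0)
  # lag / stationary days carry the constructed positive slope
  expect_lt(prof$p_one_sided[prof$day == 2], 0.05)
  expect_lt(prof$p_one_sided[prof$day == 10], 0.05)

  # B = 1 is a single deterministic draw under the seed
  p1 <- slope_profile_by_day(cells, des, days = 10, B = 1, seed = 9)
  p2 <- slope_profile_by_day(cells, des, days = 10, B = 1, seed = 9)
  expect_identical(p1$slope_mean, p2$slope_mean)
})

test_that("group comparison is null for identical groups, extreme for disjoint ones", {
  des <- manual_design(rep(0.5, 6))
  cells <- synth_cells(c(1, 1.1, 0.9, 1, 1.05, 0.95), n = 80, sd = 0.2, seed = 10)
  same <- compare_groups(cells, des, des$line_id[1:3], des$line_id[1:3],
                         B = 200, n_cells = 80, seed = 11)
  expect_equal(same$diff_obs, 0)
  expect_gt(same$p_two_sided, 0.5)

  apart <- synth_cells(c(0.2, 0.2, 0.2, 3, 3, 3), n = 80, sd = 0.1, seed = 12)
  sep <- compare_groups(apart, des, des$line_id[1:3], des$line_id[4:6],
                        B = 200, n_cells = 80, seed = 13)
  expect_equal(sep$p_two_sided, 0) # complete separation: smallest attainable
  expect_lt(sep$diff_obs, 0)
  expect_named(glance(sep), c("difference", "mean_a", "mean_b", "std.error",
                              "p.value", "B"))
})
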