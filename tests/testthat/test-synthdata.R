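test_that("design assigns lines evenly to treatments and strains", {
  d <- generate_design(seed = 1)
  expect_equal(nrow(d), 36)
  expect_equal(sum(d$regime == "constant"), 4)
  expect_equal(as.vector(table(d$rho_bar)), rep(8L, 4))
  expect_equal(as.vector(table(d$strain)), c(18L, 18L))
  expect_true(all(is.na(d$predictability[d$regime == "constant"])))
  fl <- d[d$regime == "fluctuating", ]
  expect_equal(fl$predictability, fl$realized_rho^2)

  d1 <- generate_design(n_fluct = 4, n_const = 0, seed = 2)
  expect_equal(sort(d1$rho_bar), c(-0.5, 0, 0.5, 0.9))
  expect_error(generate_design(n_fluct = 6), "divisible")
})

test_that("design is deterministic under its seed", {
  expect_identical(generate_design(n_fluct = 8, seed = 3),
                   generate_design(n_fluct = 8, seed = 3))
})

test_that("growth curve follows the closed-form logistic", {
  p0 <- generator_params(r_max = 0, growth_noise_sd = 0)
  expect_equal(generate_growth_curve(p0)$cells_per_ml, rep(2e4, 11))

  p <- generator_params(r_max = 1, K = 1e6, N0 = 2e4, growth_noise_sd = 0)
  g <- generate_growth_curve(p, days = 0:1)
  expect_equal(g$cells_per_ml[2], 1e6 * 2e4 * exp(1) / (1e6 + 2e4 * (exp(1) - 1)))

  g_long <- generate_growth_curve(p, days = c(0, 50))
  expect_equal(g_long$cells_per_ml[2], 1e6, tolerance = 1e-6)
})

test_that("a clean generator produces only events that pass gating", {
  p <- generator_params(debris_fraction = 0, dead_fraction = 0,
                        doublet_fraction = 0)
  d <- manual_design(0.5)
  ev <- generate_events(d[1, ], 2.4, 5, 2000, p, seed = 1)
  expect_equal(nrow(gate_alive(ev)), 2000)
  expect_equal(nrow(remove_doublets(ev)), 2000)
})

test_that("alive-singlet mean shift matches the constructed plasticity", {
  # with slope 0 and flat ontogeny, the low-vs-high mean difference has norm
  # intercept * phase_gain * ||salinity_effect||
  p <- generator_params(plasticity_slope = 0, plasticity_intercept = 0.8,
                        line_noise_sd = 0, # exact construction, no line effect
                        ontogeny_amplitude = 0, debris_fraction = 0,
                        dead_fraction = 0, doublet_fraction = 0)
  d <- manual_design(0.3)
  n <- 1e5
  lo <- generate_events(d[1, ], 0.8, 10, n, p, seed = 1)
  hi <- generate_events(d[1, ], 4.0, 10, n, p, seed = 2)
  # remove the bead offsets the generator adds, as the pipeline would
  lo_c <- bead_correct(lo, generate_beads(0.8, 5000, p, seed = 3))
  hi_c <- bead_correct(hi, generate_beads(4.0, 5000, p, seed = 4))
  gain <- p$phase_gain[["stationary"]]
  expected <- 0.8 * gain * sqrt(sum(p$salinity_effect^2))
  got <- plasticity_distance(lo_c, hi_c)
  se <- sqrt(2 * 3 * 0.3^2 / n) # crude SE of a 3-channel mean-difference norm
  expect_equal(got, expected, tolerance = 5 * se / expected)

  # a phase with zero gain shows no salinity effect at all
  p0 <- generator_params(phase_gain = c(lag = 0, exponential = 0, stationary = 0),
                         ontogeny_amplitude = 0, debris_fraction = 0,
                         dead_fraction = 0, doublet_fraction = 0)
  lo0 <- generate_events(d[1, ], 0.8, 10, 2e4, p0, seed = 5)
  hi0 <- generate_events(d[1, ], 4.0, 10, 2e4, p0, seed = 6)
  lo0_c <- bead_correct(lo0, generate_beads(0.8, 5000, p0, seed = 7))
  hi0_c <- bead_correct(hi0, generate_beads(4.0, 5000, p0, seed = 8))
  expect_lt(plasticity_distance(lo0_c, hi0_c), 0.02)
})

test_that("unknown assay salinity is rejected", {
  expect_error(generate_events(manual_design(0.5)[1, ], 1.6, 5, 10), "unknown")
  expect_error(generate_beads(1.6), "unknown")
})

test_that("beads centre on the configured offsets and are reproducible", {
  p <- generator_params()
  b <- generate_beads(0.8, 1000, p, seed = 1)
  expect_equal(nrow(b), 1000)
  expect_equal(colMeans(b[c("fsc", "ssc", "red_b")]),
               c(fsc = 0.12, ssc = 0.08, red_b = 0.05), tolerance = 0.01)
  expect_identical(b, generate_beads(0.8, 1000, p, seed = 1))

  p0 <- generator_params(bead_offsets = matrix(0, 3, 3,
                                               dimnames = list(c("0.8", "2.4", "4"), NULL)))
  b0 <- generate_beads(2.4, 2000, p0, seed = 2)
  expect_equal(colMeans(b0[c("fsc", "ssc", "red_b")]),
               c(fsc = 0, ssc = 0, red_b = 0), tolerance = 0.01)
})

test_that("bead correction cancels the generator's salinity offsets", {
  d <- manual_design(0.5)
  base <- generator_params(debris_fraction = 0, dead_fraction = 0,
                           doublet_fraction = 0)
  shifted <- generator_params(debris_fraction = 0, dead_fraction = 0,
                              doublet_fraction = 0,
                              bead_offsets = rbind(`0.8` = c(0.9, -0.4, 0.6),
                                                   `2.4` = c(0, 0, 0),
                                                   `4` = c(-0.7, 0.5, -0.3)))
  n <- 1e5
  get_means <- function(p, seed_ev, seed_bd) {
    ev <- generate_events(d[1, ], 0.8, 10, n, p, seed = seed_ev)
    cc <- bead_correct(ev, generate_beads(0.8, 5000, p, seed = seed_bd))
    colMeans(cc[c("fsc_c", "ssc_c", "red_b_c")])
  }
  m_base <- get_means(base, 1, 2)
  m_shift <- get_means(shifted, 1, 2)
  se3 <- 3 * 0.3 / sqrt(n)
  expect_true(all(abs(m_base - m_shift) < 3 * se3 + 3 * 0.05 / sqrt(5000)))
})

test_that("study generation is deterministic and density-limited", {
  d <- generate_design(n_fluct = 4, n_const = 0, seed = 1)
  st1 <- generate_study(d, days = c(0, 10), salinities = c(0.8, 4.0),
                        n_events = 100, seed = 4)
  st2 <- generate_study(d, days = c(0, 10), salinities = c(0.8, 4.0),
                        n_events = 100, seed = 4)
  expect_identical(st1$events, st2$events)
  expect_equal(nrow(st1$events), 4 * 2 * 2 * 100)

  # density-limited rule: counts bounded by min_events and max_events
  st3 <- generate_study(d[1, ], days = c(0, 10), salinities = 2.4, seed = 5)
  counts <- dplyr::count(st3$events, day)$n
  expect_true(all(counts >= 150))
  expect_true(all(counts <= st3$params$max_events))
  expect_lt(counts[1], counts[2]) # day 0 density-limited, day 10 near cap
})

test_that("event class mixture matches the configured fractions", {
  p <- generator_params() # 5% debris, 10% dead, 5% doublets
  ev <- generate_events(manual_design(0.5)[1, ], 2.4, 5, 2e4, p, seed = 9)
  frac <- table(ev$.class) / nrow(ev)
  expect_lt(abs(frac[["dead"]] - 0.10), 0.01)
  expect_lt(abs(frac[["debris"]] - 0.05), 0.01)
  expect_lt(abs(frac[["doublet"]] - 0.05), 0.01)
})

test_that("study CSV round-trips through the standard dialect", {
  d <- generate_design(n_fluct = 4, n_const = 0, seed = 1)
  st <- generate_study(d, days = 10, salinities = c(0.8, 4.0), n_events = 30,
                       seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_study_csv(st, dir)
  ev <- read_events_csv(paths[["events"]])
  expect_named(ev, c("line_id", "salinity_M", "day", "fsc", "ssc", "red_b",
                     "yellow_b", "fsc_w"))
  expect_equal(nrow(ev), nrow(st$events))
  expect_equal(ev$fsc, st$events$fsc, tolerance = 1e-9)
})
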