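test_that("PCA recovers a known diagonal covariance", {
  withr::with_seed(1, {
    x <- data.frame(fsc_c = rnorm(5000, 0, 2), ssc_c = rnorm(5000, 0, 1),
                    red_b_c = rnorm(5000, 0, 0.5))
  })
  m <- pca_morphospace(x)
  expect_equal(m$sdev^2, c(4, 1, 0.25), tolerance = 0.1)
  # axes align with the original channels; sign convention fixes orientation
  expect_equal(abs(m$loadings["fsc_c", 1]), 1, tolerance = 0.01)
  expect_true(all(apply(m$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  # centred scores: the mean projects to the origin
  expect_equal(colMeans(as.matrix(m$scores[c("PC1", "PC2", "PC3")])),
               c(PC1 = 0, PC2 = 0, PC3 = 0), tolerance = 1e-12)
})

test_that("collinear channels collapse onto fewer components", {
  withr::with_seed(2, {
    a <- rnorm(100)
    x <- data.frame(fsc_c = a, ssc_c = 2 * a, red_b_c = rnorm(100, 0, 0.1))
  })
  m <- pca_morphospace(x)
  expect_lt(m$sdev[3]^2, 1e-20)
})

test_that("condition centroids average cells then lines", {
  cells <- synth_cells(c(1, 1), n = 40, sd = 0.05)
  m <- pca_morphospace(cells)
  cent <- condition_centroids(m$scores)
  expect_equal(nrow(cent), 4) # 2 lines x 2 salinities x 1 day
  one <- cells[cells$line_id == "L01" & cells$salinity_M == 0.8, ]
  expect_equal(cent$PC1[cent$line_id == "L01" & cent$salinity_M == 0.8],
               mean(m$scores$PC1[m$scores$line_id == "L01" &
                                   m$scores$salinity_M == 0.8]))

  # two lines with centroids c and -c average to zero at treatment level
  sc <- tibble::tibble(line_id = rep(c("A1", "A2"), each = 10),
                       salinity_M = 0.8, day = 1,
                       PC1 = rep(c(2, -2), each = 10),
                       PC2 = rep(c(-1, 1), each = 10))
  des <- tibble::tibble(line_id = c("A1", "A2"), regime = "fluctuating",
                        rho_bar = 0.5)
  tc <- condition_centroids(sc, des)
  expect_equal(tc$PC1, 0)
  expect_equal(tc$PC2, 0)
  expect_equal(tc$n_lines, 2)

  # single line per treatment: SE undefined, flagged NA
  tc1 <- condition_centroids(sc[1:10, ], des[1, ])
  expect_true(is.na(tc1$se_PC1))
})

test_that("day-ordered centroids trace the generator's closed ontogenic loop", {
  d <- manual_design(0.5)
  p <- generator_params(debris_fraction = 0, dead_fraction = 0,
                        doublet_fraction = 0)
  st <- generate_study(d, params = p, days = 0:10, salinities = 2.4,
                       n_events = 300, seed = 6)
  cells <- bead_correct(st$events, st$beads)
  cent <- condition_centroids(pca_morphospace(cells)$scores)
  cent <- cent[order(cent$day), ]
  pos <- as.matrix(cent[c("PC1", "PC2")])
  d_start_end <- sqrt(sum((pos[1, ] - pos[11, ])^2))
  d_start_mid <- sqrt(sum((pos[1, ] - pos[6, ])^2))
  expect_lt(d_start_end, d_start_mid)
})

test_that("design terms carry the expected degrees of freedom", {
  md_f <- tidyr::expand_grid(strain = c("A", "B"), day = 1:10,
                             salinity = c(0.8, 2.4, 4.0)) |>
    dplyr::mutate(growth_rate = rnorm(dplyr::n()),
                  predictability = runif(dplyr::n()))
  des_f <- build_design(md_f, regime = "fluctuating")
  expect_equal(vapply(des_f, `[[`, 0L, "df"),
               c(strain = 1L, growth_rate = 1L, day = 9L, salinity = 2L,
                 predictability = 1L, `salinity:predictability` = 2L,
                 `day:salinity` = 18L, `day:predictability` = 9L,
                 `day:salinity:predictability` = 18L))

  md_c <- tidyr::expand_grid(strain = c("A", "B"), day = 1:10,
                             salinity = c(0.8, 4.0)) |>
    dplyr::mutate(growth_rate = rnorm(dplyr::n()))
  des_c <- build_design(md_c, regime = "constant")
  expect_equal(vapply(des_c, `[[`, 0L, "df"),
               c(strain = 1L, growth_rate = 1L, day = 9L, salinity = 1L,
                 `day:salinity` = 9L))

  # a single categorical with L levels contributes L - 1 columns
  md1 <- data.frame(g = letters[rep(1:5, 3)])
  expect_equal(build_design(md1, terms = "g")$g$df, 4L)

  expect_error(build_design(data.frame(day = c(1, NA)), terms = "day"), "NA")
})

test_that("a perfectly explained response leaves zero residual share", {
  withr::with_seed(3, {
    md <- data.frame(g = rep(c("a", "b", "c"), each = 5))
    X <- stats::model.matrix(~g, md)
    B <- matrix(rnorm(9), 3, 3)
    Y <- X %*% B
  })
  part <- rda_partition(Y, build_design(md, terms = "g"), n_perm = 0)
  df <- as.data.frame(part)
  expect_equal(df$r2[df$term == "g"], 1, tolerance = 1e-12)
  expect_equal(df$r2[df$term == "Residual"], 0, tolerance = 1e-12)
})

test_that("sequential shares equal the brute-force SS decomposition", {
  # one 2-level factor on a 6 x 3 toy matrix: between-group SS over total SS
  withr::with_seed(4, {
    md <- data.frame(g = rep(c("lo", "hi"), each = 3))
    Y <- matrix(rnorm(18), 6, 3)
  })
  part <- as.data.frame(rda_partition(Y, build_design(md, terms = "g"),
                                      n_perm = 0))
  between <- sum(sapply(1:3, function(j) {
    m <- tapply(Y[, j], md$g, mean)
    sum(3 * (m - mean(Y[, j]))^2)
  }))
  total <- sum(scale(Y, scale = FALSE)^2)
  expect_equal(part$r2[part$term == "g"], between / total, tolerance = 1e-12)
})

test_that("term and residual shares always sum to one", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(10:30, 1)
      md <- data.frame(g = sample(c("a", "b", "c"), n, replace = TRUE),
                       x = rnorm(n))
      Y <- matrix(rnorm(3 * n), n, 3)
    })
    part <- as.data.frame(rda_partition(Y, build_design(md, terms = c("g", "x")),
                                        n_perm = 0))
    expect_equal(sum(part$r2[part$term != "Total"]), 1, tolerance = 1e-10)
  }
})

test_that("total explained variation is invariant to term order", {
  withr::with_seed(5, {
    md <- data.frame(g = rep(c("a", "b"), 10), x = rnorm(20))
    Y <- matrix(rnorm(60), 20, 3) + md$x
  })
  p1 <- as.data.frame(rda_partition(Y, build_design(md, terms = c("g", "x")),
                                    n_perm = 0))
  p2 <- as.data.frame(rda_partition(Y, build_design(md, terms = c("x", "g")),
                                    n_perm = 0))
  expect_equal(p1$r2[p1$term == "Residual"], p2$r2[p2$term == "Residual"],
               tolerance = 1e-10)
  # but the sequential attribution itself differs when predictors correlate
})

test_that("partition agrees with vegan's RDA term decomposition", {
  skip_if_not_installed("vegan")
  withr::with_seed(6, {
    md <- data.frame(g = rep(c("a", "b", "c"), each = 8), x = rnorm(24))
    Y <- matrix(rnorm(72), 24, 3) + 0.5 * md$x
  })
  ours <- as.data.frame(rda_partition(Y, build_design(md, terms = c("g", "x")),
                                      n_perm = 0))
  v <- vegan::rda(Y ~ g + x, data = md)
  av <- suppressWarnings(vegan::anova.cca(v, by = "terms", permutations = 19))
  expect_equal(ours$variance[1:2], av$Variance[1:2], tolerance = 1e-8)
  expect_equal(ours$variance[ours$term == "Residual"],
               av$Variance[3], tolerance = 1e-8)
})

test_that("marginal shares match sequential for orthogonal last terms", {
  withr::with_seed(7, {
    md <- data.frame(x = rnorm(30))
    Y <- matrix(rnorm(90), 30, 3)
  })
  part <- rda_partition(Y, build_design(md, terms = "x"), n_perm = 0,
                        marginal = TRUE)
  df <- as.data.frame(part)
  expect_equal(df$r2_marginal[1], df$r2[1], tolerance = 1e-10)
})

test_that("a strong effect reaches the smallest attainable permutation p", {
  withr::with_seed(8, {
    md <- data.frame(g = rep(c("a", "b"), each = 15))
    Y <- matrix(rnorm(90, sd = 0.1), 30, 3)
    Y[md$g == "b", ] <- Y[md$g == "b", ] + 5
  })
  part <- as.data.frame(rda_partition(Y, build_design(md, terms = "g"),
                                      n_perm = 999, seed = 1))
  expect_equal(part$p[part$term == "g"], 1 / 1000)
})

test_that("rank-deficient added terms get reduced df with a warning", {
  md <- data.frame(g = rep(c("a", "b"), each = 4),
                   h = rep(c("x", "y"), each = 4)) # h duplicates g
  Y <- matrix(rnorm(24), 8, 3)
  expect_warning(part <- rda_partition(Y, build_design(md, terms = c("g", "h")),
                                       n_perm = 0), "collinearity")
  df <- as.data.frame(part)
  expect_equal(df$df[df$term == "h"], 0)
})
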