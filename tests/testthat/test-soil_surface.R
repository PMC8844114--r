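test_that("sampling design arithmetic and offset geometry", {
  d <- design_soil_grid(c(500, 400), seed = 51)
  expect_equal(attr(d, "n_grid"), 238) # 17 x 14 grid at 30 m
  expect_equal(attr(d, "n_planned"), 714)
  expect_equal(nrow(d), 714)
  # offsets sit at exactly 2, 5 or 15 m from their parent before clipping
  off <- d[d$type == "offset", ]
  parents <- d[d$type == "grid", ]
  raw_x <- parents$x[off$parent] + off$offset_dist * cos(off$bearing)
  raw_y <- parents$y[off$parent] + off$offset_dist * sin(off$bearing)
  dist_raw <- sqrt((raw_x - parents$x[off$parent])^2 +
                   (raw_y - parents$y[off$parent])^2)
  expect_true(all(abs(dist_raw - off$offset_dist) < 1e-9))
  expect_true(all(off$offset_dist %in% c(2, 5, 15)))
  # all points inside the half-open plot
  expect_true(all(d$x >= 0 & d$x < 500 & d$y >= 0 & d$y < 400))
  # seeded layout reproducible
  expect_identical(design_soil_grid(c(500, 400), seed = 51), d)
})

test_that("variogram fitting recovers known exponential parameters", {
  # simulate directly from the model via Cholesky of the exact covariance,
  # on a grid-plus-offsets layout: the close pairs identify the nugget
  set.seed(52)
  d <- design_soil_grid(c(1500, 1200), spacing = 90)
  xy <- cbind(d$x, d$y)
  nugget <- 0.5
  psill <- 2
  rng <- 50
  C <- psill * exp(-as.matrix(dist(xy)) / rng) + diag(nugget, nrow(xy))
  z <- as.vector(crossprod(chol(C), rnorm(nrow(xy))))
  fit <- fit_variogram(data.frame(x = xy[, 1], y = xy[, 2], v = z), "v",
                       model = "exponential")
  expect_lt(abs(fit$nugget - nugget) / nugget, 0.25)
  expect_lt(abs(fit$psill - psill) / psill, 0.25)
  expect_lt(abs(fit$range - rng) / rng, 0.25)
})

test_that("pure-nugget data yield a flat variogram, sill near variance", {
  set.seed(53)
  n <- 400
  df <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300),
                   v = rnorm(n, sd = 2))
  ev <- empirical_variogram(df[, c("x", "y")], df$v)
  # no trend across lags: among well-populated bins, semivariance stays
  # within 25% of the variance at both ends
  ev <- ev[ev$n >= 50, ]
  expect_lt(abs(ev$gamma[1] - ev$gamma[nrow(ev)]) / var(df$v), 0.25)
  fit <- fit_variogram(df, "v")
  expect_lt(abs(fit$sill - var(df$v)) / var(df$v), 0.25)
  expect_error(fit_variogram(data.frame(x = 1:40, y = 1:40, v = 1), "v"),
               "zero variance")
})

test_that("kriging reproduces constants and interpolates exactly", {
  g <- quadrat_grid(c(20, 20), 5)
  set.seed(54)
  samples <- data.frame(x = runif(12, 0, 20), y = runif(12, 0, 20))
  vgm <- list(model = "spherical", nugget = 0.4, psill = 2, range = 12)
  # constant field: weights sum to 1 so prediction is the constant
  samples$c7 <- rep(7, 12)
  expect_equal(krige(samples, "c7", g, vgm)$values, rep(7, 16))
  # zero nugget: prediction at a sample location equals the sample value
  vgm0 <- list(model = "exponential", nugget = 0, psill = 1.5, range = 8)
  samples$v <- rnorm(12)
  samples$x[1] <- 2.5 # quadrat centre (0,0) is at (2.5, 2.5)
  samples$y[1] <- 2.5
  pred <- krige(samples, "v", g, vgm0)
  expect_equal(pred$values[1], samples$v[1], tolerance = 1e-8)
})

test_that("kriging matches the direct linear-system oracle", {
  set.seed(55)
  g <- quadrat_grid(c(30, 20), 10)
  samples <- data.frame(x = c(3, 25, 14, 8, 27), y = c(4, 6, 15, 18, 17),
                        v = c(1.2, -0.5, 3.1, 0.4, 2.2))
  vgm <- list(model = "spherical", nugget = 0.3, psill = 1.8, range = 15)
  pred <- krige(samples, "v", g, vgm)
  ctr <- quadrat_centers(g)
  for (q in seq_len(n_quadrats(g))) {
    expect_equal(pred$values[q],
                 ok_oracle(samples$x, samples$y, samples$v,
                           ctr$x[q], ctr$y[q], vgm),
                 tolerance = 1e-9)
  }
})

test_that("kriging is linear in the sample values", {
  set.seed(56)
  g <- quadrat_grid(c(40, 40), 20)
  samples <- data.frame(x = runif(20, 0, 40), y = runif(20, 0, 40),
                        v = rnorm(20))
  samples$w <- 3 * samples$v - 2
  vgm <- list(model = "gaussian", nugget = 0.2, psill = 1, range = 10)
  pv <- krige(samples, "v", g, vgm)$values
  pw <- krige(samples, "w", g, vgm)$values
  expect_equal(pw, 3 * pv - 2, tolerance = 1e-8)
})

test_that("soil_summary recomputes mean and SD per field", {
  g <- quadrat_grid(c(20, 10), 5)
  f1 <- grid_field(g, "AP", rep(1.8, 8))
  f2 <- grid_field(g, "AK", c(1:8))
  tab <- soil_summary(list(f1, f2))
  expect_equal(tab$sd[1], 0)
  expect_equal(tab$mean[2], mean(1:8))
  expect_equal(tab$sd[2], sd(1:8))
})

test_that("smooth-field means are nearly scale-invariant", {
  st <- tiny_study()
  vg <- fit_variogram(st$soil_samples, "OM")
  means <- vapply(c(10, 20, 50), function(sc) {
    mean(krige(st$soil_samples, "OM", quadrat_grid(c(300, 200), sc),
               vg)$values)
  }, numeric(1))
  expect_lt(max(means) - min(means), 0.02 * mean(means))
})
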