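test_that("standardize_traits centres, scales, and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_traits(m)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(s), c(a = 0, b = 0))
  expect_equal(apply(s, 2, sd), c(a = 1, b = 1))
  expect_equal(unname(standardize_traits(s)), unname(s))

  m2 <- cbind(a = c(1, 2, 3), flat = c(4, 4, 4))
  expect_error(standardize_traits(m2), "flat")
})

test_that("trait_distance is Euclidean, symmetric, zero-diagonal", {
  m <- rbind(s1 = c(0, 0), s2 = c(3, 4))
  attr(m, "standardized") <- TRUE
  d <- trait_distance(m)
  expect_equal(d["s1", "s2"], 5)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))

  set.seed(31)
  m5 <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), NULL))
  attr(m5, "standardized") <- TRUE
  d5 <- trait_distance(m5)
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(d5[i, j], sqrt(sum((m5[i, ] - m5[j, ])^2)))
    }
  }
  expect_equal(d5, t(d5))
})

test_that("pcoa_embed reproduces Euclidean input exactly, no correction", {
  set.seed(32)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  d <- as.matrix(dist(X))
  sp <- pcoa_embed(d)
  expect_equal(sp$correction, "none")
  expect_lt(max(abs(as.matrix(dist(sp$points)) - d)), 1e-8)
  expect_true(all(diff(sp$eig) <= 1e-12))
})

test_that("equilateral triangle gives two equal eigenvalues 0.5", {
  d <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  sp <- pcoa_embed(d)
  expect_equal(length(sp$eig), 2)
  expect_equal(sp$eig, c(0.5, 0.5))
})

test_that("non-Euclidean distances are corrected and recorded", {
  d <- matrix(1, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 2.5 # violates the triangle inequality
  # eigen-decomposition oracle: double-centred Gower matrix has a negative
  # eigenvalue, so a correction is required
  A <- -0.5 * d^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  expect_lt(min(eigen(G, symmetric = TRUE)$values), -1e-8)
  sp <- pcoa_embed(d)
  expect_equal(sp$correction, "cailliez")
  emb <- as.matrix(dist(sp$points))
  expect_true(all(emb >= d - 1e-8)) # Cailliez adds a positive constant
  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("fdis matches hand cases and the weighted-centroid oracle", {
  expect_equal(fdis(matrix(c(2, 7), 1, 2), 5), 0)
  expect_equal(fdis(matrix(c(-1, 1), 2, 1), c(3, 3)), 1)
  expect_true(is.na(fdis(matrix(0, 2, 1), c(0, 0))))

  coords <- rbind(c(0, 0), c(1, 0), c(0, 2), c(2, 2))
  a <- c(1, 2, 3, 4)
  expect_equal(fdis(coords, a), fdis_oracle(coords, a))

  set.seed(33)
  for (i in 1:25) {
    cm <- random_community()
    expect_equal(fdis(cm$coords, cm$abund), fdis_oracle(cm$coords, cm$abund),
                 tolerance = 1e-12)
  }
})

test_that("fdis invariances: abundance rescaling, rotation, centroid point", {
  set.seed(34)
  cm <- random_community(10, 3)
  base <- fdis(cm$coords, cm$abund)
  # relative-abundance property
  expect_equal(fdis(cm$coords, 7.3 * cm$abund), base)
  # rigid rotation of coordinates
  qr_ <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(fdis(cm$coords %*% qr_, cm$abund), base)
  # adding a species at the weighted centroid never increases FDis
  keep <- cm$abund > 0
  ctr <- colSums(cm$coords[keep, , drop = FALSE] * cm$abund[keep]) /
    sum(cm$abund)
  for (a_new in c(0.5, 2, 10)) {
    expect_lte(fdis(rbind(cm$coords, ctr), c(cm$abund, a_new)), base + 1e-12)
  }
})

test_that("1-D FDis equals the abundance-weighted MAD", {
  set.seed(35)
  for (i in 1:10) {
    x <- rnorm(6)
    a <- rpois(6, 3) + 1
    expect_equal(fdis(matrix(x), a), wmad_oracle(x, a), tolerance = 1e-12)
  }
})

test_that("dispersion_map agrees with per-quadrat oracle calls", {
  st <- tiny_study()
  traits <- standardize_traits(st$traits)
  space <- pcoa_embed(trait_distance(traits))
  comm <- make_grid(st$census, 50)
  map <- dispersion_map(comm, space)
  X <- space$points[comm$species, , drop = FALSE]
  for (q in sample(n_quadrats(comm$grid), 12)) {
    expect_equal(map$fdis[q], fdis_oracle(X, comm$abundance[q, ]),
                 tolerance = 1e-10)
  }
  # multivariate map differs from every single-trait map
  for (tr in colnames(traits)) {
    m1 <- dispersion_map(comm, single_trait_space(traits, tr), tr)
    expect_gt(max(abs(m1$fdis - map$fdis), na.rm = TRUE), 1e-6)
  }
})

test_that("monospecific quadrats have FDis 0", {
  df <- data.frame(stem_id = 1:4, x = c(1, 2, 6, 7), y = rep(1, 4),
                   species = c("a", "a", "b", "b"), dbh = rep(2, 4))
  cen <- as_census_table(df, c(10, 5))
  traits <- standardize_traits(cbind(t1 = c(1, 2, 3), t2 = c(5, 1, 2)))
  rownames(traits) <- c("a", "b", "c")
  space <- pcoa_embed(trait_distance(traits))
  map <- dispersion_map(make_grid(cen, 5), space)
  expect_equal(map$fdis, c(0, 0))
})
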