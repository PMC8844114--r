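test_that("shuffle_labels permutes assignments, not the coordinate set", {
  set.seed(41)
  traits <- standardize_traits(matrix(rnorm(24), 8, 3,
                                      dimnames = list(paste0("s", 1:8), NULL)))
  space <- pcoa_embed(trait_distance(traits))
  # identity permutation leaves the dispersion map unchanged
  same <- shuffle_labels(space, seq_len(8))
  expect_equal(same$points, space$points)
  # any permutation conserves the multiset of coordinates
  p <- sample(8)
  sh <- shuffle_labels(space, p)
  expect_equal(sh$points[order(p), , drop = FALSE],
               unname(space$points) * 1, ignore_attr = TRUE)
  expect_equal(sort(unname(sh$points[, 1])), sort(unname(space$points[, 1])))
  expect_error(shuffle_labels(space, c(1, 1, 3:8)))
})

test_that("label permutations are uniform over the symmetric group", {
  perms <- null_permutations(4, n_rand = 12000, seed = 42)
  expect_equal(dim(perms), c(12000, 4))
  key <- apply(perms, 1, paste, collapse = "")
  counts <- table(key)
  expect_equal(length(counts), 24)
  # each of the 24 permutations within 3 binomial SDs of 12000/24
  expected <- 12000 / 24
  sigma <- sqrt(12000 * (1 / 24) * (23 / 24))
  expect_true(all(abs(counts - expected) <= 3.5 * sigma))
})

test_that("zfdis applies the standardized effect size formula", {
  df <- data.frame(stem_id = 1:4, x = c(1, 2, 6, 7), y = rep(1, 4),
                   species = c("a", "b", "a", "c"), dbh = rep(2, 4))
  cen <- as_census_table(df, c(10, 5))
  comm <- make_grid(cen, 5)
  map <- structure(list(grid = comm$grid, trait_set = "multivariate",
                        fdis = c(2, 3), richness = c(2, 2),
                        n_stems = c(2, 2), zfdis = NULL),
                   class = "dispersion_map")
  # synthetic ensemble with known mean and SD per quadrat
  null1 <- c(1.5, 2.0, 2.5) # mean 2, sd 0.5 -> obs 2 gives z = 0
  null2 <- c(2.0, 2.5, 3.0) # mean 2.5, sd 0.25... use sample sd
  ens <- structure(list(fdis = rbind(null1, null2), n_rand = 3, seed = NULL),
                   class = "null_ensemble")
  out <- zfdis(map, ens)
  expect_equal(out$zfdis[1], 0)
  expect_equal(out$zfdis[2], (3 - mean(null2)) / sd(null2))
  # null SD zero -> NA, flagged as missing
  ens0 <- structure(list(fdis = rbind(c(1, 1, 1), null2), n_rand = 3,
                         seed = NULL), class = "null_ensemble")
  expect_true(is.na(zfdis(map, ens0)$zfdis[1]))
})

test_that("null ensemble matches a naive per-permutation oracle", {
  set.seed(43)
  df <- data.frame(stem_id = 1:30, x = runif(30, 0, 15), y = runif(30, 0, 5),
                   species = sample(paste0("s", 1:6), 30, TRUE),
                   dbh = runif(30, 1, 10))
  cen <- as_census_table(df, c(15, 5))
  comm <- make_grid(cen, 5)
  traits <- standardize_traits(matrix(rnorm(18), 6, 3,
                                      dimnames = list(paste0("s", 1:6), NULL)))
  space <- pcoa_embed(trait_distance(traits))
  perms <- null_permutations(6, n_rand = 50, seed = 44)
  ens <- null_fdis(comm, space, perms)
  # oracle: loop quadrats and permutations, direct formula each time
  A <- matrix(0, n_quadrats(comm$grid), 6,
              dimnames = list(NULL, space$species))
  A[, comm$species] <- comm$abundance
  for (r in c(1, 7, 50)) {
    Xp <- space$points[perms[r, ], , drop = FALSE]
    for (q in seq_len(nrow(A))) {
      expect_equal(ens$fdis[q, r], fdis_oracle(Xp, A[q, ]),
                   tolerance = 1e-12)
    }
  }
  # two-pass mean/SD oracle for the SES itself
  map <- dispersion_map(comm, space)
  z <- zfdis(map, ens)
  for (q in seq_len(nrow(A))) {
    mu <- mean(ens$fdis[q, ])
    s <- sd(ens$fdis[q, ])
    if (s > 0) expect_equal(z$zfdis[q], (map$fdis[q] - mu) / s)
  }
})

test_that("identical seeds give bit-identical ZFDis maps", {
  st <- tiny_study()
  traits <- standardize_traits(st$traits)
  space <- pcoa_embed(trait_distance(traits))
  comm <- make_grid(st$census, 50)
  m1 <- dispersion_with_null(comm, space,
                             null_permutations(60, 49, seed = 99))
  m2 <- dispersion_with_null(comm, space,
                             null_permutations(60, 49, seed = 99))
  expect_identical(m1$zfdis, m2$zfdis)
})

test_that("interquartile_table reports IQR by scale with the rule tag", {
  g <- quadrat_grid(c(20, 10), 5)
  mk <- function(z, scale) {
    gr <- quadrat_grid(c(20, 10), scale)
    structure(list(grid = gr, trait_set = "multivariate",
                   fdis = rep(1, n_quadrats(gr)),
                   richness = rep(2, n_quadrats(gr)),
                   n_stems = rep(2, n_quadrats(gr)), zfdis = z),
              class = "dispersion_map")
  }
  tab <- interquartile_table(list(mk(c(1, 2, 3, 4, NA, NA, NA, NA), 5),
                                  mk(rep(2, 2), 10)))
  expect_equal(tab$iqr[1], IQR(1:4)) # type-7 rule: 1.5
  expect_equal(tab$iqr[2], 0)
  expect_equal(tab$quantile_type, c(7, 7))
  expect_equal(tab$n, c(4, 2))
  expect_error(interquartile_table(list(mk(NULL, 5))), "zfdis")
})
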