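# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive reimplementation (explicit loops,
# textbook formulas) kept free of the package's vectorized code paths.

# Direct weighted-centroid FDis: plain loop over present species.
fdis_oracle <- function(coords, abund) {
  coords <- as.matrix(coords)
  keep <- abund > 0
  if (!any(keep)) return(NA_real_)
  x <- coords[keep, , drop = FALSE]
  a <- unname(abund[keep])
  ctr <- rep(0, ncol(x))
  for (k in seq_len(ncol(x))) ctr[k] <- sum(a * x[, k]) / sum(a)
  tot <- 0
  for (i in seq_len(nrow(x))) {
    tot <- tot + a[i] * sqrt(sum((x[i, ] - ctr)^2))
  }
  tot / sum(a)
}

# 1-D FDis is the abundance-weighted mean absolute deviation from the
# abundance-weighted mean.
wmad_oracle <- function(x, a) {
  m <- sum(a * x) / sum(a)
  sum(a * abs(x - m)) / sum(a)
}

# Textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
}

# Ordinary-kriging prediction at a single point by direct solve of the
# semivariance system, built element by element.
ok_oracle <- function(sx, sy, z, px, py, vgm) {
  n <- length(z)
  gam <- function(h) {
    traitscape::variogram_value(h, vgm$nugget, vgm$psill, vgm$range,
                                model = vgm$model)
  }
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- gam(sqrt((sx[i] - sx[j])^2 + (sy[i] - sy[j])^2))
    }
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- c(vapply(seq_len(n), function(i) {
    gam(sqrt((sx[i] - px)^2 + (sy[i] - py)^2))
  }, numeric(1)), 1)
  lambda <- solve(A, b)
  sum(lambda[seq_len(n)] * z)
}

# Exhaustive torus-translation null distribution by triple loop over the
# four orientations and all shifts, correlating against a fixed map.
torus_null_oracle <- function(z, values, nx, ny) {
  M <- matrix(values, nx, ny)
  variants <- list(M,
                   M[nx:1, , drop = FALSE],
                   M[nx:1, ny:1, drop = FALSE],
                   M[, ny:1, drop = FALSE])
  out <- numeric(0)
  for (V in variants) {
    for (dy in 0:(ny - 1)) {
      for (dx in 0:(nx - 1)) {
        shifted <- matrix(0, nx, ny)
        for (i in 1:nx) {
          for (j in 1:ny) {
            shifted[i, j] <- V[((i - 1 + dx) %% nx) + 1,
                               ((j - 1 + dy) %% ny) + 1]
          }
        }
        out <- c(out, cor(z, as.vector(shifted)))
      }
    }
  }
  out
}

# Small census data frame on a given plot.
toy_census_df <- function() {
  data.frame(
    stem_id = c("a", "b", "c"),
    x = c(0.5, 4.2, 9.9),
    y = c(0.1, 3.3, 7.7),
    species = c("sp1", "sp2", "sp1"),
    dbh = c(2.0, 5.5, 1.0)
  )
}

# Random small community fixtures: coordinates and abundances.
random_community <- function(n_species = 8, n_axes = 3) {
  coords <- matrix(rnorm(n_species * n_axes), n_species, n_axes)
  abund <- rpois(n_species, 2)
  if (all(abund == 0)) abund[1] <- 1
  list(coords = coords, abund = abund)
}

# Tiny synthetic study shared by several suites (cached per session).
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(desk_config(seed = 7))
    }
    cache
  }
})
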