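# Soil sampling design, variogram fitting, and ordinary kriging onto
# quadrat grids.
#
# No spatial-statistics package in the dependency stack provides ordinary
# kriging, so the semivariogram fit (weighted least squares) and the kriging
# solve are implemented directly; both are small dense linear-algebra
# problems at forest-plot sample sizes (<= ~700 points), and each has an
# independent oracle in the test suite.

#' Canonical soil variable names
#'
#' The nine topsoil properties carried through the pipeline: pH, soil
#' moisture (SM, %), organic matter (OM, g/kg), available nitrogen (AN,
#' mg/kg), available phosphorus (AP, mg/kg), available potassium (AK,
#' mg/kg), total nitrogen (TN, g/kg), total phosphorus (TP, g/kg), total
#' potassium (TK, g/kg).
#' @return character vector of length 9.
#' @export
soil_variables <- function() {
  c("pH", "SM", "OM", "AN", "AP", "AK", "TN", "TP", "TK")
}

#' Design a regular-grid soil sampling layout with paired offset points
#'
#' Lays sample points on a regular `spacing` x `spacing` m grid anchored at
#' the plot origin, and pairs each grid point with two additional points at
#' a distance drawn from `offsets` in a uniformly random compass direction,
#' clipped to the plot. On a 500 x 400 m plot with 30 m spacing this gives
#' 238 grid points and 714 planned samples.
#'
#' @param plot_dim numeric length 2, metres.
#' @param spacing grid spacing in metres (default 30).
#' @param offsets candidate offset distances in metres (default 2, 5, 15).
#' @param seed optional integer seed.
#' @return data.frame with columns `x`, `y`, `type` (`"grid"`/`"offset"`),
#'   `parent` (grid-point id), `offset_dist`, `bearing`; attribute
#'   `n_planned` gives the planned sample count (3 per grid point).
#' @export
design_soil_grid <- function(plot_dim, spacing = 30, offsets = c(2, 5, 15),
                             seed = NULL) {
  stopifnot(spacing < min(plot_dim))
  if (!is.null(seed)) set.seed(seed)
  gx <- seq(0, plot_dim[1] - 1e-9, by = spacing)
  gy <- seq(0, plot_dim[2] - 1e-9, by = spacing)
  g <- expand.grid(x = gx, y = gy)
  ng <- nrow(g)
  id <- seq_len(ng)
  d <- sample(offsets, 2 * ng, replace = TRUE)
  theta <- runif(2 * ng, 0, 2 * pi)
  px <- rep(g$x, each = 2) + d * cos(theta)
  py <- rep(g$y, each = 2) + d * sin(theta)
  eps <- 1e-6
  out <- rbind(
    data.frame(x = g$x, y = g$y, type = "grid", parent = id,
               offset_dist = 0, bearing = NA_real_),
    data.frame(x = pmin(pmax(px, 0), plot_dim[1] - eps),
               y = pmin(pmax(py, 0), plot_dim[2] - eps),
               type = "offset", parent = rep(id, each = 2),
               offset_dist = d, bearing = theta)
  )
  rownames(out) <- NULL
  attr(out, "n_planned") <- 3L * ng
  attr(out, "n_grid") <- ng
  out
}

#' Semivariogram model value
#'
#' Semivariance gamma(h) for the spherical, exponential or Gaussian model
#' with nugget, partial sill and range parameters. gamma(0) = 0 by
#' convention (the nugget is the limit from above), which makes ordinary
#' kriging an exact interpolator at sample locations.
#'
#' @param h non-negative lag distances.
#' @param nugget,psill,range model parameters (all >= 0; `range > 0`). For
#'   the exponential model `range` is the e-folding distance; for the
#'   Gaussian model the analogous shape parameter.
#' @param model `"spherical"`, `"exponential"` or `"gaussian"`.
#' @return semivariances, same length as `h`.
#' @export
variogram_value <- function(h, nugget, psill, range,
                            model = c("spherical", "exponential",
                                      "gaussian")) {
  model <- match.arg(model)
  s <- switch(model,
    spherical = ifelse(h >= range, 1, 1.5 * (h / range) - 0.5 * (h / range)^3),
    exponential = 1 - exp(-h / range),
    gaussian = 1 - exp(-(h / range)^2))
  ifelse(h == 0, 0, nugget + psill * s)
}

#' Empirical semivariogram
#'
#' Method-of-moments estimate binned up to `cutoff` (default one third of
#' the maximum pairwise distance). Lag-bin boundaries are quadratically
#' spaced, so bins are narrow at short lags: sampling designs that pair
#' grid points with close offset points then resolve the nugget instead of
#' smearing the close pairs into one wide first bin.
#'
#' @param coords n x 2 coordinate matrix.
#' @param z values at `coords`.
#' @param n_bins number of lag bins (default 15).
#' @param cutoff maximum lag distance considered.
#' @return data.frame with columns `dist` (mean lag in bin), `gamma`, `n`
#'   (pair count); empty bins are dropped.
#' @export
empirical_variogram <- function(coords, z, n_bins = 15, cutoff = NULL) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(z))
  dmat <- dist(coords)
  if (is.null(cutoff)) cutoff <- max(dmat) / 3
  gsq <- 0.5 * dist(z)^2
  dvec <- as.numeric(dmat)
  keep <- dvec > 0 & dvec <= cutoff
  bins <- cut(dvec[keep],
              breaks = cutoff * seq(0, 1, length.out = n_bins + 1)^2,
              include.lowest = TRUE)
  data.frame(
    dist = as.numeric(tapply(dvec[keep], bins, mean)),
    gamma = as.numeric(tapply(as.numeric(gsq)[keep], bins, mean)),
    n = as.integer(table(bins))
  )[!is.na(tapply(dvec[keep], bins, mean)), , drop = FALSE]
}

#' Fit a semivariogram model by weighted least squares
#'
#' Fits nugget, partial sill and range to the empirical semivariogram by
#' minimizing `sum n_j (gamma_hat_j - gamma_j)^2 / gamma_j^2` (Cressie
#' weights) with box constraints keeping all parameters non-negative.
#'
#' @param samples data.frame with columns `x`, `y` and soil variables.
#' @param variable variable (column) name to fit.
#' @param model semivariogram model tag (default `"spherical"`).
#' @param n_bins,cutoff passed to [empirical_variogram()].
#' @return A `variogram_fit`: list with `model`, `nugget`, `psill`, `range`,
#'   `sill` (nugget + psill), `rmse` (on binned points), `empirical`,
#'   `convergence`.
#' @export
fit_variogram <- function(samples, variable,
                          model = c("spherical", "exponential", "gaussian"),
                          n_bins = 15, cutoff = NULL) {
  model <- match.arg(model)
  z <- samples[[variable]]
  if (is.null(z)) stop("no column '", variable, "' in samples", call. = FALSE)
  if (var(z) == 0) {
    stop("variable '", variable, "' has zero variance; cannot fit a ",
         "variogram", call. = FALSE)
  }
  ev <- empirical_variogram(samples[, c("x", "y")], z, n_bins = n_bins,
                            cutoff = cutoff)
  vz <- var(z)
  obj <- function(p) {
    g <- variogram_value(ev$dist, p[1], p[2], p[3], model = model)
    sum(ev$n * (ev$gamma - g)^2 / pmax(g, 1e-8 * vz)^2)
  }
  # multi-start L-BFGS-B: nugget-heavy, structure-heavy and balanced
  # splits of the variance, short and long range guesses
  starts <- list(
    c(max(min(ev$gamma) / 2, 1e-6 * vz), max(vz - min(ev$gamma) / 2,
                                             1e-4 * vz),
      max(ev$dist) / 2),
    c(1e-4 * vz, vz, max(ev$dist) / 6),
    c(vz / 2, vz / 2, max(ev$dist) / 3)
  )
  fits <- lapply(starts, function(p0) {
    tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(0, 1e-8 * vz, 1e-3 * max(ev$dist)),
            upper = c(2 * vz, 4 * vz, 10 * max(ev$dist))),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  fit <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  g_fit <- variogram_value(ev$dist, fit$par[1], fit$par[2], fit$par[3],
                           model = model)
  structure(
    list(model = model, nugget = unname(fit$par[1]),
         psill = unname(fit$par[2]), range = unname(fit$par[3]),
         sill = unname(fit$par[1] + fit$par[2]),
         rmse = sqrt(mean((ev$gamma - g_fit)^2)),
         empirical = ev, convergence = fit$convergence),
    class = "variogram_fit"
  )
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf(
    "variogram_fit (%s): nugget %.4g, partial sill %.4g, range %.4g m\n",
    x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Ordinary kriging onto a quadrat grid
#'
#' Predicts the variable at every quadrat centre by ordinary kriging with a
#' global search neighbourhood (all samples). Kriging weights solve the
#' standard semivariance system with a Lagrange multiplier enforcing that
#' weights sum to one, so a constant field is reproduced exactly and, with
#' zero nugget, prediction at a sample location returns the sample value.
#' Duplicate sample coordinates are jittered by 1e-6 m to keep the system
#' nonsingular.
#'
#' @param samples data.frame with `x`, `y` and the variable column.
#' @param variable variable name.
#' @param grid a `quadrat_grid`.
#' @param variogram a `variogram_fit` (or a list with `model`, `nugget`,
#'   `psill`, `range`).
#' @return A `grid_field`: list with `grid`, `variable`, `values`
#'   (per-quadrat predictions, quadrat-index order) and the variogram used.
#' @export
krige <- function(samples, variable, grid, variogram) {
  stopifnot(inherits(grid, "quadrat_grid"))
  z <- samples[[variable]]
  sx <- samples$x
  sy <- samples$y
  dup <- duplicated(cbind(sx, sy))
  if (any(dup)) {
    sx[dup] <- sx[dup] + runif(sum(dup), -1e-6, 1e-6)
    sy[dup] <- sy[dup] + runif(sum(dup), -1e-6, 1e-6)
  }
  n <- length(z)
  vg <- function(h) variogram_value(h, variogram$nugget, variogram$psill,
                                    variogram$range, model = variogram$model)
  G <- vg(as.matrix(dist(cbind(sx, sy))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  ctr <- quadrat_centers(grid)
  D0 <- sqrt(outer(ctr$x, sx, "-")^2 + outer(ctr$y, sy, "-")^2)
  B <- rbind(t(vg(D0)), 1)
  W <- solve(A, B)
  wsum <- colSums(W[seq_len(n), , drop = FALSE])
  if (max(abs(wsum - 1)) > 1e-6) {
    stop("kriging weights do not sum to 1; system ill-conditioned",
         call. = FALSE)
  }
  grid_field(grid, variable, as.vector(crossprod(W[seq_len(n), , drop = FALSE], z)),
             variogram = variogram)
}

#' Construct a grid field
#'
#' A per-quadrat environmental surface (kriged soil variable, PCA axis
#' score, or ground-truth value) on the same grid as the community maps it
#' will be compared with.
#'
#' @param grid a `quadrat_grid`.
#' @param variable variable name.
#' @param values numeric vector, one value per quadrat in index order.
#' @param ... extra metadata stored in the object.
#' @return A `grid_field`.
#' @export
grid_field <- function(grid, variable, values, ...) {
  stopifnot(inherits(grid, "quadrat_grid"),
            length(values) == n_quadrats(grid))
  structure(list(grid = grid, variable = variable,
                 values = as.numeric(values), ...),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field '%s' (%g m): %d quadrats, mean %.4g, sd %.4g\n",
              x$variable, x$grid$scale, n_quadrats(x$grid),
              mean(x$values), sd(x$values)))
  invisible(x)
}

#' Descriptive statistics of grid fields
#'
#' Mean and standard deviation of each field over its quadrats, one row per
#' (variable, scale).
#'
#' @param fields list of `grid_field` objects.
#' @return data.frame with columns `variable`, `scale`, `n_quadrats`,
#'   `mean`, `sd`.
#' @export
soil_summary <- function(fields) {
  stopifnot(all(vapply(fields, inherits, logical(1), "grid_field")))
  do.call(rbind, lapply(fields, function(f) {
    data.frame(variable = f$variable, scale = f$grid$scale,
               n_quadrats = n_quadrats(f$grid),
               mean = mean(f$values), sd = sd(f$values))
  }))
}
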