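# Dispersion-environment correlations, torus-translation significance
# tests, and correlation-versus-scale trends.

as_field_values <- function(x) {
  if (inherits(x, "dispersion_map")) {
    if (is.null(x$zfdis)) stop("dispersion map has no zfdis; run zfdis() first",
                               call. = FALSE)
    return(x$zfdis)
  }
  if (inherits(x, "grid_field")) return(x$values)
  as.numeric(x)
}

#' Pearson correlation between two quadrat maps
#'
#' Quadrats with a missing value in either map are dropped pairwise. Fewer
#' than 3 complete pairs, or zero variance in either map, gives `NA` with an
#' explanatory `reason` attribute.
#'
#' @param a,b `dispersion_map` (its `zfdis`), `grid_field`, or numeric
#'   vectors of equal length.
#' @return Pearson r (scalar), possibly `NA` with attribute `reason`.
#' @export
pearson_r <- function(a, b) {
  va <- as_field_values(a)
  vb <- as_field_values(b)
  stopifnot(length(va) == length(vb))
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3) {
    return(structure(NA_real_, reason = "fewer than 3 complete pairs"))
  }
  if (sd(va[ok]) == 0 || sd(vb[ok]) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  cor(va[ok], vb[ok])
}

# Matrix view of per-quadrat values: element [col, row] with column index
# (x) varying fastest, matching the quadrat ordering of quadrat_grid.
field_matrix <- function(values, grid) {
  matrix(values, nrow = grid$nx, ncol = grid$ny)
}

# The four orientation variants of a map: original, mirror image
# (reflection across the vertical axis), 180-degree rotation, and rotated
# mirror. Together with all cyclic translations these form the torus null
# family; the family is the same whichever single reflection is chosen,
# because the translation group closes over the alternatives.
orientation_variants <- function(M) {
  list(original = M,
       mirror = M[rev(seq_len(nrow(M))), , drop = FALSE],
       rotated = M[rev(seq_len(nrow(M))), rev(seq_len(ncol(M))), drop = FALSE],
       rotated_mirror = M[, rev(seq_len(ncol(M))), drop = FALSE])
}

# All nx*ny cyclic translations of one orientation, as columns of a
# (nx*ny) x (nx*ny) matrix. Column 1 is the untranslated map.
cyclic_translations <- function(M) {
  nx <- nrow(M)
  ny <- ncol(M)
  out <- matrix(0, nx * ny, nx * ny)
  k <- 0L
  for (dy in 0:(ny - 1)) {
    for (dx in 0:(nx - 1)) {
      k <- k + 1L
      out[, k] <- as.vector(M[((seq_len(nx) - 1L + dx) %% nx) + 1L,
                              ((seq_len(ny) - 1L + dy) %% ny) + 1L,
                              drop = FALSE])
    }
  }
  out
}

#' Number of torus-translated maps for a grid
#'
#' Four orientation variants times all `nx * ny` cyclic translations,
#' including the identity translation of the true orientation.
#'
#' @param grid a `quadrat_grid`.
#' @return integer map count `4 * nx * ny`.
#' @export
torus_n_maps <- function(grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  4L * n_quadrats(grid)
}

#' All torus-translated maps of a grid field
#'
#' Materializes every translated map (each a permutation of the original
#' values) as columns of a matrix. Intended for small grids and for
#' oracle-style checks; [torus_test()] streams the translations instead.
#'
#' @param field a `grid_field` (or numeric vector with a `grid`).
#' @param grid the `quadrat_grid` (taken from `field` if omitted).
#' @return numeric matrix `n_quadrats x (4 * n_quadrats)`; column 1 is the
#'   identity map. Attribute `variant` labels each column's orientation.
#' @export
torus_maps <- function(field, grid = NULL) {
  if (inherits(field, "grid_field")) {
    grid <- field$grid
    values <- field$values
  } else {
    values <- as.numeric(field)
  }
  stopifnot(inherits(grid, "quadrat_grid"),
            length(values) == n_quadrats(grid))
  if (torus_n_maps(grid) * as.double(n_quadrats(grid)) > 5e7) {
    stop("grid too large to materialize all torus maps; use torus_test()",
         call. = FALSE)
  }
  vars <- orientation_variants(field_matrix(values, grid))
  out <- do.call(cbind, lapply(vars, cyclic_translations))
  attr(out, "variant") <- rep(names(vars), each = n_quadrats(grid))
  out
}

#' Torus-translation test of a dispersion-environment correlation
#'
#' Compares the observed Pearson correlation between a ZFDis map and an
#' environmental field against the null distribution of correlations
#' obtained by translating the environmental map over a torus (edges
#' wrapping in the four cardinal directions) in all four orientation
#' variants, while the dispersion map stays fixed. Translation preserves
#' each map's internal spatial autocorrelation, which a naive test of r
#' would ignore. The null set includes the identity translation, so
#' p-values are bounded below by `1 / n_maps` and the test is exact.
#'
#' The decision rule is two one-sided tests: significant-positive if the
#' observed r is higher than a fraction `1 - alpha` of the null values
#' (`p_high <= alpha`), significant-negative if lower than a fraction
#' `alpha` (`p_low <= alpha`); with the default `alpha = 0.05` the overall
#' two-tailed level is 10%.
#'
#' Quadrats with missing ZFDis are dropped pairwise within each
#' translation.
#'
#' @param zfdis_map a `dispersion_map` with `zfdis` filled (or a numeric
#'   vector).
#' @param field a `grid_field` on the same grid.
#' @param alpha one-sided significance level (default 0.05).
#' @return A `torus_test_result`: list with `observed_r`, `null_r` (length
#'   `n_maps`, first element the identity = observed r), `n_maps`, `p_low`,
#'   `p_high`, `verdict` (`"significant-negative"`, `"significant-positive"`
#'   or `"nonsignificant"`), `alpha`.
#' @export
torus_test <- function(zfdis_map, field, alpha = 0.05) {
  stopifnot(inherits(field, "grid_field"))
  grid <- field$grid
  z <- as_field_values(zfdis_map)
  stopifnot(length(z) == n_quadrats(grid))
  obs <- pearson_r(z, field$values)
  if (is.na(obs)) {
    return(structure(list(observed_r = NA_real_, null_r = NULL,
                          n_maps = torus_n_maps(grid), p_low = NA_real_,
                          p_high = NA_real_, verdict = NA_character_,
                          alpha = alpha),
                     class = "torus_test_result"))
  }
  vars <- orientation_variants(field_matrix(field$values, grid))
  null_r <- unlist(lapply(vars, function(M) {
    X <- cyclic_translations(M)
    suppressWarnings(as.vector(cor(z, X, use = "pairwise.complete.obs")))
  }), use.names = FALSE)
  n_maps <- length(null_r)
  p_high <- mean(null_r >= obs)
  p_low <- mean(null_r <= obs)
  verdict <- if (p_high <= alpha) {
    "significant-positive"
  } else if (p_low <= alpha) {
    "significant-negative"
  } else {
    "nonsignificant"
  }
  structure(list(observed_r = obs, null_r = null_r, n_maps = n_maps,
                 p_low = p_low, p_high = p_high, verdict = verdict,
                 alpha = alpha),
            class = "torus_test_result")
}

#' @export
print.torus_test_result <- function(x, ...) {
  cat(sprintf(
    "torus_test: r = %.3f, %d maps, p_low = %.4f, p_high = %.4f -> %s\n",
    x$observed_r, x$n_maps, x$p_low, x$p_high, x$verdict))
  invisible(x)
}

#' Trend of correlation against quadrat area
#'
#' Ordinary least-squares regression of the per-scale observed correlations
#' on quadrat area (scale squared, m^2), with a 95% confidence interval on
#' the slope. At least 3 scales with non-missing r are required.
#'
#' @param r per-scale observed correlations (or list of
#'   `torus_test_result`).
#' @param scale quadrat sides in metres, same length as `r`.
#' @return A `scale_trend`: list with `data` (scale, area, r), `slope`,
#'   `intercept`, `conf` (95% CI on slope), `fit` (the `lm`).
#' @export
scale_trend <- function(r, scale) {
  if (is.list(r) && all(vapply(r, inherits, logical(1), "torus_test_result"))) {
    r <- vapply(r, function(t) t$observed_r, numeric(1))
  }
  stopifnot(length(r) == length(scale))
  df <- data.frame(scale = scale, area = scale^2, r = as.numeric(r))
  ok <- is.finite(df$r)
  if (sum(ok) < 3) stop("scale_trend needs at least 3 scales with a valid r",
                        call. = FALSE)
  fit <- lm(r ~ area, data = df[ok, ])
  ci <- confint(fit, "area", level = 0.95)
  structure(list(data = df, slope = unname(coef(fit)["area"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 conf = c(lower = ci[1], upper = ci[2]), fit = fit),
            class = "scale_trend")
}

#' @export
print.scale_trend <- function(x, ...) {
  cat(sprintf("scale_trend: slope %.3e per m^2 (95%% CI %.3e, %.3e)\n",
              x$slope, x$conf[1], x$conf[2]))
  invisible(x)
}
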