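# PCA of quadrat-level soil variables and Horn's parallel analysis.

#' PCA of soil grid fields
#'
#' Principal components analysis of the per-quadrat values of several grid
#' fields on one grid. The PCA is run on the correlation matrix (variables
#' standardized), because soil variables carry heterogeneous units. Axis
#' signs are arbitrary in PCA; for deterministic output each axis is flipped
#' if needed so that the loading of the `anchor` variable (default organic
#' matter, OM) is positive.
#'
#' @param fields named list of `grid_field` objects on a common grid.
#' @param anchor variable whose loading fixes each axis sign; if its loading
#'   is zero on an axis the first non-zero loading is used instead.
#' @return A `soil_pca`: list with `loadings` (variable x axis, orthonormal
#'   columns), `scores` (quadrat x axis), `eig` (eigenvalues, decreasing),
#'   `cum_prop` (cumulative variance proportions), `grid`, `variables`.
#' @export
soil_pca <- function(fields, anchor = "OM") {
  stopifnot(length(fields) >= 2,
            all(vapply(fields, inherits, logical(1), "grid_field")))
  grid <- fields[[1]]$grid
  X <- vapply(fields, function(f) {
    stopifnot(identical(f$grid, grid))
    f$values
  }, numeric(n_quadrats(grid)))
  colnames(X) <- vapply(fields, function(f) f$variable, character(1))
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("constant field(s): ", paste(colnames(X)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  load <- pr$rotation
  scores <- pr$x
  if (!anchor %in% rownames(load)) anchor <- rownames(load)[1]
  for (k in seq_len(ncol(load))) {
    a <- load[anchor, k]
    if (a == 0) a <- load[which(load[, k] != 0)[1], k]
    if (a < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  eig <- pr$sdev^2
  structure(
    list(loadings = load, scores = scores, eig = eig,
         cum_prop = cumsum(eig) / sum(eig), grid = grid,
         variables = colnames(X), data = X),
    class = "soil_pca"
  )
}

#' @export
print.soil_pca <- function(x, ...) {
  cat(sprintf("soil_pca: %d variables, %d quadrats (%g m)\n",
              length(x$variables), n_quadrats(x$grid), x$grid$scale))
  cat(sprintf("  cumulative variance PC1-PC2: %.3f\n", x$cum_prop[2]))
  invisible(x)
}

#' Horn's parallel analysis for axis retention
#'
#' Compares observed correlation-matrix eigenvalues against the mean
#' eigenvalues of `n_iter` standard-normal matrices of the same dimensions.
#' Adjusted eigenvalue k = observed_k - (mean random_k - 1); leading axes
#' with adjusted eigenvalue > 1 are retained (the mean-eigenvalue rule, the
#' convention of the paran implementation this follows).
#'
#' @param data quadrat x variable numeric matrix, or a `soil_pca`.
#' @param n_iter random replicates, at least 100 (default 1000).
#' @param seed optional integer seed.
#' @return list with `observed`, `random_mean`, `adjusted` eigenvalues and
#'   `retained` (count of leading axes with adjusted eigenvalue > 1).
#' @export
horn_parallel <- function(data, n_iter = 1000, seed = NULL) {
  if (inherits(data, "soil_pca")) data <- data$data
  data <- as.matrix(data)
  stopifnot(n_iter >= 100)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  p <- ncol(data)
  observed <- prcomp(data, center = TRUE, scale. = TRUE)$sdev^2
  rand <- matrix(0, n_iter, p)
  for (i in seq_len(n_iter)) {
    rand[i, ] <- prcomp(matrix(rnorm(n * p), n, p), scale. = TRUE)$sdev^2
  }
  random_mean <- colMeans(rand)
  adjusted <- observed - (random_mean - 1)
  above <- adjusted > 1
  retained <- if (all(above)) p else which(!above)[1] - 1L
  list(observed = observed, random_mean = random_mean, adjusted = adjusted,
       retained = as.integer(retained), n_iter = n_iter, seed = seed)
}

#' Export PCA axis scores as grid fields
#'
#' Exports the first `n_axes` axis scores (default PC1 and PC2) as
#' `grid_field` objects regardless of the parallel-analysis verdict, so the
#' same composite gradients are available at every scale; the retention
#' verdict travels separately from [horn_parallel()].
#'
#' @param pca a `soil_pca`.
#' @param n_axes number of axes to export (default 2).
#' @return named list of `grid_field` objects (`PC1`, `PC2`, ...).
#' @export
axis_fields <- function(pca, n_axes = 2) {
  stopifnot(inherits(pca, "soil_pca"), ncol(pca$scores) >= n_axes)
  out <- lapply(seq_len(n_axes), function(k) {
    grid_field(pca$grid, paste0("PC", k), pca$scores[, k])
  })
  names(out) <- paste0("PC", seq_len(n_axes))
  out
}
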