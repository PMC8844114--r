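# Trait standardization, PCoA embedding and functional dispersion (FDis).

#' Read a species x trait table from CSV
#'
#' First column is the species code; remaining columns are continuous
#' traits. Values must be complete and numeric.
#'
#' @param path CSV file path.
#' @return numeric matrix, species in rows (rownames), traits in columns.
#' @export
read_traits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("trait table needs a species column plus traits")
  sp <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("trait table contains missing values", call. = FALSE)
  rownames(m) <- sp
  m
}

#' Standardize traits to zero mean and unit SD
#'
#' Each trait column is centred on zero and rescaled to standard deviation
#' one, so traits with different units and magnitudes contribute equally to
#' trait-space distances. Idempotent on already-standardized input.
#'
#' @param traits numeric species x trait matrix.
#' @return matrix of the same shape with attribute `standardized = TRUE`.
#' @export
standardize_traits <- function(traits) {
  traits <- as.matrix(traits)
  sds <- apply(traits, 2, sd)
  if (any(sds == 0)) {
    stop("constant trait column(s): ",
         paste(colnames(traits)[sds == 0], collapse = ", "), call. = FALSE)
  }
  out <- scale(traits)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' Species-species Euclidean distance matrix
#'
#' @param traits standardized species x trait matrix (see
#'   [standardize_traits()]).
#' @return symmetric numeric matrix with zero diagonal and species dimnames.
#' @export
trait_distance <- function(traits) {
  if (!isTRUE(attr(traits, "standardized"))) {
    warning("traits do not appear to be standardized; distances will be ",
            "dominated by large-magnitude traits")
  }
  as.matrix(dist(traits))
}

#' Embed a distance matrix by principal coordinates analysis
#'
#' Wraps [ape::pcoa()]. A genuinely Euclidean distance matrix is embedded
#' exactly with no correction. When negative eigenvalues beyond numerical
#' noise appear, the requested correction (default Cailliez) is applied and
#' recorded, so that embedding distances reproduce the corrected distances.
#' Axes with eigenvalue below `1e-10 * max(eigenvalue)` are dropped as
#' numerical noise; all substantive axes are retained.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param correction `"cailliez"` (default), `"lingoes"`, or `"none"`.
#' @return A `trait_space`: list with `points` (species x axis coordinates),
#'   `eig` (retained eigenvalues, decreasing), `correction` (tag applied,
#'   `"none"` if the input was Euclidean), `species`.
#' @export
pcoa_embed <- function(d, correction = c("cailliez", "lingoes", "none")) {
  correction <- match.arg(correction)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  res <- ape::pcoa(as.dist(d))
  eig <- res$values$Eigenvalues
  tol <- 1e-8 * max(eig)
  applied <- "none"
  if (min(eig) < -tol && correction != "none") {
    res <- ape::pcoa(as.dist(d), correction = correction)
    applied <- correction
  }
  if (applied == "none") {
    pts <- res$vectors
    eig_keep <- res$values$Eigenvalues[seq_len(ncol(pts))]
  } else {
    pts <- res$vectors.cor
    eig_keep <- res$values$Corr_eig[seq_len(ncol(pts))]
  }
  keep <- eig_keep > 1e-10 * max(eig_keep)
  pts <- pts[, keep, drop = FALSE]
  eig_keep <- eig_keep[keep]
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("A", seq_len(ncol(pts)))
  structure(list(points = pts, eig = eig_keep, correction = applied,
                 species = rownames(d)),
            class = "trait_space")
}

#' One-dimensional trait space for a single trait
#'
#' Uses a single standardized trait column as a 1-D coordinate system, so
#' FDis and null models run identically for single traits and the
#' multivariate set.
#'
#' @param traits standardized species x trait matrix.
#' @param trait trait (column) name.
#' @return A `trait_space` with a single axis.
#' @export
single_trait_space <- function(traits, trait) {
  stopifnot(trait %in% colnames(traits))
  pts <- traits[, trait, drop = FALSE]
  structure(list(points = pts, eig = var(pts[, 1]) * (nrow(pts) - 1),
                 correction = "none", species = rownames(traits)),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat(sprintf("trait_space: %d species, %d axes (correction: %s)\n",
              nrow(x$points), ncol(x$points), x$correction))
  invisible(x)
}

#' Abundance-weighted functional dispersion of one community
#'
#' FDis is the abundance-weighted mean distance of species to the
#' abundance-weighted centroid: with coordinates `x_j` and abundances
#' `a_j`, centroid `c = sum(a_j x_j) / sum(a_j)` and
#' `FDis = sum(a_j ||x_j - c||) / sum(a_j)`. A community with a single
#' species has FDis 0; an empty community has no FDis (`NA`).
#'
#' @param coords species x axis coordinate matrix (or a `trait_space`).
#' @param abund non-negative abundances, one per row of `coords`.
#' @return non-negative scalar, or `NA_real_` for an empty community.
#' @export
fdis <- function(coords, abund) {
  if (inherits(coords, "trait_space")) coords <- coords$points
  coords <- as.matrix(coords)
  stopifnot(length(abund) == nrow(coords), all(abund >= 0))
  tot <- sum(abund)
  if (tot == 0) return(NA_real_)
  pres <- abund > 0
  x <- coords[pres, , drop = FALSE]
  a <- abund[pres]
  ctr <- colSums(x * a) / tot
  d <- sqrt(rowSums(sweep(x, 2, ctr)^2))
  sum(a * d) / tot
}

# Vectorized FDis for every quadrat of an abundance matrix A (quadrats x
# species) against coordinates X (species x axis). Returns NA for empty
# quadrats. ||x_s - c_q||^2 expanded as x2 - 2 c.x + c2 keeps this a pair of
# matrix products.
fdis_all <- function(A, X) {
  n <- rowSums(A)
  C <- (A %*% X) / ifelse(n > 0, n, 1)
  x2 <- rowSums(X^2)
  c2 <- rowSums(C^2)
  D2 <- matrix(x2, nrow(A), ncol(A), byrow = TRUE) - 2 * (C %*% t(X)) + c2
  M <- sqrt(pmax(D2, 0))
  out <- rowSums(A * M) / ifelse(n > 0, n, 1)
  out[n == 0] <- NA_real_
  out
}

#' Per-quadrat functional dispersion map
#'
#' Computes abundance-weighted FDis for every quadrat of a community in a
#' given trait space. All community species must be present in the trait
#' space (apply the untraited-species policy when reading the census).
#'
#' @param comm a `quadrat_community`.
#' @param space a `trait_space` (multivariate or single trait).
#' @param trait_set label stored with the map, default `"multivariate"`.
#' @return A `dispersion_map`: list with `grid`, `trait_set`, `fdis`
#'   (per-quadrat values, `NA` for empty quadrats), `richness`, `n_stems`,
#'   and `zfdis = NULL` until filled by [zfdis()].
#' @export
dispersion_map <- function(comm, space, trait_set = "multivariate") {
  stopifnot(inherits(comm, "quadrat_community"), inherits(space, "trait_space"))
  missing_sp <- setdiff(comm$species, space$species)
  if (length(missing_sp)) {
    stop("community species missing from trait space: ",
         paste(head(missing_sp, 5), collapse = ", "), call. = FALSE)
  }
  X <- space$points[comm$species, , drop = FALSE]
  structure(
    list(grid = comm$grid, trait_set = trait_set,
         fdis = fdis_all(comm$abundance, X),
         richness = rowSums(comm$abundance > 0),
         n_stems = rowSums(comm$abundance),
         zfdis = NULL),
    class = "dispersion_map"
  )
}

#' @export
print.dispersion_map <- function(x, ...) {
  cat(sprintf(
    "dispersion_map (%s, %g m): %d quadrats, FDis median %.3f%s\n",
    x$trait_set, x$grid$scale, n_quadrats(x$grid),
    median(x$fdis, na.rm = TRUE),
    if (is.null(x$zfdis)) "" else ", ZFDis filled"))
  invisible(x)
}
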