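# Taxa-shuffle null model and standardized effect size (ZFDis).
#
# One label permutation is drawn per randomization for the whole plot and
# applied at every scale within that randomization. This conserves every
# quadrat's abundance vector and every species' plot-level abundance and
# occurrence frequency exactly; only the assignment of trait coordinates to
# taxon labels changes. Per-quadrat independent shuffles would break the
# plot-level occurrence constraint and are deliberately not offered.

#' Draw plot-level taxa-label permutations
#'
#' @param n_species number of species in the trait space.
#' @param n_rand number of randomizations (default 999).
#' @param seed optional integer seed, recorded as an attribute.
#' @return integer matrix `n_rand x n_species`; each row is a uniform random
#'   permutation of `1:n_species`.
#' @export
null_permutations <- function(n_species, n_rand = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perms <- t(replicate(n_rand, sample.int(n_species)))
  structure(perms, seed = seed, n_rand = n_rand)
}

#' Shuffle taxon labels of a trait space
#'
#' Reassigns trait coordinates to species labels according to a permutation:
#' species `i` receives the coordinates of species `perm[i]`. The multiset
#' of coordinates is unchanged.
#'
#' @param space a `trait_space`.
#' @param perm integer permutation of `1:nrow(space$points)`.
#' @return A `trait_space` with permuted coordinate assignment.
#' @export
shuffle_labels <- function(space, perm) {
  stopifnot(inherits(space, "trait_space"),
            length(perm) == nrow(space$points),
            setequal(perm, seq_along(perm)))
  pts <- space$points[perm, , drop = FALSE]
  rownames(pts) <- space$species
  space$points <- pts
  space
}

#' Null FDis ensemble for one community
#'
#' Applies each plot-level label permutation to the trait space and
#' recomputes per-quadrat FDis, yielding the null distribution used for the
#' standardized effect size.
#'
#' @param comm a `quadrat_community`.
#' @param space a `trait_space`.
#' @param perms permutation matrix from [null_permutations()]; permutation
#'   indices refer to the species order of `space`.
#' @return A `null_ensemble`: list with `fdis` (quadrats x randomizations
#'   matrix), `n_rand`, `seed`.
#' @export
null_fdis <- function(comm, space, perms) {
  stopifnot(inherits(comm, "quadrat_community"), inherits(space, "trait_space"))
  # align community columns to the full trait-space species set so that the
  # plot-level permutation indexes one shared species order
  A <- matrix(0L, n_quadrats(comm$grid), length(space$species),
              dimnames = list(NULL, space$species))
  A[, comm$species] <- comm$abundance
  X <- space$points
  n_rand <- nrow(perms)
  out <- matrix(NA_real_, nrow(A), n_rand)
  for (r in seq_len(n_rand)) {
    out[, r] <- fdis_all(A, X[perms[r, ], , drop = FALSE])
  }
  structure(list(fdis = out, n_rand = n_rand, seed = attr(perms, "seed")),
            class = "null_ensemble")
}

#' Standardized effect size of functional dispersion
#'
#' Fills `zfdis = (FDis_observed - mean(null FDis)) / SD(null FDis)` per
#' quadrat, using the sample SD (n - 1) of the null values. Positive values
#' indicate trait overdispersion, negative values trait clustering. Quadrats
#' whose null SD is zero (e.g. monospecific quadrats, where every labelling
#' gives FDis 0) get `NA`.
#'
#' @param map a `dispersion_map` from [dispersion_map()].
#' @param ensemble a `null_ensemble` from [null_fdis()] on the same grid.
#' @return The map with `zfdis` filled and attributes `n_rand`, `seed`.
#' @export
zfdis <- function(map, ensemble) {
  stopifnot(inherits(map, "dispersion_map"), inherits(ensemble, "null_ensemble"),
            nrow(ensemble$fdis) == n_quadrats(map$grid))
  mu <- rowMeans(ensemble$fdis)
  sdev <- apply(ensemble$fdis, 1, sd)
  z <- unname((map$fdis - mu) / sdev)
  z[!is.finite(z)] <- NA_real_
  map$zfdis <- z
  attr(map, "n_rand") <- ensemble$n_rand
  attr(map, "seed") <- ensemble$seed
  map
}

#' Observed and null dispersion in one call
#'
#' Convenience wrapper: observed FDis map, null ensemble, and ZFDis.
#'
#' @inheritParams null_fdis
#' @param trait_set label for the map.
#' @return A `dispersion_map` with `zfdis` filled.
#' @export
dispersion_with_null <- function(comm, space, perms,
                                 trait_set = "multivariate") {
  map <- dispersion_map(comm, space, trait_set = trait_set)
  zfdis(map, null_fdis(comm, space, perms))
}

#' Interquartile ranges of ZFDis by scale and trait set
#'
#' @param maps list of `dispersion_map` objects with `zfdis` filled.
#' @param type quantile rule passed to [stats::IQR()] (default 7, the R
#'   default), recorded in the output.
#' @return data.frame with columns `trait_set`, `scale`, `n`, `iqr`,
#'   `quantile_type`.
#' @export
interquartile_table <- function(maps, type = 7) {
  stopifnot(all(vapply(maps, inherits, logical(1), "dispersion_map")))
  rows <- lapply(maps, function(m) {
    if (is.null(m$zfdis)) stop("zfdis not filled for a map", call. = FALSE)
    z <- m$zfdis[!is.na(m$zfdis)]
    data.frame(trait_set = m$trait_set, scale = m$grid$scale,
               n = length(z),
               iqr = if (length(z)) IQR(z, type = type) else NA_real_,
               quantile_type = type)
  })
  do.call(rbind, rows)
}
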