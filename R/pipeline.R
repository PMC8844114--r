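# End-to-end analysis: census + traits + soil samples -> per-scale ZFDis
# maps, kriged environmental surfaces, torus-translation verdicts, and
# correlation-versus-scale trends.

#' Run the full dispersion-environment analysis
#'
#' From raw inputs (a census table, a species x trait matrix, and a soil
#' sample table), computes at each quadrat scale: the abundance-weighted
#' FDis map in corrected PCoA trait space, its taxa-shuffle standardized
#' effect size (ZFDis), ordinary-kriged environmental surfaces, the Pearson
#' correlation of ZFDis with each surface with a torus-translation verdict,
#' and the linear trend of r against quadrat area.
#'
#' @param census a `census_table` (or a `synthetic_study`, from which
#'   census, traits and soil samples are taken).
#' @param traits species x trait matrix; ignored when `census` is a study.
#' @param soil_samples data.frame `x`, `y` + soil variables; ignored when
#'   `census` is a study.
#' @param scales quadrat sides in metres (default 5, 10, 20, 50).
#' @param n_rand null-model randomizations (default 199 for interactive
#'   runs; use 999 for final analyses).
#' @param env_vars soil variables to test against (default the three
#'   availability-class nutrients AP, AK, AN).
#' @param with_pca also krige all nine soil variables, run a per-scale PCA
#'   with parallel analysis, and test PC1/PC2 as composite gradients.
#' @param trait_sets `"multivariate"` and/or individual trait names.
#' @param alpha one-sided torus-test level (default 0.05).
#' @param vgm_model semivariogram model tag.
#' @param correction PCoA negative-eigenvalue correction.
#' @param seed seed for the null-model permutations.
#' @return A `traitscape_analysis`: list with `results` (data.frame: scale,
#'   variable, trait_set, r, p_low, p_high, verdict, n_maps), `trends`
#'   (per variable x trait set [scale_trend()] objects), `maps`, `fields`,
#'   `space`, `pca` (per-scale PCA + parallel analysis when requested).
#' @export
run_study_analysis <- function(census, traits = NULL, soil_samples = NULL,
                               scales = c(5, 10, 20, 50), n_rand = 199,
                               env_vars = c("AP", "AK", "AN"),
                               with_pca = FALSE,
                               trait_sets = "multivariate",
                               alpha = 0.05,
                               vgm_model = "spherical",
                               correction = "cailliez", seed = NULL) {
  if (inherits(census, "synthetic_study")) {
    traits <- census$traits
    soil_samples <- census$soil_samples
    census <- census$census
  }
  stopifnot(inherits(census, "census_table"), !is.null(traits),
            !is.null(soil_samples))

  traits_std <- standardize_traits(traits)
  space_mv <- pcoa_embed(trait_distance(traits_std), correction = correction)
  spaces <- list()
  for (ts in trait_sets) {
    spaces[[ts]] <- if (ts == "multivariate") {
      space_mv
    } else {
      single_trait_space(traits_std, ts)
    }
  }
  perms <- null_permutations(nrow(traits_std), n_rand = n_rand, seed = seed)

  krige_vars <- if (with_pca) soil_variables() else env_vars
  vgms <- lapply(setNames(krige_vars, krige_vars), function(v) {
    fit_variogram(soil_samples, v, model = vgm_model)
  })

  maps <- list()
  fields <- list()
  pca_out <- list()
  results <- list()
  for (s in as.character(scales)) {
    sc <- as.numeric(s)
    comm <- make_grid(census, sc)
    for (ts in trait_sets) {
      maps[[ts]][[s]] <- dispersion_with_null(comm, spaces[[ts]], perms,
                                              trait_set = ts)
    }
    kriged <- lapply(setNames(krige_vars, krige_vars), function(v) {
      krige(soil_samples, v, comm$grid, vgms[[v]])
    })
    env_fields <- kriged[env_vars]
    if (with_pca) {
      pca <- soil_pca(kriged)
      pca_out[[s]] <- list(pca = pca,
                           parallel = horn_parallel(pca, seed = seed))
      env_fields <- c(env_fields, axis_fields(pca, n_axes = 2))
    }
    fields[[s]] <- env_fields
    for (v in names(env_fields)) {
      for (ts in trait_sets) {
        tt <- torus_test(maps[[ts]][[s]], env_fields[[v]], alpha = alpha)
        results[[length(results) + 1L]] <- data.frame(
          scale = sc, variable = v, trait_set = ts,
          r = tt$observed_r, p_low = tt$p_low, p_high = tt$p_high,
          verdict = tt$verdict, n_maps = tt$n_maps)
      }
    }
  }
  results <- do.call(rbind, results)

  trends <- list()
  for (v in unique(results$variable)) {
    for (ts in trait_sets) {
      sub <- results[results$variable == v & results$trait_set == ts, ]
      trends[[v]][[ts]] <- tryCatch(scale_trend(sub$r, sub$scale),
                                    error = function(e) NULL)
    }
  }

  structure(
    list(results = results, trends = trends, maps = maps, fields = fields,
         space = space_mv, pca = pca_out, variograms = vgms,
         n_rand = n_rand, seed = seed, alpha = alpha),
    class = "traitscape_analysis"
  )
}

#' @export
print.traitscape_analysis <- function(x, ...) {
  cat("traitscape_analysis (", x$n_rand, " randomizations)\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}
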