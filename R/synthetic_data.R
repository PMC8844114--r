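# Synthetic forest-plot generator.
#
# Builds a full virtual study -- autocorrelated soil surfaces with a
# grid-plus-offsets sampling design, a species pool with correlated traits
# and log-series-like regional abundances, and a stem census assembled
# quadrat by quadrat with a Gaussian trait filter whose width responds to
# designated "limited", "non-limited" and "saturated" soil resources. The
# ground truth (true surfaces, per-quadrat filter strength) is stored for
# recovery tests only and is never read by the analysis pipeline.

#' Default means and SDs of the nine soil variables
#'
#' Plot-level means and standard deviations used by the soil-field
#' generator, on the measurement scales of a subtropical forest topsoil
#' survey (pH unitless; SM %; OM g/kg; AN, AP, AK mg/kg; TN, TP g/kg; TK
#' g/kg).
#'
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
soil_variable_defaults <- function() {
  data.frame(
    variable = soil_variables(),
    mean = c(3.75, 18.84, 60.95, 201.74, 1.81, 55.04, 1.18, 0.28, 18.28),
    sd = c(0.08, 2.67, 10.93, 35.50, 1.06, 19.20, 0.49, 0.05, 3.34)
  )
}

#' Configuration for a synthetic study
#'
#' Defaults describe a full-size 500 x 400 m census plot with 134
#' trait-sampled species; [desk_config()] gives a smaller preset for
#' routine end-to-end runs. Effect sizes are constrained to the conceptual
#' resource-availability model: `beta["limited"] <= 0` (trait filtering
#' tightens, dispersion falls, where the limited resource is high),
#' `beta["non_limited"] >= 0`, `beta["saturated"] = 0`.
#'
#' @param plot_dim plot width and height in metres.
#' @param n_species species-pool size.
#' @param n_stems total stem count.
#' @param n_traits number of continuous traits.
#' @param trait_cor common pairwise trait correlation in the pool.
#' @param abund_par log-series-like shape parameter in (0, 1); larger is
#'   more even.
#' @param soil_range e-folding autocorrelation range of soil surfaces (m).
#' @param soil_nugget nugget fraction (non-spatial variance share) of soil
#'   samples.
#' @param soil_cor share of soil-surface variance from a common latent
#'   surface, inducing inter-variable correlation; the three role variables
#'   are kept independent of it so each availability class is separately
#'   identifiable.
#' @param grid_spacing,offsets soil sampling design (see
#'   [design_soil_grid()]).
#' @param roles mapping of availability classes to soil variables.
#' @param beta log-scale effect of each standardized resource on local
#'   filter width.
#' @param sigma0 baseline Gaussian filter width in standardized trait
#'   units; `Inf` disables trait filtering (random assembly).
#' @param assembly_scale quadrat side (m) at which stems are assembled.
#' @param optimum_range,optimum_amp autocorrelation range (m) and amplitude
#'   of the drifting local trait optimum.
#' @param lattice_spacing spacing (m) of the simulation lattice for random
#'   surfaces; must divide both plot dimensions.
#' @param seed integer seed making the whole study reproducible.
#' @return list of class `study_config`.
#' @export
study_config <- function(plot_dim = c(500, 400), n_species = 134,
                         n_stems = 20000, n_traits = 6, trait_cor = 0.3,
                         abund_par = 0.98, soil_range = 40,
                         soil_nugget = 0.2, soil_cor = 0.3,
                         grid_spacing = 30, offsets = c(2, 5, 15),
                         roles = c(limited = "AP", non_limited = "AK",
                                   saturated = "AN"),
                         beta = c(limited = -0.8, non_limited = 0.8,
                                  saturated = 0),
                         sigma0 = 2, assembly_scale = 10,
                         optimum_range = 150, optimum_amp = 0.5,
                         lattice_spacing = 10, seed = NULL) {
  stopifnot(n_species >= 2, n_stems >= 1, n_traits >= 1,
            trait_cor >= 0, trait_cor < 1,
            soil_nugget >= 0, soil_nugget <= 1,
            soil_cor >= 0, soil_cor < 1,
            all(names(roles) == c("limited", "non_limited", "saturated")),
            all(roles %in% soil_variables()),
            plot_dim %% lattice_spacing == 0,
            plot_dim %% assembly_scale == 0)
  if (beta[["limited"]] > 0 || beta[["non_limited"]] < 0 ||
      beta[["saturated"]] != 0) {
    stop("effect signs must match roles: beta[limited] <= 0, ",
         "beta[non_limited] >= 0, beta[saturated] = 0", call. = FALSE)
  }
  structure(
    list(plot_dim = plot_dim, n_species = n_species, n_stems = n_stems,
         n_traits = n_traits, trait_cor = trait_cor, abund_par = abund_par,
         soil_range = soil_range, soil_nugget = soil_nugget,
         soil_cor = soil_cor, grid_spacing = grid_spacing,
         offsets = offsets, roles = roles, beta = beta, sigma0 = sigma0,
         assembly_scale = assembly_scale, optimum_range = optimum_range,
         optimum_amp = optimum_amp, lattice_spacing = lattice_spacing,
         seed = seed),
    class = "study_config"
  )
}

#' Desk-scale study preset
#'
#' A 300 x 200 m plot with 21,600 stems of 60 species, tiling exactly at
#' the 5/10/20/50 m analysis scales. The stem density (0.36 stems per
#' square metre, about 140 stems per 20 m quadrat) matches large forest
#' dynamics plots, so per-quadrat dispersion estimates carry realistic
#' sampling noise; the whole pipeline at 199 randomizations still runs in
#' seconds.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
desk_config <- function(seed = NULL, ...) {
  args <- list(...)
  defaults <- list(plot_dim = c(300, 200), n_species = 60, n_stems = 21600,
                   seed = seed)
  do.call(study_config, utils::modifyList(defaults, args))
}

# -- Gaussian random fields on a lattice ------------------------------------
# Surfaces are simulated exactly (Cholesky of the exponential correlation
# matrix) on a regular lattice that includes the plot boundary, then read
# anywhere in the plot by bilinear interpolation. The Cholesky factor is
# shared by all surfaces with the same range.

grf_lattice <- function(plot_dim, spacing, range) {
  xs <- seq(0, plot_dim[1], by = spacing)
  ys <- seq(0, plot_dim[2], by = spacing)
  g <- expand.grid(x = xs, y = ys)
  h <- as.matrix(dist(g))
  C <- exp(-h / range) + diag(1e-8, nrow(g))
  list(xs = xs, ys = ys, L = chol(C), n = nrow(g))
}

grf_draw <- function(lat) {
  as.vector(crossprod(lat$L, rnorm(lat$n)))
}

grf_interp <- function(lat, values, x, y) {
  dx <- lat$xs[2] - lat$xs[1]
  dy <- lat$ys[2] - lat$ys[1]
  nx <- length(lat$xs)
  ny <- length(lat$ys)
  V <- matrix(values, nx, ny)
  i <- pmin(pmax(floor(x / dx) + 1L, 1L), nx - 1L)
  j <- pmin(pmax(floor(y / dy) + 1L, 1L), ny - 1L)
  tx <- (x - lat$xs[i]) / dx
  ty <- (y - lat$ys[j]) / dy
  V[cbind(i, j)] * (1 - tx) * (1 - ty) +
    V[cbind(i + 1L, j)] * tx * (1 - ty) +
    V[cbind(i, j + 1L)] * (1 - tx) * ty +
    V[cbind(i + 1L, j + 1L)] * tx * ty
}

#' Generate true soil surfaces and a sampled soil table
#'
#' Simulates one spatially autocorrelated surface per soil variable (an
#' exponential-correlation Gaussian random field with a common latent
#' component inducing inter-variable correlation), scaled to the default
#' plot-level means and SDs, then samples it at a regular-grid-plus-offsets
#' layout with nugget (measurement) noise. Strictly positive variables are
#' floored at 2% of their mean.
#'
#' @param config a `study_config`. Uses the current RNG state; seed the
#'   stream (or call via [simulate_study()]) for reproducibility.
#' @return list with `truth` (a `soil_truth`: lattice plus per-variable
#'   surface values) and `samples` (data.frame: `x`, `y`, nine soil
#'   columns).
#' @export
gen_soil_fields <- function(config) {
  stopifnot(inherits(config, "study_config"))
  defs <- soil_variable_defaults()
  lat <- grf_lattice(config$plot_dim, config$lattice_spacing,
                     config$soil_range)
  common <- grf_draw(lat)
  # role variables stay independent of the common fertility factor so each
  # availability class carries a separately identifiable spatial signal
  role_vars <- unname(config$roles)
  smooth <- vapply(seq_len(nrow(defs)), function(v) {
    w <- if (defs$variable[v] %in% role_vars) 0 else config$soil_cor
    sqrt(w) * common + sqrt(1 - w) * grf_draw(lat)
  }, numeric(lat$n))
  colnames(smooth) <- defs$variable
  truth <- structure(list(lattice = lat, smooth = smooth, defs = defs,
                          nugget = config$soil_nugget),
                     class = "soil_truth")
  design <- design_soil_grid(config$plot_dim, spacing = config$grid_spacing,
                             offsets = config$offsets)
  samples <- data.frame(x = design$x, y = design$y)
  for (v in defs$variable) {
    mu <- defs$mean[defs$variable == v]
    sdv <- defs$sd[defs$variable == v]
    s <- mu + sdv * sqrt(1 - config$soil_nugget) *
      grf_interp(lat, smooth[, v], design$x, design$y) +
      sdv * sqrt(config$soil_nugget) * rnorm(nrow(design))
    if (v != "pH") s <- pmax(s, 0.02 * mu)
    samples[[v]] <- s
  }
  list(truth = truth, samples = samples)
}

#' True (noise-free) soil surface on a quadrat grid
#'
#' Reads the ground-truth surface at quadrat centres. For recovery checks
#' only; the analysis pipeline sees only the sampled soil table.
#'
#' @param truth a `soil_truth` from [gen_soil_fields()].
#' @param variable soil variable name.
#' @param grid a `quadrat_grid`.
#' @return A `grid_field`.
#' @export
true_soil_field <- function(truth, variable, grid) {
  stopifnot(inherits(truth, "soil_truth"),
            variable %in% colnames(truth$smooth))
  defs <- truth$defs
  mu <- defs$mean[defs$variable == variable]
  sdv <- defs$sd[defs$variable == variable]
  ctr <- quadrat_centers(grid)
  vals <- mu + sdv * sqrt(1 - truth$nugget) *
    grf_interp(truth$lattice, truth$smooth[, variable], ctr$x, ctr$y)
  if (variable != "pH") vals <- pmax(vals, 0.02 * mu)
  grid_field(grid, variable, vals)
}

#' Generate a species pool with correlated traits
#'
#' Traits are drawn from a multivariate normal with common pairwise
#' correlation `trait_cor`; regional relative abundances follow a
#' log-series-like ranked distribution `p_i` proportional to `b^i / i`
#' (heavy-tailed, few dominants and many rare species). Trait values are
#' assigned to species independently of abundance rank.
#'
#' @param config a `study_config`. Uses the current RNG state.
#' @return list with `traits` (species x trait matrix, species `sp001`...)
#'   and `abundance` (named relative abundances summing to 1).
#' @export
gen_species_pool <- function(config) {
  stopifnot(inherits(config, "study_config"))
  S <- config$n_species
  K <- config$n_traits
  Sigma <- matrix(config$trait_cor, K, K)
  diag(Sigma) <- 1
  traits <- MASS::mvrnorm(S, mu = rep(0, K), Sigma = Sigma)
  rownames(traits) <- sprintf("sp%03d", seq_len(S))
  colnames(traits) <- if (K == 6) {
    c("Hmax", "LA", "SLA", "LDMC", "LT", "WD")
  } else {
    paste0("t", seq_len(K))
  }
  i <- seq_len(S)
  p <- config$abund_par^i / i
  p <- p / sum(p)
  names(p) <- rownames(traits)
  list(traits = traits, abundance = p)
}

#' Assemble a stem census under environment-dependent trait filtering
#'
#' Stems are placed quadrat by quadrat at the assembly scale. Within a
#' quadrat, species are sampled with weights proportional to regional
#' abundance times a Gaussian penalty on the trait-space distance to a
#' locally favoured optimum. The penalty width is
#' `sigma(q) = sigma0 * exp(b_lim z_lim + b_non z_non + b_sat z_sat)`,
#' where the `z` are the standardized local values of the limited,
#' non-limited and saturated resource surfaces: realized trait dispersion
#' falls where the limited resource is high, rises with the non-limited
#' resource, and ignores the saturated one. The local optimum drifts
#' smoothly across the plot. With `sigma0 = Inf` assembly is random with
#' respect to traits. Stem coordinates are uniform within the quadrat; DBH
#' is lognormal above the 1 cm census threshold.
#'
#' @param config a `study_config`. Uses the current RNG state.
#' @param soil output of [gen_soil_fields()] (its `truth` is used).
#' @param pool output of [gen_species_pool()].
#' @return list with `census` (a `census_table`) and `truth` (data.frame of
#'   per-assembly-quadrat filter width and standardized resource values).
#' @export
gen_census <- function(config, soil, pool) {
  stopifnot(inherits(config, "study_config"))
  agrid <- quadrat_grid(config$plot_dim, config$assembly_scale)
  nq <- n_quadrats(agrid)
  zr <- vapply(c("limited", "non_limited", "saturated"), function(role) {
    f <- true_soil_field(soil$truth, config$roles[[role]], agrid)
    as.vector(scale(f$values))
  }, numeric(nq))
  log_sigma <- log(config$sigma0) +
    zr %*% config$beta[c("limited", "non_limited", "saturated")]
  sigma <- exp(as.vector(log_sigma))

  Ts <- standardize_traits(pool$traits)
  K <- ncol(Ts)
  ctr <- quadrat_centers(agrid)
  opt_lat <- grf_lattice(config$plot_dim, config$lattice_spacing,
                         config$optimum_range)
  opt <- vapply(seq_len(K), function(k) {
    v <- grf_interp(opt_lat, grf_draw(opt_lat), ctr$x, ctr$y)
    config$optimum_amp * as.vector(scale(v))
  }, numeric(nq))

  p <- pool$abundance
  S <- length(p)
  n_per_q <- as.vector(rmultinom(1, config$n_stems, rep(1, nq)))
  if (is.finite(config$sigma0)) {
    d2 <- matrix(rowSums(opt^2), nq, S) - 2 * (opt %*% t(Ts)) +
      matrix(rowSums(Ts^2), nq, S, byrow = TRUE)
    logw <- sweep(-d2, 1, 2 * sigma^2, "/")
    logw <- logw + matrix(log(p), nq, S, byrow = TRUE)
    logw <- logw - apply(logw, 1, max)
    Wt <- exp(logw)
  } else {
    Wt <- matrix(p, nq, S, byrow = TRUE)
  }
  sp_idx <- integer(config$n_stems)
  pos <- 1L
  for (q in seq_len(nq)) {
    if (n_per_q[q] == 0) next
    take <- sample.int(S, n_per_q[q], replace = TRUE, prob = Wt[q, ])
    sp_idx[pos:(pos + n_per_q[q] - 1L)] <- take
    pos <- pos + n_per_q[q]
  }
  qid <- rep(seq_len(nq), n_per_q)
  col <- ((qid - 1L) %% agrid$nx)
  row <- ((qid - 1L) %/% agrid$nx)
  n <- config$n_stems
  df <- data.frame(
    stem_id = sprintf("s%06d", seq_len(n)),
    x = (col + runif(n)) * agrid$scale,
    y = (row + runif(n)) * agrid$scale,
    species = rownames(Ts)[sp_idx],
    dbh = 1 + rlnorm(n, meanlog = log(2), sdlog = 0.8)
  )
  truth <- data.frame(quadrat = seq_len(nq), sigma = sigma,
                      z_limited = zr[, "limited"],
                      z_non_limited = zr[, "non_limited"],
                      z_saturated = zr[, "saturated"])
  list(census = as_census_table(df, config$plot_dim),
       truth = truth)
}

#' Generate a complete synthetic study
#'
#' Seeds the RNG once from `config$seed` and runs [gen_soil_fields()],
#' [gen_species_pool()] and [gen_census()] in sequence, so identical
#' configurations reproduce the study bit-exactly.
#'
#' @param config a `study_config`.
#' @return A `synthetic_study`: list with `config`, `census`, `traits`,
#'   `regional_abundance`, `soil_samples`, and `truth` (list with `soil`, a
#'   `soil_truth`, and `assembly`, the per-quadrat filter record). The
#'   `truth` element exists for recovery tests only.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  soil <- gen_soil_fields(config)
  pool <- gen_species_pool(config)
  cen <- gen_census(config, soil, pool)
  structure(
    list(config = config, census = cen$census, traits = pool$traits,
         regional_abundance = pool$abundance, soil_samples = soil$samples,
         truth = list(soil = soil$truth, assembly = cen$truth)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d stems, %d species, %g x %g m plot, %d soil samples\n",
    nrow(x$census), x$config$n_species, x$config$plot_dim[1],
    x$config$plot_dim[2], nrow(x$soil_samples)))
  invisible(x)
}

#' Write a synthetic study to CSV files
#'
#' Writes `census.csv`, `traits.csv` and `soil_samples.csv` (the pipeline
#' inputs) plus `truth/assembly.csv` (ground truth, for recovery checks
#' only).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(study$census), file.path(dir, "census.csv"),
            row.names = FALSE)
  tr <- data.frame(species = rownames(study$traits), study$traits,
                   row.names = NULL)
  write.csv(tr, file.path(dir, "traits.csv"), row.names = FALSE)
  write.csv(study$soil_samples, file.path(dir, "soil_samples.csv"),
            row.names = FALSE)
  write.csv(study$truth$assembly, file.path(dir, "truth", "assembly.csv"),
            row.names = FALSE)
  invisible(dir)
}
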