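# Census tables and quadrat grids.
#
# Coordinates use a half-open convention: a stem belongs to quadrat
# [i*scale, (i+1)*scale) x [j*scale, (j+1)*scale), so every stem inside
# [0, W) x [0, H) falls in exactly one quadrat and x == W or y == H is
# invalid input.

#' Quadrat grid for a rectangular plot
#'
#' Tiles a `plot_dim[1]` x `plot_dim[2]` metre plot into square quadrats of
#' side `scale` metres. The scale must divide both plot dimensions exactly;
#' partial edge quadrats are not supported.
#'
#' Quadrats are indexed 1..`nx*ny` in row-major order over (column, row):
#' index `q = (row - 1) * nx + col`, with column 1 at x = 0 and row 1 at
#' y = 0.
#'
#' @param plot_dim numeric length 2, plot width and height in metres.
#' @param scale quadrat side in metres.
#' @return An object of class `quadrat_grid` with elements `scale`, `nx`,
#'   `ny`, `plot_dim`.
#' @export
quadrat_grid <- function(plot_dim, scale) {
  stopifnot(length(plot_dim) == 2, all(plot_dim > 0), length(scale) == 1,
            scale > 0)
  nx <- plot_dim[1] / scale
  ny <- plot_dim[2] / scale
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("scale ", scale, " m does not tile a ", plot_dim[1], " x ",
         plot_dim[2], " m plot into whole quadrats", call. = FALSE)
  }
  structure(
    list(scale = scale, nx = as.integer(round(nx)), ny = as.integer(round(ny)),
         plot_dim = as.numeric(plot_dim)),
    class = "quadrat_grid"
  )
}

#' Number of quadrats in a grid
#' @param grid a `quadrat_grid`.
#' @return integer quadrat count `nx * ny`.
#' @export
n_quadrats <- function(grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  grid$nx * grid$ny
}

#' Map plot coordinates to quadrat indices
#'
#' @param grid a `quadrat_grid`.
#' @param x,y coordinates in metres, `0 <= x < plot width` etc.
#' @return integer vector of quadrat indices (row-major, see
#'   [quadrat_grid()]).
#' @export
quadrat_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "quadrat_grid"))
  if (any(x < 0 | x >= grid$plot_dim[1] | y < 0 | y >= grid$plot_dim[2])) {
    stop("coordinates outside the half-open plot extent", call. = FALSE)
  }
  col <- floor(x / grid$scale)
  row <- floor(y / grid$scale)
  as.integer(row * grid$nx + col + 1L)
}

#' Quadrat centre coordinates
#'
#' @param grid a `quadrat_grid`.
#' @return data.frame with columns `quadrat`, `col`, `row`, `x`, `y`; `x`,`y`
#'   are quadrat-centre coordinates in metres, ordered by quadrat index.
#' @export
quadrat_centers <- function(grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  q <- seq_len(n_quadrats(grid))
  col <- ((q - 1L) %% grid$nx) + 1L
  row <- ((q - 1L) %/% grid$nx) + 1L
  data.frame(quadrat = q, col = col, row = row,
             x = (col - 0.5) * grid$scale, y = (row - 0.5) * grid$scale)
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("quadrat_grid: %g x %g m plot, %g m quadrats (%d x %d = %d)\n",
              x$plot_dim[1], x$plot_dim[2], x$scale, x$nx, x$ny,
              n_quadrats(x)))
  invisible(x)
}

validate_census <- function(df, plot_dim, dbh_min, src = "census table") {
  required <- c("stem_id", "x", "y", "species", "dbh")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(src, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("x", "y", "dbh")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad)) {
      stop(src, ": non-numeric or missing '", col, "' in row ", bad[1],
           call. = FALSE)
    }
    df[[col]] <- v
  }
  out <- which(df$x < 0 | df$x >= plot_dim[1] | df$y < 0 | df$y >= plot_dim[2])
  if (length(out)) {
    stop(src, ": coordinates outside [0, ", plot_dim[1], ") x [0, ",
         plot_dim[2], ") in row ", out[1], " (stem ",
         df$stem_id[out[1]], ")", call. = FALSE)
  }
  keep <- df$dbh >= dbh_min
  n_below <- sum(!keep)
  df <- df[keep, required, drop = FALSE]
  df$species <- as.character(df$species)
  rownames(df) <- NULL
  structure(df, plot_dim = as.numeric(plot_dim), dbh_min = dbh_min,
            n_below_dbh = n_below, n_untraited = 0L,
            class = c("census_table", "data.frame"))
}

#' Build a census table from a data frame
#'
#' Validates stem records against the plot extent and the minimum-DBH census
#' rule. Stems with `dbh < dbh_min` are dropped and counted (attribute
#' `n_below_dbh`). Optionally drops stems whose species is absent from a
#' trait table (attribute `n_untraited`), mirroring the common situation
#' where only the most abundant species are trait-sampled.
#'
#' @param df data.frame with columns `stem_id`, `x`, `y`, `species`, `dbh`
#'   (coordinates in metres, DBH in cm).
#' @param plot_dim numeric length 2, plot width and height in metres.
#' @param dbh_min minimum DBH retained, default 1 cm.
#' @param species_pool optional character vector of species with trait data.
#' @param untraited what to do with stems of species not in `species_pool`:
#'   `"drop"` (default, with count recorded), `"error"`, or `"keep"`.
#' @return A `census_table` (data.frame subclass) with attributes
#'   `plot_dim`, `dbh_min`, `n_below_dbh`, `n_untraited`.
#' @export
as_census_table <- function(df, plot_dim, dbh_min = 1,
                            species_pool = NULL,
                            untraited = c("drop", "error", "keep")) {
  untraited <- match.arg(untraited)
  cen <- validate_census(df, plot_dim, dbh_min)
  if (!is.null(species_pool)) {
    miss <- !(cen$species %in% species_pool)
    if (any(miss)) {
      if (untraited == "error") {
        stop("census contains ", sum(miss),
             " stems of species absent from the trait table", call. = FALSE)
      }
      if (untraited == "drop") {
        attr_keep <- attributes(cen)
        n_un <- sum(miss)
        cen <- cen[!miss, , drop = FALSE]
        rownames(cen) <- NULL
        for (a in c("plot_dim", "dbh_min", "n_below_dbh")) {
          attr(cen, a) <- attr_keep[[a]]
        }
        attr(cen, "n_untraited") <- n_un
        class(cen) <- c("census_table", "data.frame")
      }
    }
  }
  cen
}

#' Read a stem census from CSV
#'
#' Expects a header row and columns `stem_id`, `x`, `y`, `species`, `dbh`.
#' See [as_census_table()] for validation and filtering rules.
#'
#' @inheritParams as_census_table
#' @param path CSV file path.
#' @return A `census_table`.
#' @export
read_census <- function(path, plot_dim, dbh_min = 1, species_pool = NULL,
                        untraited = c("drop", "error", "keep")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_census_table(df, plot_dim, dbh_min = dbh_min,
                  species_pool = species_pool, untraited = untraited)
}

#' @export
print.census_table <- function(x, ...) {
  pd <- attr(x, "plot_dim")
  cat(sprintf("census_table: %d stems, %d species, %g x %g m plot\n",
              nrow(x), length(unique(x$species)), pd[1], pd[2]))
  cat(sprintf("  excluded: %d below %g cm DBH, %d without trait data\n",
              attr(x, "n_below_dbh"), attr(x, "dbh_min"),
              attr(x, "n_untraited")))
  invisible(x)
}

#' Tile a census into a quadrat community
#'
#' Assigns every stem to exactly one quadrat (half-open intervals) and
#' tabulates a quadrat x species abundance matrix of stem counts.
#'
#' @param census a `census_table`.
#' @param scale quadrat side in metres; must divide both plot dimensions.
#' @return A `quadrat_community`: list with `grid` ([quadrat_grid()]),
#'   `species` (sorted character vector), and `abundance` (integer matrix,
#'   quadrats x species).
#' @export
make_grid <- function(census, scale) {
  stopifnot(inherits(census, "census_table"))
  grid <- quadrat_grid(attr(census, "plot_dim"), scale)
  q <- quadrat_index(grid, census$x, census$y)
  species <- sort(unique(census$species))
  ab <- table(factor(q, levels = seq_len(n_quadrats(grid))),
              factor(census$species, levels = species))
  ab <- matrix(as.integer(ab), nrow = n_quadrats(grid),
               dimnames = list(NULL, species))
  structure(list(grid = grid, species = species, abundance = ab),
            class = "quadrat_community")
}

#' @export
print.quadrat_community <- function(x, ...) {
  cat(sprintf("quadrat_community: %d quadrats (%g m), %d species, %d stems\n",
              n_quadrats(x$grid), x$grid$scale, length(x$species),
              sum(x$abundance)))
  invisible(x)
}

#' Per-scale abundance and richness summary
#'
#' Mean, standard error (sample SD / sqrt(number of quadrats)), minimum and
#' maximum of per-quadrat stem count and species richness.
#'
#' @param comm a `quadrat_community`.
#' @return data.frame with one row per metric (`abundance`, `richness`).
#' @export
community_summary <- function(comm) {
  stopifnot(inherits(comm, "quadrat_community"))
  n <- rowSums(comm$abundance)
  s <- rowSums(comm$abundance > 0)
  summarise <- function(v) {
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    c(mean = mean(v), se = se, min = min(v), max = max(v))
  }
  out <- rbind(abundance = summarise(n), richness = summarise(s))
  data.frame(scale = comm$grid$scale,
             n_quadrats = n_quadrats(comm$grid),
             metric = rownames(out), out, row.names = NULL)
}
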