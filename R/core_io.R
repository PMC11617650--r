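# Domain types, tabular readers/writers, and prediction-grid construction.

PHENOTYPE_COLUMNS <- c("trial_id", "genotype_id", "year", "irrigated",
                       "region", "lat", "lon", "yield_blue")
PEDIGREE_COLUMNS <- c("genotype_id", "dam_id", "sire_id")
UNKNOWN_PARENT <- "UNKNOWN"

#' Read and validate a phenotype table of trial-level standardized BLUEs
#'
#' The file is a UTF-8 CSV with header
#' `trial_id,genotype_id,year,irrigated,region,lat,lon,yield_blue`; one row
#' per (trial, genotype) combination. Each trial must carry a single set of
#' metadata (year, irrigation flag, region, coordinates).
#'
#' @param path path to a delimited text file.
#' @return a validated `data.frame` of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(df)
}

#' Validate an in-memory phenotype table
#'
#' @param df data.frame with the phenotype schema (see [read_phenotypes()]).
#' @return the table, typed and classed `phenotype_table`.
#' @export
validate_phenotypes <- function(df) {
  missing_cols <- setdiff(PHENOTYPE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  yb <- suppressWarnings(as.numeric(df$yield_blue))
  bad <- which(!is.finite(yb))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite yield_blue at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$yield_blue <- yb
  df$year <- as.integer(df$year)
  df$irrigated <- as.logical(df$irrigated)
  df$trial_id <- as.character(df$trial_id)
  df$genotype_id <- as.character(df$genotype_id)
  key <- paste(df$trial_id, df$genotype_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (trial_id, genotype_id) pair(s), e.g. ",
         sub("\r", " / ", key[duplicated(key)][1]), call. = FALSE)
  }
  meta <- unique(df[, c("trial_id", "year", "irrigated", "region", "lat", "lon")])
  if (anyDuplicated(meta$trial_id)) {
    stop("trial(s) with inconsistent metadata: ",
         paste(unique(meta$trial_id[duplicated(meta$trial_id)]), collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a pedigree table
#'
#' CSV with header `genotype_id,dam_id,sire_id`. Unknown parents are coded
#' `UNKNOWN` (empty or `NA` cells are normalized to `UNKNOWN`). Genotypes
#' with both parents unknown are founders (or competitor hybrids).
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `pedigree`.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_pedigree(df)
}

#' @rdname read_pedigree
#' @param df in-memory pedigree data.frame.
#' @export
validate_pedigree <- function(df) {
  missing_cols <- setdiff(PEDIGREE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("pedigree is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in PEDIGREE_COLUMNS) {
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]]) | df[[cc]] == ""] <- UNKNOWN_PARENT
  }
  if (anyDuplicated(df$genotype_id)) {
    stop("duplicated genotype_id in pedigree: ",
         df$genotype_id[duplicated(df$genotype_id)][1], call. = FALSE)
  }
  named_parents <- setdiff(unique(c(df$dam_id, df$sire_id)), UNKNOWN_PARENT)
  orphans <- setdiff(named_parents, df$genotype_id)
  if (length(orphans) > 0) {
    extra <- data.frame(genotype_id = orphans, dam_id = UNKNOWN_PARENT,
                        sire_id = UNKNOWN_PARENT, stringsAsFactors = FALSE)
    df <- rbind(df, extra)
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read an environmental covariate table
#'
#' CSV with header `location_id,lat,lon,<covariate...>`; rows keyed by a
#' trial or grid-bin id. Missing covariate cells are imputed by the column
#' median (count reported via message). An optional `sources` attribute (a
#' named character vector covariate -> source tag) can be attached by the
#' caller; the synthetic generator sets it automatically.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `covariate_table`.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_covariates(df)
}

#' @rdname read_covariates
#' @param df in-memory covariate data.frame.
#' @export
validate_covariates <- function(df) {
  needed <- c("location_id", "lat", "lon")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  covs <- setdiff(names(df), needed)
  if (length(covs) < 1) stop("covariate table has no covariate columns", call. = FALSE)
  if (anyDuplicated(names(df))) stop("duplicated column names", call. = FALSE)
  if (anyDuplicated(df$location_id)) stop("duplicated location_id", call. = FALSE)
  n_imputed <- 0L
  for (cc in covs) {
    v <- as.numeric(df[[cc]])
    nas <- !is.finite(v)
    if (any(nas)) {
      v[nas] <- stats::median(v[!nas])
      n_imputed <- n_imputed + sum(nas)
    }
    df[[cc]] <- v
  }
  if (n_imputed > 0) message("imputed ", n_imputed,
                             " missing covariate cells by column median")
  df$location_id <- as.character(df$location_id)
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Names of the covariate columns of a covariate table
#' @param covariates a `covariate_table`.
#' @return character vector of covariate column names.
#' @export
covariate_names <- function(covariates) {
  setdiff(names(covariates), c("location_id", "lat", "lon"))
}

#' Build the prediction grid covering the trial network
#'
#' Projects the trial points to local planar km, takes their convex hull,
#' dilates it by `buffer_km` (Euclidean distance to the hull polygon), and
#' lays a regular square lattice of `cell_size_km` cells over the dilated
#' region. A bin is kept iff its centroid lies inside the dilated hull. The
#' lattice is anchored at the buffered bounding-box minimum so the
#' construction is invariant to the order of the input points.
#'
#' @param trial_points data.frame with `lat`, `lon` columns (degrees, WGS84).
#' @param cell_size_km cell side length in km (default 5, i.e. 25 km^2 bins).
#' @param buffer_km buffer beyond the hull in km (default 50).
#' @return an object of class `prediction_grid`: list with `bins` (data.frame
#'   `bin_id, lat, lon, x_km, y_km`), `cell_size_km`, `buffer_km`, `origin`
#'   (lat/lon of the projection reference) and `hull_km` (hull vertices, km).
#' @export
build_prediction_grid <- function(trial_points, cell_size_km = 5, buffer_km = 50) {
  pts <- unique(data.frame(lat = as.numeric(trial_points$lat),
                           lon = as.numeric(trial_points$lon)))
  if (nrow(pts) < 3) stop("need at least 3 distinct trial points", call. = FALSE)
  origin <- c(mean(pts$lat), mean(pts$lon))
  xy <- project_local_km(pts$lat, pts$lon, origin)
  hull_idx <- grDevices::chull(xy)
  if (length(hull_idx) < 3) stop("trial points are collinear", call. = FALSE)
  hull <- xy[hull_idx, , drop = FALSE]
  # area check: chull of >=3 points can still be degenerate numerically
  a <- 0
  n <- nrow(hull)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- a + hull[i, 1] * hull[j, 2] - hull[j, 1] * hull[i, 2]
  }
  if (abs(a) < 1e-9) stop("trial points are collinear", call. = FALSE)

  x0 <- min(xy[, 1]) - buffer_km
  y0 <- min(xy[, 2]) - buffer_km
  nx <- max(1L, ceiling((diff(range(xy[, 1])) + 2 * buffer_km) / cell_size_km))
  ny <- max(1L, ceiling((diff(range(xy[, 2])) + 2 * buffer_km) / cell_size_km))
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size_km
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size_km
  cand <- expand.grid(x_km = xc, y_km = yc, KEEP.OUT.ATTRS = FALSE)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    distance_to_polygon(c(cand$x_km[i], cand$y_km[i]), hull) <= buffer_km + 1e-9
  }, logical(1))
  bins <- cand[keep, , drop = FALSE]
  if (nrow(bins) == 0) {
    # degenerate: cell larger than the buffered hull; keep the hull centroid cell
    bins <- data.frame(x_km = mean(hull[, 1]), y_km = mean(hull[, 2]))
  }
  ll <- unproject_local_km(bins$x_km, bins$y_km, origin)
  bins <- data.frame(bin_id = sprintf("B%05d", seq_len(nrow(bins))),
                     lat = ll[, "lat"], lon = ll[, "lon"],
                     x_km = bins$x_km, y_km = bins$y_km,
                     stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  structure(list(bins = bins, cell_size_km = cell_size_km,
                 buffer_km = buffer_km, origin = origin, hull_km = hull),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("prediction_grid:", nrow(x$bins), "bins of", x$cell_size_km,
      "km, buffer", x$buffer_km, "km\n")
  invisible(x)
}

#' Locate grid bins for arbitrary coordinates
#'
#' Returns, for each (lat, lon) pair, the id of the nearest grid-bin centroid
#' (in planar km).
#'
#' @param grid a `prediction_grid`.
#' @param lat,lon coordinate vectors in degrees.
#' @return character vector of bin ids.
#' @export
nearest_bin <- function(grid, lat, lon) {
  xy <- project_local_km(lat, lon, grid$origin)
  vapply(seq_len(nrow(xy)), function(i) {
    d2 <- (grid$bins$x_km - xy[i, 1])^2 + (grid$bins$y_km - xy[i, 2])^2
    grid$bins$bin_id[which.min(d2)]
  }, character(1))
}

#' Write a per-bin map layer as long-format CSV
#'
#' One row per bin: `bin_id, lat, lon, value`. `NA`/`NaN` values are written
#' as the literal token `NA` and round-trip through [read_grid_layer()].
#'
#' @param grid a `prediction_grid`.
#' @param values numeric vector, one value per bin (in grid bin order).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_grid_layer <- function(grid, values, path) {
  if (length(values) != nrow(grid$bins)) {
    stop("length(values) (", length(values), ") != number of bins (",
         nrow(grid$bins), ")", call. = FALSE)
  }
  out <- data.frame(bin_id = grid$bins$bin_id, lat = grid$bins$lat,
                    lon = grid$bins$lon, value = as.numeric(values))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_layer
#' @export
read_grid_layer <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration with study-scale defaults
#'
#' Central container for every tunable. Defaults follow the study design
#' where one is stated (10 000 trees, K = 7 markers, 1000 ensemble runs,
#' 5 km cells, 50 km buffer, 4 breeding zones) and field-standard choices
#' elsewhere.
#'
#' @param n_trees number of regression trees in the marker bank.
#' @param K number of engineered enviromic markers (tree clusters).
#' @param n_runs number of ensemble model runs.
#' @param subsample_fraction genotype subsample fraction per tree.
#' @param alpha significance level for per-bin statistical ties.
#' @param n_zones number of breeding zones.
#' @param cell_size_km,buffer_km prediction-grid geometry in km.
#' @param variogram_model theoretical variogram model for kriging.
#' @param seed integer random seed.
#' @param ... further named tunables stored verbatim.
#' @return a list of class `reem_config`.
#' @export
reem_config <- function(n_trees = 10000, K = 7, n_runs = 1000,
                        subsample_fraction = 0.5, alpha = 0.05, n_zones = 4,
                        cell_size_km = 5, buffer_km = 50,
                        variogram_model = "spherical", seed = 1, ...) {
  cfg <- c(list(n_trees = n_trees, K = K, n_runs = n_runs,
                subsample_fraction = subsample_fraction, alpha = alpha,
                n_zones = n_zones, cell_size_km = cell_size_km,
                buffer_km = buffer_km, variogram_model = variogram_model,
                seed = as.integer(seed)), list(...))
  stopifnot(cfg$n_trees >= 1, cfg$K >= 1, cfg$n_runs >= 1,
            cfg$subsample_fraction > 0, cfg$subsample_fraction <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$n_zones >= 2)
  class(cfg) <- "reem_config"
  cfg
}

#' Read / write a run configuration (YAML)
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(reem_config, cfg)
}

#' @rdname read_config
#' @param config a `reem_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a phenotype / pedigree / covariate table as CSV
#' @param x the table.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
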