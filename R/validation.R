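# Cross-validation harness for the three models, trial-level metrics, and
# ordinary kriging of predictive-ability surfaces.
#
# Metrics are computed within trial and summarized across trials: pooling
# records over trials can reverse within-trial associations (Simpson's
# paradox), so pooled correlations are avoided by design.

#' Per-trial predictive-ability metrics
#'
#' Pearson r, Spearman rho (average ranks on ties) and RMSE computed within
#' each trial; trials with fewer than `min_genotypes` records are skipped.
#' The scheme summary is the unweighted mean and SD over trials.
#'
#' @param observed,predicted numeric vectors, one entry per record.
#' @param trial_ids character vector aligning records to trials.
#' @param min_genotypes minimum records per evaluated trial (default 3).
#' @return object of class `validation_report`: `per_trial` data.frame
#'   (trial_id, n, pearson, spearman, rmse) and `summary` (mean/sd rows).
#' @export
per_trial_metrics <- function(observed, predicted, trial_ids,
                              min_genotypes = 3) {
  stopifnot(length(observed) == length(predicted),
            length(observed) == length(trial_ids))
  rows <- lapply(sort(unique(trial_ids)), function(tt) {
    sel <- trial_ids == tt
    if (sum(sel) < min_genotypes) return(NULL)
    o <- observed[sel]; p <- predicted[sel]
    if (stats::sd(o) == 0 || stats::sd(p) == 0) {
      r <- rho <- NA_real_
    } else {
      r <- stats::cor(o, p)
      rho <- stats::cor(o, p, method = "spearman")
    }
    data.frame(trial_id = tt, n = sum(sel), pearson = r, spearman = rho,
               rmse = sqrt(mean((o - p)^2)), stringsAsFactors = FALSE)
  })
  per_trial <- do.call(rbind, rows)
  summarize_validation(per_trial)
}

summarize_validation <- function(per_trial, scheme = NA_character_,
                                 model = NA_character_) {
  metrics <- c("pearson", "spearman", "rmse")
  if (is.null(per_trial)) {
    per_trial <- data.frame(trial_id = character(0), n = integer(0),
                            pearson = numeric(0), spearman = numeric(0),
                            rmse = numeric(0), stringsAsFactors = FALSE)
  }
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_trial[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(per_trial[[m]],
                                               na.rm = TRUE), numeric(1)),
    n_trials = nrow(per_trial), stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_trial = per_trial, summary = summary, scheme = scheme,
                 model = model), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report", if (!is.na(x$scheme)) paste0("(", x$scheme, ", ",
                                                        x$model, ")"), ":",
      nrow(x$per_trial), "trials; mean Pearson",
      signif(x$summary$mean[x$summary$metric == "pearson"], 3), "\n")
  invisible(x)
}

# Fit on training trials and predict the test records, per model.
cv_fold_predict <- function(model, train, test, trial_covariates, kinship,
                            cfg, frozen = NULL, seed = 1) {
  test_trials <- unique(test$trial_id)
  if (model == "baseline") {
    fit <- suppressMessages(suppressWarnings(
      baseline_gxe_fit(train, kinship, tol = cfg$tol, maxit = cfg$maxit)))
    return(predict_baseline(fit, test$genotype_id, test$irrigated))
  }
  if (is.null(frozen)) {
    train_cov <- trial_covariates[trial_covariates$location_id %in%
                                    unique(train$trial_id), ]
    bank <- fit_tree_bank(train_cov, train, n_trees = cfg$cv_n_trees,
                          subsample_fraction = cfg$subsample_fraction,
                          seed = seed)
    eem_set <- cluster_and_aggregate(bank, K = cfg$K,
                                     reference_covariates = trial_covariates)
  } else {
    bank <- frozen$bank
    eem_set <- frozen$eem_set
  }
  at_all <- eem_values_at(eem_set, bank, trial_covariates)
  markers <- at_all$eem
  if (model == "kernel") {
    fit <- suppressWarnings(kernel_gxe_fit(
      train, markers[unique(train$trial_id), , drop = FALSE], kinship,
      tol = cfg$tol, maxit = cfg$maxit))
    return(predict_kernel(fit, test$genotype_id,
                          markers[test$trial_id, , drop = FALSE]))
  }
  # reaction-norm ensemble; held-out trials play the role of "bins"
  test_cov <- trial_covariates[trial_covariates$location_id %in% test_trials, ]
  train_cov <- trial_covariates[trial_covariates$location_id %in%
                                  unique(train$trial_id), ]
  ens <- suppressMessages(ensemble_reem(
    train, bank, eem_set, kinship, train_cov, test_cov,
    n_runs = cfg$cv_n_runs, seed = seed, tol = cfg$tol, maxit = cfg$maxit,
    max_drop_fraction = cfg$max_drop_fraction))
  ens$mean[cbind(test$genotype_id, test$trial_id)]
}

cv_config <- function(config = list()) {
  defaults <- list(K = 4, cv_n_trees = 150, cv_n_runs = 8,
                   subsample_fraction = 0.5, tol = 1e-6, maxit = 1500,
                   min_genotypes = 3, max_drop_fraction = 0.5)
  defaults[names(config)] <- config
  defaults
}

#' Leave-one-trial-out cross-validation
#'
#' For each trial, the chosen model is refit without it and its records are
#' predicted at the held-out trial's covariates, then scored with
#' [per_trial_metrics()]. For the marker-based models the tree bank is
#' refit per fold by default; pass `frozen = list(bank, eem_set)` for the
#' fast frozen-bank mode (documented leakage of the held-out trial mean
#' into the marker engine).
#'
#' @param phenotypes a `phenotype_table`.
#' @param trial_covariates covariates at all trials.
#' @param kinship a `kinship_matrix`.
#' @param model `"reem"`, `"baseline"` or `"kernel"`.
#' @param config list of tunables (`K`, `cv_n_trees`, `cv_n_runs`, ...).
#' @param frozen optional prefit `list(bank, eem_set)`.
#' @param seed integer seed.
#' @return a `validation_report`.
#' @export
loo_trial_cv <- function(phenotypes, trial_covariates, kinship,
                         model = c("reem", "baseline", "kernel"),
                         config = list(), frozen = NULL, seed = 1) {
  model <- match.arg(model)
  cfg <- cv_config(config)
  trials <- sort(unique(phenotypes$trial_id))
  if (length(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  pred <- rep(NA_real_, nrow(phenotypes))
  for (i in seq_along(trials)) {
    test_sel <- phenotypes$trial_id == trials[i]
    test <- phenotypes[test_sel, ]
    train <- phenotypes[!test_sel, ]
    stopifnot(!any(test$trial_id %in% train$trial_id))  # no fold leakage
    p <- tryCatch(
      cv_fold_predict(model, train, test, trial_covariates, kinship, cfg,
                      frozen = frozen, seed = seed + i),
      error = function(e) {
        warning("fold ", trials[i], " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(p)) pred[test_sel] <- p
  }
  ok <- !is.na(pred)
  rep_ <- per_trial_metrics(phenotypes$yield_blue[ok], pred[ok],
                            phenotypes$trial_id[ok],
                            min_genotypes = cfg$min_genotypes)
  rep_$scheme <- "loo"; rep_$model <- model
  rep_$predictions <- pred
  rep_
}

#' Leave-region-out cross-validation
#'
#' One fold per region label: the model is trained on the other regions and
#' scored per trial within the held-out region. The `overall` report pools
#' all folds' trial-level metrics into a single mean and SD.
#'
#' @inheritParams loo_trial_cv
#' @return list with `per_region` (named list of `validation_report`) and
#'   `overall` (a `validation_report` over all trials).
#' @export
leave_region_out_cv <- function(phenotypes, trial_covariates, kinship,
                                model = c("reem", "baseline", "kernel"),
                                config = list(), frozen = NULL, seed = 1) {
  model <- match.arg(model)
  cfg <- cv_config(config)
  regions <- sort(unique(phenotypes$region))
  if (length(regions) < 2) stop("need at least 2 regions", call. = FALSE)
  pred <- rep(NA_real_, nrow(phenotypes))
  per_region <- list()
  for (rg in regions) {
    test_sel <- phenotypes$region == rg
    if (!any(test_sel)) next
    test <- phenotypes[test_sel, ]
    train <- phenotypes[!test_sel, ]
    stopifnot(length(intersect(test$trial_id, train$trial_id)) == 0)
    p <- tryCatch(
      cv_fold_predict(model, train, test, trial_covariates, kinship, cfg,
                      frozen = frozen, seed = seed + which(regions == rg)),
      error = function(e) {
        warning("region ", rg, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(p)) next
    pred[test_sel] <- p
    rr <- per_trial_metrics(test$yield_blue, p, test$trial_id,
                            min_genotypes = cfg$min_genotypes)
    rr$scheme <- paste0("region:", rg); rr$model <- model
    per_region[[rg]] <- rr
  }
  ok <- !is.na(pred)
  overall <- per_trial_metrics(phenotypes$yield_blue[ok], pred[ok],
                               phenotypes$trial_id[ok],
                               min_genotypes = cfg$min_genotypes)
  overall$scheme <- "region-overall"; overall$model <- model
  overall$predictions <- pred
  list(per_region = per_region, overall = overall)
}

# spherical semivariogram
sph_gamma <- function(h, nugget, psill, range_) {
  ifelse(h <= 0, 0,
         ifelse(h >= range_, nugget + psill,
                nugget + psill * (1.5 * h / range_ -
                                    0.5 * (h / range_)^3)))
}

#' Fit a spherical variogram to an empirical semivariogram by WLS
#'
#' Empirical semivariances are binned into `n_lags` equal-width lags up to
#' half the maximum pairwise distance and the spherical model (nugget,
#' partial sill, range) is fit by weighted least squares with pair-count
#' weights.
#'
#' @param xy n x 2 planar coordinates (km).
#' @param values numeric vector at the points.
#' @param n_lags number of lag bins (default 15).
#' @return list with `nugget`, `psill`, `range_km` and the binned empirical
#'   variogram (`lag`, `gamma`, `n_pairs`).
#' @export
fit_spherical_variogram <- function(xy, values, n_lags = 15) {
  n <- nrow(xy)
  dmat <- as.matrix(stats::dist(xy))
  ut <- upper.tri(dmat)
  h <- dmat[ut]
  sv <- 0.5 * outer(values, values, "-")[ut]^2
  hmax <- max(h) / 2
  breaks <- seq(0, hmax, length.out = n_lags + 1)
  lag_idx <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(lag_idx)
  gamma_hat <- tapply(sv[keep], lag_idx[keep], mean)
  n_pairs <- tapply(sv[keep], lag_idx[keep], length)
  lag_mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  lags <- as.integer(names(gamma_hat))
  emp <- data.frame(lag = lag_mid[lags], gamma = as.numeric(gamma_hat),
                    n_pairs = as.integer(n_pairs))
  obj <- function(par) {
    g <- sph_gamma(emp$lag, par[1], par[2], par[3])
    sum(emp$n_pairs * (g - emp$gamma)^2)
  }
  v0 <- stats::var(values)
  init <- c(nugget = 0, psill = max(v0, 1e-12), range_ = hmax / 2)
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-12, 1e-6),
                      upper = c(v0 * 2 + 1e-12, v0 * 10 + 1e-6, hmax * 4))
  list(nugget = unname(opt$par[1]), psill = unname(opt$par[2]),
       range_km = unname(opt$par[3]), empirical = emp)
}

#' Ordinary kriging of per-trial predictive abilities over the grid
#'
#' Fits a spherical variogram to the ability values at the trial locations
#' and solves the ordinary-kriging system (weights constrained to sum to 1)
#' at every grid bin. With a zero nugget the predictor interpolates the
#' observed values exactly. If all abilities are identical the pure-nugget
#' shortcut returns a constant surface.
#'
#' @param trial_points data.frame with `lat`, `lon` of the trials.
#' @param abilities numeric predictive abilities (one per trial row).
#' @param grid the `prediction_grid`.
#' @param n_lags lag bins for the variogram fit.
#' @param variogram optional list(nugget, psill, range_km) to skip fitting.
#' @return object of class `kriged_surface`: `surface` (named per-bin),
#'   `variogram`, `weights` (bins x trials matrix), `weight_sums`.
#' @export
krige_ability <- function(trial_points, abilities, grid, n_lags = 15,
                          variogram = NULL) {
  keep <- is.finite(abilities)
  if (sum(keep) < 5) stop("need at least 5 finite ability values",
                          call. = FALSE)
  pts <- trial_points[keep, , drop = FALSE]
  v <- abilities[keep]
  xy <- project_local_km(pts$lat, pts$lon, grid$origin)
  bins <- grid$bins
  if (stats::sd(v) == 0) {
    return(structure(list(
      surface = stats::setNames(rep(v[1], nrow(bins)), bins$bin_id),
      variogram = list(nugget = 0, psill = 0, range_km = NA_real_),
      weights = NULL,
      weight_sums = stats::setNames(rep(1, nrow(bins)), bins$bin_id)),
      class = "kriged_surface"))
  }
  vg <- if (is.null(variogram)) fit_spherical_variogram(xy, v, n_lags) else
    variogram
  n <- nrow(xy)
  G <- sph_gamma(as.matrix(stats::dist(xy)), vg$nugget, vg$psill,
                 vg$range_km)
  aug <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(bins$x_km, xy[, 1], "-")^2 +
               outer(bins$y_km, xy[, 2], "-")^2)
  g0 <- sph_gamma(d0, vg$nugget, vg$psill, vg$range_km)
  rhs <- rbind(t(g0), 1)
  lam <- solve(aug, rhs)[seq_len(n), , drop = FALSE]  # weights x bins
  surface <- drop(crossprod(lam, v))
  structure(list(surface = stats::setNames(surface, bins$bin_id),
                 variogram = vg, weights = t(lam),
                 weight_sums = stats::setNames(colSums(lam), bins$bin_id)),
            class = "kriged_surface")
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat("kriged_surface over", length(x$surface), "bins; variogram nugget",
      signif(x$variogram$nugget, 3), "psill", signif(x$variogram$psill, 3),
      "range", signif(x$variogram$range_km, 4), "km\n")
  invisible(x)
}
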