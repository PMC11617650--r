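# Engineered enviromic markers (EEMs): bootstrap trial means over genotype
# subsets, fit a large CART regression-tree bank on environmental
# covariates, cluster the tree predictors into K forests, aggregate each
# forest into one standardized marker, and tally covariate importance
# (an envirome-wide association summary).

#' Bootstrap environment means over a genotype subsample
#'
#' Draws a random genotype subsample and computes, per trial, the mean yield
#' BLUE over the sampled genotypes present in that trial. Trials where fewer
#' than two sampled genotypes appear are topped up with extra genotypes from
#' that trial; trials with fewer than two records in total are excluded with
#' a warning.
#'
#' @param phenotypes a `phenotype_table`.
#' @param subsample_fraction fraction of the genotype census to sample.
#' @param seed optional integer seed (`NULL` = use the ambient RNG stream,
#'   as the tree-bank fitter does per tree).
#' @return list with `m` (named per-trial mean vector) and `genotypes`
#'   (the sampled ids).
#' @export
environment_means <- function(phenotypes, subsample_fraction = 0.5,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- table(phenotypes$trial_id)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding trial(s) with < 2 records: ",
            paste(small, collapse = ", "))
    phenotypes <- phenotypes[!phenotypes$trial_id %in% small, ]
  }
  gens <- unique(phenotypes$genotype_id)
  n_take <- max(2L, round(subsample_fraction * length(gens)))
  I <- if (n_take >= length(gens)) gens else sample(gens, n_take)
  sel <- split(seq_len(nrow(phenotypes)), phenotypes$trial_id)
  m <- vapply(sel, function(rows) {
    hit <- rows[phenotypes$genotype_id[rows] %in% I]
    if (length(hit) < 2) {
      extra <- setdiff(rows, hit)
      hit <- c(hit, sample(extra, min(length(extra), 2 - length(hit))))
    }
    mean(phenotypes$yield_blue[hit])
  }, numeric(1))
  list(m = m, genotypes = I)
}

#' Fit a bank of CART regression trees predicting trial means
#'
#' For each tree: draw a genotype subsample, recompute the per-trial
#' environment mean, draw a random covariate subset (default size
#' `sqrt(p)`, the random-forest rule), and fit a CART regression tree
#' (recursive partitioning on residual sums of squares, `rpart`) of the
#' means on the covariate subset over trials. The bank stores the fitted
#' trees, their impurity-decrease importances, and the genotype subsamples.
#'
#' @param trial_covariates a `covariate_table` whose `location_id` matches
#'   the phenotype `trial_id`s.
#' @param phenotypes a `phenotype_table`.
#' @param n_trees number of trees (the study default is 10 000).
#' @param subsample_fraction genotype subsample fraction per tree.
#' @param mtry covariates sampled per tree (default `floor(sqrt(p))`).
#' @param min_leaf minimum trials per leaf (small-n default 2).
#' @param seed integer seed.
#' @return an object of class `tree_bank`.
#' @export
fit_tree_bank <- function(trial_covariates, phenotypes, n_trees = 1000,
                          subsample_fraction = 0.5, mtry = NULL,
                          min_leaf = 2, seed = 1) {
  covs <- covariate_names(trial_covariates)
  trials <- intersect(trial_covariates$location_id,
                      unique(phenotypes$trial_id))
  if (length(trials) < 5) stop("need at least 5 trials", call. = FALSE)
  phenotypes <- phenotypes[phenotypes$trial_id %in% trials, ]
  W <- as.data.frame(trial_covariates[match(trials,
                                            trial_covariates$location_id),
                                      covs, drop = FALSE])
  rownames(W) <- trials
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(covs))))
  mtry <- min(mtry, length(covs))
  set.seed(seed)
  ctrl <- rpart::rpart.control(minsplit = 2 * min_leaf, minbucket = min_leaf,
                               cp = 0, xval = 0, maxcompete = 0,
                               maxsurrogate = 0)
  trees <- vector("list", n_trees)
  importances <- vector("list", n_trees)
  subsamples <- vector("list", n_trees)
  n_constant <- 0L
  for (i in seq_len(n_trees)) {
    em <- environment_means(phenotypes, subsample_fraction)
    J <- if (mtry >= length(covs)) covs else sample(covs, mtry)
    df <- W[names(em$m), J, drop = FALSE]
    df$.m <- em$m
    fit <- rpart::rpart(.m ~ ., data = df, method = "anova", control = ctrl)
    fit$call <- NULL  # drop environment baggage; predict() does not need it
    trees[[i]] <- fit
    imp <- fit$variable.importance
    importances[[i]] <- if (is.null(imp)) numeric(0) else imp
    subsamples[[i]] <- em$genotypes
    if (is.null(imp)) n_constant <- n_constant + 1L
  }
  if (n_constant == n_trees) {
    message("tree bank is degenerate: all trees are constants ",
            "(no covariate splits)")
  }
  structure(list(trees = trees, importances = importances,
                 subsamples = subsamples, covariates = covs,
                 trial_ids = trials, n_trees = n_trees, mtry = mtry,
                 sources = attr(trial_covariates, "sources")),
            class = "tree_bank")
}

#' @export
print.tree_bank <- function(x, ...) {
  cat("tree_bank:", x$n_trees, "CART trees over", length(x$trial_ids),
      "trials,", length(x$covariates), "covariates (mtry", x$mtry, ")\n")
  invisible(x)
}

#' Predict all (or selected) bank trees at a set of locations
#'
#' @param bank a `tree_bank`.
#' @param covariates a `covariate_table` for the target locations.
#' @param trees optional integer indices of trees to evaluate.
#' @return numeric matrix locations x trees (rownames = location ids).
#' @export
predict_bank <- function(bank, covariates, trees = NULL) {
  if (is.null(trees)) trees <- seq_len(bank$n_trees)
  newdata <- as.data.frame(covariates[, bank$covariates, drop = FALSE])
  P <- vapply(trees, function(i) {
    unname(stats::predict(bank$trees[[i]], newdata = newdata))
  }, numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  rownames(P) <- covariates$location_id
  P
}

#' Cluster tree predictors into K forests and aggregate into EEMs
#'
#' The trees' prediction vectors over a reference location set (normally the
#' prediction grid) are standardized and clustered by agglomerative
#' hierarchical clustering (average linkage, distance = 1 - Pearson
#' correlation), cut at K clusters. The k-th engineered enviromic marker is
#' the mean of cluster k's standardized tree predictions, re-standardized
#' over the reference locations. The mean over *all* trees gives the single
#' comprehensive "wide-environment gradient". Trees with constant
#' predictions over the reference set carry no gradient information and are
#' left unclustered (`NA` label).
#'
#' @param bank a `tree_bank`.
#' @param K number of markers (study default 7).
#' @param reference_covariates `covariate_table` of the reference locations.
#' @return an object of class `eem_set` holding the marker matrix
#'   (`eem_values`, locations x K), the wide gradient, the tree-to-cluster
#'   map and all standardization constants needed to evaluate markers at new
#'   locations.
#' @export
cluster_and_aggregate <- function(bank, K = 7, reference_covariates) {
  if (K > bank$n_trees) stop("K exceeds the number of trees", call. = FALSE)
  P <- predict_bank(bank, reference_covariates)
  mu <- colMeans(P)
  sd_ <- apply(P, 2, stats::sd)
  active <- which(sd_ > 0)
  if (length(active) < K) {
    stop("fewer than K non-constant trees", call. = FALSE)
  }
  Pstd <- sweep(sweep(P[, active, drop = FALSE], 2, mu[active]), 2,
                sd_[active], "/")
  cluster_of_tree <- rep(NA_integer_, bank$n_trees)
  if (length(active) == K) {
    cluster_of_tree[active] <- seq_len(K)
  } else {
    cm <- suppressWarnings(stats::cor(Pstd))
    cm[!is.finite(cm)] <- 0
    d <- stats::as.dist(1 - cm)
    hc <- stats::hclust(d, method = "average")
    cluster_of_tree[active] <- stats::cutree(hc, k = K)
  }
  eem_raw <- vapply(seq_len(K), function(k) {
    rowMeans(Pstd[, cluster_of_tree[active] == k, drop = FALSE])
  }, numeric(nrow(P)))
  wide_raw <- rowMeans(Pstd)
  eem_center <- colMeans(eem_raw)
  eem_scale <- apply(eem_raw, 2, stats::sd)
  eem_scale[eem_scale == 0] <- 1
  eem <- sweep(sweep(eem_raw, 2, eem_center), 2, eem_scale, "/")
  colnames(eem) <- paste0("eem", seq_len(K))
  rownames(eem) <- reference_covariates$location_id
  wide_center <- mean(wide_raw)
  wide_scale <- stats::sd(wide_raw)
  if (!is.finite(wide_scale) || wide_scale == 0) wide_scale <- 1
  structure(list(K = K, cluster_of_tree = cluster_of_tree,
                 eem_values = eem,
                 wide_gradient = stats::setNames(
                   (wide_raw - wide_center) / wide_scale,
                   reference_covariates$location_id),
                 eem_raw = eem_raw, wide_raw = wide_raw,
                 tree_mu = mu, tree_sd = sd_,
                 eem_center = eem_center, eem_scale = eem_scale,
                 wide_center = wide_center, wide_scale = wide_scale,
                 reference_ids = reference_covariates$location_id),
            class = "eem_set")
}

#' @export
print.eem_set <- function(x, ...) {
  cat("eem_set:", x$K, "markers over", length(x$reference_ids),
      "reference locations;", sum(!is.na(x$cluster_of_tree)),
      "clustered trees\n")
  invisible(x)
}

#' Evaluate the EEMs (and wide gradient) at new locations
#'
#' Uses the standardization constants learned on the reference location set,
#' so marker values at trials and at grid bins share one scale.
#'
#' @param eem_set an `eem_set`.
#' @param bank the `tree_bank` the set was built from.
#' @param covariates `covariate_table` of the target locations.
#' @return list with `eem` (locations x K matrix) and `wide` (vector).
#' @export
eem_values_at <- function(eem_set, bank, covariates) {
  P <- predict_bank(bank, covariates)
  sd_ <- eem_set$tree_sd
  active <- which(sd_ > 0)
  Pstd <- sweep(sweep(P[, active, drop = FALSE], 2, eem_set$tree_mu[active]),
                2, sd_[active], "/")
  cl <- eem_set$cluster_of_tree[active]
  eem_raw <- vapply(seq_len(eem_set$K), function(k) {
    rowMeans(Pstd[, cl == k, drop = FALSE])
  }, numeric(nrow(P)))
  eem_raw <- matrix(eem_raw, nrow = nrow(P))
  eem <- sweep(sweep(eem_raw, 2, eem_set$eem_center), 2, eem_set$eem_scale,
               "/")
  colnames(eem) <- paste0("eem", seq_len(eem_set$K))
  rownames(eem) <- covariates$location_id
  wide <- (rowMeans(Pstd) - eem_set$wide_center) / eem_set$wide_scale
  list(eem = eem, wide = stats::setNames(wide, covariates$location_id))
}

#' Standardized single-tree marker values at locations
#'
#' Used by the model ensemble, where each run regresses on one sampled tree
#' predictor per cluster, standardized with the reference-set constants.
#'
#' @param eem_set an `eem_set`.
#' @param bank the `tree_bank`.
#' @param covariates target locations.
#' @param trees integer tree indices.
#' @return matrix locations x length(trees).
#' @export
tree_values_at <- function(eem_set, bank, covariates, trees) {
  P <- predict_bank(bank, covariates, trees = trees)
  sd_ <- eem_set$tree_sd[trees]
  sd_[sd_ == 0] <- 1
  sweep(sweep(P, 2, eem_set$tree_mu[trees]), 2, sd_, "/")
}

#' Envirome-wide importance tally
#'
#' For each tree (model iteration) covariates are ranked by their impurity
#' importance; the tally counts, per covariate, how often it occupied rank
#' 1..`top_k`. Mean importance is the per-tree-normalized importance share
#' averaged over all informative trees, and `source_shares` aggregates it by
#' data-source tag, normalized to sum to 100%.
#'
#' @param bank a `tree_bank`.
#' @param top_k number of rank positions tallied (default 5).
#' @return list with `tally` (data.frame: covariate, rank1..rank`top_k`
#'   counts, mean_importance, source) and `source_shares` (named numeric,
#'   percentages summing to 100).
#' @export
ewas_tally <- function(bank, top_k = 5) {
  covs <- bank$covariates
  counts <- matrix(0L, length(covs), top_k,
                   dimnames = list(covs, paste0("rank", seq_len(top_k))))
  share_sum <- stats::setNames(numeric(length(covs)), covs)
  n_used <- 0L
  for (imp in bank$importances) {
    if (length(imp) == 0) next
    n_used <- n_used + 1L
    shares <- imp / sum(imp)
    share_sum[names(shares)] <- share_sum[names(shares)] + shares
    ranked <- names(sort(imp, decreasing = TRUE))
    for (r in seq_len(min(top_k, length(ranked)))) {
      counts[ranked[r], r] <- counts[ranked[r], r] + 1L
    }
  }
  mean_importance <- if (n_used > 0) share_sum / n_used else share_sum
  src <- bank$sources
  source_of <- if (is.null(src)) rep("unknown", length(covs)) else
    unname(src[covs])
  source_of[is.na(source_of)] <- "unknown"
  tally <- data.frame(covariate = covs, counts,
                      mean_importance = unname(mean_importance),
                      source = source_of, stringsAsFactors = FALSE,
                      row.names = NULL)
  tot <- tapply(mean_importance, source_of, sum)
  source_shares <- 100 * tot / sum(tot)
  list(tally = tally, source_shares = source_shares, n_iterations = n_used)
}

#' Validate the marker engine: in-sample and leave-one-trial-out correlation
#'
#' `fit_correlation` is the Pearson correlation between observed trial means
#' and the in-sample ensemble prediction (mean over all trees).
#' `loo_correlation` refits a (reduced) bank without each trial in turn,
#' predicts the held-out trial mean, and reports the Pearson correlation
#' between observed and held-out-predicted means over all trials.
#'
#' @param trial_covariates covariates at trials.
#' @param phenotypes a `phenotype_table`.
#' @param n_trees trees for the full fit.
#' @param loo_n_trees trees per leave-one-out refit (reduced for speed).
#' @param subsample_fraction genotype subsample per tree.
#' @param seed integer seed.
#' @return list with `fit_correlation`, `loo_correlation`, `m` (observed
#'   trial means) and `loo_predictions`.
#' @export
validate_eems <- function(trial_covariates, phenotypes, n_trees = 500,
                          loo_n_trees = 200, subsample_fraction = 0.5,
                          seed = 1) {
  trials <- intersect(trial_covariates$location_id,
                      unique(phenotypes$trial_id))
  if (length(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  m_obs <- environment_means(phenotypes, subsample_fraction = 1)$m[trials]
  if (stats::sd(m_obs) == 0) {
    warning("zero variance in trial means; correlations undefined")
    return(list(fit_correlation = NA_real_, loo_correlation = NA_real_,
                m = m_obs, loo_predictions = rep(NA_real_, length(m_obs))))
  }
  bank <- fit_tree_bank(trial_covariates, phenotypes, n_trees = n_trees,
                        subsample_fraction = subsample_fraction, seed = seed)
  fit_pred <- rowMeans(predict_bank(bank, trial_covariates))
  fit_pred <- fit_pred[trials]
  fit_correlation <- stats::cor(m_obs, fit_pred)
  loo_pred <- stats::setNames(numeric(length(trials)), trials)
  for (i in seq_along(trials)) {
    keep <- phenotypes$trial_id != trials[i]
    cov_keep <- trial_covariates[trial_covariates$location_id != trials[i], ]
    bank_i <- fit_tree_bank(cov_keep, phenotypes[keep, ],
                            n_trees = loo_n_trees,
                            subsample_fraction = subsample_fraction,
                            seed = seed + i)
    target <- trial_covariates[trial_covariates$location_id == trials[i], ]
    loo_pred[i] <- mean(predict_bank(bank_i, target))
  }
  list(fit_correlation = fit_correlation,
       loo_correlation = stats::cor(m_obs, loo_pred),
       m = m_obs, loo_predictions = loo_pred)
}
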