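# Synthetic study generator: spatially autocorrelated collinear covariate
# fields, a founder/hybrid pedigree, genotype reaction-norm effects drawn
# from N(0, Sigma (x) A), and unbalanced multi-year trials — the exact
# statistical structure the reaction-norm model assumes, so every pipeline
# stage is testable without proprietary trial or satellite data.

# symmetric matrix square root with eigenvalue clipping at zero
mat_sqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate spatially autocorrelated, collinear covariate fields on a grid
#'
#' Each base field is a low-rank Gaussian random field: a weighted sum of
#' Gaussian kernels centred at random anchor points, with kernel width set by
#' `range_km`, standardized over the bins. Collinear copies of each causal
#' field add independent noise calibrated so the pairwise correlation with
#' the parent field is about 0.9 — emulating the strong multicollinearity of
#' stacked satellite/climate/soil layers. Covariate names carry a source tag
#' prefix (`sat_`, `clim_`, `wx_`, `soil_`) recorded in the `sources`
#' attribute.
#'
#' @param grid a `prediction_grid`.
#' @param n_causal number of causal base fields.
#' @param n_noise number of non-causal base fields.
#' @param n_collinear_per_causal collinear copies per causal field.
#' @param range_km spatial correlation range of the fields, km.
#' @param seed integer seed.
#' @param n_anchors kernel anchors per field (controls field roughness).
#' @return a `covariate_table` for the grid bins, with attributes `sources`
#'   (named character vector) and `causal` (names of the causal columns).
#' @export
simulate_covariate_fields <- function(grid, n_causal = 3, n_noise = 20,
                                      n_collinear_per_causal = 3,
                                      range_km = 150, seed = 1,
                                      n_anchors = 100) {
  stopifnot(n_causal >= 0, n_noise >= 0, n_collinear_per_causal >= 0,
            range_km > 0)
  bins <- grid$bins
  if (nrow(bins) == 0) stop("empty prediction grid", call. = FALSE)
  set.seed(seed)
  xr <- range(bins$x_km); yr <- range(bins$y_km)
  pad <- range_km / 2
  gen_field <- function() {
    ax <- stats::runif(n_anchors, xr[1] - pad, xr[2] + pad)
    ay <- stats::runif(n_anchors, yr[1] - pad, yr[2] + pad)
    w <- stats::rnorm(n_anchors)
    d2 <- outer(bins$x_km, ax, "-")^2 + outer(bins$y_km, ay, "-")^2
    standardize(exp(-d2 / (2 * range_km^2)) %*% w)
  }
  src_tags <- c("sat", "clim", "wx", "soil")
  sources_of <- c(sat = "satellite", clim = "climate", wx = "weather",
                  soil = "soil")
  cols <- list(); srcs <- character(0); causal_names <- character(0)
  k <- 0L
  next_name <- function(tag) sprintf("%s_ec%03d", tag, k)
  for (i in seq_len(n_causal)) {
    k <- k + 1L
    tag <- src_tags[(k - 1L) %% 4L + 1L]
    nm <- next_name(tag)
    f <- gen_field()
    cols[[nm]] <- f
    srcs[nm] <- sources_of[tag]
    causal_names <- c(causal_names, nm)
    # noise sd such that cor(parent, copy) ~ 0.9 for standardized parent
    s <- sqrt(1 / 0.9^2 - 1)
    for (j in seq_len(n_collinear_per_causal)) {
      k <- k + 1L
      tag2 <- src_tags[(k - 1L) %% 4L + 1L]
      nm2 <- next_name(tag2)
      cols[[nm2]] <- standardize(f + stats::rnorm(nrow(bins), sd = s))
      srcs[nm2] <- sources_of[tag2]
    }
  }
  for (i in seq_len(n_noise)) {
    k <- k + 1L
    tag <- src_tags[(k - 1L) %% 4L + 1L]
    nm <- next_name(tag)
    cols[[nm]] <- gen_field()
    srcs[nm] <- sources_of[tag]
  }
  df <- data.frame(location_id = bins$bin_id, lat = bins$lat, lon = bins$lon,
                   stringsAsFactors = FALSE)
  for (nm in names(cols)) df[[nm]] <- as.numeric(cols[[nm]])
  df <- validate_covariates(df)
  attr(df, "sources") <- srcs
  attr(df, "causal") <- causal_names
  df
}

#' Simulate a founder/hybrid pedigree
#'
#' Parents are founders with unknown dam/sire; each hybrid is a cross of two
#' distinct parents sampled without replacement per cross. A configurable
#' fraction of hybrids are "competitors" with both parents unknown.
#'
#' @param n_parents number of founder parent lines (>= 2 if any pedigreed
#'   hybrid is requested).
#' @param n_hybrids number of hybrids.
#' @param competitor_fraction fraction of hybrids with unknown parents.
#' @param seed integer seed.
#' @return a `pedigree` data.frame; parents named `P001...`, hybrids `H001...`.
#' @export
simulate_pedigree <- function(n_parents, n_hybrids, competitor_fraction = 0.1,
                              seed = 1) {
  if (n_hybrids > 0 && n_parents < 2) {
    stop("need at least 2 parents to produce hybrids", call. = FALSE)
  }
  set.seed(seed)
  parents <- sprintf("P%03d", seq_len(n_parents))
  hybrids <- sprintf("H%03d", seq_len(n_hybrids))
  n_comp <- round(competitor_fraction * n_hybrids)
  is_comp <- rep(FALSE, n_hybrids)
  if (n_comp > 0) is_comp[sample.int(n_hybrids, n_comp)] <- TRUE
  dam <- sire <- rep(UNKNOWN_PARENT, n_hybrids)
  for (i in seq_len(n_hybrids)) {
    if (!is_comp[i]) {
      pr <- sample(parents, 2)
      dam[i] <- pr[1]; sire[i] <- pr[2]
    }
  }
  validate_pedigree(data.frame(
    genotype_id = c(parents, hybrids),
    dam_id = c(rep(UNKNOWN_PARENT, n_parents), dam),
    sire_id = c(rep(UNKNOWN_PARENT, n_parents), sire),
    stringsAsFactors = FALSE))
}

#' Draw genotype intercept and reaction-norm slopes from N(0, Sigma (x) A)
#'
#' Matrix-normal draw: `U = L_A %*% Z %*% t(L_S)` with `L_A L_A' = A`,
#' `L_S L_S' = Sigma_true` (symmetric square roots with eigenvalues clipped
#' at zero), `Z` iid standard normal. Row r, column s of the result is the
#' s-th coefficient of genotype r, so `cov(U[i, r], U[j, s]) =
#' Sigma_true[r, s] * A[i, j]`.
#'
#' @param kinship a `kinship_matrix` (or plain PSD matrix with dimnames), or
#'   `NULL` for unrelated genotypes (identity A; give `n_genotypes`).
#' @param Sigma_true (K_true+1) x (K_true+1) covariance of
#'   (intercept, slopes).
#' @param seed integer seed.
#' @param n_genotypes number of genotypes when `kinship` is `NULL`.
#' @return numeric matrix genotypes x (K_true+1), rownames = genotype ids,
#'   colnames `u0, u1, ...`.
#' @export
simulate_genetic_effects <- function(kinship, Sigma_true, seed = 1,
                                     n_genotypes = NULL) {
  A <- if (inherits(kinship, "kinship_matrix")) kinship$A else kinship
  Sigma_true <- as.matrix(Sigma_true)
  ev <- eigen((Sigma_true + t(Sigma_true)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("Sigma_true is not positive semidefinite", call. = FALSE)
  }
  set.seed(seed)
  q <- if (is.null(A)) n_genotypes else nrow(A)
  p <- nrow(Sigma_true)
  LS <- mat_sqrt(Sigma_true)
  U <- matrix(stats::rnorm(q * p), q, p) %*% t(LS)
  if (!is.null(A)) U <- mat_sqrt(A) %*% U
  dimnames(U) <- list(if (is.null(A)) sprintf("G%05d", seq_len(q)) else
    rownames(A), paste0("u", seq_len(p) - 1L))
  U
}

#' Build the true environmental gradients from causal covariates
#'
#' Each gradient is a fixed linear combination of the causal covariate
#' columns passed through a saturating `tanh` nonlinearity and standardized
#' over the bins — recoverable by a nonparametric tree ensemble but not by
#' any single linear covariate.
#'
#' @param covariates a `covariate_table` with a `causal` attribute (or
#'   explicit `causal` argument).
#' @param K_true number of gradients.
#' @param seed integer seed.
#' @param causal character vector of causal covariate names.
#' @return matrix bins x K_true of standardized gradients, rownames =
#'   location ids; attribute `weights` holds the combination weights.
#' @export
make_true_gradients <- function(covariates, K_true = 2, seed = 1,
                                causal = attr(covariates, "causal")) {
  if (is.null(causal) || length(causal) == 0) {
    stop("no causal covariates recorded", call. = FALSE)
  }
  set.seed(seed)
  Wc <- as.matrix(covariates[, causal, drop = FALSE])
  wts <- matrix(stats::rnorm(length(causal) * K_true), length(causal), K_true)
  G <- apply(tanh(scale(Wc %*% wts)), 2, standardize)
  G <- matrix(G, ncol = K_true,
              dimnames = list(covariates$location_id,
                              paste0("g", seq_len(K_true))))
  attr(G, "weights") <- wts
  G
}

#' Simulate unbalanced multi-year trials and phenotypes on the grid
#'
#' Trials are placed at sampled grid bins (optionally biased toward
#' favourable bins); each trial receives a random, unbalanced subset of the
#' phenotyped genotypes. The phenotype of genotype g in the trial at bin b is
#' `year effect + env_main_sd * env_quality(b) + u0_g +
#' sum_k u_kg * gradient_k(b) + e`, `e ~ N(0, sigma_e^2)`, where
#' `env_quality` is the mean of the true gradients — an environment
#' main-effect term that makes trial means reflect environmental quality, as
#' in real multi-environment trial data.
#'
#' @param grid a `prediction_grid`.
#' @param gradients true gradient matrix from [make_true_gradients()].
#' @param u_true genotype effect matrix from [simulate_genetic_effects()]
#'   (columns `u0, u1..`, at least `ncol(gradients)+1` columns; extra slope
#'   columns are ignored).
#' @param phenotyped character vector of genotype ids that get records
#'   (e.g. the hybrids).
#' @param n_trials number of trials (<= number of bins).
#' @param genotypes_per_trial target genotypes per trial; actual counts vary
#'   uniformly between 60% of this and this (unbalanced design).
#' @param years vector of calendar years to sample from.
#' @param year_effects named numeric per-year offsets (default drawn
#'   N(0, 0.25)).
#' @param sigma_e residual SD.
#' @param env_main_sd scale of the environment main effect.
#' @param irrigated_fraction fraction of irrigated trials.
#' @param favor_high if `TRUE`, bin sampling is biased toward high
#'   `env_quality` bins, mimicking trial concentration in the best areas.
#' @param env_quality optional named per-bin environment-quality vector
#'   (standardized). Defaults to the mean of the gradients; the study
#'   wrapper passes its own causal-covariate combination so the quality
#'   signal cannot cancel when gradients are anti-correlated.
#' @param seed integer seed.
#' @return a `phenotype_table`; attribute `trials` is a per-trial data.frame
#'   with the bin id and the true environment mean (for oracle checks).
#' @export
simulate_trials_and_phenotypes <- function(grid, gradients, u_true,
                                           phenotyped, n_trials = 40,
                                           genotypes_per_trial = 30,
                                           years = 2017:2021,
                                           year_effects = NULL,
                                           sigma_e = 0.5, env_main_sd = 1,
                                           irrigated_fraction = 0.25,
                                           favor_high = FALSE,
                                           env_quality = NULL, seed = 1) {
  bins <- grid$bins
  if (n_trials > nrow(bins)) stop("more trials than bins", call. = FALSE)
  if (genotypes_per_trial > length(phenotyped)) {
    stop("genotypes_per_trial exceeds the phenotyped census", call. = FALSE)
  }
  K_true <- ncol(gradients)
  stopifnot(ncol(u_true) >= K_true + 1)
  set.seed(seed)
  if (is.null(year_effects)) {
    year_effects <- stats::setNames(stats::rnorm(length(years), sd = 0.5),
                                    as.character(years))
  }
  if (is.null(env_quality)) env_quality <- rowMeans(gradients)
  prob <- if (favor_high) exp(env_quality) else NULL
  trial_bins <- sample(seq_len(nrow(bins)), n_trials, prob = prob)
  trial_year <- sample(as.character(years), n_trials, replace = TRUE)
  trial_irr <- stats::runif(n_trials) < irrigated_fraction
  # region label by planar quadrant about the grid median: gives a natural
  # leave-region-out structure
  qx <- bins$x_km[trial_bins] > stats::median(bins$x_km)
  qy <- bins$y_km[trial_bins] > stats::median(bins$y_km)
  trial_region <- c("SW", "SE", "NW", "NE")[1L + qx + 2L * qy]
  n_min <- max(2L, round(0.6 * genotypes_per_trial))
  recs <- vector("list", n_trials)
  trials <- data.frame(trial_id = sprintf("T%03d", seq_len(n_trials)),
                       bin_id = bins$bin_id[trial_bins],
                       lat = bins$lat[trial_bins], lon = bins$lon[trial_bins],
                       year = as.integer(trial_year), irrigated = trial_irr,
                       region = trial_region, stringsAsFactors = FALSE)
  trials$env_mean_true <- year_effects[trial_year] +
    env_main_sd * env_quality[trial_bins]
  for (t in seq_len(n_trials)) {
    ng <- sample(seq(n_min, genotypes_per_trial), 1)
    gset <- sample(phenotyped, ng)
    b <- trial_bins[t]
    gvals <- u_true[gset, 1] +
      as.matrix(u_true[gset, 1 + seq_len(K_true), drop = FALSE]) %*%
      gradients[b, ]
    y <- year_effects[trial_year[t]] + env_main_sd * env_quality[b] +
      as.numeric(gvals) + stats::rnorm(ng, sd = sigma_e)
    recs[[t]] <- data.frame(trial_id = trials$trial_id[t], genotype_id = gset,
                            year = trials$year[t],
                            irrigated = trials$irrigated[t],
                            region = trials$region[t], lat = trials$lat[t],
                            lon = trials$lon[t], yield_blue = y,
                            stringsAsFactors = FALSE)
  }
  phen <- validate_phenotypes(do.call(rbind, recs))
  attr(phen, "trials") <- trials
  phen
}

#' Simulate a complete synthetic enviromic study
#'
#' Convenience wrapper chaining grid construction, covariate fields,
#' pedigree, kinship, genetic effects, gradients, and phenotypes, returning
#' everything downstream stages need plus the generative truth.
#'
#' @param n_region_points random points whose hull defines the study region.
#' @param region_extent_deg half-extent of the region in degrees.
#' @param cell_size_km,buffer_km grid geometry (km).
#' @param n_parents,n_hybrids pedigree census.
#' @param K_true number of true gradients.
#' @param Sigma_true true (K_true+1)-square covariance of intercept+slopes;
#'   default has intercept variance 1 and slope variances 0.5 — enough
#'   genotype-by-environment interaction for rank switching across the
#'   gradient.
#' @param sigma_e residual SD.
#' @param n_trials,genotypes_per_trial,years trial design.
#' @param n_causal,n_noise,n_collinear_per_causal,range_km covariate design.
#' @param env_main_sd environment main-effect scale.
#' @param favor_high bias trial placement toward favourable bins.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return list with `grid`, `covariates`, `pedigree`, `kinship`,
#'   `phenotypes`, `trials`, and `truth` (class `sim_truth`).
#' @export
simulate_enviromic_study <- function(n_region_points = 8,
                                     region_extent_deg = 2,
                                     cell_size_km = 5, buffer_km = 50,
                                     n_parents = 30, n_hybrids = 60,
                                     K_true = 2, Sigma_true = NULL,
                                     sigma_e = 0.5, n_trials = 40,
                                     genotypes_per_trial = 30,
                                     years = 2017:2021, n_causal = 3,
                                     n_noise = 20,
                                     n_collinear_per_causal = 3,
                                     range_km = 100, env_main_sd = 1,
                                     favor_high = FALSE, seed = 1) {
  set.seed(seed)
  sub_seeds <- sample.int(2^30, 7)
  region <- data.frame(
    lat = -25 + stats::runif(n_region_points, -region_extent_deg,
                             region_extent_deg),
    lon = -52 + stats::runif(n_region_points, -region_extent_deg,
                             region_extent_deg))
  grid <- build_prediction_grid(region, cell_size_km = cell_size_km,
                                buffer_km = buffer_km)
  covariates <- simulate_covariate_fields(
    grid, n_causal = n_causal, n_noise = n_noise,
    n_collinear_per_causal = n_collinear_per_causal, range_km = range_km,
    seed = sub_seeds[1])
  pedigree <- simulate_pedigree(n_parents, n_hybrids, seed = sub_seeds[2])
  kinship <- additive_relationship(pedigree)
  if (is.null(Sigma_true)) {
    Sigma_true <- diag(c(1, rep(0.5, K_true)))
    Sigma_true[1, -1] <- Sigma_true[-1, 1] <- 0.1
  }
  u_true <- simulate_genetic_effects(kinship, Sigma_true, seed = sub_seeds[3])
  gradients <- make_true_gradients(covariates, K_true = K_true,
                                   seed = sub_seeds[4])
  hybrids <- grep("^H", pedigree$genotype_id, value = TRUE)
  # environment quality gets its own causal-covariate combination so the
  # main-effect signal survives even when the gradients are mutually
  # anti-correlated (inevitable with a single causal field)
  env_quality <- make_true_gradients(covariates, K_true = 1,
                                     seed = sub_seeds[7])[, 1]
  phenotypes <- simulate_trials_and_phenotypes(
    grid, gradients, u_true, phenotyped = hybrids, n_trials = n_trials,
    genotypes_per_trial = genotypes_per_trial, years = years,
    sigma_e = sigma_e, env_main_sd = env_main_sd, favor_high = favor_high,
    env_quality = env_quality, seed = sub_seeds[5])
  truth <- structure(list(Sigma_true = Sigma_true, u_true = u_true,
                          gradients = gradients,
                          env_quality = env_quality,
                          sigma_e = sigma_e, env_main_sd = env_main_sd,
                          causal = attr(covariates, "causal"),
                          seed = seed),
                     class = "sim_truth")
  list(grid = grid, covariates = covariates, pedigree = pedigree,
       kinship = kinship, phenotypes = phenotypes,
       trials = attr(phenotypes, "trials"), truth = truth)
}
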