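# Enviromic marker engineering: environment means, tree bank, clustering
# and aggregation, importance tallies, marker validation.

test_that("environment means reduce to plain trial means at full sampling", {
  phen <- toy_phenotypes()
  em <- environment_means(phen, subsample_fraction = 1, seed = 1)
  expect_equal(em$m, c(T1 = 1.5, T2 = 4))
  # variance of the bootstrapped mean shrinks as the fraction grows
  sim <- demo_sim()
  spread <- function(frac) {
    reps <- replicate(200,
      environment_means(sim$phenotypes, subsample_fraction = frac)$m[["T001"]])
    var(reps)
  }
  set.seed(1)
  expect_lt(spread(0.9), spread(0.3))
})

test_that("small trials are excluded with a warning", {
  phen <- toy_phenotypes()
  one <- validate_phenotypes(rbind(as.data.frame(phen), data.frame(
    trial_id = "T3", genotype_id = "G1", year = 2020L, irrigated = FALSE,
    region = "A", lat = -23, lon = -50, yield_blue = 9)))
  expect_warning(em <- environment_means(one, 1), "excluding")
  expect_false("T3" %in% names(em$m))
})

test_that("degenerate banks predict the grand mean everywhere", {
  sim <- demo_sim()
  tc <- demo_trial_covariates()
  const <- tc[, c("location_id", "lat", "lon")]
  const$w_const <- 1
  const <- validate_covariates(const)
  expect_message(
    bank <- fit_tree_bank(const, sim$phenotypes, n_trees = 10,
                          subsample_fraction = 1, seed = 1),
    "degenerate")
  P <- predict_bank(bank, const)
  m <- environment_means(sim$phenotypes, 1)$m
  expect_equal(unname(P[1, ]), rep(mean(m[bank$trial_ids]), 10))
  # n_trees = 1: bank prediction equals that tree's prediction
  b1 <- fit_tree_bank(tc, sim$phenotypes, n_trees = 1, seed = 2)
  expect_equal(predict_bank(b1, tc),
               predict_bank(b1, tc, trees = 1))
})

test_that("marker columns are standardized and reproduce the wide gradient", {
  es <- demo_eems()
  expect_equal(colMeans(es$eem_values), rep(0, es$K), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(apply(es$eem_values, 2, sd), rep(1, es$K),
               ignore_attr = TRUE, tolerance = 1e-9)
  # cluster-size-weighted mean of the raw markers equals the wide gradient
  # before re-standardization
  sizes <- tabulate(es$cluster_of_tree, es$K)
  recon <- drop(es$eem_raw %*% sizes) / sum(sizes)
  expect_equal(recon, es$wide_raw, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("identical trees collapse onto the wide gradient; anti-correlated families split", {
  sim <- demo_sim()
  tc <- demo_trial_covariates()
  b1 <- fit_tree_bank(tc, sim$phenotypes, n_trees = 1, seed = 3)
  same <- b1
  same$trees <- rep(b1$trees, 4)
  same$importances <- rep(b1$importances, 4)
  same$subsamples <- rep(b1$subsamples, 4)
  same$n_trees <- 4L
  es <- cluster_and_aggregate(same, K = 2,
                              reference_covariates = sim$covariates)
  expect_equal(unname(es$eem_values[, 1]), unname(es$eem_values[, 2]))
  expect_equal(unname(es$eem_values[, 1]), unname(es$wide_gradient))
  # two exactly anti-correlated tree families: fit CART stumps on m = w and
  # m = -w so their standardized predictions are mirror images
  w <- tc[[covariate_names(tc)[1]]]
  df_pos <- data.frame(.m = w, w = w)
  df_neg <- data.frame(.m = -w, w = w)
  ctrl <- rpart::rpart.control(minsplit = 4, minbucket = 2, cp = 0,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  tpos <- rpart::rpart(.m ~ w, df_pos, control = ctrl)
  tneg <- rpart::rpart(.m ~ w, df_neg, control = ctrl)
  fam <- b1
  fam$trees <- list(tpos, tpos, tneg, tneg)
  fam$importances <- rep(list(c(w = 1)), 4)
  fam$subsamples <- rep(b1$subsamples, 4)
  fam$n_trees <- 4L
  fam$covariates <- "w"
  cov_ref <- sim$covariates
  cov_ref$w <- cov_ref[[covariate_names(cov_ref)[1]]]
  es2 <- cluster_and_aggregate(fam, K = 2, reference_covariates = cov_ref)
  cl <- es2$cluster_of_tree
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
  expect_error(cluster_and_aggregate(fam, K = 10, cov_ref), "K exceeds")
})

test_that("marker values at permuted locations permute identically", {
  sim <- demo_sim()
  es <- demo_eems()
  bank <- demo_bank()
  perm <- sample(nrow(sim$covariates))
  v1 <- eem_values_at(es, bank, sim$covariates)
  v2 <- eem_values_at(es, bank, sim$covariates[perm, ])
  expect_equal(v2$eem, v1$eem[perm, ])
  expect_equal(v2$wide, v1$wide[perm])
})

test_that("importance tally ranks the planted causal covariate first", {
  tal <- ewas_tally(demo_bank())
  expect_equal(sum(tal$source_shares), 100, tolerance = 1e-9)
  # at this small trial count smooth noise fields can top the list by
  # chance, but the causal family (causal fields and their collinear
  # copies) must reach the top 5 by mean importance; the sharp version of
  # this check runs at 50 trials in the acceptance suite
  nm <- covariate_names(demo_sim()$covariates)
  causal <- attr(demo_sim()$covariates, "causal")
  family <- unlist(lapply(match(causal, nm), function(i) nm[i:(i + 3)]))
  top5 <- tal$tally$covariate[order(-tal$tally$mean_importance)][1:5]
  expect_gt(length(intersect(top5, family)), 0)
  # single-covariate bank: rank 1 in 100% of informative iterations
  sim <- demo_sim()
  tc <- demo_trial_covariates()
  onecov <- validate_covariates(
    cbind(tc[, c("location_id", "lat", "lon")],
          w1 = tc[[covariate_names(tc)[1]]]))
  bank1 <- fit_tree_bank(onecov, sim$phenotypes, n_trees = 30, seed = 1)
  tal1 <- ewas_tally(bank1)
  expect_equal(tal1$tally$rank1[tal1$tally$covariate == "w1"],
               tal1$n_iterations)
})

test_that("the aggregated gradient is stable under tree-count scaling", {
  # a 10x smaller bank with a different seed reproduces the wide gradient:
  # the ensemble is what matters, not the individual trees
  sim <- demo_sim()
  tc <- demo_trial_covariates()
  big <- fit_tree_bank(tc, sim$phenotypes, n_trees = 800, seed = 1)
  small <- fit_tree_bank(tc, sim$phenotypes, n_trees = 80, seed = 2)
  e_big <- cluster_and_aggregate(big, K = 3,
                                 reference_covariates = sim$covariates)
  e_small <- cluster_and_aggregate(small, K = 3,
                                   reference_covariates = sim$covariates)
  expect_gt(cor(e_big$wide_gradient, e_small$wide_gradient), 0.95)
})

test_that("marker validation separates signal from noise", {
  # low-residual, strong-environment study: the marker engine should
  # predict held-out trial means well; with phenotypes replaced by pure
  # noise the leave-one-out correlation collapses
  sim <- simulate_enviromic_study(n_trials = 30, n_hybrids = 30,
                                  n_parents = 10, genotypes_per_trial = 20,
                                  cell_size_km = 12, buffer_km = 30,
                                  sigma_e = 0.1, env_main_sd = 2, seed = 11)
  tc <- trial_covariate_rows(sim$covariates, sim$trials)
  val <- validate_eems(tc, sim$phenotypes, n_trees = 150, loo_n_trees = 60,
                       seed = 1)
  expect_gt(val$fit_correlation, 0.9)
  expect_gt(val$loo_correlation, 0.7)
  noise <- sim$phenotypes
  set.seed(9)
  noise$yield_blue <- rnorm(nrow(noise))
  valn <- validate_eems(tc, noise, n_trees = 80, loo_n_trees = 40, seed = 1)
  expect_lt(abs(valn$loo_correlation), 0.45)
  expect_error(validate_eems(tc[1:2, ], sim$phenotypes), "at least 3")
})
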