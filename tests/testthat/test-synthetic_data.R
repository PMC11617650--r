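# Synthetic-data generator: covariate fields, pedigree, genetic effects,
# trials and phenotypes.

test_that("covariate fields have the requested census and collinearity", {
  sim <- demo_sim()
  g <- build_prediction_grid(data.frame(lat = c(-25, -25.5, -24.6, -25.2),
                                        lon = c(-52, -51.5, -51.8, -52.3)),
                             cell_size_km = 10, buffer_km = 20)
  one <- simulate_covariate_fields(g, n_causal = 1, n_noise = 0,
                                   n_collinear_per_causal = 0, seed = 1)
  expect_length(covariate_names(one), 1)
  # collinear copies correlate strongly with their parent field
  cv <- simulate_covariate_fields(g, n_causal = 2, n_noise = 3,
                                  n_collinear_per_causal = 2,
                                  range_km = 80, seed = 1)
  causal <- attr(cv, "causal")
  nm <- covariate_names(cv)
  for (cz in causal) {
    copies <- nm[seq(match(cz, nm) + 1, match(cz, nm) + 2)]
    for (cp in copies) {
      expect_gt(abs(cor(cv[[cz]], cv[[cp]])), 0.8)
    }
  }
  expect_error(simulate_covariate_fields(g, n_causal = -1), "n_causal")
})

test_that("covariate fields are spatially autocorrelated", {
  g <- build_prediction_grid(data.frame(lat = c(-25, -26, -24.5, -25.4),
                                        lon = c(-52, -51, -51.6, -52.4)),
                             cell_size_km = 10, buffer_km = 30)
  range_km <- 15
  d2 <- outer(g$bins$x_km, g$bins$x_km, "-")^2 +
    outer(g$bins$y_km, g$bins$y_km, "-")^2
  near <- which(d2 > 0 & d2 < 12^2, arr.ind = TRUE)
  far <- which(d2 > (10 * range_km)^2, arr.ind = TRUE)
  expect_gt(nrow(far), 0)
  near_wins <- 0
  n_fields <- 100
  cv <- simulate_covariate_fields(g, n_causal = 0, n_noise = n_fields,
                                  n_collinear_per_causal = 0,
                                  range_km = range_km, seed = 1)
  for (nm in covariate_names(cv)) {
    v <- cv[[nm]]
    dn <- mean(abs(v[near[, 1]] - v[near[, 2]]))
    df_ <- mean(abs(v[far[, 1]] - v[far[, 2]]))
    if (dn < df_) near_wins <- near_wins + 1
  }
  expect_gt(near_wins / n_fields, 0.95)
})

test_that("pedigree generator reproduces the study census shape", {
  ped <- simulate_pedigree(2, 1, competitor_fraction = 0, seed = 1)
  h <- ped[ped$genotype_id == "H001", ]
  expect_setequal(c(h$dam_id, h$sire_id), c("P001", "P002"))
  # acyclic with all named parents present: additive_relationship succeeds
  big <- simulate_pedigree(85, 79, seed = 3)
  expect_equal(nrow(big), 164)
  expect_equal(sum(grepl("^H", big$genotype_id)), 79)
  expect_equal(sum(grepl("^P", big$genotype_id)), 85)
  A <- additive_relationship(big)
  expect_true(all(diag(A$A) >= 1))
  expect_error(simulate_pedigree(1, 5), "at least 2")
})

test_that("genetic effects follow the matrix-normal structure", {
  expect_equal(unname(simulate_genetic_effects(diag(3), matrix(0, 2, 2))),
               matrix(0, 3, 2))
  # unrelated genotypes (A = I) moment check: empirical covariance of
  # (intercept, slope) close to Sigma_true at large n
  St <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  U <- simulate_genetic_effects(NULL, St, seed = 1, n_genotypes = 20000)
  expect_equal(cov(U), St, ignore_attr = TRUE, tolerance = 0.05)
  # identical twin rows in A give identical effect vectors
  A <- diag(3); A[1, 2] <- A[2, 1] <- 1
  U2 <- simulate_genetic_effects(A, St, seed = 2)
  expect_equal(U2[1, ], U2[2, ], tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(simulate_genetic_effects(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("noise-free phenotypes follow the stated reaction-norm arithmetic", {
  sim <- demo_sim()
  grads <- sim$truth$gradients
  ids <- sim$kinship$ids
  hyb <- grep("^H", ids, value = TRUE)
  # all slopes zero, sigma_e = 0, single year, no environment main effect:
  # a genotype's phenotype is constant across trials
  u0 <- cbind(rnorm(length(ids)), 0, 0)
  rownames(u0) <- ids
  phen <- simulate_trials_and_phenotypes(
    sim$grid, grads, u0, hyb, n_trials = 8, genotypes_per_trial = 6,
    years = 2020, year_effects = c("2020" = 0.3), sigma_e = 0,
    env_main_sd = 0, seed = 4)
  spread <- tapply(phen$yield_blue, phen$genotype_id,
                   function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  # known slope, sigma_e = 0: between-trial differences equal
  # slope x gradient difference
  u1 <- cbind(0, 1, 0)[rep(1, length(ids)), ]
  rownames(u1) <- ids
  phen2 <- simulate_trials_and_phenotypes(
    sim$grid, grads, u1, hyb, n_trials = 8, genotypes_per_trial = 6,
    years = 2020, year_effects = c("2020" = 0), sigma_e = 0,
    env_main_sd = 0, seed = 5)
  tr2 <- attr(phen2, "trials")
  g1 <- grads[tr2$bin_id[1], 1]
  g2 <- grads[tr2$bin_id[2], 1]
  y1 <- phen2$yield_blue[phen2$trial_id == tr2$trial_id[1]][1]
  y2 <- phen2$yield_blue[phen2$trial_id == tr2$trial_id[2]][1]
  expect_equal(y1 - y2, g1 - g2, tolerance = 1e-12)
})

test_that("trial design is unbalanced and the generator is deterministic", {
  sim <- demo_sim()
  counts <- table(sim$phenotypes$trial_id)
  expect_gt(length(unique(as.integer(counts))), 1)
  sim2 <- simulate_enviromic_study(n_trials = 14, n_hybrids = 24,
                                   n_parents = 10,
                                   genotypes_per_trial = 12,
                                   cell_size_km = 12, buffer_km = 30,
                                   seed = 1)
  expect_identical(sim$phenotypes$yield_blue, sim2$phenotypes$yield_blue)
  expect_identical(as.data.frame(sim$covariates),
                   as.data.frame(sim2$covariates))
  expect_error(simulate_trials_and_phenotypes(
    sim$grid, sim$truth$gradients, sim$truth$u_true,
    grep("^H", sim$kinship$ids, value = TRUE), n_trials = 5,
    genotypes_per_trial = 1000), "census")
})

test_that("per-trial true environment means are exposed for oracle checks", {
  sim <- demo_sim()
  tr <- sim$trials
  expect_true(all(c("bin_id", "env_mean_true") %in% names(tr)))
  # the observed trial mean tracks the true environment mean (the sampled
  # genotype subsets add genetic noise on top, so the association is strong
  # but not perfect at 14 trials)
  m <- tapply(sim$phenotypes$yield_blue, sim$phenotypes$trial_id, mean)
  expect_gt(cor(m[tr$trial_id], tr$env_mean_true), 0.5)
})
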