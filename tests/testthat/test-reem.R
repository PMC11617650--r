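# Reaction-norm mixed model: design assembly, REML, predictions, ensemble,
# stability angles.

tiny_instance <- function(seed = 1, K = 1, n_genotypes = 3, n_trials = 3) {
  set.seed(seed)
  ped <- validate_pedigree(data.frame(
    genotype_id = c("P1", "P2", sprintf("G%d", seq_len(n_genotypes))),
    dam_id = c("UNKNOWN", "UNKNOWN", rep("P1", n_genotypes)),
    sire_id = c("UNKNOWN", "UNKNOWN", rep("P2", n_genotypes)),
    stringsAsFactors = FALSE))
  kin <- additive_relationship(ped)
  trials <- sprintf("T%d", seq_len(n_trials))
  M <- matrix(rnorm(n_trials * K), n_trials, K,
              dimnames = list(trials, paste0("eem", seq_len(K))))
  recs <- expand.grid(trial_id = trials,
                      genotype_id = sprintf("G%d", seq_len(n_genotypes)),
                      stringsAsFactors = FALSE)
  yr <- setNames(rep(c(2019L, 2020L), length.out = n_trials), trials)
  phen <- validate_phenotypes(data.frame(
    recs, year = yr[recs$trial_id], irrigated = FALSE, region = "A",
    lat = -25, lon = -52, yield_blue = rnorm(nrow(recs)),
    stringsAsFactors = FALSE))
  list(phen = phen, kin = kin, M = M)
}

test_that("design assembly produces the stated block-diagonal structure", {
  ti <- tiny_instance(n_genotypes = 2, n_trials = 2)
  d <- assemble_design(ti$phen, ti$M, ids = ti$kin$ids)
  expect_equal(ncol(d$Z), length(ti$kin$ids) * 2)
  # rows of genotype g carry [1, eps(trial)] in g's block, zeros elsewhere
  g1 <- match("G1", ti$kin$ids)
  for (i in which(ti$phen$genotype_id == "G1")) {
    blk <- d$Z[i, (g1 - 1) * 2 + 1:2]
    expect_equal(blk, c(1, ti$M[ti$phen$trial_id[i], 1]),
                 ignore_attr = TRUE)
    expect_equal(sum(d$Z[i, ] != 0), 2)
  }
  # K = 0 reduces to a genotype incidence matrix
  d0 <- assemble_design(ti$phen, NULL, ids = ti$kin$ids)
  expect_equal(ncol(d0$Z), length(ti$kin$ids))
  expect_true(all(d0$Z %in% c(0, 1)))
  expect_equal(rowSums(d0$Z), rep(1, nrow(ti$phen)))
  # linkage errors
  bad <- ti$M[1, , drop = FALSE]
  expect_error(assemble_design(ti$phen, bad, ids = ti$kin$ids),
               "missing from the marker table")
  expect_error(assemble_design(ti$phen, ti$M, ids = c("X")), "absent")
})

test_that("BLUE/BLUP at fixed variance components equal the dense conditional-mean oracle", {
  for (seed in 1:5) {
    ti <- tiny_instance(seed = seed, K = 1, n_genotypes = 3, n_trials = 3)
    d <- assemble_design(ti$phen, ti$M, ids = ti$kin$ids)
    Sigma <- matrix(c(1, 0.2, 0.2, 0.5), 2)
    fit <- fit_reml(d, ti$kin, fixed_varcomp = list(Sigma = Sigma,
                                                    sigma_e2 = 0.3))
    oracle <- dense_mme_oracle(d, ti$kin$A, Sigma, 0.3)
    expect_lt(max(abs(fit$b - oracle$b)), 1e-6)
    expect_lt(max(abs(as.numeric(t(fit$u)) - oracle$u)), 1e-6)
  }
})

test_that("solutions are invariant to record order", {
  ti <- tiny_instance(seed = 3)
  d1 <- assemble_design(ti$phen, ti$M, ids = ti$kin$ids)
  perm <- sample(nrow(ti$phen))
  d2 <- assemble_design(ti$phen[perm, ], ti$M, ids = ti$kin$ids)
  fv <- list(Sigma = diag(c(1, 0.5)), sigma_e2 = 0.4)
  f1 <- fit_reml(d1, ti$kin, fixed_varcomp = fv)
  f2 <- fit_reml(d2, ti$kin, fixed_varcomp = fv)
  expect_equal(f1$u, f2$u, tolerance = 1e-10)
  expect_equal(f1$b, f2$b, tolerance = 1e-10)
})

test_that("REML shrinks genetic variances toward zero when no genetic signal exists", {
  # data simulated with Sigma = 0: phenotype = year effect + noise
  set.seed(1)
  ped <- simulate_pedigree(6, 20, seed = 1)
  kin <- additive_relationship(ped)
  hyb <- grep("^H", kin$ids, value = TRUE)
  trials <- sprintf("T%02d", 1:12)
  M <- matrix(rnorm(12), 12, 1, dimnames = list(trials, "eem1"))
  recs <- expand.grid(trial_id = trials, genotype_id = hyb,
                      stringsAsFactors = FALSE)
  yr <- setNames(rep(2018:2020, length.out = 12), trials)
  phen <- validate_phenotypes(data.frame(
    recs, year = yr[recs$trial_id], irrigated = FALSE, region = "A",
    lat = -25, lon = -52,
    yield_blue = 0.3 * yr[recs$trial_id] - 600 + rnorm(nrow(recs)),
    stringsAsFactors = FALSE))
  d <- assemble_design(phen, M, ids = kin$ids)
  fit <- suppressWarnings(fit_reml(d, kin, structure = "unstructured",
                                   tol = 1e-7))
  expect_lt(fit$Sigma[1, 1], 0.05 * fit$sigma_e2)
  expect_lt(fit$Sigma[2, 2], 0.05 * fit$sigma_e2)
})

test_that("pedigree kinship shrinks related genotypes toward each other", {
  # full-sib families; same data fit with pedigree A vs identity A
  set.seed(2)
  ped <- simulate_pedigree(8, 24, competitor_fraction = 0, seed = 2)
  kin <- additive_relationship(ped)
  hyb <- grep("^H", kin$ids, value = TRUE)
  trials <- sprintf("T%02d", 1:8)
  recs <- expand.grid(trial_id = trials, genotype_id = hyb,
                      stringsAsFactors = FALSE)
  phen <- validate_phenotypes(data.frame(
    recs, year = 2020L, irrigated = FALSE, region = "A", lat = -25,
    lon = -52, yield_blue = rnorm(nrow(recs)), stringsAsFactors = FALSE))
  d <- assemble_design(phen, NULL, ids = kin$ids)
  fv <- list(Sigma = matrix(1), sigma_e2 = 1)
  fped <- fit_reml(d, kin, fixed_varcomp = fv)
  iid <- kin; iid$A <- diag(length(kin$ids))
  dimnames(iid$A) <- dimnames(kin$A)
  fiid <- fit_reml(d, iid, fixed_varcomp = fv)
  # mean absolute BLUP difference between relatives (a > 0) is smaller
  # under the pedigree model
  rel <- which(kin$A > 0.2 & upper.tri(kin$A), arr.ind = TRUE)
  dif <- function(u) mean(abs(u[rel[, 1], 1] - u[rel[, 2], 1]))
  expect_lt(dif(fped$u), dif(fiid$u))
})

test_that("bin predictions follow the reaction-norm arithmetic", {
  fit <- structure(list(
    b = c(y2019 = 1, y2020 = 3),
    u = matrix(c(0.5, -0.5, 0, 1, 0, 0), 2, 3,
               dimnames = list(c("G1", "G2"), c("u0", "u1", "u2"))),
    Sigma = diag(3), sigma_e2 = 1, K = 2L,
    ids = c("G1", "G2")), class = "reem_fit")
  M <- matrix(c(0, 1, 2, 0, 0, 0), 3, 2,
              dimnames = list(c("b1", "b2", "b3"), c("eem1", "eem2")))
  pred <- predict_bins(fit, M)
  # G1 has zero slopes: flat surface at mean(b) + u0
  expect_equal(unname(pred["G1", ]), rep(2.5, 3))
  # G2 slope 1 on marker 1: differences across bins equal marker differences
  expect_equal(unname(diff(pred["G2", ])), unname(diff(M[, 1])))
  expect_error(predict_bins(fit, M, genotypes = "NOPE"), "unknown genotype")
})

test_that("stability angles map slopes to degrees", {
  expect_equal(stability_angles(c(1, 0, -1)), c(45, 0, -45))
  draws <- matrix(c(1, 0, -1, 1, 1, 1), 3, 2,
                  dimnames = list(NULL, c("G1", "G2")))
  st <- stability_angles(draws)
  expect_equal(st$summary$angle_min, c(-45, 45))
  expect_equal(st$summary$angle_max, c(45, 45))
  expect_equal(st$summary$angle_mean, c(0, 45))
})

test_that("ensemble over identical trees is degenerate with zero spread", {
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
  ens <- ensemble_reem(sim$phenotypes, same, es, sim$kinship, tc,
                       sim$covariates, n_runs = 3, seed = 1)
  expect_equal(ens$n_runs_used, 3)
  # runs agree up to the REML solver tolerance, so the run-to-run spread is
  # negligible against the genetic signal
  expect_lt(max(ens$se), 0.01 * sd(ens$mean))
})

test_that("ensemble outputs are coherent on demo data", {
  ens <- demo_ensemble()
  expect_equal(dim(ens$mean), dim(ens$se))
  expect_true(all(ens$se >= 0))
  # pooled Sigma symmetric PSD
  S <- ens$Sigma_pooled
  expect_equal(S, t(S), tolerance = 1e-10)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # slope draws cover runs x markers for every genotype in the kinship
  expect_equal(ncol(ens$slope_draws), length(demo_sim()$kinship$ids))
  expect_equal(nrow(ens$slope_draws), ens$n_runs_used * demo_eems()$K)
})
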