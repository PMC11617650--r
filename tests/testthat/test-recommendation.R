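# Statistical ties, geographic representativeness, occupation summaries,
# parental recommendation.

test_that("statistical ties follow the t-test and its normal limit", {
  mu <- c(G1 = 3, G2 = 2, G3 = 1)
  # zero SEs with distinct means: only the best is tied
  expect_equal(statistical_ties(mu, c(G1 = 0, G2 = 0, G3 = 0)), "G1")
  # equal means: everyone tied
  expect_setequal(statistical_ties(c(G1 = 1, G2 = 1, G3 = 1),
                                   c(G1 = 0.1, G2 = 0.1, G3 = 0.1),
                                   df = 100), c("G1", "G2", "G3"))
  # normal-approximation boundary: delta = 1.96 * sqrt(2) * se at large df
  # gives p just under 0.05, so the trailing genotype is excluded; slightly
  # smaller delta keeps it
  se <- 0.5
  d_out <- 1.96 * sqrt(2) * se
  d_in <- 1.90 * sqrt(2) * se
  expect_equal(statistical_ties(c(A = d_out, B = 0), c(A = se, B = se),
                                alpha = 0.05, df = 1e6), "A")
  expect_setequal(statistical_ties(c(A = d_in, B = 0), c(A = se, B = se),
                                   alpha = 0.05, df = 1e6), c("A", "B"))
})

test_that("representativeness picks the nearest tied genotype with stated tie-breaks", {
  expect_equal(representativeness_select(
    c("G1", "G2"), c(G1 = 1, G2 = 100), c(G1 = 1, G2 = 5)), "G1")
  # distance tie: higher mean wins
  expect_equal(representativeness_select(
    c("G1", "G2"), c(G1 = 7, G2 = 7), c(G1 = 1, G2 = 5)), "G2")
  # full tie: lexicographic id
  expect_equal(representativeness_select(
    c("Gb", "Ga"), c(Ga = 7, Gb = 7), c(Ga = 1, Gb = 1)), "Ga")
})

test_that("alpha trades predicted mean against representativeness monotonically", {
  # constructed bin: the best-yield genotype is trialed far away, a
  # statistically tied one nearby. Under the tie rule (tied iff p > alpha)
  # a moderate alpha keeps the near genotype in the tied set so it wins;
  # alpha -> 1 collapses the tie to the distant top yielder.
  sim <- demo_sim()
  grid <- sim$grid
  phen <- sim$phenotypes
  gens <- sort(unique(phen$genotype_id))[1:4]
  B <- nrow(grid$bins)
  mean_mat <- matrix(rep(c(1.0, 0.95, 0.2, 0.1), B), 4, B,
                     dimnames = list(gens, grid$bins$bin_id))
  se_mat <- matrix(0.2, 4, B, dimnames = dimnames(mean_mat))
  fake <- list(mean = mean_mat, se = se_mat, n_runs_used = 50)
  # make genotype 1 distant: keep only its records in the farthest trial
  far_trial <- phen$trial_id[which.max(phen$lon)]
  keep <- phen$genotype_id != gens[1] | phen$trial_id == far_trial
  phen2 <- phen[keep, ]
  if (!gens[1] %in% phen2$genotype_id) {
    add <- phen[phen$trial_id == far_trial, ][1, ]
    add$genotype_id <- gens[1]
    phen2 <- validate_phenotypes(rbind(as.data.frame(phen2), add))
  }
  rec_wide <- recommend_genotypes(fake, grid, phen2, alpha = 0.05,
                                  genotypes = gens)
  rec_none <- recommend_genotypes(fake, grid, phen2, alpha = 1 - 1e-9,
                                  genotypes = gens)
  # with no ties the top-yield genotype wins everywhere
  expect_true(all(rec_none$winners$winner == gens[1]))
  # wide ties let nearer tied genotypes take bins; winner mean never
  # exceeds the no-tie winner mean at any bin
  m_wide <- mean_mat[cbind(rec_wide$winners$winner,
                           rec_wide$winners$bin_id)]
  m_none <- mean_mat[cbind(rec_none$winners$winner,
                           rec_none$winners$bin_id)]
  expect_true(all(m_wide <= m_none + 1e-12))
  expect_gt(sum(rec_wide$winners$winner != gens[1]), 0)
})

test_that("occupation summary accounts for every bin", {
  sim <- demo_sim()
  ens <- demo_ensemble()
  rec <- recommend_genotypes(ens, sim$grid, sim$phenotypes)
  st <- stability_angles(ens$slope_draws)$summary
  occ <- occupation_summary(rec, sim$phenotypes, sim$grid, st)
  expect_equal(sum(occ$bins_won), nrow(sim$grid$bins))
  expect_equal(sum(occ$pct_area), 100, tolerance = 1e-9)
  expect_true(all(c("angle_min", "angle_max", "angle_mean") %in%
                    names(occ)))
  # single candidate genotype occupies everything
  g1 <- rownames(ens$mean)[rownames(ens$mean) %in%
                             sim$phenotypes$genotype_id][1]
  rec1 <- recommend_genotypes(ens, sim$grid, sim$phenotypes,
                              genotypes = g1)
  occ1 <- occupation_summary(rec1, sim$phenotypes, sim$grid)
  expect_equal(occ1$pct_area, 100)
})

test_that("parental recommendation propagates through kinship", {
  sim <- demo_sim()
  ens <- demo_ensemble()
  parents <- grep("^P", sim$kinship$ids, value = TRUE)
  pr <- parental_recommendation(ens, parents)
  expect_equal(nrow(pr), ncol(ens$mean))
  expect_true(all(pr$top1 != pr$top2))
  # mid-parent identity
  b <- 5
  expect_equal(pr$cross_value[b],
               (ens$mean[pr$top1[b], b] + ens$mean[pr$top2[b], b]) / 2)
  expect_error(parental_recommendation(ens, character(0)), "no parents")
  # a founder with no phenotyped descendants shrinks to the prior mean:
  # its surface is flat at the mean fixed effect
  lone <- validate_pedigree(data.frame(
    genotype_id = c(sim$pedigree$genotype_id, "P999"),
    dam_id = c(sim$pedigree$dam_id, "UNKNOWN"),
    sire_id = c(sim$pedigree$sire_id, "UNKNOWN"),
    stringsAsFactors = FALSE))
  kin2 <- additive_relationship(lone)
  ti <- demo_trial_covariates()
  ens2 <- ensemble_reem(sim$phenotypes, demo_bank(), demo_eems(), kin2,
                        ti, sim$covariates, n_runs = 2, seed = 5)
  expect_equal(diff(range(ens2$mean["P999", ])), 0, tolerance = 1e-8)
  # parents of high-merit hybrids sit above parents of low-merit hybrids
  hyb_means <- rowMeans(ens$mean)[grep("^H", sim$kinship$ids)]
  par_means <- rowMeans(ens$mean)[parents]
  ped <- sim$pedigree
  child_merit <- vapply(parents, function(p) {
    kids <- ped$genotype_id[ped$dam_id == p | ped$sire_id == p]
    kids <- intersect(kids, names(hyb_means))
    if (length(kids) == 0) NA_real_ else mean(hyb_means[kids])
  }, numeric(1))
  ok <- !is.na(child_merit)
  expect_gt(cor(par_means[ok], child_merit[ok]), 0.5)
})
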