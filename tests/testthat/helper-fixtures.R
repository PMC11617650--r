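# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small synthetic study shared across test files
demo_sim <- function() {
  fixture("demo_sim", function() {
    simulate_enviromic_study(n_trials = 14, n_hybrids = 24, n_parents = 10,
                             genotypes_per_trial = 12, cell_size_km = 12,
                             buffer_km = 30, seed = 1)
  })
}

demo_trial_covariates <- function() {
  fixture("demo_tc", function() {
    sim <- demo_sim()
    trial_covariate_rows(sim$covariates, sim$trials)
  })
}

demo_bank <- function() {
  fixture("demo_bank", function() {
    fit_tree_bank(demo_trial_covariates(), demo_sim()$phenotypes,
                  n_trees = 120, seed = 1)
  })
}

demo_eems <- function() {
  fixture("demo_eems", function() {
    cluster_and_aggregate(demo_bank(), K = 3,
                          reference_covariates = demo_sim()$covariates)
  })
}

demo_ensemble <- function() {
  fixture("demo_ensemble", function() {
    sim <- demo_sim()
    ensemble_reem(sim$phenotypes, demo_bank(), demo_eems(), sim$kinship,
                  demo_trial_covariates(), sim$covariates, n_runs = 6,
                  seed = 2)
  })
}

# tiny phenotype table built in code
toy_phenotypes <- function() {
  validate_phenotypes(data.frame(
    trial_id = c("T1", "T1", "T2", "T2"),
    genotype_id = c("G1", "G2", "G1", "G2"),
    year = 2020L, irrigated = FALSE, region = "A",
    lat = c(-25, -25, -24, -24), lon = c(-52, -52, -51, -51),
    yield_blue = c(1, 2, 3, 5), stringsAsFactors = FALSE))
}

# independent recursive-coancestry oracle (for kinship tests): A = 2 f
coancestry_oracle <- function(ped) {
  ids <- ped$genotype_id
  dam <- match(ped$dam_id, ids)
  sire <- match(ped$sire_id, ids)
  n <- length(ids)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(dam[i], sire[i]))
    } else {
      # recurse on the individual appearing later (parents precede
      # offspring in these generated pedigrees)
      a <- max(i, j); b <- min(i, j)
      0.5 * (f(dam[a], b) + f(sire[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# random pedigree with parents at lower indices (selfing allowed)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  dam <- sire <- rep("UNKNOWN", n)
  ids <- sprintf("I%02d", seq_len(n))
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) > 0.4) {
      dam[i] <- ids[sample.int(i - 1, 1)]
      sire[i] <- ids[sample.int(i - 1, 1)]
    }
  }
  validate_pedigree(data.frame(genotype_id = ids, dam_id = dam,
                               sire_id = sire, stringsAsFactors = FALSE))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nn <- comb2(sum(tab))
  exp_ <- si * sj / nn
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# dense joint-normal conditional-mean oracle for the mixed model at fixed
# variance components: BLUE by GLS, BLUP = G Z' Vinv (y - X b)
dense_mme_oracle <- function(design, A, Sigma, sigma_e2) {
  G <- kronecker(A, Sigma)  # genotype-major blocks
  V <- design$Z %*% G %*% t(design$Z) + diag(sigma_e2, length(design$y))
  Vinv <- solve(V)
  XtVinvX <- t(design$X) %*% Vinv %*% design$X
  b <- solve(XtVinvX, t(design$X) %*% Vinv %*% design$y)
  u <- G %*% t(design$Z) %*% Vinv %*% (design$y - design$X %*% b)
  list(b = drop(b), u = drop(u))
}
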