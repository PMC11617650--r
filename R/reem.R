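# Random-regression reaction-norm mixed model ("reaction to engineered
# enviromic markers"): y = Xb + Zu + e with u ~ N(0, Sigma (x) A),
# e ~ N(0, I sigma_e^2). Z is block-diagonal over genotypes, each block
# [1 | eps_1(trial) ... eps_K(trial)]. REML by EM iterations on the
# mixed-model equations; the ensemble refits the model with one sampled
# tree-predictor per marker cluster per run and averages predictions.

#' Assemble the design of the reaction-norm mixed model
#'
#' Builds `y`, the fixed-effect design `X` (one intercept per year by
#' default) and the block-diagonal random design `Z`: for each genotype the
#' block is a leading column of ones (overall genetic merit, as in ordinary
#' pedigree BLUP) followed by the K marker values of the record's trial.
#' With `trial_markers = NULL` (K = 0) `Z` reduces to a genotype incidence
#' matrix.
#'
#' @param phenotypes a `phenotype_table`.
#' @param trial_markers numeric matrix trials x K with rownames = trial ids,
#'   or `NULL` for K = 0.
#' @param ids genotype ids defining the random-effect order (the kinship
#'   ids; may include unphenotyped parents, which simply get empty rows).
#' @param fixed `"year"` (default), `"irrigated"` or `"intercept"`.
#' @return list with `y`, `X`, `Z`, `q`, `K`, `p`, `ids`, `fixed_levels`.
#' @export
assemble_design <- function(phenotypes, trial_markers = NULL, ids,
                            fixed = c("year", "irrigated", "intercept")) {
  fixed <- match.arg(fixed)
  n <- nrow(phenotypes)
  gidx <- match(phenotypes$genotype_id, ids)
  if (anyNA(gidx)) {
    stop("genotype(s) absent from the kinship ids: ",
         paste(unique(phenotypes$genotype_id[is.na(gidx)])[1:3],
               collapse = ", "), call. = FALSE)
  }
  K <- if (is.null(trial_markers)) 0L else ncol(trial_markers)
  if (K > 0) {
    tm <- match(phenotypes$trial_id, rownames(trial_markers))
    if (anyNA(tm)) {
      stop("trial(s) missing from the marker table: ",
           paste(unique(phenotypes$trial_id[is.na(tm)])[1:3],
                 collapse = ", "), call. = FALSE)
    }
    M <- trial_markers[tm, , drop = FALSE]
  }
  X <- switch(fixed,
    year = {
      f <- factor(phenotypes$year)
      if (nlevels(f) == 1) matrix(1, n, 1, dimnames = list(NULL, "intercept"))
      else stats::model.matrix(~ 0 + f)
    },
    irrigated = {
      f <- factor(phenotypes$irrigated)
      if (nlevels(f) == 1) {
        warning("single irrigation level; fitting a plain intercept")
        matrix(1, n, 1, dimnames = list(NULL, "intercept"))
      } else stats::model.matrix(~ 0 + f)
    },
    intercept = matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  colnames(X) <- sub("^f", fixed, colnames(X))
  q <- length(ids)
  Z <- matrix(0, n, q * (K + 1L))
  for (i in seq_len(n)) {
    j0 <- (gidx[i] - 1L) * (K + 1L)
    Z[i, j0 + 1L] <- 1
    if (K > 0) Z[i, j0 + 1L + seq_len(K)] <- M[i, ]
  }
  list(y = phenotypes$yield_blue, X = X, Z = Z, q = q, K = K,
       p = ncol(X), ids = ids, fixed_levels = colnames(X))
}

# bend a symmetric matrix to be positive definite (eigenvalue floor)
bend_pd <- function(S, eps_rel = 1e-6) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  floor_ <- eps_rel * max(e$values, 1e-12)
  if (min(e$values) >= floor_) return(S)
  v <- pmax(e$values, floor_)
  e$vectors %*% (v * t(e$vectors))
}

#' Fit the reaction-norm mixed model by REML (EM on the MME)
#'
#' Estimates the (K+1)-square coefficient covariance `Sigma` and the
#' residual variance by expectation-maximization steps on Henderson's
#' mixed-model equations, with `Sigma` bent to positive definite at each
#' iterate. BLUEs of the fixed effects and BLUPs of all genotype
#' coefficients (including unphenotyped relatives, via A) come from the MME
#' at convergence. With `fixed_varcomp` supplied the variance components are
#' held fixed and the MME are solved once — the mode used by the
#' small-instance conditional-mean oracle tests.
#'
#' @param design output of [assemble_design()].
#' @param kinship a `kinship_matrix` (ids must match `design$ids`).
#' @param structure `"auto"` (diagonal fallback when q < 5(K+1)),
#'   `"unstructured"` or `"diagonal"`.
#' @param init optional warm start: list with `Sigma`, `sigma_e2`.
#' @param fixed_varcomp optional list with `Sigma`, `sigma_e2` to hold fixed.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum number of MME solves (the SQUAREM-accelerated EM
#'   uses about three per cycle).
#' @return an object of class `reem_fit`: `b`, `u` (genotypes x (K+1)
#'   matrix), `Sigma`, `sigma_e2`, `loglik`, `converged`, `n_iter`,
#'   `structure`, plus design metadata.
#' @export
fit_reml <- function(design, kinship, structure = c("auto", "unstructured",
                                                    "diagonal"),
                     init = NULL, fixed_varcomp = NULL, tol = 1e-8,
                     maxit = 1000) {
  structure <- match.arg(structure)
  A <- if (inherits(kinship, "kinship_matrix")) kinship$A else kinship
  stopifnot(nrow(A) == design$q)
  y <- design$y; X <- design$X; Z <- design$Z
  n <- length(y); p <- design$p; q <- design$q; K <- design$K; m <- K + 1L
  if (n <= p || qr(X)$rank < p) stop("singular or over-saturated fixed design",
                                     call. = FALSE)
  A <- psd_repair(A)
  if (inherits(A, "kinship_matrix")) A <- A$A
  cA <- chol(A)
  Ainv <- chol2inv(cA)
  logdetA <- 2 * sum(log(diag(cA)))
  if (structure == "auto") {
    structure <- if (q < 5 * m) "diagonal" else "unstructured"
    if (structure == "diagonal" && is.null(fixed_varcomp)) {
      message("fit_reml: q = ", q, " < 5*(K+1); using diagonal Sigma")
    }
  }
  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y * y)
  vy <- stats::var(y)
  if (!is.null(fixed_varcomp)) {
    Sigma <- as.matrix(fixed_varcomp$Sigma); sigma_e2 <- fixed_varcomp$sigma_e2
  } else if (!is.null(init) && !is.null(init$Sigma) &&
             nrow(init$Sigma) == m) {
    Sigma <- as.matrix(init$Sigma); sigma_e2 <- init$sigma_e2
  } else {
    Sigma <- diag(rep(vy / (2 * m), m), m)
    sigma_e2 <- vy / 2
  }
  # genotype-major ordering: coefficient r of genotype g is column
  # (g-1)(K+1)+r of Z, so Cov(u) = A (x) Sigma
  solve_mme <- function(Sigma, sigma_e2, want_inverse = TRUE) {
    Sinv <- chol2inv(chol(bend_pd(Sigma)))
    Ginv <- kronecker(Ainv, Sinv)
    C <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ)) / sigma_e2
    ui <- p + seq_len(q * m)
    C[ui, ui] <- C[ui, ui] + Ginv
    ch <- chol(C)
    rhs <- c(Xty, Zty) / sigma_e2
    if (want_inverse) {
      Cinv <- chol2inv(ch)
      sol <- drop(Cinv %*% rhs)
    } else {
      Cinv <- NULL
      sol <- drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
    }
    b <- sol[seq_len(p)]; u <- sol[-seq_len(p)]
    yPy <- (yty - sum(b * Xty) - sum(u * Zty)) / sigma_e2
    m2l <- 2 * sum(log(diag(ch))) + q * determinant_pd(Sigma) +
      m * logdetA + n * log(sigma_e2) + yPy
    list(b = b, u = u, Cinv = Cinv, loglik = -0.5 * m2l, yPy = yPy)
  }
  if (!is.null(fixed_varcomp)) {
    s <- solve_mme(Sigma, sigma_e2)
    return(finish_reem_fit(s, Sigma, sigma_e2, design, TRUE, 0L, structure))
  }
  # one EM update of (Sigma, sigma_e2) given an MME solution
  em_update <- function(s) {
    se2 <- max((yty - sum(s$b * Xty) - sum(s$u * Zty)) / (n - p),
               1e-10 * vy)
    Snew <- matrix(0, m, m)
    for (r in seq_len(m)) {
      ir <- p + seq(r, by = m, length.out = q)
      ur <- s$u[seq(r, by = m, length.out = q)]
      for (ss in r:m) {
        is_ <- p + seq(ss, by = m, length.out = q)
        us <- s$u[seq(ss, by = m, length.out = q)]
        pev <- s$Cinv[ir, is_, drop = FALSE]
        val <- (sum(ur * (Ainv %*% us)) + sum(Ainv * t(pev))) / q
        Snew[r, ss] <- Snew[ss, r] <- val
      }
    }
    if (structure == "diagonal") Snew <- diag(diag(Snew), m)
    list(Sigma = bend_pd(Snew), sigma_e2 = se2)
  }
  # parameter vector: lower triangle of Sigma (diagonal only when
  # structure = "diagonal") followed by sigma_e2
  par_idx <- if (structure == "diagonal") {
    cbind(seq_len(m), seq_len(m))
  } else {
    lt <- which(lower.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
    lt[order(lt[, 2], lt[, 1]), , drop = FALSE]
  }
  n_sig <- nrow(par_idx)
  pack <- function(Sigma, se2) c(Sigma[par_idx], se2)
  unpack <- function(th) {
    S <- matrix(0, m, m)
    S[par_idx] <- th[-length(th)]
    S[par_idx[, 2:1, drop = FALSE]] <- th[-length(th)]
    list(Sigma = bend_pd(S), sigma_e2 = max(th[length(th)], 1e-10 * vy))
  }
  WtW <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), ZtZ))
  Wz <- cbind(t(XtZ), ZtZ)  # (q m) x (p + q m)

  # average-information step: REML scores and AI matrix for all Sigma
  # parameters + sigma_e2, computed from one MME factorization.
  ai_step <- function(s, Sigma, sigma_e2) {
    Sinv <- chol2inv(chol(bend_pd(Sigma)))
    Um <- matrix(s$u, nrow = m)             # coefficients x genotypes
    Wmat <- Sinv %*% Um %*% Ainv            # G^{-1} u, matrix form
    ehat <- y - drop(X %*% s$b) - drop(Z %*% s$u)
    # T = Z' P Z, contracted against A per coefficient pair
    Tm <- (ZtZ - Wz %*% s$Cinv %*% t(Wz) / sigma_e2) / sigma_e2
    T4 <- array(Tm, c(m, q, m, q))
    Tr1 <- matrix(0, m, m)
    for (r in seq_len(m)) for (ss in seq_len(m)) {
      Tr1[r, ss] <- sum(T4[r, , ss, ] * A)
    }
    AWq <- A %*% t(Wmat)                    # q x m
    Q1 <- Wmat %*% AWq                      # m x m
    WA <- t(AWq)                            # m x q, = Wmat %*% A
    trP <- (n - sum(s$Cinv * WtW) / sigma_e2) / sigma_e2
    score <- numeric(n_sig + 1L)
    Fm <- matrix(0, n, n_sig + 1L)
    for (k in seq_len(n_sig)) {
      r <- par_idx[k, 1]; ss <- par_idx[k, 2]
      if (r == ss) {
        score[k] <- -0.5 * (Tr1[r, r] - Q1[r, r])
        V <- matrix(0, m, q)
        V[r, ] <- WA[r, ]
      } else {
        score[k] <- -0.5 * (2 * Tr1[r, ss] - 2 * Q1[r, ss])
        V <- matrix(0, m, q)
        V[r, ] <- WA[ss, ]
        V[ss, ] <- WA[r, ]
      }
      Fm[, k] <- Z %*% as.numeric(V)
    }
    score[n_sig + 1L] <- -0.5 * (trP - sum(ehat^2) / sigma_e2^2)
    Fm[, n_sig + 1L] <- ehat / sigma_e2
    # P f via the MME factorization
    WtF <- crossprod(X, Fm)
    WtF <- rbind(WtF, crossprod(Z, Fm)) / sigma_e2
    PF <- (Fm - cbind(X, Z) %*% (s$Cinv %*% WtF)) / sigma_e2
    AI <- 0.5 * crossprod(Fm, PF)
    step <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI)), n_sig + 1L),
                           score),
                     error = function(e) NULL)
    list(step = step, score = score)
  }

  th <- pack(Sigma, sigma_e2)
  ll_old <- -Inf; converged <- FALSE; n_solve <- 0L
  rel_change <- Inf
  s <- solve_mme(Sigma, sigma_e2); n_solve <- n_solve + 1L
  while (n_solve < maxit) {
    rel_change <- abs(s$loglik - ll_old) / (abs(ll_old) + 1e-10)
    if (is.finite(ll_old) && rel_change < tol) {
      converged <- TRUE
      break
    }
    ll_old <- s$loglik
    accepted <- FALSE
    ai <- ai_step(s, Sigma, sigma_e2)
    step <- ai$step
    if (!is.null(step) && all(is.finite(step))) {
      # damped AI-Newton with likelihood safeguard
      for (damp in c(1, 0.5, 0.1)) {
        pp <- unpack(th + damp * step)
        cand <- tryCatch(solve_mme(pp$Sigma, pp$sigma_e2),
                         error = function(e) NULL)
        n_solve <- n_solve + 1L
        if (!is.null(cand) && is.finite(cand$loglik) &&
            cand$loglik >= s$loglik - 1e-10 * abs(s$loglik)) {
          Sigma <- pp$Sigma; sigma_e2 <- pp$sigma_e2
          th <- pack(Sigma, sigma_e2)
          s <- cand
          accepted <- TRUE
          break
        }
        if (n_solve >= maxit) break
      }
    }
    if (!accepted && n_solve < maxit) {
      # SQUAREM-extrapolated EM fallback: two EM maps plus a safeguarded
      # extrapolation, so rejected AI steps still make real progress
      upd1 <- em_update(s)
      s1 <- solve_mme(upd1$Sigma, upd1$sigma_e2); n_solve <- n_solve + 1L
      upd2 <- em_update(s1)
      th0 <- pack(Sigma, sigma_e2)
      th1 <- pack(upd1$Sigma, upd1$sigma_e2)
      th2 <- pack(upd2$Sigma, upd2$sigma_e2)
      r_ <- th1 - th0
      v_ <- (th2 - th1) - r_
      nv <- sqrt(sum(v_^2))
      done <- FALSE
      if (nv > 0 && n_solve < maxit) {
        alpha <- max(1, sqrt(sum(r_^2)) / nv)
        pp <- unpack(th0 + 2 * alpha * r_ + alpha^2 * v_)
        cand <- tryCatch(solve_mme(pp$Sigma, pp$sigma_e2),
                         error = function(e) NULL)
        n_solve <- n_solve + 1L
        if (!is.null(cand) && is.finite(cand$loglik) &&
            cand$loglik >= s1$loglik) {
          Sigma <- pp$Sigma; sigma_e2 <- pp$sigma_e2
          s <- cand
          done <- TRUE
        }
      }
      if (!done) {
        pp <- unpack(th2)
        if (n_solve < maxit) {
          cand <- tryCatch(solve_mme(pp$Sigma, pp$sigma_e2),
                           error = function(e) NULL)
          n_solve <- n_solve + 1L
          if (!is.null(cand)) {
            Sigma <- pp$Sigma; sigma_e2 <- pp$sigma_e2
            s <- cand
          } else {
            Sigma <- upd1$Sigma; sigma_e2 <- upd1$sigma_e2
            s <- s1
          }
        } else {
          Sigma <- upd1$Sigma; sigma_e2 <- upd1$sigma_e2
          s <- s1
        }
      }
      th <- pack(Sigma, sigma_e2)
    }
  }
  if (!converged) warning("fit_reml did not converge in ", maxit,
                          " MME solves")
  out <- finish_reem_fit(s, Sigma, sigma_e2, design, converged,
                         n_solve, structure)
  out$rel_change <- rel_change
  out
}

determinant_pd <- function(S) {
  2 * sum(log(diag(chol(bend_pd(S)))))
}

finish_reem_fit <- function(s, Sigma, sigma_e2, design, converged, n_iter,
                            structure) {
  m <- design$K + 1L
  U <- matrix(s$u, nrow = design$q, ncol = m, byrow = TRUE,
              dimnames = list(design$ids, paste0("u", seq_len(m) - 1L)))
  dimnames(Sigma) <- list(paste0("u", seq_len(m) - 1L),
                          paste0("u", seq_len(m) - 1L))
  structure(list(b = stats::setNames(s$b, design$fixed_levels), u = U,
                 Sigma = Sigma, sigma_e2 = sigma_e2, loglik = s$loglik,
                 converged = converged, n_iter = n_iter,
                 structure = structure, K = design$K, ids = design$ids),
            class = "reem_fit")
}

#' @export
print.reem_fit <- function(x, ...) {
  cat("reem_fit: K =", x$K, "markers,", nrow(x$u), "genotypes; sigma_e2 =",
      signif(x$sigma_e2, 4), if (x$converged) "(converged)" else
        "(NOT converged)", "\n")
  invisible(x)
}

#' Predict genotype-by-bin surfaces from a fitted model
#'
#' `yhat(g, bin) = b_bar + u0_g + sum_k u_kg * eps_k(bin)` with `b_bar` set
#' by `year_policy` (default the mean of the fitted year intercepts — maps
#' are drawn for a "typical" year).
#'
#' @param fit a `reem_fit`.
#' @param bin_markers matrix bins x K of marker values on the training
#'   marker scale (rownames = bin ids); `NULL` when K = 0.
#' @param year_policy `"mean"` or a fixed-effect level name.
#' @param genotypes genotype ids to predict (default all in the fit).
#' @return matrix genotypes x bins of predicted yields.
#' @export
predict_bins <- function(fit, bin_markers = NULL, year_policy = "mean",
                         genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- rownames(fit$u)
  miss <- setdiff(genotypes, rownames(fit$u))
  if (length(miss) > 0) stop("unknown genotype(s): ",
                             paste(miss[1:3], collapse = ", "), call. = FALSE)
  b_bar <- if (identical(year_policy, "mean")) mean(fit$b) else {
    if (!year_policy %in% names(fit$b)) stop("unknown fixed level ",
                                             year_policy, call. = FALSE)
    fit$b[[year_policy]]
  }
  U <- fit$u[genotypes, , drop = FALSE]
  if (fit$K == 0 || is.null(bin_markers)) {
    out <- matrix(b_bar + U[, 1], length(genotypes), 1,
                  dimnames = list(genotypes, "all"))
    return(out)
  }
  stopifnot(ncol(bin_markers) == fit$K)
  out <- b_bar + U[, 1] +
    U[, -1, drop = FALSE] %*% t(bin_markers)
  dimnames(out) <- list(genotypes, rownames(bin_markers))
  out
}

#' Yield potential per bin (mean over genotypes)
#' @param predictions genotype x bin matrix.
#' @return named numeric per-bin mean.
#' @export
yield_potential <- function(predictions) colMeans(predictions)

#' Reaction-norm ensemble: many model runs over sampled marker predictors
#'
#' Each run draws one tree predictor per marker cluster, standardizes the K
#' regressors with the reference-grid constants, refits the reaction-norm
#' model by REML, and predicts every genotype (including unphenotyped
#' parents) at every grid bin. Predictions are averaged over runs; the
#' run-to-run spread gives a standard error per (genotype, bin), and the
#' slope draws across runs and markers feed the stability angles. Runs whose
#' REML fit fails or does not converge are dropped (an error is raised if
#' more than `max_drop_fraction` are lost).
#'
#' @param phenotypes a `phenotype_table`.
#' @param bank the `tree_bank`.
#' @param eem_set the `eem_set` built on the prediction grid.
#' @param kinship a `kinship_matrix` over all genotypes to predict.
#' @param trial_covariates,bin_covariates covariate tables at trials / bins.
#' @param n_runs number of ensemble runs (study default 1000).
#' @param seed integer seed.
#' @param structure,tol,maxit passed to [fit_reml()] (warm-started between
#'   runs).
#' @param one_marker_per_run if `TRUE`, each run uses a single sampled
#'   marker (K = 1 per run) instead of one predictor per cluster.
#' @param max_drop_fraction run-drop tolerance.
#' @return object of class `ensemble_prediction`: `mean` and `se`
#'   (genotype x bin), `slope_draws` (draws x genotype matrix of
#'   standardized-scale slopes), `Sigma_pooled`, `sigma_e2_pooled`,
#'   `run_log`, `n_runs_used`, `b_mean`.
#' @export
ensemble_reem <- function(phenotypes, bank, eem_set, kinship,
                          trial_covariates, bin_covariates, n_runs = 50,
                          seed = 1, structure = "auto", tol = 1e-6,
                          maxit = 600, one_marker_per_run = FALSE,
                          max_drop_fraction = 0.2) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  ids <- kinship$ids
  clusters <- seq_len(eem_set$K)
  members <- lapply(clusters, function(k)
    which(eem_set$cluster_of_tree == k))
  bins <- bin_covariates$location_id
  q <- length(ids)
  mean_acc <- matrix(0, q, length(bins), dimnames = list(ids, bins))
  m2_acc <- mean_acc
  slope_draws <- list()
  Sigma_sum <- NULL; se2_sum <- 0; b_sum <- NULL
  run_log <- data.frame(run = integer(0), converged = logical(0),
                        n_iter = integer(0), loglik = numeric(0),
                        sigma_e2 = numeric(0))
  used <- 0L
  warm <- NULL
  for (r in seq_len(n_runs)) {
    trees <- vapply(members, function(ix) ix[sample.int(length(ix), 1)],
                    integer(1))
    if (one_marker_per_run) trees <- trees[sample.int(length(trees), 1)]
    Mt <- tree_values_at(eem_set, bank, trial_covariates, trees)
    Mb <- tree_values_at(eem_set, bank, bin_covariates, trees)
    colnames(Mt) <- colnames(Mb) <- paste0("eem", seq_along(trees))
    fit <- tryCatch({
      design <- assemble_design(phenotypes, Mt, ids = ids, fixed = "year")
      suppressWarnings(fit_reml(design, kinship, structure = structure,
                                init = warm, tol = tol, maxit = maxit))
    }, error = function(e) NULL)
    # a run is usable if REML reached the tolerance, or stopped at the
    # iteration cap with the likelihood essentially flat
    ok <- !is.null(fit) &&
      (fit$converged || isTRUE(fit$rel_change < 1e-3))
    run_log <- rbind(run_log, data.frame(
      run = r, converged = ok,
      n_iter = if (is.null(fit)) NA_integer_ else fit$n_iter,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      sigma_e2 = if (is.null(fit)) NA_real_ else fit$sigma_e2))
    if (!ok) next
    warm <- list(Sigma = fit$Sigma, sigma_e2 = fit$sigma_e2)
    used <- used + 1L
    pred <- predict_bins(fit, Mb)
    delta <- pred - mean_acc
    mean_acc <- mean_acc + delta / used
    m2_acc <- m2_acc + delta * (pred - mean_acc)
    slope_draws[[used]] <- t(fit$u[, -1, drop = FALSE])  # markers x genotypes
    Sigma_sum <- if (is.null(Sigma_sum)) fit$Sigma else Sigma_sum + fit$Sigma
    se2_sum <- se2_sum + fit$sigma_e2
    b_sum <- if (is.null(b_sum)) fit$b else b_sum + fit$b
  }
  if (used < (1 - max_drop_fraction) * n_runs) {
    stop("more than ", 100 * max_drop_fraction,
         "% of ensemble runs failed (", n_runs - used, " of ", n_runs, ")",
         call. = FALSE)
  }
  se <- if (used > 1) sqrt(m2_acc / (used - 1)) / sqrt(used) else m2_acc * 0
  draws <- do.call(rbind, slope_draws)
  structure(list(mean = mean_acc, se = se, slope_draws = draws,
                 Sigma_pooled = Sigma_sum / used,
                 sigma_e2_pooled = se2_sum / used,
                 b_mean = b_sum / used, run_log = run_log,
                 n_runs_used = used, ids = ids),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat("ensemble_prediction:", x$n_runs_used, "runs,", nrow(x$mean),
      "genotypes x", ncol(x$mean), "bins\n")
  invisible(x)
}

#' Adaptability/stability angles from reaction-norm slopes
#'
#' Transforms slopes (standardized yield per standardized gradient unit)
#' into angular degrees, `atan(slope) * 180 / pi` in (-90, 90): near 0
#' degrees = stable, near 45 = strongly responsive; negative angles mean
#' yield falls along a rising gradient. The summary mirrors the min / max /
#' mean columns of the study's genotype table, taken over all sampled
#' markers across runs.
#'
#' @param slope_draws numeric matrix draws x genotypes (e.g.
#'   `ensemble$slope_draws`) or a vector of slopes.
#' @return for a matrix: list with `angles` (same shape) and `summary`
#'   (data.frame genotype_id, angle_min, angle_max, angle_mean); for a
#'   vector: the angles.
#' @export
stability_angles <- function(slope_draws) {
  ang <- atan(slope_draws) * 180 / pi
  if (is.null(dim(ang))) return(ang)
  summary <- data.frame(genotype_id = colnames(ang),
                        angle_min = apply(ang, 2, min),
                        angle_max = apply(ang, 2, max),
                        angle_mean = colMeans(ang),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(angles = ang, summary = summary)
}
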