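# Comparator models: a covariate-free baseline G x E model and an
# environmental-kernel model built on the same engineered markers as the
# random-regression model.

#' Baseline G x E model (no environmental covariates)
#'
#' `y = irrigation (fixed) + genotype (random, A sigma_g^2) + e`. With
#' trial-level BLUEs there is one record per (trial, genotype), so the iid
#' trial-by-genotype interaction is statistically confounded with the
#' residual and is absorbed there. Prediction for a new trial is the
#' irrigation effect plus the genotype main-effect BLUP, hence constant
#' across trials under the same irrigation level.
#'
#' @param phenotypes a `phenotype_table`.
#' @param kinship a `kinship_matrix`.
#' @param ... passed to [fit_reml()].
#' @return a `reem_fit` with K = 0 (class also `baseline_fit`).
#' @export
baseline_gxe_fit <- function(phenotypes, kinship, ...) {
  design <- assemble_design(phenotypes, NULL, ids = kinship$ids,
                            fixed = "irrigated")
  fit <- fit_reml(design, kinship, ...)
  class(fit) <- c("baseline_fit", class(fit))
  fit
}

#' Predict new records from a baseline fit
#'
#' @param fit a `baseline_fit`.
#' @param genotype_id character vector.
#' @param irrigated logical vector (recycled).
#' @return numeric predictions.
#' @export
predict_baseline <- function(fit, genotype_id, irrigated = FALSE) {
  lev <- paste0("irrigated", irrigated)
  b <- if (all(lev %in% names(fit$b))) fit$b[lev] else rep(mean(fit$b),
                                                           length(lev))
  unname(b + fit$u[genotype_id, 1])
}

#' Linear environment kernel from standardized marker vectors
#'
#' `K_E = E E' / mean(diag(E E'))` over trials (unit mean diagonal), the
#' standard scaling for reaction-norm environmental kernels.
#'
#' @param trial_markers matrix trials x K, rownames = trial ids.
#' @return list with `K` (trials x trials) and `scale` (the diagonal mean
#'   divisor, needed for cross-covariances to new locations).
#' @export
environment_kernel <- function(trial_markers) {
  G <- tcrossprod(as.matrix(trial_markers))
  sc <- mean(diag(G))
  if (sc <= 0) sc <- 1
  list(K = G / sc, scale = sc)
}

#' Generic dense REML for variance components on covariance kernels
#'
#' `y = Xb + sum_k z_k + e`, `z_k ~ N(0, sigma_k^2 K_k)`. EM updates
#' `sigma_k^2 <- sigma_k^2 + sigma_k^4 (y'P K_k P y - tr(P K_k)) / n` with
#' `P` the REML projection matrix; suitable for the record counts this
#' package works at (n up to a few thousand).
#'
#' @param y response vector.
#' @param X fixed design matrix.
#' @param kernels named list of n x n PSD matrices.
#' @param fixed_varcomp optional named numeric (components + `"residual"`)
#'   to hold fixed.
#' @param tol,maxit EM convergence controls.
#' @return list: `varcomp` (named, incl. residual), `b`, `Vinv`, `resid`
#'   (`y - Xb`), `loglik`, `converged`, `n_iter`.
#' @export
fit_kernel_reml <- function(y, X, kernels, fixed_varcomp = NULL, tol = 1e-6,
                            maxit = 200) {
  n <- length(y)
  p <- ncol(X)
  nk <- length(kernels)
  vy <- stats::var(y)
  vc <- c(rep(vy / (nk + 1), nk), vy / (nk + 1))
  names(vc) <- c(names(kernels), "residual")
  est <- is.null(fixed_varcomp)
  if (!est) vc <- fixed_varcomp[names(vc)]
  ll_old <- -Inf; converged <- !est; it <- 0L
  repeat {
    it <- it + 1L
    V <- diag(vc[["residual"]], n)
    for (k in seq_len(nk)) V <- V + vc[[k]] * kernels[[k]]
    cV <- chol(V)
    Vinv <- chol2inv(cV)
    XtVinv <- crossprod(X, Vinv)
    XtVinvX <- XtVinv %*% X
    cXVX <- chol(XtVinvX)
    b <- drop(chol2inv(cXVX) %*% (XtVinv %*% y))
    P <- Vinv - t(XtVinv) %*% chol2inv(cXVX) %*% XtVinv
    Py <- drop(P %*% y)
    loglik <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cXVX))) +
                        sum(y * Py))
    if (!est) break
    if (is.finite(ll_old) &&
        abs(loglik - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- loglik
    for (k in seq_len(nk)) {
      Kk <- kernels[[k]]
      KPy <- drop(Kk %*% Py)
      upd <- vc[[k]] + vc[[k]]^2 * (sum(Py * KPy) - sum(P * Kk)) / n
      vc[[k]] <- max(upd, 1e-8 * vy)
    }
    upd <- vc[["residual"]] + vc[["residual"]]^2 *
      (sum(Py * Py) - sum(diag(P))) / n
    vc[["residual"]] <- max(upd, 1e-8 * vy)
    if (it >= maxit) break
  }
  if (!converged) warning("fit_kernel_reml did not converge in ", maxit,
                          " iterations")
  list(varcomp = vc, b = b, Vinv = Vinv, resid = y - drop(X %*% b),
       loglik = loglik, converged = converged, n_iter = it)
}

#' Environmental-kernel G x E model on the engineered markers
#'
#' Record-level covariance built from three terms: genotype main effect
#' (pedigree A), environment main effect (linear kernel of the standardized
#' marker vectors, unit mean diagonal) and their interaction (elementwise
#' product), following the reaction-norm kernel tradition. Fit by
#' [fit_kernel_reml()].
#'
#' @param phenotypes a `phenotype_table`.
#' @param trial_markers matrix trials x K of marker values at trials.
#' @param kinship a `kinship_matrix`.
#' @param terms subset of `c("genotype", "environment", "interaction")`.
#' @param fixed_varcomp optional named numeric to hold variances fixed.
#' @param ... passed to [fit_kernel_reml()].
#' @return object of class `kernel_fit` carrying the fit and everything
#'   needed for cross-covariance prediction at new locations.
#' @export
kernel_gxe_fit <- function(phenotypes, trial_markers, kinship,
                           terms = c("genotype", "environment",
                                     "interaction"),
                           fixed_varcomp = NULL, ...) {
  terms <- match.arg(terms, several.ok = TRUE)
  A <- kinship$A
  gi <- match(phenotypes$genotype_id, kinship$ids)
  ti <- match(phenotypes$trial_id, rownames(trial_markers))
  if (anyNA(ti)) stop("trial(s) missing from the marker table", call. = FALSE)
  ek <- environment_kernel(trial_markers)
  KG <- A[gi, gi]
  KE <- ek$K[ti, ti]
  kernels <- list()
  if ("genotype" %in% terms) kernels$genotype <- KG
  if ("environment" %in% terms) kernels$environment <- KE
  if ("interaction" %in% terms) kernels$interaction <- KG * KE
  ev <- eigen((kernels[[length(kernels)]] +
                 t(kernels[[length(kernels)]])) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev))) {
    stop("non-PSD kernel after scaling", call. = FALSE)
  }
  X <- matrix(1, nrow(phenotypes), 1, dimnames = list(NULL, "intercept"))
  fit <- fit_kernel_reml(phenotypes$yield_blue, X, kernels,
                         fixed_varcomp = fixed_varcomp, ...)
  structure(list(fit = fit, terms = names(kernels), kinship = kinship,
                 trial_markers = as.matrix(trial_markers),
                 kernel_scale = ek$scale,
                 train_genotype = phenotypes$genotype_id,
                 train_trial = phenotypes$trial_id),
            class = "kernel_fit")
}

#' Predict new (genotype, location) records from a kernel fit
#'
#' Uses the kernel cross-covariances between new records and the training
#' records: `yhat = b0 + c*' V^{-1} (y - X b)`.
#'
#' @param object a `kernel_fit`.
#' @param genotype_id character vector of genotypes for the new records.
#' @param new_markers matrix (records x K) of marker values at the new
#'   records' locations (rows recycled if a single location).
#' @return numeric predictions.
#' @export
predict_kernel <- function(object, genotype_id, new_markers) {
  new_markers <- matrix(new_markers, ncol = ncol(object$trial_markers))
  if (nrow(new_markers) == 1 && length(genotype_id) > 1) {
    new_markers <- new_markers[rep(1, length(genotype_id)), , drop = FALSE]
  }
  A <- object$kinship$A
  gi_new <- match(genotype_id, object$kinship$ids)
  gi_tr <- match(object$train_genotype, object$kinship$ids)
  ti_tr <- match(object$train_trial, rownames(object$trial_markers))
  CG <- A[gi_new, gi_tr, drop = FALSE]
  CE <- (new_markers %*% t(object$trial_markers[ti_tr, , drop = FALSE])) /
    object$kernel_scale
  vc <- object$fit$varcomp
  Cstar <- matrix(0, length(genotype_id), length(gi_tr))
  if ("genotype" %in% object$terms) Cstar <- Cstar + vc[["genotype"]] * CG
  if ("environment" %in% object$terms) {
    Cstar <- Cstar + vc[["environment"]] * CE
  }
  if ("interaction" %in% object$terms) {
    Cstar <- Cstar + vc[["interaction"]] * (CG * CE)
  }
  drop(object$fit$b[1] + Cstar %*% (object$fit$Vinv %*% object$fit$resid))
}
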