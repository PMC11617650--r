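# Breeding zones: per-bin genetic variances and bin-to-bin genetic
# correlations implied by Sigma and the marker surfaces, Ward clustering of
# bins into zones, and zone summaries.

#' Genetic variance/correlation structure over the prediction grid
#'
#' With `z(bin) = (1, eps_1..eps_K)'` and coefficient covariance `Sigma`,
#' the additive genetic variance at a bin is `z' Sigma z` and the genetic
#' covariance between bins i and j is `z_i' Sigma z_j`. The full bin-by-bin
#' matrix is never materialized: the object stores `M = Z sqrt(Sigma)` so
#' any covariance is an O(K) dot product evaluated lazily.
#'
#' @param Sigma (K+1)-square PSD coefficient covariance (e.g. the pooled
#'   ensemble estimate).
#' @param bin_markers matrix bins x K of marker values (rownames bin ids).
#' @return object of class `genetic_surface`: `variance` (named), `M`,
#'   `bin_ids`.
#' @export
genetic_surface <- function(Sigma, bin_markers) {
  Z <- cbind(1, as.matrix(bin_markers))
  stopifnot(ncol(Z) == nrow(Sigma))
  M <- Z %*% mat_sqrt(Sigma)
  v <- rowSums(M * M)
  ids <- rownames(bin_markers)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Z)))
  structure(list(variance = stats::setNames(v, ids), M = M, bin_ids = ids),
            class = "genetic_surface")
}

#' Genetic correlation between bins
#'
#' @param surface a `genetic_surface`.
#' @param i,j bin ids or indices (vectorized, recycled).
#' @return numeric correlations in [-1, 1]; `NA` where a bin has zero
#'   genetic variance.
#' @export
gen_correlation <- function(surface, i, j) {
  ii <- if (is.character(i)) match(i, surface$bin_ids) else i
  jj <- if (is.character(j)) match(j, surface$bin_ids) else j
  num <- rowSums(surface$M[ii, , drop = FALSE] *
                   surface$M[jj, , drop = FALSE])
  den <- sqrt(surface$variance[ii] * surface$variance[jj])
  out <- ifelse(den > 0, num / den, NA_real_)
  unname(pmin(1, pmax(-1, out)))
}

#' Genetic correlation matrix for a subset of bins
#' @param surface a `genetic_surface`.
#' @param bins bin ids or indices.
#' @return square correlation matrix (NA rows for zero-variance bins).
#' @export
gen_correlation_matrix <- function(surface, bins) {
  ii <- if (is.character(bins)) match(bins, surface$bin_ids) else bins
  Ms <- surface$M[ii, , drop = FALSE]
  C <- tcrossprod(Ms)
  v <- surface$variance[ii]
  den <- sqrt(outer(v, v))
  R <- ifelse(den > 0, C / den, NA_real_)
  R <- pmin(pmax(R, -1), 1)
  dimnames(R) <- list(surface$bin_ids[ii], surface$bin_ids[ii])
  R
}

#' Delineate breeding zones by Ward clustering of genetic correlations
#'
#' Ward agglomeration (`ward.D2`) on the distance `d = sqrt(2 (1 - r))`
#' over a subsample of bins (the full bin-by-bin matrix is quadratic), with
#' the remaining bins assigned to the nearest zone centroid in marker space.
#' Zone labels are ordered by descending zone-mean yield potential, so zone
#' 1 is the most productive.
#'
#' @param surface a `genetic_surface`.
#' @param bin_markers matrix bins x K (the same used for the surface).
#' @param n_zones number of zones (study default 4).
#' @param yield_potential named per-bin mean predicted yield, used only to
#'   order the zone labels (optional).
#' @param subsample max bins entering the Ward step (default 2000).
#' @param seed integer seed for the subsample.
#' @return object of class `zone_map`: `zone_of_bin` (named integer),
#'   `n_zones`, `centroids`, `subsample_ids`.
#' @export
ward_zones <- function(surface, bin_markers, n_zones = 4,
                       yield_potential = NULL, subsample = 2000, seed = 1) {
  stopifnot(n_zones >= 2)
  ids <- surface$bin_ids
  ord <- order(ids)  # selection by sorted id: invariant to input row order
  set.seed(seed)
  sub <- if (length(ids) > subsample) {
    sort(sample(ord, subsample))
  } else ord
  sub_ids <- ids[sub]
  E <- as.matrix(bin_markers)[sub, , drop = FALSE]
  if (nrow(unique(round(E, 10))) < n_zones) {
    stop("fewer distinct marker profiles than zones", call. = FALSE)
  }
  R <- gen_correlation_matrix(surface, sub)
  R[!is.finite(R)] <- 0
  d <- stats::as.dist(sqrt(pmax(2 * (1 - R), 0)))
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = n_zones)
  centroids <- t(vapply(seq_len(n_zones), function(z) {
    colMeans(E[cl == z, , drop = FALSE])
  }, numeric(ncol(E))))
  zone <- integer(length(ids))
  zone[sub] <- cl
  rest <- setdiff(seq_along(ids), sub)
  if (length(rest) > 0) {
    Er <- as.matrix(bin_markers)[rest, , drop = FALSE]
    d2 <- outer(rowSums(Er^2), rowSums(centroids^2), "+") -
      2 * Er %*% t(centroids)
    zone[rest] <- apply(d2, 1, which.min)
  }
  # relabel by descending mean yield potential
  if (!is.null(yield_potential)) {
    zm <- vapply(seq_len(n_zones), function(z) {
      mean(yield_potential[ids[zone == z]])
    }, numeric(1))
    relabel <- match(seq_len(n_zones), order(zm, decreasing = TRUE))
    zone <- relabel[zone]
    centroids <- centroids[order(zm, decreasing = TRUE), , drop = FALSE]
  }
  structure(list(zone_of_bin = stats::setNames(zone, ids),
                 n_zones = n_zones, centroids = centroids,
                 subsample_ids = sub_ids),
            class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("zone_map:", x$n_zones, "zones over", length(x$zone_of_bin), "bins (",
      paste(tabulate(x$zone_of_bin, x$n_zones), collapse = "/"), ")\n")
  invisible(x)
}

#' Summarize breeding zones
#'
#' Per zone: bin count, trial count, top-1 selection gain, and the
#' within/between-zone mean genetic correlations (computed on the Ward
#' subsample). On the standardized yield scale the gain is reported as an
#' absolute difference (`gain_type = "absolute"`); a percentage of a
#' near-zero standardized mean would be meaningless. With predictions on an
#' original positive scale, `scale = "original"` reports
#' `100 * (top1 - mean) / |mean|`.
#'
#' @param zones a `zone_map`.
#' @param predictions genotype x bin prediction matrix (columns = bins).
#' @param surface the `genetic_surface`.
#' @param trial_bin_ids character vector: the grid bin of each trial.
#' @param scale `"standardized"` (absolute gain) or `"original"` (% gain).
#' @return list with `zone_table` (data.frame) and `correlation`
#'   (n_zones-square within/between mean correlation matrix).
#' @export
zone_summary <- function(zones, predictions, surface,
                         trial_bin_ids = character(0),
                         scale = c("standardized", "original")) {
  scale <- match.arg(scale)
  ids <- names(zones$zone_of_bin)
  z <- zones$zone_of_bin
  top1 <- apply(predictions, 2, max)
  allm <- colMeans(predictions)
  sub <- zones$subsample_ids
  Rsub <- gen_correlation_matrix(surface, sub)
  zsub <- z[sub]
  corr <- matrix(NA_real_, zones$n_zones, zones$n_zones)
  for (a in seq_len(zones$n_zones)) {
    for (b in a:zones$n_zones) {
      block <- Rsub[zsub == a, zsub == b, drop = FALSE]
      if (a == b) {
        vals <- block[upper.tri(block)]
        corr[a, a] <- if (length(vals) > 0) mean(vals, na.rm = TRUE) else 1
      } else {
        corr[a, b] <- corr[b, a] <- mean(block, na.rm = TRUE)
      }
    }
  }
  rows <- lapply(seq_len(zones$n_zones), function(zz) {
    zb <- ids[z == zz]
    mt <- mean(top1[zb]); ma <- mean(allm[zb])
    gain <- if (scale == "original") 100 * (mt - ma) / abs(ma) else mt - ma
    data.frame(zone = zz, bin_count = length(zb),
               trial_count = sum(trial_bin_ids %in% zb),
               mean_potential = ma, top1_gain = gain,
               gain_type = if (scale == "original") "percent" else
                 "absolute",
               within_correlation = corr[zz, zz], stringsAsFactors = FALSE)
  })
  list(zone_table = do.call(rbind, rows), correlation = corr)
}

#' Genetic variance along the wide environmental gradient
#'
#' Pairs each bin's additive genetic variance with its wide-gradient value
#' and adds a local-regression trend for plotting. `span = Inf` returns the
#' global mean as the trend.
#'
#' @param surface a `genetic_surface`.
#' @param wide_gradient named per-bin wide-gradient values.
#' @param span lowess smoother span (fraction of points).
#' @return data.frame `bin_id, gradient, variance, trend` sorted by
#'   gradient.
#' @export
variance_gradient_profile <- function(surface, wide_gradient, span = 2 / 3) {
  g <- wide_gradient[surface$bin_ids]
  v <- surface$variance
  ord <- order(g)
  trend <- if (is.infinite(span)) rep(mean(v), length(v)) else
    stats::lowess(g[ord], v[ord], f = span)$y
  data.frame(bin_id = surface$bin_ids[ord], gradient = unname(g[ord]),
             variance = unname(v[ord]), trend = trend,
             stringsAsFactors = FALSE, row.names = NULL)
}
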