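# Per-bin genotype recommendation: statistical ties around the best
# genotype, geographic representativeness (distance to the nearest trial of
# each tied genotype), occupation summaries, and parental-line picks.

#' Genotypes statistically tied with the best at one bin
#'
#' Two-sided t-test of the difference between the best mean and each other
#' genotype's mean, with SE `sqrt(se_best^2 + se_g^2)` from the ensemble run
#' distribution; a genotype is tied iff p > alpha. The best genotype is
#' always tied with itself.
#'
#' @param means,ses named numeric vectors over genotypes at one bin.
#' @param alpha significance level (default 0.05).
#' @param df t degrees of freedom (effective ensemble runs - 1).
#' @return character vector of tied genotype ids (always includes the best).
#' @export
statistical_ties <- function(means, ses, alpha = 0.05, df = Inf) {
  stopifnot(length(df) == 1, df > 0)
  best <- which.max(means)
  delta <- means[best] - means
  sed <- sqrt(ses[best]^2 + ses^2)
  pval <- ifelse(sed > 0, 2 * stats::pt(-delta / sed, df = df),
                 ifelse(delta == 0, 1, 0))
  names(means)[pval > alpha | seq_along(means) == best]
}

#' Pick the winner among tied genotypes by geographic representativeness
#'
#' The winner is the tied genotype whose nearest trial (planar km) is
#' closest to the bin centroid; ties are broken by higher predicted mean,
#' then lexicographic id.
#'
#' @param tied character vector of tied genotype ids.
#' @param distances named numeric: distance (km) from the bin to each
#'   genotype's nearest trial.
#' @param means named numeric predicted means at the bin.
#' @return the winning genotype id.
#' @export
representativeness_select <- function(tied, distances, means) {
  d <- distances[tied]
  m <- means[tied]
  ord <- order(d, -m, tied)
  tied[ord[1]]
}

#' Per-bin genotype recommendation over the whole grid
#'
#' Two-step rule per bin: (1) find the genotypes statistically tied with
#' the top-ranked one; (2) among those, pick the genotype with the highest
#' geographic representativeness (minimum distance to one of its own
#' trials). Genotypes never trialed cannot win and are excluded up front.
#'
#' @param ensemble an `ensemble_prediction` (or any list with `mean`, `se`
#'   genotype x bin matrices and `n_runs_used`).
#' @param grid the `prediction_grid`.
#' @param phenotypes the `phenotype_table` (provides trial locations per
#'   genotype).
#' @param alpha tie significance level.
#' @param df t degrees of freedom (default `n_runs_used - 1`).
#' @param genotypes candidate genotype ids (default: all phenotyped ones).
#' @return object of class `recommendation_map`: data.frame `winners`
#'   (bin_id, winner, n_tied, distance_km) plus the distance matrix.
#' @export
recommend_genotypes <- function(ensemble, grid, phenotypes, alpha = 0.05,
                                df = NULL, genotypes = NULL) {
  if (is.null(df)) df <- max(1, ensemble$n_runs_used - 1)
  trialed <- unique(phenotypes$genotype_id)
  if (is.null(genotypes)) genotypes <- trialed
  dropped <- setdiff(genotypes, trialed)
  if (length(dropped) > 0) {
    message("excluding ", length(dropped),
            " never-trialed genotype(s) from winning")
    genotypes <- intersect(genotypes, trialed)
  }
  genotypes <- sort(intersect(genotypes, rownames(ensemble$mean)))
  stopifnot(length(genotypes) > 0)
  bins <- grid$bins
  # min distance from every bin centroid to each genotype's trials
  trials <- unique(phenotypes[, c("trial_id", "lat", "lon")])
  txy <- project_local_km(trials$lat, trials$lon, grid$origin)
  D <- matrix(Inf, length(genotypes), nrow(bins),
              dimnames = list(genotypes, bins$bin_id))
  for (gi in seq_along(genotypes)) {
    tg <- unique(phenotypes$trial_id[phenotypes$genotype_id ==
                                       genotypes[gi]])
    rows <- match(tg, trials$trial_id)
    d2 <- outer(bins$x_km, txy[rows, 1], "-")^2 +
      outer(bins$y_km, txy[rows, 2], "-")^2
    D[gi, ] <- sqrt(apply(d2, 1, min))
  }
  M <- ensemble$mean[genotypes, , drop = FALSE]
  S <- ensemble$se[genotypes, , drop = FALSE]
  winners <- data.frame(bin_id = bins$bin_id, winner = NA_character_,
                        n_tied = NA_integer_, distance_km = NA_real_,
                        stringsAsFactors = FALSE)
  for (b in seq_len(nrow(bins))) {
    mb <- stats::setNames(M[, b], genotypes)
    sb <- stats::setNames(S[, b], genotypes)
    db <- stats::setNames(D[, b], genotypes)
    tied <- statistical_ties(mb, sb, alpha = alpha, df = df)
    w <- representativeness_select(tied, db, mb)
    winners$winner[b] <- w
    winners$n_tied[b] <- length(tied)
    winners$distance_km[b] <- D[w, b]
  }
  structure(list(winners = winners, distances = D, alpha = alpha, df = df),
            class = "recommendation_map")
}

#' @export
print.recommendation_map <- function(x, ...) {
  tab <- sort(table(x$winners$winner), decreasing = TRUE)
  cat("recommendation_map:", nrow(x$winners), "bins;",
      length(tab), "winning genotypes (top:", names(tab)[1],
      sprintf("%.1f%%)", 100 * tab[1] / nrow(x$winners)), "\n")
  invisible(x)
}

#' Area-occupation summary per winning genotype
#'
#' Mirrors the study's genotype table: per winner, the number (and %) of
#' bins won, the number of distinct trial bins in which the genotype was
#' measured, the measured years, and (when supplied) the stability-angle
#' summary.
#'
#' @param recommendation a `recommendation_map`.
#' @param phenotypes the `phenotype_table`.
#' @param grid the `prediction_grid`.
#' @param stability optional stability summary data.frame from
#'   [stability_angles()] (joined by genotype_id).
#' @return data.frame sorted by bins won (descending).
#' @export
occupation_summary <- function(recommendation, phenotypes, grid,
                               stability = NULL) {
  w <- recommendation$winners
  n_bins <- nrow(w)
  tab <- sort(table(w$winner), decreasing = TRUE)
  trials <- unique(phenotypes[, c("trial_id", "lat", "lon")])
  trials$bin_id <- nearest_bin(grid, trials$lat, trials$lon)
  phen_bin <- trials$bin_id[match(phenotypes$trial_id, trials$trial_id)]
  rows <- lapply(names(tab), function(g) {
    sel <- phenotypes$genotype_id == g
    data.frame(genotype_id = g, bins_won = as.integer(tab[[g]]),
               pct_area = 100 * tab[[g]] / n_bins,
               trial_bins = length(unique(phen_bin[sel])),
               measured_years = paste(sort(unique(phenotypes$year[sel])),
                                      collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(stability)) {
    out <- merge(out, stability, by = "genotype_id", all.x = TRUE,
                 sort = FALSE)
    out <- out[order(-out$bins_won), ]
    rownames(out) <- NULL
  }
  out
}

#' Parental-line recommendation maps and suggested crosses
#'
#' Parents are typically unphenotyped; their coefficient BLUPs propagate
#' through the pedigree relationship matrix, so their predicted surfaces
#' come from the same ensemble prediction matrix. Per bin the top two
#' parents are reported with the suggested cross top1 x top2; the cross's
#' expected additive value is the mid-parent mean (dominance/heterosis is
#' deliberately not modeled).
#'
#' @param ensemble an `ensemble_prediction` whose `mean` matrix includes the
#'   parent rows.
#' @param parents character vector of parental line ids.
#' @return data.frame `bin_id, top1, top2, cross, cross_value`.
#' @export
parental_recommendation <- function(ensemble, parents) {
  parents <- intersect(parents, rownames(ensemble$mean))
  if (length(parents) == 0) stop("no parents in the prediction set",
                                 call. = FALSE)
  P <- ensemble$mean[parents, , drop = FALSE]
  top <- apply(P, 2, function(v) order(v, decreasing = TRUE)[1:2])
  top1 <- parents[top[1, ]]
  top2 <- if (length(parents) > 1) parents[top[2, ]] else NA_character_
  cross <- ifelse(is.na(top2) | top1 == top2, NA_character_,
                  paste(top1, top2, sep = " x "))
  cv <- vapply(seq_len(ncol(P)), function(b) {
    if (is.na(top2[b])) NA_real_ else (P[top1[b], b] + P[top2[b], b]) / 2
  }, numeric(1))
  data.frame(bin_id = colnames(P), top1 = top1, top2 = top2, cross = cross,
             cross_value = cv, stringsAsFactors = FALSE, row.names = NULL)
}
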