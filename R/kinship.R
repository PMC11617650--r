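# Additive (numerator) relationship matrix from pedigree records.

#' Additive relationship matrix by the tabular method
#'
#' Computes Wright's numerator relationship matrix A from a pedigree using
#' the recursive tabular method after an internal topological sort:
#' `a(i,j) = 0.5 * (a(j, dam_i) + a(j, sire_i))` for j processed before i and
#' `a(i,i) = 1 + 0.5 * a(dam_i, sire_i)`; unknown parents contribute 0.
#' Genotypes with both parents unknown (founders and competitor hybrids) are
#' treated as unrelated and non-inbred (diagonal 1).
#'
#' @param pedigree a `pedigree` data.frame (see [read_pedigree()]).
#' @return an object of class `kinship_matrix`: list with `ids` (character)
#'   and `A` (symmetric numeric matrix with those dimnames).
#' @export
additive_relationship <- function(pedigree) {
  ped <- validate_pedigree(as.data.frame(pedigree))
  ids <- ped$genotype_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  dam <- ifelse(ped$dam_id == UNKNOWN_PARENT, NA_integer_, idx[ped$dam_id])
  sire <- ifelse(ped$sire_id == UNKNOWN_PARENT, NA_integer_, idx[ped$sire_id])

  # Kahn topological sort (parents before offspring); detects cycles.
  n_par <- (!is.na(dam)) + (!is.na(sire))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam[i], sire[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  order <- integer(0)
  queue <- which(n_par == 0)
  remaining <- n_par
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- ids[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(cyc, 5), collapse = ", "), call. = FALSE)
  }

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  done <- integer(0)
  for (i in order) {
    di <- dam[i]; si <- sire[i]
    if (length(done) > 0) {
      a_dam <- if (is.na(di)) 0 else A[done, di]
      a_sire <- if (is.na(si)) 0 else A[done, si]
      aij <- 0.5 * (a_dam + a_sire)
      A[done, i] <- aij
      A[i, done] <- aij
    }
    f <- if (is.na(di) || is.na(si)) 0 else 0.5 * A[di, si]
    A[i, i] <- 1 + f
    done <- c(done, i)
  }
  structure(list(ids = ids, A = A), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", length(x$ids), "genotypes, mean diagonal",
      round(mean(diag(x$A)), 4), "\n")
  invisible(x)
}

#' Repair near-PSD symmetric matrices by minimal diagonal jitter
#'
#' Numerical safeguard before Cholesky-based solves. If the smallest
#' eigenvalue is below `-tolerance` the matrix is treated as structurally
#' indefinite and an error is raised; otherwise the smallest power-of-ten
#' diagonal jitter that lets `chol()` succeed is added (and reported).
#'
#' @param A symmetric numeric matrix, or a `kinship_matrix`.
#' @param tolerance negative-eigenvalue tolerance (default 1e-8, scaled by
#'   the largest absolute eigenvalue).
#' @return same type as the input, with the (possibly jittered) matrix and an
#'   attribute `jitter` recording the amount added.
#' @export
psd_repair <- function(A, tolerance = 1e-8) {
  is_kin <- inherits(A, "kinship_matrix")
  M <- if (is_kin) A$A else A
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    stop("matrix is not symmetric", call. = FALSE)
  }
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -tolerance * scale) {
    stop("matrix is structurally indefinite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  jitter <- 0
  ok <- !inherits(try(chol(M), silent = TRUE), "try-error")
  while (!ok) {
    jitter <- if (jitter == 0) 1e-12 * scale else jitter * 10
    if (jitter > 1e-2 * scale) {
      stop("could not repair matrix within jitter budget", call. = FALSE)
    }
    ok <- !inherits(try(chol(M + diag(jitter, nrow(M))), silent = TRUE),
                    "try-error")
  }
  if (jitter > 0) {
    M <- M + diag(jitter, nrow(M))
    message("psd_repair: added diagonal jitter ", format(jitter))
  }
  out <- if (is_kin) structure(list(ids = A$ids, A = M), class = "kinship_matrix") else M
  attr(out, "jitter") <- jitter
  out
}

#' Write a kinship matrix as a square CSV with id header row/column
#' @param kinship a `kinship_matrix`.
#' @param path output path.
#' @export
write_kinship <- function(kinship, path) {
  utils::write.csv(as.data.frame(kinship$A), path, row.names = TRUE)
  invisible(path)
}
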