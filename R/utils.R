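#' Quasi-uniform points on the unit sphere
#'
#' Deterministic Fibonacci (golden-angle) spiral lattice. Used both for
#' placing candidate SAS points on expanded atom spheres and for laying out
#' shell atoms in the synthetic structure generator; it is deterministic so
#' surface generation needs no random seed.
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)              # polar angle
  theta <- pi * (1 + sqrt(5)) * i         # golden-angle azimuth
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

# Euclidean distances from each row of `points` (m x 3) to each row of
# `atoms` (n x 3); returns m x n matrix. Cross-product formulation keeps the
# inner loop in BLAS.
cross_dist <- function(points, atoms) {
  points <- matrix(as.numeric(points), ncol = 3)
  atoms <- matrix(as.numeric(atoms), ncol = 3)
  d2 <- outer(rowSums(points^2), rep(1, nrow(atoms))) +
    outer(rep(1, nrow(points)), rowSums(atoms^2)) -
    2 * tcrossprod(points, atoms)
  d2[d2 < 0] <- 0  # guard tiny negatives from cancellation
  sqrt(d2)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Area under the ROC curve for point-level scores
#'
#' Rank-based (Mann-Whitney) AUC of ligandability scores against binary
#' point labels. Ties in score contribute 1/2.
#'
#' @param scores numeric vector of scores.
#' @param labels logical vector, `TRUE` for positive points.
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
point_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Append a timestamped key = value block to a run log file (or do nothing
# when `log_file` is NULL). Every CLI entry point logs its resolved config.
log_lines <- function(log_file, ...) {
  if (is.null(log_file)) return(invisible(NULL))
  lines <- unlist(list(...))
  cat(lines, file = log_file, sep = "\n", append = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
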