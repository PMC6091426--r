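# From scored SAS points to ranked pockets: threshold, single-linkage
# clustering at 3 A, scoring by the sum of squared member scores, and
# mapping each pocket to adjacent surface atoms and residues.

#' Select candidate points by score threshold
#'
#' @param cloud a scored `pr_sas_cloud`.
#' @param threshold score threshold in `[0, 1]`; points with score >=
#'   threshold are selected (inclusive boundary).
#' @return integer indices of selected points.
#' @export
select_candidate_points <- function(cloud, threshold) {
  stopifnot(inherits(cloud, "pr_sas_cloud"))
  if (is.null(cloud$scores)) stop("cloud has no scores")
  if (threshold < 0 || threshold > 1)
    stop("threshold must be within [0, 1], got ", threshold)
  which(cloud$scores >= threshold)
}

#' Single-linkage clustering of 3D points
#'
#' Two points share a cluster iff they are connected by a chain of pairwise
#' distances <= `cutoff`, i.e. clusters are the connected components of the
#' distance-threshold graph. Computed by cutting the single-linkage
#' dendrogram at the cutoff height; the partition is unique and independent
#' of point order.
#'
#' @param points m x 3 coordinate matrix.
#' @param cutoff linkage distance cutoff in Angstrom (default 3).
#' @return list of integer index vectors, one per cluster (arbitrary
#'   order).
#' @export
cluster_points <- function(points, cutoff = 3) {
  stopifnot(cutoff > 0)
  points <- matrix(as.numeric(points), ncol = 3)
  m <- nrow(points)
  if (m == 0) return(list())
  if (m == 1) return(list(1L))
  tree <- stats::hclust(stats::dist(points), method = "single")
  membership <- stats::cutree(tree, h = cutoff)
  unname(split(seq_len(m), membership))
}

#' Build, score and rank pockets from clustered points
#'
#' Clusters smaller than `min_cluster_size` are discarded. A pocket's score
#' is the sum of squared ligandability scores of its member points, so many
#' confident points outrank many lukewarm ones. Pockets are sorted by score
#' descending, ties broken by larger point count, then by lexicographic
#' center coordinates, and assigned ranks 1..K.
#'
#' @param clusters list of point-index vectors (from [cluster_points()],
#'   indices into the cloud's points).
#' @param cloud the scored `pr_sas_cloud` the indices refer to.
#' @param min_cluster_size minimum member-point count (default 3).
#' @param contact_cutoff pocket-to-atom contact distance in Angstrom used
#'   to assign surface atoms and residues (default 3.5).
#' @return list of `pr_pocket` objects, ranked.
#' @export
score_and_rank <- function(clusters, cloud, min_cluster_size = 3L,
                           contact_cutoff = 3.5) {
  stopifnot(inherits(cloud, "pr_sas_cloud"))
  clusters <- Filter(function(idx) length(idx) >= min_cluster_size, clusters)
  pockets <- lapply(clusters, finalize_pocket, cloud = cloud,
                    contact_cutoff = contact_cutoff)
  if (length(pockets) == 0) return(list())
  score <- vapply(pockets, `[[`, numeric(1), "score")
  size <- vapply(pockets, function(p) length(p$point_idx), integer(1))
  cx <- vapply(pockets, function(p) p$center[1], numeric(1))
  cy <- vapply(pockets, function(p) p$center[2], numeric(1))
  cz <- vapply(pockets, function(p) p$center[3], numeric(1))
  ord <- order(-score, -size, cx, cy, cz)
  pockets <- pockets[ord]
  for (k in seq_along(pockets)) pockets[[k]]$rank <- k
  pockets
}

#' Finalize a single pocket from a point cluster
#'
#' The center is the score-weighted centroid of the member points (plain
#' centroid when all scores are zero); surface atoms are the protein atoms
#' within `contact_cutoff` of any member point; residues are the distinct
#' residue ids of those atoms, written as `<chain>_<resno><insert>` tokens
#' (pockets may span multiple chains).
#'
#' @param idx integer indices of the cluster's points in the cloud.
#' @param cloud the scored `pr_sas_cloud`.
#' @param contact_cutoff contact distance in Angstrom (default 3.5).
#' @return an object of class `pr_pocket`.
#' @export
finalize_pocket <- function(idx, cloud, contact_cutoff = 3.5) {
  stopifnot(length(idx) >= 1)
  pts <- cloud$points[idx, , drop = FALSE]
  s <- if (is.null(cloud$scores)) rep(0, length(idx)) else cloud$scores[idx]
  w <- if (sum(s) > 0) s / sum(s) else rep(1 / length(idx), length(idx))
  center <- as.numeric(crossprod(pts, w))
  names(center) <- c("x", "y", "z")

  at <- cloud$structure$atoms
  d <- cross_dist(pts, atom_coords(cloud$structure))
  near <- which(apply(d, 2, min) <= contact_cutoff)
  res_tok <- unique(paste0(at$chain[near], "_", at$resno[near],
                           at$insert[near]))
  structure(list(rank = NA_integer_,
                 score = sum(s^2),
                 center = center,
                 point_idx = idx,
                 member_points = pts,
                 member_scores = s,
                 surface_atoms = near,
                 surface_atom_serials = at$serial[near],
                 residue_ids = res_tok),
            class = "pr_pocket")
}

#' @export
print.pr_pocket <- function(x, ...) {
  cat(sprintf(
    "<pr_pocket> rank %s score %.3f center (%.2f, %.2f, %.2f) %d points, %d atoms, %d residues\n",
    ifelse(is.na(x$rank), "?", x$rank), x$score,
    x$center[1], x$center[2], x$center[3],
    length(x$point_idx), length(x$surface_atoms), length(x$residue_ids)))
  invisible(x)
}

#' Extract ranked pockets from a scored point cloud
#'
#' Convenience wrapper chaining [select_candidate_points()],
#' [cluster_points()] and [score_and_rank()].
#'
#' @param cloud a scored `pr_sas_cloud`.
#' @param threshold ligandability score threshold (default 0.35).
#' @param cluster_cutoff single-linkage distance cutoff in Angstrom
#'   (default 3).
#' @param min_cluster_size minimum pocket size in points (default 3).
#' @param contact_cutoff surface-atom contact distance in Angstrom
#'   (default 3.5).
#' @return ranked list of `pr_pocket`.
#' @export
extract_pockets <- function(cloud, threshold = 0.35, cluster_cutoff = 3,
                            min_cluster_size = 3L, contact_cutoff = 3.5) {
  sel <- select_candidate_points(cloud, threshold)
  if (length(sel) == 0) return(list())
  clusters <- cluster_points(cloud$points[sel, , drop = FALSE],
                             cutoff = cluster_cutoff)
  clusters <- lapply(clusters, function(ci) sel[ci])
  score_and_rank(clusters, cloud, min_cluster_size = min_cluster_size,
                 contact_cutoff = contact_cutoff)
}
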