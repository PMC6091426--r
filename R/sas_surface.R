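# Solvent accessible surface point sampling.
#
# For each atom, candidate points are placed on a deterministic Fibonacci
# lattice on the sphere of radius (vdW radius + probe radius); candidates
# falling strictly inside any other atom's expanded sphere are discarded.
# The survivors are the SAS points: regularly spaced samples of the surface
# a solvent probe center can reach.

# van der Waals radii (Angstrom) by element; unknown elements fall back to
# the carbon value with a warning.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
.vdw_default <- 1.70

#' van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  element <- toupper(element)
  r <- unname(.vdw_table[element])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius ", .vdw_default, " A")
    r[is.na(r)] <- .vdw_default
  }
  r
}

#' Generate regularly spaced points on the solvent accessible surface
#'
#' @param structure a `pr_structure`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param samples_per_atom candidate points per atom sphere (default 100,
#'   giving a mean inter-point spacing of roughly 1 A on an exposed carbon).
#' @return an object of class `pr_sas_cloud`: `points` (n x 3 matrix),
#'   `owner` (index of the atom whose expanded sphere each point lies on),
#'   the generating parameters, and the source `structure`.
#' @export
generate_sas_points <- function(structure, probe_radius = 1.4,
                                samples_per_atom = 100L) {
  stopifnot(inherits(structure, "pr_structure"),
            probe_radius >= 0, samples_per_atom >= 1)
  xyz <- atom_coords(structure)
  n <- nrow(xyz)
  radii <- vdw_radius(structure$atoms$element) + probe_radius
  # orient the sampling lattice in the structure's principal-axes frame so
  # the point cloud is equivariant under rigid motion of the structure
  unit <- fibonacci_sphere(samples_per_atom) %*% t(.structure_frame(xyz))
  tol <- 1e-6

  # atoms i, j can occlude each other's candidates iff their expanded
  # spheres intersect
  dm <- cross_dist(xyz, xyz)
  pts <- vector("list", n)
  owner <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- sweep(unit * radii[i], 2, xyz[i, ], "+")
    nb <- which(dm[i, ] < radii[i] + radii & seq_len(n) != i)
    if (length(nb) > 0) {
      dc <- cross_dist(cand, xyz[nb, , drop = FALSE])
      keep <- rowSums(dc < rep(radii[nb] - tol, each = nrow(dc))) == 0
      cand <- cand[keep, , drop = FALSE]
    }
    pts[[i]] <- cand
    owner[[i]] <- rep.int(i, nrow(cand))
  }
  points <- do.call(rbind, pts)
  dimnames(points) <- list(NULL, c("x", "y", "z"))

  structure(list(points = points,
                 owner = unlist(owner),
                 probe_radius = probe_radius,
                 samples_per_atom = as.integer(samples_per_atom),
                 structure = structure,
                 features = NULL,
                 schema = NULL,
                 scores = NULL,
                 labels = NULL),
            class = "pr_sas_cloud")
}

# Deterministic structure-intrinsic orthonormal frame: principal axes of
# the atom coordinates, each axis' sign fixed by the third moment of the
# coordinates along it (falling back to the identity for degenerate
# spectra, e.g. a single atom or a perfectly symmetric cloud).
.structure_frame <- function(xyz) {
  if (nrow(xyz) < 4) return(diag(3))
  centered <- sweep(xyz, 2, colMeans(xyz))
  cv <- crossprod(centered) / nrow(xyz)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values
  if (ev[1] < 1e-8) return(diag(3))
  # distinct spectrum required for a well-defined, rotation-covariant frame
  if (min(abs(diff(ev))) / ev[1] < 1e-6) return(diag(3))
  v <- eg$vectors
  for (k in 1:2) {
    s3 <- sum((centered %*% v[, k])^3)
    if (abs(s3) < 1e-9) return(diag(3))
    if (s3 < 0) v[, k] <- -v[, k]
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

#' @export
print.pr_sas_cloud <- function(x, ...) {
  cat("<pr_sas_cloud> ", nrow(x$points), " SAS points over ",
      nrow(x$structure$atoms), " atoms (probe ", x$probe_radius, " A)",
      if (!is.null(x$scores)) " [scored]", "\n", sep = "")
  invisible(x)
}

#' Protein atoms within a radius of a query point
#'
#' Inclusive boundary: atoms at distance exactly `radius` are returned.
#'
#' @param cloud a `pr_sas_cloud` (or a `pr_structure`).
#' @param center numeric 3-vector.
#' @param radius query radius in Angstrom, > 0.
#' @return integer indices (rows of `structure$atoms`) of matching atoms.
#' @export
atoms_within <- function(cloud, center, radius) {
  stopifnot(radius > 0, length(center) == 3)
  structure <- if (inherits(cloud, "pr_sas_cloud")) cloud$structure else cloud
  d <- cross_dist(matrix(center, 1, 3), atom_coords(structure))
  which(d[1, ] <= radius)
}

#' Write SAS points as a pseudo-atom PDB file
#'
#' Each point becomes a HETATM record (residue `STP`), with the
#' ligandability score (when present) stored in the B-factor column. This is
#' the labeled-SAS-point debug output that visualization scripts color.
#'
#' @param cloud a `pr_sas_cloud`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points_pdb <- function(cloud, path) {
  stopifnot(inherits(cloud, "pr_sas_cloud"))
  n <- nrow(cloud$points)
  b <- if (is.null(cloud$scores)) rep(0, n) else round(cloud$scores, 2)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cloud$points)),
                   type = rep("HETATM", n),
                   eleno = seq_len(n),
                   elety = rep("P", n),
                   resid = rep("STP", n),
                   chain = rep("P", n),
                   resno = rep(1L, n),
                   o = rep(1, n),
                   b = b,
                   elesy = rep("He", n))
  invisible(path)
}
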