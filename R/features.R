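# Feature computation for SAS points.
#
# Two kinds of features describe a point's local chemical neighbourhood:
#   * projected atom properties: for each physico-chemical property p, the
#     sum over protein atoms a within the projection radius R of
#     w(d) * p(a), with the linear distance weight w(d) = 1 - d/R;
#   * direct geometric descriptors assigned to the point itself, chiefly
#     protrusion: the number of protein atoms within 10 A of the point, a
#     proxy for its buriedness.
#
# The feature schema (which features, in which order) is configurable; a
# trained model records its schema and refuses to score mismatched vectors.
# The single-feature schema c("protrusion") reproduces the purely geometric
# reduced mode of the predictor.

# Residue-level property values for the 20 standard amino acids.
# hydrophobicity: Kyte-Doolittle index; aromaticity / charge / polarity:
# standard categorical assignments.
.residue_props <- local({
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  hydro <- c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
             3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2)
  arom <- as.numeric(aa %in% c("PHE", "TYR", "TRP", "HIS"))
  charge <- ifelse(aa %in% c("ARG", "LYS"), 1,
                   ifelse(aa %in% c("ASP", "GLU"), -1,
                          ifelse(aa == "HIS", 0.5, 0)))
  polar <- as.numeric(aa %in% c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS",
                                "LYS", "SER", "THR", "TYR", "CYS"))
  data.frame(resid_name = aa, hydrophobicity = hydro, aromaticity = arom,
             charge = charge, polarity = polar, stringsAsFactors = FALSE)
})

# Element-level hydrogen-bonding capability (heavy atoms; hydrogens are
# not modelled). Unlisted elements score 0.
.element_donor <- c(N = 1, O = 0.5, S = 0.3)
.element_acceptor <- c(O = 1, N = 0.5, S = 0.5)

.projected_names <- c("hydrophobicity", "aromaticity", "charge",
                      "hb_donor", "hb_acceptor", "polarity", "bfactor")
.direct_names <- c("protrusion", "atom_count_6", "atom_count_4")

#' Default feature schema
#'
#' Seven projected atom properties followed by three direct geometric
#' descriptors. The schema is an ordered character vector; pass a subset
#' (e.g. `"protrusion"` alone for the purely geometric reduced mode) to
#' [compute_features()] and [train_model()].
#'
#' @return character vector of feature names.
#' @export
default_feature_schema <- function() c(.projected_names, .direct_names)

#' Neighbourhood parameters for feature computation
#'
#' @param projection_radius radius (A) of the property projection
#'   neighbourhood; atoms beyond it contribute nothing (default 6).
#' @param protrusion_radius radius (A) of the protrusion counting sphere
#'   (default 10).
#' @param aggregation `"sum"` (default) projects the distance-weighted sum
#'   of each property; `"mean"` divides by the sum of weights, isolating
#'   property composition from local atom density.
#' @return an object of class `neighbourhood_params`.
#' @export
neighbourhood_params <- function(projection_radius = 6,
                                 protrusion_radius = 10,
                                 aggregation = c("sum", "mean")) {
  stopifnot(projection_radius > 0, protrusion_radius > 0)
  structure(list(projection_radius = projection_radius,
                 protrusion_radius = protrusion_radius,
                 aggregation = match.arg(aggregation)),
            class = "neighbourhood_params")
}

#' Linear distance weight for property projection
#'
#' `w(d) = 1 - d/radius`: 1 at the point itself, 0 at the edge of the
#' neighbourhood.
#'
#' @param d distance(s) in Angstrom, `0 <= d <= radius`.
#' @param radius neighbourhood radius in Angstrom.
#' @return numeric weight(s) in `[0, 1]`.
#' @export
distance_weight <- function(d, radius = 6) {
  stopifnot(radius > 0, all(d >= 0), all(d <= radius))
  1 - d / radius
}

#' Per-atom physico-chemical property matrix
#'
#' Looks up residue-level properties (hydrophobicity, aromaticity, charge,
#' polarity) by residue name and element-level hydrogen-bond donor/acceptor
#' capability by element; atoms of unknown residues fall back to neutral
#' residue values. The B-factor column is passed through from the
#' structure.
#'
#' @param structure a `pr_structure`.
#' @return numeric matrix, one row per protein atom, columns
#'   hydrophobicity, aromaticity, charge, hb_donor, hb_acceptor, polarity,
#'   bfactor.
#' @export
atom_properties <- function(structure) {
  at <- structure$atoms
  m <- match(at$resid_name, .residue_props$resid_name)
  hydro <- ifelse(is.na(m), 0, .residue_props$hydrophobicity[m])
  arom <- ifelse(is.na(m), 0, .residue_props$aromaticity[m])
  charge <- ifelse(is.na(m), 0, .residue_props$charge[m])
  polar <- ifelse(is.na(m), 0, .residue_props$polarity[m])
  donor <- unname(.element_donor[at$element]); donor[is.na(donor)] <- 0
  accep <- unname(.element_acceptor[at$element]); accep[is.na(accep)] <- 0
  cbind(hydrophobicity = hydro, aromaticity = arom, charge = charge,
        hb_donor = donor, hb_acceptor = accep, polarity = polar,
        bfactor = at$b)
}

#' Project distance-weighted atom properties onto points
#'
#' For each point and property, sums `w(d) * p(a)` over atoms within the
#' projection radius (or the weighted mean when
#' `params$aggregation == "mean"`). Points with no atom in range get zeros.
#'
#' @param points m x 3 coordinate matrix.
#' @param atoms_xyz n x 3 protein atom coordinate matrix.
#' @param properties n x k per-atom property matrix.
#' @param params a `neighbourhood_params`.
#' @return m x k matrix of projected values.
#' @export
project_properties <- function(points, atoms_xyz, properties,
                               params = neighbourhood_params()) {
  points <- matrix(as.numeric(points), ncol = 3)
  properties <- as.matrix(properties)
  r <- params$projection_radius
  out <- matrix(0, nrow(points), ncol(properties),
                dimnames = list(NULL, colnames(properties)))
  for (block in .point_blocks(nrow(points))) {
    d <- cross_dist(points[block, , drop = FALSE], atoms_xyz)
    w <- 1 - d / r
    w[d > r] <- 0
    proj <- w %*% properties
    if (params$aggregation == "mean") {
      ws <- rowSums(w)
      proj <- proj / ifelse(ws > 0, ws, 1)
    }
    out[block, ] <- proj
  }
  out
}

#' Protrusion of points: protein atom count within a sphere
#'
#' The number of protein atoms within `radius` (inclusive) of each point —
#' high for points buried in concave invaginations, low for points on
#' convex protrusions.
#'
#' @param points m x 3 coordinate matrix.
#' @param atoms_xyz n x 3 protein atom coordinate matrix.
#' @param radius counting radius in Angstrom (default 10).
#' @return integer vector of counts.
#' @export
protrusion <- function(points, atoms_xyz, radius = 10) {
  stopifnot(radius > 0)
  points <- matrix(as.numeric(points), ncol = 3)
  out <- integer(nrow(points))
  for (block in .point_blocks(nrow(points))) {
    d <- cross_dist(points[block, , drop = FALSE], atoms_xyz)
    out[block] <- as.integer(rowSums(d <= radius))
  }
  out
}

.point_blocks <- function(n, size = 4000L) {
  if (n == 0) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Compute the feature matrix of a SAS point cloud
#'
#' Assembles, in schema order, the projected atom properties and direct
#' geometric descriptors of every point. The result and the schema are
#' stored on the cloud.
#'
#' @param cloud a `pr_sas_cloud`.
#' @param schema ordered character vector of feature names; see
#'   [default_feature_schema()] for the valid names.
#' @param params a `neighbourhood_params`.
#' @return the cloud with `features` (matrix, one row per point, columns
#'   named by schema) and `schema` set.
#' @export
compute_features <- function(cloud, schema = default_feature_schema(),
                             params = neighbourhood_params()) {
  stopifnot(inherits(cloud, "pr_sas_cloud"), length(schema) >= 1)
  valid <- default_feature_schema()
  bad <- setdiff(schema, valid)
  if (length(bad) > 0)
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(valid, collapse = ", "))
  xyz <- atom_coords(cloud$structure)
  pts <- cloud$points
  feat <- matrix(NA_real_, nrow(pts), length(schema),
                 dimnames = list(NULL, schema))

  proj_wanted <- intersect(schema, .projected_names)
  if (length(proj_wanted) > 0) {
    props <- atom_properties(cloud$structure)[, proj_wanted, drop = FALSE]
    feat[, proj_wanted] <- project_properties(pts, xyz, props, params)
  }
  if ("protrusion" %in% schema)
    feat[, "protrusion"] <- protrusion(pts, xyz, params$protrusion_radius)
  if ("atom_count_6" %in% schema)
    feat[, "atom_count_6"] <- protrusion(pts, xyz, params$projection_radius)
  if ("atom_count_4" %in% schema)
    feat[, "atom_count_4"] <- protrusion(pts, xyz, 4)

  stopifnot(all(is.finite(feat)))
  cloud$features <- feat
  cloud$schema <- schema
  cloud
}
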