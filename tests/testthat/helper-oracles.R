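# Shared helpers: in-memory toy structures, hand-formatted PDB records, and
# independent brute-force oracles that the implementation is checked
# against. Oracles are deliberately naive (double loops, BFS over an
# explicit adjacency matrix) and share no code with the package internals.

toy_structure <- function(xyz, element = "C", chain = "A",
                          resno = NULL, resid_name = "ALA", b = 0,
                          id = "toy") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(serial = seq_len(n),
                      name = paste0("C", seq_len(n)),
                      resid_name = rep_len(resid_name, n),
                      chain = rep_len(chain, n),
                      resno = if (is.null(resno)) seq_len(n)
                              else rep_len(resno, n),
                      insert = "",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      b = rep_len(b, n),
                      element = rep_len(element, n),
                      stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms, het_groups = list(),
                 chains = sort(unique(atoms$chain))),
            class = "pr_structure")
}

toy_ligand <- function(xyz, residue_name = "LIG", chain = "L", resno = 900L) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  structure(list(residue_name = residue_name, chain = chain, resno = resno,
                 insert = "",
                 atoms = data.frame(serial = seq_len(nrow(xyz)),
                                    name = paste0("C", seq_len(nrow(xyz))),
                                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                    element = "C", stringsAsFactors = FALSE),
                 relevant = TRUE, min_distance_to_protein = NA_real_),
            class = "pr_ligand")
}

# Minimal scored cloud over an explicit point set, for the pocket module.
toy_cloud <- function(points, scores = NULL, structure = NULL) {
  points <- matrix(as.numeric(points), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (is.null(structure)) structure <- toy_structure(points)
  structure(list(points = points, owner = seq_len(nrow(points)),
                 probe_radius = 1.4, samples_per_atom = 1L,
                 structure = structure, features = NULL, schema = NULL,
                 scores = scores, labels = NULL),
            class = "pr_sas_cloud")
}

# Hand-formatted fixed-width PDB record (independent of bio3d).
pdb_line <- function(type, serial, name, alt, resid, chain, resno,
                     x, y, z, occ = 1, b = 0, elesy = "C", icode = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resid, chain, resno, icode,
          x, y, z, occ, b, elesy)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# --- brute-force oracles ---------------------------------------------------

bf_dist <- function(a, b) sqrt(sum((a - b)^2))

bf_atoms_within <- function(xyz, center, radius) {
  hits <- integer(0)
  for (i in seq_len(nrow(xyz)))
    if (bf_dist(xyz[i, ], center) <= radius) hits <- c(hits, i)
  hits
}

bf_protrusion <- function(points, xyz, radius) {
  out <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    cnt <- 0L
    for (j in seq_len(nrow(xyz)))
      if (bf_dist(points[i, ], xyz[j, ]) <= radius) cnt <- cnt + 1L
    out[i] <- cnt
  }
  out
}

bf_project <- function(points, xyz, properties, radius) {
  out <- matrix(0, nrow(points), ncol(properties))
  for (i in seq_len(nrow(points))) {
    for (j in seq_len(nrow(xyz))) {
      d <- bf_dist(points[i, ], xyz[j, ])
      if (d <= radius)
        out[i, ] <- out[i, ] + (1 - d / radius) * properties[j, ]
    }
  }
  out
}

# Connected components of the <=cutoff adjacency graph by BFS.
bf_components <- function(points, cutoff) {
  n <- nrow(points)
  adj <- as.matrix(dist(points)) <= cutoff
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Canonical form of a partition (list of index sets) for set comparison.
canonical_partition <- function(membership_or_list) {
  sets <- if (is.list(membership_or_list)) membership_or_list
          else split(seq_along(membership_or_list), membership_or_list)
  sets <- lapply(sets, function(s) sort(as.integer(s)))
  unname(sets[order(vapply(sets, `[`, integer(1), 1))])
}

# Pair-counting AUC (ties count 1/2).
bf_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small rotation + translation used by rigid-motion tests.
rigid_motion <- function(xyz, angles = c(0.3, -0.7, 1.1),
                         shift = c(5, -3, 2)) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  sweep(xyz %*% t(Rz %*% Ry %*% Rx), 2, shift, "+")
}

# Random compact atom cloud for oracle-equivalence fixtures.
random_atom_cloud <- function(n, box = 12) {
  matrix(runif(3 * n, -box, box), ncol = 3)
}
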