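# Synthetic structure generator.
#
# Emulates a globular protein as a jittered atom ball: a quasi-uniform
# shell of surface atoms over a cubic-lattice interior. Each pocket is a
# concave invagination carved by removing atoms inside a "bite" sphere
# placed at the surface (plus a slight inward displacement of the wall
# atoms), so the protrusion feature genuinely differs between pocket and
# open-shell points. A compact pseudo-ligand (HETATM group LIG) is placed
# inside each pocket within contact distance of the lining atoms, and the
# lining atoms' B-factors are shifted by `property_contrast`, giving a
# tunable property signal on top of the geometric one. The seed fully
# determines the output file.

#' Specification of a synthetic fixture structure
#'
#' @param n_shell_atoms atoms on the outer shell (default 300; with the
#'   interior lattice this yields roughly 500 protein atoms).
#' @param shell_radius outer radius in Angstrom (default 14).
#' @param n_pockets number of carved pockets (default 1); pockets must not
#'   overlap on the shell, otherwise generation fails.
#' @param pocket_depth radial depth of the carved invagination in Angstrom
#'   (default 6); 0 carves nothing (flat null surface).
#' @param pocket_mouth_radius radius of the carving bite sphere in
#'   Angstrom (default 5.5).
#' @param ligand_size heavy atoms per pseudo-ligand (default 8).
#' @param property_contrast B-factor shift applied to pocket-lining atoms
#'   (default 30); 0 removes the property signal.
#' @param noise_sd positional jitter of atoms in Angstrom (default 0.3).
#' @param seed integer seed fully determining the structure.
#' @param n_chains 1 (default) or 2; with 2, atoms are split into chains A
#'   and B by hemisphere, so equatorial pockets span both chains.
#' @param pocket_directions optional matrix of unit vectors (one row per
#'   pocket) pinning pocket placement; random when `NULL`.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_shell_atoms = 300L,
                         shell_radius = 14,
                         n_pockets = 1L,
                         pocket_depth = 6,
                         pocket_mouth_radius = 5.5,
                         ligand_size = 8L,
                         property_contrast = 30,
                         noise_sd = 0.3,
                         seed = 1L,
                         n_chains = 1L,
                         pocket_directions = NULL) {
  stopifnot(n_shell_atoms >= 50, shell_radius >= 8, n_pockets >= 0,
            pocket_depth >= 0, pocket_mouth_radius > 0, ligand_size >= 1,
            property_contrast >= 0, noise_sd >= 0, n_chains %in% c(1L, 2L))
  structure(list(n_shell_atoms = as.integer(n_shell_atoms),
                 shell_radius = shell_radius,
                 n_pockets = as.integer(n_pockets),
                 pocket_depth = pocket_depth,
                 pocket_mouth_radius = pocket_mouth_radius,
                 ligand_size = as.integer(ligand_size),
                 property_contrast = property_contrast,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 n_chains = as.integer(n_chains),
                 pocket_directions = pocket_directions),
            class = "fixture_spec")
}

# Cubic lattice points (jittered later) filling the ball of radius r_max.
.interior_lattice <- function(r_max, spacing = 3.2) {
  g <- seq(-r_max, r_max, by = spacing)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  grid[sqrt(rowSums(grid^2)) <= r_max, , drop = FALSE]
}

# Choose pocket directions whose surface mouths do not overlap.
.pocket_directions <- function(spec) {
  if (!is.null(spec$pocket_directions)) {
    u <- matrix(spec$pocket_directions, ncol = 3)
    stopifnot(nrow(u) == spec$n_pockets)
    return(u / sqrt(rowSums(u^2)))
  }
  min_sep <- 2 * spec$pocket_mouth_radius + 3
  chosen <- matrix(numeric(0), 0, 3)
  for (k in seq_len(spec$n_pockets)) {
    ok <- FALSE
    for (try in 1:3000) {
      v <- rnorm(3); v <- v / sqrt(sum(v^2))
      if (nrow(chosen) == 0 ||
          min(sqrt(rowSums(sweep(chosen, 2, v)^2))) * spec$shell_radius >
          min_sep) {
        chosen <- rbind(chosen, v); ok <- TRUE; break
      }
    }
    if (!ok) stop("infeasible fixture geometry: cannot place ",
                  spec$n_pockets, " non-overlapping pockets on a shell of ",
                  "radius ", spec$shell_radius)
  }
  chosen
}

#' Generate a synthetic structure with known pockets
#'
#' Writes a valid PDB file (readable by [load_structure()]) and returns the
#' ground truth. Identical specs (same seed) give byte-identical files.
#'
#' @param spec a `fixture_spec`.
#' @param path output PDB path (default: a tempfile).
#' @return invisibly, a list with `path`, `pocket_centers` (matrix of
#'   ligand centroids, 0 rows when `n_pockets = 0`), `bite_centers`, and
#'   `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- with_seed(spec$seed, .build_fixture(spec))
  .write_fixture_pdb(res, path)
  invisible(list(path = path, pocket_centers = res$pocket_centers,
                 bite_centers = res$bite_centers, spec = spec))
}

.build_fixture <- function(spec) {
  R <- spec$shell_radius
  shell <- fibonacci_sphere(spec$n_shell_atoms) * R
  interior <- .interior_lattice(R - 1.6)
  prot <- rbind(shell, interior)
  prot <- prot + matrix(rnorm(length(prot), 0, spec$noise_sd), ncol = 3)

  b <- rep(0, nrow(prot))
  dirs <- if (spec$n_pockets > 0) .pocket_directions(spec) else
    matrix(numeric(0), 0, 3)
  bite_centers <- dirs * (R + spec$pocket_mouth_radius - spec$pocket_depth)
  ligands <- list()
  pocket_centers <- matrix(numeric(0), 0, 3,
                           dimnames = list(NULL, c("x", "y", "z")))

  for (k in seq_len(spec$n_pockets)) {
    bc <- bite_centers[k, ]
    if (spec$pocket_depth > 0) {
      d <- sqrt(colSums((t(prot) - bc)^2))
      removed <- d < spec$pocket_mouth_radius
      prot <- prot[!removed, , drop = FALSE]
      b <- b[!removed]
      d <- d[!removed]
      # smooth the wall: pull near-boundary atoms slightly toward the bite
      wall <- d < spec$pocket_mouth_radius + 1.2
      if (any(wall)) {
        shift <- t(bc - t(prot[wall, , drop = FALSE]))
        shift <- shift / pmax(sqrt(rowSums(shift^2)), 1e-9) * 0.5
        prot[wall, ] <- prot[wall, , drop = FALSE] + shift
      }
      # property contrast on the pocket lining
      lining <- sqrt(colSums((t(prot) - bc)^2)) < spec$pocket_mouth_radius + 2
      b[lining] <- spec$property_contrast
    } else if (spec$property_contrast > 0) {
      lining <- sqrt(colSums((t(prot) - bc)^2)) < spec$pocket_mouth_radius + 2
      b[lining] <- spec$property_contrast
    }

    lig <- .place_ligand(spec, dirs[k, ], prot)
    ligands[[k]] <- lig
    pocket_centers <- rbind(pocket_centers, colMeans(lig))
  }

  list(prot = prot, b = b, ligands = ligands,
       pocket_centers = pocket_centers, bite_centers = bite_centers,
       spec = spec)
}

# Place a compact pseudo-ligand along direction u, nudged radially until it
# is in contact with (but not clashing into) the pocket lining.
.place_ligand <- function(spec, u, prot) {
  r_c <- spec$shell_radius - spec$pocket_depth + 2.2
  offsets <- if (spec$ligand_size == 1) matrix(0, 1, 3) else
    rbind(c(0, 0, 0), fibonacci_sphere(spec$ligand_size - 1) * 1.3)
  offsets <- offsets + matrix(rnorm(length(offsets), 0, 0.1), ncol = 3)
  for (i in 1:80) {
    lig <- sweep(offsets, 2, u * r_c, "+")
    d <- cross_dist(lig, prot)
    dmin <- min(d)                      # closest approach (clash guard)
    dmax <- max(apply(d, 1, min))       # least-contacted ligand atom
    if (dmin < 1.2) { r_c <- r_c + 0.2; next }
    if (dmax > 3.5 && dmin > 1.5) { r_c <- r_c - 0.2; next }
    break
  }
  if (min(cross_dist(lig, prot)) > 4)
    stop("fixture ligand could not be placed in contact with the protein")
  dimnames(lig) <- list(NULL, c("x", "y", "z"))
  lig
}

.write_fixture_pdb <- function(res, path) {
  prot <- res$prot
  np <- nrow(prot)
  chain <- if (res$spec$n_chains == 2) ifelse(prot[, 3] >= 0, "A", "B")
  else rep("A", np)
  # group pseudo-atoms into 4-atom pseudo-residues per chain
  resno <- integer(np)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    resno[idx] <- ceiling(seq_along(idx) / 4)
  }
  lig_n <- vapply(res$ligands, nrow, integer(1))
  lig_xyz <- if (length(res$ligands)) do.call(rbind, res$ligands) else
    matrix(numeric(0), 0, 3)
  nl <- nrow(lig_xyz)

  # atom names unique within each pseudo-residue (C1..C4 / C1..Cn)
  prot_name <- paste0("C", stats::ave(seq_len(np), paste(chain, resno),
                                      FUN = seq_along))
  lig_name <- if (nl > 0) paste0("C", unlist(lapply(lig_n, seq_len))) else
    character(0)

  xyz <- rbind(prot, lig_xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = c(rep("ATOM", np), rep("HETATM", nl)),
    eleno = seq_len(np + nl),
    elety = c(prot_name, lig_name),
    resid = c(rep("ALA", np), rep("LIG", nl)),
    chain = c(chain, rep("L", nl)),
    resno = c(resno, rep(900L + seq_along(lig_n), times = lig_n)),
    o = rep(1, np + nl),
    b = round(c(res$b, rep(0, nl)), 2),
    elesy = rep("C", np + nl))
  invisible(path)
}

#' Generate a dataset of synthetic structures
#'
#' Writes `n_structures` fixture PDBs under `dir/structures/` plus a
#' dataset list file (`dir/dataset.ds`, one path per line relative to the
#' dataset file, `#` comments allowed). Per-structure seeds are derived
#' deterministically from the master seed.
#'
#' @param n_structures number of structures (>= 1).
#' @param template a `fixture_spec` used for every structure (its seed is
#'   replaced by the derived per-structure seed).
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @return list with `dataset_file`, `paths`, and `pocket_centers` (list of
#'   per-structure ligand-centroid matrices).
#' @export
generate_dataset <- function(n_structures, template = fixture_spec(),
                             dir = tempfile("fixture_set_"), seed = 1L) {
  stopifnot(n_structures >= 1)
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_structures))
  paths <- character(n_structures)
  centers <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    sp <- template
    sp$seed <- seeds[i]
    rel <- file.path("structures", sprintf("fixt_%03d.pdb", i))
    out <- generate_fixture(sp, file.path(dir, rel))
    paths[i] <- rel
    centers[[i]] <- out$pocket_centers
  }
  ds <- file.path(dir, "dataset.ds")
  writeLines(c("# synthetic fixture dataset", paths), ds)
  list(dataset_file = ds, paths = file.path(dir, paths),
       pocket_centers = centers)
}
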