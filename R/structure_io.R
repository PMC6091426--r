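# PDB ingestion and ligand relevance filtering.
#
# A structure is split into protein atoms (the surface being described) and
# HET groups (candidate ligands). Waters and hydrogens are dropped outright;
# non-standard amino acids recorded as HETATM inside polymer chains are kept
# as protein atoms since they are part of the surface.

.water_resids <- c("HOH", "DOD", "WAT", "H2O")

# Common modified/non-standard amino acids that appear as HETATM records
# within polymer chains.
.modified_aa <- c("MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "CSO", "CSD",
                  "HYP", "MLY", "M3L", "KCX", "LLP", "CME", "OCS", "PCA")

#' Default ligand relevance rules
#'
#' A HET group counts as a relevant (binding-site defining) ligand iff its
#' residue name is not on the exclusion list, it has at least `min_atoms`
#' heavy atoms, and its closest heavy atom lies within `contact_cutoff` of
#' some protein atom. The exclusion list covers waters, common
#' buffer/cryoprotectant molecules and isolated single ions.
#'
#' @param min_atoms minimum heavy-atom count (default 5).
#' @param contact_cutoff maximum ligand-to-protein distance in Angstrom
#'   (default 4).
#' @param excluded character vector of excluded residue names.
#' @return an object of class `relevance_rules`.
#' @export
relevance_rules <- function(min_atoms = 5,
                            contact_cutoff = 4,
                            excluded = default_excluded_ligands()) {
  stopifnot(min_atoms >= 1, contact_cutoff > 0)
  structure(list(min_atoms = as.integer(min_atoms),
                 contact_cutoff = contact_cutoff,
                 excluded = toupper(excluded)),
            class = "relevance_rules")
}

#' @rdname relevance_rules
#' @export
default_excluded_ligands <- function() {
  c(.water_resids,
    # isolated ions
    "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU", "NI", "CO",
    "CD", "HG", "BR", "IOD", "F", "CS", "LI", "SR", "BA", "NH4", "AZI",
    "SCN", "NO3", "CN",
    # buffer / cryo agents
    "SO4", "PO4", "GOL", "EDO", "PEG", "PG4", "P6G", "1PE", "ACT", "DMS",
    "BME", "MPD", "TRS", "EPE", "MES", "FMT", "ACY", "CIT", "TLA", "MLI",
    "IMD", "BCT", "CO3")
}

#' Load a protein structure from a PDB file
#'
#' Reads ATOM/HETATM records, drops hydrogens and waters, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by file order),
#' keeps all chains, and partitions atoms into protein atoms and HET groups.
#' HETATM records of common modified amino acids are treated as protein.
#'
#' @param path path to a PDB file.
#' @param model_index which MODEL of a multi-model file to use (default 1).
#' @return an object of class `pr_structure` with elements `id`, `atoms`
#'   (data frame of protein atoms), `het_groups` (list of `pr_ligand`), and
#'   `chains`.
#' @export
load_structure <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  at$elesy <- .resolve_element(at$elesy, at$elety)
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$resid <- toupper(at$resid)

  # drop hydrogens and waters
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- at[!(at$resid %in% .water_resids), , drop = FALSE]
  if (nrow(at) == 0) stop("no non-water heavy atoms in '", path, "'")

  # resolve altlocs: within each (chain, resno, insert, resid, atom name)
  # keep the highest-occupancy record, first-in-file on ties
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -at$o, seq_len(nrow(at)))
  at <- at[ord[!duplicated(key[ord])], , drop = FALSE]
  at <- at[order(as.integer(rownames(at))), , drop = FALSE]  # file order

  is_protein <- at$type == "ATOM" | at$resid %in% .modified_aa
  prot <- at[is_protein, , drop = FALSE]
  het <- at[!is_protein, , drop = FALSE]
  if (nrow(prot) == 0)
    stop("structure '", path, "' contains no protein atoms")

  atoms <- data.frame(serial = prot$eleno,
                      name = prot$elety,
                      resid_name = prot$resid,
                      chain = prot$chain,
                      resno = prot$resno,
                      insert = prot$insert,
                      x = prot$x, y = prot$y, z = prot$z,
                      b = prot$b,
                      element = prot$elesy,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL

  het_groups <- list()
  if (nrow(het) > 0) {
    gk <- paste(het$resid, het$chain, het$resno, het$insert, sep = "\r")
    for (k in unique(gk)) {
      g <- het[gk == k, , drop = FALSE]
      het_groups[[length(het_groups) + 1L]] <- structure(
        list(residue_name = g$resid[1],
             chain = g$chain[1],
             resno = g$resno[1],
             insert = g$insert[1],
             atoms = data.frame(serial = g$eleno, name = g$elety,
                                x = g$x, y = g$y, z = g$z,
                                element = g$elesy,
                                stringsAsFactors = FALSE),
             relevant = NA,
             min_distance_to_protein = NA_real_),
        class = "pr_ligand")
    }
  }

  structure(list(id = tools::file_path_sans_ext(basename(path)),
                 atoms = atoms,
                 het_groups = het_groups,
                 chains = sort(unique(atoms$chain))),
            class = "pr_structure")
}

.resolve_element <- function(elesy, elety) {
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    # fall back to the first alphabetic character of the atom name
    guess <- toupper(substr(gsub("[^A-Za-z]", "", elety[miss]), 1, 1))
    guess[guess == ""] <- "C"
    elesy[miss] <- guess
  }
  toupper(elesy)
}

#' @export
print.pr_structure <- function(x, ...) {
  n_rel <- sum(vapply(x$het_groups, function(g) isTRUE(g$relevant), logical(1)))
  cat("<pr_structure> ", x$id, ": ", nrow(x$atoms), " protein atoms, ",
      length(x$het_groups), " HET group(s) (", n_rel, " relevant), chains: ",
      paste(x$chains, collapse = ","), "\n", sep = "")
  invisible(x)
}

# n x 3 coordinate matrix of the protein atoms
atom_coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

ligand_coords <- function(ligand) {
  as.matrix(ligand$atoms[, c("x", "y", "z")])
}

#' Flag which HET groups are relevant ligands
#'
#' Applies the rules of [relevance_rules()] to every HET group of a
#' structure, setting the `relevant` flag and recording the minimum
#' heavy-atom distance to the protein.
#'
#' @param structure a `pr_structure`.
#' @param rules a `relevance_rules` object.
#' @param log_file optional path; rule parameters and per-group decisions
#'   are appended there.
#' @return the structure with `relevant` and `min_distance_to_protein` set
#'   on every HET group.
#' @export
filter_relevant_ligands <- function(structure, rules = relevance_rules(),
                                    log_file = NULL) {
  stopifnot(inherits(structure, "pr_structure"),
            inherits(rules, "relevance_rules"))
  prot <- atom_coords(structure)
  log_lines(log_file, sprintf(
    "ligand_filter: min_atoms=%d contact_cutoff=%.2f excluded=%d names",
    rules$min_atoms, rules$contact_cutoff, length(rules$excluded)))
  structure$het_groups <- lapply(structure$het_groups, function(g) {
    d <- min(cross_dist(ligand_coords(g), prot))
    g$min_distance_to_protein <- d
    g$relevant <- !(g$residue_name %in% rules$excluded) &&
      nrow(g$atoms) >= rules$min_atoms &&
      d <= rules$contact_cutoff
    log_lines(log_file, sprintf(
      "ligand %s %s%d: atoms=%d min_dist=%.2f relevant=%s",
      g$residue_name, g$chain, g$resno, nrow(g$atoms), d, g$relevant))
    g
  })
  structure
}

#' Extract the relevant ligands of a structure
#'
#' @param structure a `pr_structure` on which [filter_relevant_ligands()]
#'   has been run.
#' @return list of `pr_ligand` objects with `relevant = TRUE`.
#' @export
relevant_ligands <- function(structure) {
  Filter(function(g) isTRUE(g$relevant), structure$het_groups)
}
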