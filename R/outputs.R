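# Prediction output artifacts: the ordered pocket CSV, and a PyMOL script
# coloring SAS points by ligandability (green = 0 to red = 1) and
# highlighting each pocket's surface atoms.

#' Write the ranked pocket list as CSV
#'
#' One row per pocket, ordered by rank: `name`, `rank`, `score`,
#' `center_x/y/z` (fixed 4 decimals), `surface_atom_ids` (space-separated
#' atom serials) and `residue_ids` (space-separated `<chain>_<resno>`
#' tokens). An empty prediction yields a header-only CSV.
#'
#' @param pockets ranked list of `pr_pocket`.
#' @param structure the predicted `pr_structure` (provides the name).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(pockets, structure, path) {
  df <- if (length(pockets) == 0) {
    data.frame(name = character(), rank = integer(), score = character(),
               center_x = character(), center_y = character(),
               center_z = character(), surface_atom_ids = character(),
               residue_ids = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(pockets, function(p) {
      data.frame(name = structure$id,
                 rank = p$rank,
                 score = sprintf("%.4f", p$score),
                 center_x = sprintf("%.4f", p$center[1]),
                 center_y = sprintf("%.4f", p$center[2]),
                 center_z = sprintf("%.4f", p$center[3]),
                 surface_atom_ids = paste(p$surface_atom_serials,
                                          collapse = " "),
                 residue_ids = paste(p$residue_ids, collapse = " "),
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PyMOL visualization script
#'
#' The script loads the structure and the SAS-point pseudo-atom PDB, colors
#' the points on a green-to-red spectrum by their ligandability score
#' (stored in the B-factor column, 0 = green, 1 = red), and colors each
#' pocket's surface atoms with a distinct color. Only files the run
#' actually wrote are referenced.
#'
#' @param structure_path path of the predicted structure PDB (referenced by
#'   basename; the script is meant to run from its output directory).
#' @param points_path path of the SAS-point PDB written by
#'   [write_points_pdb()].
#' @param pockets ranked list of `pr_pocket`.
#' @param path output script path.
#' @return `path`, invisibly.
#' @export
write_pymol_script <- function(structure_path, points_path, pockets, path) {
  palette <- c("yellow", "magenta", "cyan", "orange", "salmon", "purple",
               "slate", "wheat", "lime", "pink")
  lines <- c(
    "# generated by pocketrank",
    sprintf("load %s, protein", basename(structure_path)),
    sprintf("load %s, points", basename(points_path)),
    "hide everything",
    "show surface, protein",
    "set transparency, 0.2",
    "show nb_spheres, points",
    "# ligandability score is stored in the B-factor column (0 = green, 1 = red)",
    "spectrum b, green_red, points, minimum=0, maximum=1")
  for (p in pockets) {
    sel <- sprintf("pocket%d", p$rank)
    lines <- c(lines,
               sprintf("select %s, protein and id %s", sel,
                       paste(p$surface_atom_serials, collapse = "+")),
               sprintf("color %s, %s",
                       palette[(p$rank - 1) %% length(palette) + 1], sel))
  }
  lines <- c(lines, "deselect", "orient protein")
  writeLines(lines, path)
  invisible(path)
}
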