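# Ligand-centric evaluation of ranked pocket predictions.
#
# A predicted pocket identifies a ligand when the DCC — the distance from
# the pocket's center to the closest ligand heavy atom — is at most the
# threshold (4 A by default). Only pockets ranked within the rank cutoff are
# considered: Top-n or Top-(n+2), where n is the number of relevant ligands
# in the structure (so a single-ligand protein gets the usual Top-1 / Top-3
# cutoffs). Every relevant ligand contributes with equal weight to the
# dataset success rate.

#' Evaluation configuration
#'
#' @param dcc_threshold identification threshold in Angstrom (default 4).
#' @param rank_cutoff_mode `"top_n"`, `"top_n_plus_2"`, or `"fixed_k"`.
#' @param fixed_k rank cutoff when `rank_cutoff_mode = "fixed_k"`.
#' @return an object of class `pr_eval_config`.
#' @export
evaluation_config <- function(dcc_threshold = 4,
                              rank_cutoff_mode = c("top_n", "top_n_plus_2",
                                                   "fixed_k"),
                              fixed_k = NULL) {
  stopifnot(dcc_threshold > 0)
  mode <- match.arg(rank_cutoff_mode)
  if (mode == "fixed_k" && (is.null(fixed_k) || fixed_k < 1))
    stop("fixed_k mode needs fixed_k >= 1")
  structure(list(dcc_threshold = dcc_threshold,
                 rank_cutoff_mode = mode,
                 fixed_k = fixed_k),
            class = "pr_eval_config")
}

#' DCC: distance from pocket center to the closest ligand atom
#'
#' @param pocket a `pr_pocket` (or a numeric 3-vector center).
#' @param ligand a `pr_ligand` with at least one heavy atom.
#' @return distance in Angstrom.
#' @export
dcc <- function(pocket, ligand) {
  center <- if (inherits(pocket, "pr_pocket")) pocket$center else pocket
  stopifnot(length(center) == 3, nrow(ligand$atoms) >= 1)
  min(cross_dist(matrix(center, 1, 3), ligand_coords(ligand)))
}

.rank_cutoff <- function(n_ligands, config) {
  switch(config$rank_cutoff_mode,
         top_n = n_ligands,
         top_n_plus_2 = n_ligands + 2L,
         fixed_k = config$fixed_k)
}

#' Evaluate ranked pockets against the relevant ligands of one structure
#'
#' Only pockets with rank <= cutoff are considered (all of them when fewer
#' were predicted). A ligand is identified iff some considered pocket has
#' DCC <= the threshold; one pocket may identify several ligands and each
#' ligand needs only one identifying pocket.
#'
#' @param pockets ranked list of `pr_pocket`.
#' @param ligands list of relevant `pr_ligand`; must be non-empty.
#' @param config a `pr_eval_config`.
#' @param structure_id id string recorded in the output.
#' @return data frame with one row per ligand: `structure_id`, `ligand_id`,
#'   `identified`, `best_dcc` (over considered pockets; `NA` when none),
#'   `identifying_rank` (best rank achieving DCC <= threshold, or `NA`).
#' @export
evaluate_structure <- function(pockets, ligands,
                               config = evaluation_config(),
                               structure_id = "structure") {
  n <- length(ligands)
  if (n == 0) stop("structure has no relevant ligands to evaluate")
  cutoff <- .rank_cutoff(n, config)
  considered <- Filter(function(p) p$rank <= cutoff, pockets)
  rows <- lapply(seq_along(ligands), function(i) {
    lig <- ligands[[i]]
    lig_id <- paste0(lig$residue_name, "_", lig$chain, lig$resno)
    if (length(considered) == 0) {
      return(data.frame(structure_id = structure_id, ligand_id = lig_id,
                        identified = FALSE, best_dcc = NA_real_,
                        identifying_rank = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    d <- vapply(considered, dcc, numeric(1), ligand = lig)
    hit <- d <= config$dcc_threshold
    data.frame(structure_id = structure_id, ligand_id = lig_id,
               identified = any(hit), best_dcc = min(d),
               identifying_rank = if (any(hit))
                 as.integer(min(vapply(considered[hit],
                                       function(p) as.numeric(p$rank),
                                       numeric(1))))
               else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate predictions over a dataset
#'
#' Pools per-ligand outcomes across structures; every relevant ligand
#' counts with equal weight. Structures with zero relevant ligands are
#' skipped with a note.
#'
#' @param predictions list with one element per structure, each a list with
#'   `id`, `pockets` (ranked `pr_pocket` list) and `ligands` (relevant
#'   `pr_ligand` list).
#' @param config a `pr_eval_config`.
#' @return an object of class `pr_eval_report`: `per_ligand` data frame,
#'   `success_rate`, `n_structures` (contributing structures) and
#'   `n_ligands`.
#' @export
evaluate_dataset <- function(predictions, config = evaluation_config()) {
  rows <- list()
  n_contrib <- 0L
  for (p in predictions) {
    if (length(p$ligands) == 0) {
      message("structure ", p$id %||% "?",
              " has no relevant ligands; excluded from evaluation")
      next
    }
    n_contrib <- n_contrib + 1L
    rows[[length(rows) + 1L]] <-
      evaluate_structure(p$pockets, p$ligands, config,
                         structure_id = p$id %||% "structure")
  }
  if (length(rows) == 0)
    stop("no structure with relevant ligands; nothing to evaluate")
  per_ligand <- do.call(rbind, rows)
  structure(list(per_ligand = per_ligand,
                 success_rate = mean(per_ligand$identified),
                 n_structures = n_contrib,
                 n_ligands = nrow(per_ligand),
                 config = config),
            class = "pr_eval_report")
}

#' @export
print.pr_eval_report <- function(x, ...) {
  cat(sprintf(
    "<pr_eval_report> %d ligand(s) over %d structure(s): success rate %.1f%% (%s, DCC <= %.1f A)\n",
    x$n_ligands, x$n_structures, 100 * x$success_rate,
    x$config$rank_cutoff_mode, x$config$dcc_threshold))
  invisible(x)
}
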