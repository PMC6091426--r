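# Ligandability model: supervision from bound ligands, Random Forest
# training, and point scoring.
#
# Supervision: a SAS point is a positive example iff it lies within
# `positive_cutoff` of a heavy atom of a relevant ligand — SAS points are
# potential locations of ligand contact atoms, so a near-contact distance
# is the natural criterion. Negatives vastly outnumber positives on any
# surface, so they are randomly subsampled to a configurable ratio before
# training.

#' Model configuration
#'
#' Defaults follow the reference setup of the predictor: a forest of 200
#' trees grown with no depth limit, 6 candidate features per split.
#'
#' @param n_trees number of trees (default 200).
#' @param features_per_split candidate features per split (`mtry`); capped
#'   at the schema length (default 6).
#' @param random_seed seed controlling forest growth and negative
#'   subsampling (default 42).
#' @param positive_cutoff labeling distance in Angstrom: points within this
#'   distance of a relevant-ligand heavy atom are positives (default 2.5).
#' @param negative_ratio negatives kept per positive when subsampling
#'   (default 10); `Inf` keeps all negatives.
#' @param schema feature schema the model is trained and scored under.
#' @return an object of class `pr_model_config`.
#' @export
model_config <- function(n_trees = 200L,
                         features_per_split = 6L,
                         random_seed = 42L,
                         positive_cutoff = 2.5,
                         negative_ratio = 10,
                         schema = default_feature_schema()) {
  stopifnot(n_trees >= 1, features_per_split >= 1, positive_cutoff > 0,
            negative_ratio >= 1, length(schema) >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = as.integer(
                   min(features_per_split, length(schema))),
                 random_seed = as.integer(random_seed),
                 positive_cutoff = positive_cutoff,
                 negative_ratio = negative_ratio,
                 schema = schema),
            class = "pr_model_config")
}

#' Label SAS points from bound ligands
#'
#' A point is positive iff its distance to any heavy atom of any supplied
#' (relevant) ligand is at most `cutoff`. With no ligands, every point is
#' negative and a warning is raised (the structure contributes only
#' negative examples).
#'
#' @param cloud a `pr_sas_cloud`.
#' @param ligands list of `pr_ligand` (typically [relevant_ligands()]).
#' @param cutoff positive labeling distance in Angstrom.
#' @return the cloud with logical `labels` set (`TRUE` = positive).
#' @export
label_points <- function(cloud, ligands, cutoff = 2.5) {
  stopifnot(inherits(cloud, "pr_sas_cloud"), cutoff > 0)
  n <- nrow(cloud$points)
  if (length(ligands) == 0) {
    warning("no relevant ligands: all ", n, " points labeled negative")
    cloud$labels <- rep(FALSE, n)
    return(cloud)
  }
  lig_xyz <- do.call(rbind, lapply(ligands, ligand_coords))
  lab <- rep(FALSE, n)
  for (block in .point_blocks(n)) {
    d <- cross_dist(cloud$points[block, , drop = FALSE], lig_xyz)
    lab[block] <- apply(d, 1, min) <= cutoff
  }
  cloud$labels <- lab
  cloud
}

#' Pool labeled training points from one or more clouds
#'
#' Concatenates feature matrices and labels, then randomly subsamples
#' negatives to `config$negative_ratio` per positive (seeded by
#' `config$random_seed`).
#'
#' @param clouds list of `pr_sas_cloud` with features and labels set.
#' @param config a `pr_model_config`.
#' @return list with `x` (feature matrix), `y` (logical labels), and
#'   `n_before` (class counts before subsampling).
#' @export
collect_training_points <- function(clouds, config = model_config()) {
  stopifnot(length(clouds) >= 1)
  for (cl in clouds) {
    if (is.null(cl$features) || is.null(cl$labels))
      stop("every cloud needs features and labels before training")
    if (!identical(colnames(cl$features), config$schema))
      stop("cloud feature schema does not match config schema")
  }
  x <- do.call(rbind, lapply(clouds, `[[`, "features"))
  y <- unlist(lapply(clouds, `[[`, "labels"))
  n_before <- c(positive = sum(y), negative = sum(!y))
  pos <- which(y); neg <- which(!y)
  n_keep <- min(length(neg), ceiling(config$negative_ratio * length(pos)))
  if (length(pos) > 0 && n_keep < length(neg)) {
    keep_neg <- with_seed(config$random_seed,
                          sort(sample(neg, n_keep)))
    idx <- sort(c(pos, keep_neg))
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  list(x = x, y = y, n_before = n_before)
}

#' Train the Random Forest ligandability classifier
#'
#' Fits a probability forest with `config$n_trees` trees, unlimited depth
#' and `config$features_per_split` candidate features per split. Training
#' is single-threaded and seeded, so a fixed config and training set give a
#' bit-identical model.
#'
#' @param x feature matrix (columns must equal `config$schema`).
#' @param y logical labels (`TRUE` = positive); both classes must be
#'   present.
#' @param config a `pr_model_config`.
#' @return an object of class `pr_model`.
#' @export
train_model <- function(x, y, config = model_config()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (!identical(colnames(x), config$schema))
    stop("training feature columns do not match config schema (",
         paste(config$schema, collapse = ", "), ")")
  y <- as.logical(y)
  if (all(y)) stop("training set has no negative points")
  if (!any(y)) stop("training set has no positive points")
  fac <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- ranger::ranger(
    x = as.data.frame(x), y = fac,
    num.trees = config$n_trees,
    mtry = config$features_per_split,
    min.node.size = 1,          # grow to purity: no depth limit
    probability = TRUE,
    seed = config$random_seed,
    num.threads = 1,
    verbose = FALSE)
  fit$call <- NULL  # drop environment-dependent call for reproducible RDS
  structure(list(forest = fit,
                 config = config,
                 schema = config$schema,
                 training_summary = c(positive = sum(y),
                                      negative = sum(!y)),
                 format_version = "pocketrank-model-1"),
            class = "pr_model")
}

#' @export
print.pr_model <- function(x, ...) {
  cat("<pr_model> ", x$config$n_trees, " trees, mtry ",
      x$config$features_per_split, ", schema: ",
      paste(x$schema, collapse = ", "), "\n  trained on ",
      x$training_summary["positive"], " positive / ",
      x$training_summary["negative"], " negative points\n", sep = "")
  invisible(x)
}

#' Score the ligandability of SAS points
#'
#' Each point's score is the forest's positive-class probability, in
#' `[0, 1]`. The cloud's feature schema must be identical to the schema the
#' model was trained under.
#'
#' @param model a `pr_model`.
#' @param cloud a `pr_sas_cloud` with features computed.
#' @return the cloud with `scores` set.
#' @export
score_points <- function(model, cloud) {
  stopifnot(inherits(model, "pr_model"), inherits(cloud, "pr_sas_cloud"))
  if (is.null(cloud$features))
    stop("cloud has no features; run compute_features() first")
  if (!identical(colnames(cloud$features), model$schema))
    stop("feature schema mismatch: model expects [",
         paste(model$schema, collapse = ", "), "], cloud provides [",
         paste(colnames(cloud$features), collapse = ", "), "]")
  pred <- predict(model$forest, data = as.data.frame(cloud$features),
                  num.threads = 1, verbose = FALSE)
  cloud$scores <- as.numeric(pred$predictions[, "pos"])
  cloud
}

#' Save / load a trained model archive
#'
#' The archive holds the serialized forest, its configuration, the feature
#' schema and a format-version string; [load_model()] rejects unknown
#' versions. Serialization is uncompressed RDS, so identical models give
#' byte-identical archives.
#'
#' @param model a `pr_model`.
#' @param path archive file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the `pr_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pr_model"))
  saveRDS(unclass(model), path, compress = FALSE, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format_version, "pocketrank-model-1"))
    stop("unsupported model format version: ",
         obj$format_version %||% "<missing>")
  structure(obj, class = "pr_model")
}
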