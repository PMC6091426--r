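# Output artifacts and command entry points.

train_demo_model <- function(n = 4, seed = 301, params = list()) {
  ds <- generate_dataset(n, fixture_spec(), dir = tempfile(), seed = seed)
  list(ds = ds,
       model = run_train(ds$dataset_file, model_out = NULL, seed = 42,
                         params = params))
}

test_that("prediction CSV honours the declared column contract", {
  demo <- train_demo_model(3)
  out <- tempfile()
  res <- run_predict(pdb = demo$ds$paths[1], model = demo$model,
                     output_dir = out)
  csvs <- list.files(out, pattern = "_predictions\\.csv$", full.names = TRUE)
  expect_length(csvs, 1)
  df <- read.csv(csvs[1], stringsAsFactors = FALSE,
                 colClasses = c(surface_atom_ids = "character",
                                residue_ids = "character"))
  expect_equal(colnames(df),
               c("name", "rank", "score", "center_x", "center_y", "center_z",
                 "surface_atom_ids", "residue_ids"))
  expect_gte(nrow(df), 1)
  expect_equal(df$rank[1], 1)
  expect_true(all(diff(df$rank) == 1))
  expect_true(all(grepl("^\\d+( \\d+)*$", df$surface_atom_ids)))
  expect_true(all(grepl("^[A-Z]_\\d+", df$residue_ids)))
  # run log records version and config
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("pocketrank .* predict", log)))
  expect_true(any(grepl("threshold = 0.35", log)))
})

test_that("a structure with no point above threshold yields a header-only CSV", {
  st <- toy_structure(random_atom_cloud(10, box = 4))
  path <- tempfile(fileext = ".csv")
  write_predictions_csv(list(), st, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 0)
  expect_equal(colnames(df)[1:3], c("name", "rank", "score"))
})

test_that("the PyMOL script references written files and the score gradient", {
  demo <- train_demo_model(3)
  out <- tempfile()
  run_predict(pdb = demo$ds$paths[1], model = demo$model, output_dir = out)
  pml <- list.files(out, pattern = "\\.pml$", full.names = TRUE)
  expect_length(pml, 1)
  script <- readLines(pml)
  expect_true(any(grepl("spectrum b, green_red, points, minimum=0, maximum=1",
                        script)))
  loaded <- sub("^load ([^,]+),.*", "\\1", grep("^load ", script, value = TRUE))
  # the points file it loads was actually written next to the script
  expect_true(basename(loaded[2]) %in% list.files(out))
  sel <- grep("^select pocket", script, value = TRUE)
  expect_length(sel, sum(grepl("^color ", script)))
})

test_that("a zero-pocket prediction still writes a valid PyMOL script", {
  st <- toy_structure(random_atom_cloud(5, box = 3))
  cloud <- toy_cloud(random_atom_cloud(5), scores = rep(0.1, 5))
  p <- tempfile(fileext = ".pml")
  write_pymol_script("x.pdb", "y.pdb", list(), p)
  script <- readLines(p)
  expect_true(any(grepl("spectrum b", script)))
  expect_false(any(grepl("select pocket", script)))
})

test_that("dataset prediction is independent of the thread count", {
  demo <- train_demo_model(4)
  out1 <- tempfile(); out2 <- tempfile()
  run_predict(dataset = demo$ds$dataset_file, model = demo$model,
              output_dir = out1, threads = 1, write_pymol = FALSE)
  run_predict(dataset = demo$ds$dataset_file, model = demo$model,
              output_dir = out2, threads = 2, write_pymol = FALSE)
  csvs <- sort(list.files(out1, pattern = "csv$"))
  expect_length(csvs, 4)
  for (f in csvs)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
})

test_that("per-structure failures in dataset mode do not stop the run", {
  demo <- train_demo_model(2)
  ds_dir <- dirname(demo$ds$dataset_file)
  lines <- readLines(demo$ds$dataset_file)
  writeLines(c(lines, "structures/missing.pdb"),
             file.path(ds_dir, "broken.ds"))
  out <- tempfile()
  expect_warning(
    res <- run_predict(dataset = file.path(ds_dir, "broken.ds"),
                       model = demo$model, output_dir = out,
                       write_pymol = FALSE, write_points = FALSE),
    "prediction failed")
  expect_length(list.files(out, pattern = "csv$"), 2)
})

test_that("train and eval commands round-trip through a model archive", {
  ds <- generate_dataset(4, fixture_spec(), dir = tempfile(), seed = 881)
  held <- generate_dataset(3, fixture_spec(), dir = tempfile(), seed = 882)
  model_path <- tempfile(fileext = ".rds")
  run_train(ds$dataset_file, model_path, seed = 42)
  expect_true(file.exists(model_path))
  out <- tempfile()
  reports <- suppressMessages(run_eval(held$dataset_file, model_path,
                                       output_dir = out))
  expect_true(reports$top_n$success_rate >= 0 &&
                reports$top_n$success_rate <= 1)
  expect_gte(reports$top_n_plus_2$success_rate, reports$top_n$success_rate)
  expect_true(file.exists(file.path(out, "evaluation_top_n.csv")))
  expect_true(file.exists(file.path(out, "evaluation_summary.txt")))
  # fixed_k = 3 on single-ligand structures equals Top-(n+2)
  rep_k <- suppressMessages(run_eval(held$dataset_file, model_path,
                                     fixed_k = 3))
  expect_equal(rep_k$fixed_k$success_rate,
               reports$top_n_plus_2$success_rate)
})

test_that("training twice with the same seed gives byte-identical archives", {
  ds <- generate_dataset(2, fixture_spec(), dir = tempfile(), seed = 883)
  f1 <- tempfile(); f2 <- tempfile()
  run_train(ds$dataset_file, f1, seed = 7,
            params = list(n_trees = 30))
  run_train(ds$dataset_file, f2, seed = 7,
            params = list(n_trees = 30))
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("config files override defaults and bad keys fail loudly", {
  cfg <- tempfile()
  writeLines(c("# comment", "", "threshold = 0.5",
               "schema = protrusion, atom_count_6"), cfg)
  got <- read_config_file(cfg)
  expect_equal(got$threshold, 0.5)
  expect_equal(got$schema, c("protrusion", "atom_count_6"))
  writeLines("oops", cfg)
  expect_error(read_config_file(cfg), "malformed config line")
})

test_that("exactly one input source must be given", {
  expect_error(run_predict(model = NULL), "exactly one")
  expect_error(run_predict(pdb = "a.pdb", dataset = "b.ds", model = NULL),
               "exactly one")
})
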