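# Thresholding, single-linkage clustering, pocket scoring and ranking.

test_that("candidate selection has an inclusive boundary and range guard", {
  cloud <- toy_cloud(random_atom_cloud(3), scores = c(0.2, 0.5, 0.9))
  expect_equal(select_candidate_points(cloud, 0.5), c(2L, 3L))
  expect_equal(select_candidate_points(cloud, 0), 1:3)
  expect_error(select_candidate_points(cloud, 1.01), "within \\[0, 1\\]")
  expect_error(select_candidate_points(cloud, -0.1), "within \\[0, 1\\]")
})

test_that("single-linkage chains points through the cutoff", {
  pts <- rbind(c(0, 0, 0), c(2.9, 0, 0), c(5.8, 0, 0))
  expect_length(cluster_points(pts, 3), 1)
  expect_length(cluster_points(rbind(c(0, 0, 0), c(3.1, 0, 0)), 3), 2)
  expect_equal(cluster_points(matrix(1, 1, 3), 3), list(1L))
  expect_equal(cluster_points(matrix(numeric(0), 0, 3), 3), list())
})

test_that("clustering equals connected components of the adjacency graph", {
  set.seed(77)
  for (trial in 1:20) {
    n <- sample(5:200, 1)
    pts <- random_atom_cloud(n, box = 10)
    got <- canonical_partition(cluster_points(pts, 3))
    want <- canonical_partition(bf_components(pts, 3))
    expect_equal(got, want)
  }
})

test_that("partitions refine under smaller cutoffs", {
  set.seed(78)
  pts <- random_atom_cloud(120, box = 10)
  coarse <- cluster_points(pts, 4)
  fine <- cluster_points(pts, 2)
  # every fine cluster sits inside exactly one coarse cluster
  coarse_id <- integer(120)
  for (k in seq_along(coarse)) coarse_id[coarse[[k]]] <- k
  for (cl in fine) expect_length(unique(coarse_id[cl]), 1)
})

test_that("pocket score is the sum of squared member scores", {
  cloud <- toy_cloud(rbind(c(0, 0, 0), c(2, 0, 0)), scores = c(0.5, 0.5))
  p <- finalize_pocket(1:2, cloud)
  expect_equal(p$score, 0.5, tolerance = 1e-9)
  expect_equal(unname(p$center), c(1, 0, 0))
})

test_that("ranking favours confident points and breaks ties deterministically", {
  cloud <- toy_cloud(rbind(c(0, 0, 0), c(10, 0, 0), c(12, 0, 0)),
                     scores = c(0.9, 0.5, 0.5))
  pockets <- score_and_rank(list(1L, 2:3), cloud, min_cluster_size = 1)
  expect_equal(vapply(pockets, `[[`, numeric(1), "score"), c(0.81, 0.5),
               tolerance = 1e-9)
  expect_equal(vapply(pockets, `[[`, integer(1), "rank"), 1:2)
  # exact score tie (1.0 both): larger cluster wins
  cloud2 <- toy_cloud(rbind(c(0, 0, 0), c(10, 0, 0), c(12, 0, 0)),
                      scores = c(1, 1, 0))
  pockets2 <- score_and_rank(list(1L, 2:3), cloud2, min_cluster_size = 1)
  expect_equal(length(pockets2[[1]]$point_idx), 2)
  # full tie on score and size: lexicographically smaller center wins
  cloud3 <- toy_cloud(rbind(c(5, 0, 0), c(-5, 0, 0)), scores = c(1, 1))
  pockets3 <- score_and_rank(list(1L, 2L), cloud3, min_cluster_size = 1)
  expect_equal(unname(pockets3[[1]]$center), c(-5, 0, 0))
})

test_that("pocket ordering matches an independent re-scoring", {
  set.seed(90)
  for (trial in 1:5) {
    n <- 40
    cloud <- toy_cloud(random_atom_cloud(n, box = 30),
                       scores = runif(n))
    sizes <- c(5, 10, 10, 15)
    idx <- split(sample(n), rep(1:4, sizes))
    pockets <- score_and_rank(idx, cloud, min_cluster_size = 1)
    want <- sort(vapply(idx, function(i) sum(cloud$scores[i]^2), numeric(1)),
                 decreasing = TRUE)
    expect_equal(unname(vapply(pockets, `[[`, numeric(1), "score")),
                 unname(want), tolerance = 1e-12)
  }
})

test_that("adding a positive-score point strictly increases a pocket score", {
  cloud <- toy_cloud(random_atom_cloud(5), scores = c(0.4, 0.5, 0.6, 0.01, 0))
  s3 <- finalize_pocket(1:3, cloud)$score
  s4 <- finalize_pocket(1:4, cloud)$score
  expect_gt(s4, s3)
  expect_equal(finalize_pocket(c(1:3, 5), cloud)$score, s3)  # zero adds nothing
})

test_that("small clusters are discarded and ranks stay consecutive", {
  cloud <- toy_cloud(random_atom_cloud(6), scores = rep(0.8, 6))
  pockets <- score_and_rank(list(1:3, 4L, 5:6), cloud, min_cluster_size = 2)
  expect_length(pockets, 2)
  expect_equal(vapply(pockets, `[[`, integer(1), "rank"), 1:2)
  scores <- vapply(pockets, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
})

test_that("pocket surface atoms and residues come from a contact scan", {
  st <- toy_structure(rbind(c(0, 0, -3), c(0, 0, 3), c(20, 0, 0)),
                      chain = c("A", "B", "B"), resno = c(1, 7, 8))
  cloud <- toy_cloud(rbind(c(0, 0, -1), c(0, 0, 1)), scores = c(1, 1),
                     structure = st)
  p <- finalize_pocket(1:2, cloud, contact_cutoff = 2.5)
  expect_setequal(p$surface_atoms, 1:2)
  expect_setequal(p$residue_ids, c("A_1", "B_7"))
})

test_that("a carved pocket on a two-chain fixture spans both chains", {
  fx <- generate_fixture(fixture_spec(n_chains = 2, seed = 15,
                                      pocket_directions = c(1, 0, 0)))
  st <- load_structure(fx$path)
  expect_equal(st$chains, c("A", "B"))
  cloud <- generate_sas_points(st)
  # score synthetically: points near the known pocket mouth are positive
  d <- sqrt(colSums((t(cloud$points) - fx$bite_centers[1, ])^2))
  cloud$scores <- ifelse(d < 6, 1, 0)
  pockets <- extract_pockets(cloud, threshold = 0.5)
  expect_gte(length(pockets), 1)
  chains <- unique(substr(pockets[[1]]$residue_ids, 1, 1))
  expect_setequal(chains, c("A", "B"))
  # chain tokens verified against a brute-force contact scan
  px <- as.matrix(st$atoms[, c("x", "y", "z")])
  near <- rep(FALSE, nrow(px))
  for (i in seq_len(nrow(pockets[[1]]$member_points)))
    near <- near | sqrt(colSums((t(px) - pockets[[1]]$member_points[i, ])^2)) <= 3.5
  expect_setequal(pockets[[1]]$surface_atoms, which(near))
})

test_that("identical inputs give identical pocket lists", {
  set.seed(91)
  cloud <- toy_cloud(random_atom_cloud(80, box = 8), scores = runif(80))
  p1 <- extract_pockets(cloud, threshold = 0.3, min_cluster_size = 2)
  p2 <- extract_pockets(cloud, threshold = 0.3, min_cluster_size = 2)
  expect_identical(p1, p2)
})
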