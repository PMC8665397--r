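test_that("degenerate cluster counts behave: k = 1 and k = n", {
  bl <- blob_embeddings(n = 12, k = 3, d = 4, seed = 1)
  one <- fit_kmeans(bl$X, 1, seed = 2)
  expect_true(all(one$assignment == 1))
  U <- bl$X$vectors / sqrt(rowSums(bl$X$vectors^2))
  expect_equal(as.numeric(one$centroids), colMeans(U), tolerance = 1e-12)

  full <- fit_kmeans(bl$X, 12, seed = 2)
  expect_equal(full$inertia, 0, tolerance = 1e-12)
  expect_length(unique(full$assignment), 12)

  expect_error(fit_kmeans(bl$X, 13, seed = 1), class = "credlift_cluster_error")
})

test_that("two far-separated blobs are recovered exactly and reproducibly", {
  bl <- blob_embeddings(n = 200, k = 2, d = 8, seed = 4)
  m1 <- fit_kmeans(bl$X, 2, seed = 5)
  # perfect agreement with the generating partition, up to label switching
  tab <- table(bl$member, m1$assignment)
  expect_equal(sum(apply(tab, 1, max)), 200)

  m2 <- fit_kmeans(bl$X, 2, seed = 5)
  expect_identical(m1$assignment, m2$assignment)

  # cross-check against stats::kmeans on the same normalized matrix
  U <- bl$X$vectors / sqrt(rowSums(bl$X$vectors^2))
  km <- stats::kmeans(U, centers = 2, nstart = 5)
  tab2 <- table(km$cluster, m1$assignment)
  expect_equal(sum(apply(tab2, 1, max)), 200)
  expect_equal(m1$inertia, km$tot.withinss, tolerance = 1e-8)
})

test_that("fitted models satisfy their invariants on random instances", {
  for (seed in 1:3) {
    bl <- blob_embeddings(n = 60, k = 4, d = 6, seed = seed, spread = 0.5)
    m <- fit_kmeans(bl$X, 5, seed = seed)
    expect_setequal(unique(m$assignment), 1:5)  # no empty clusters
    expect_true(all(m$distance >= 0 & m$distance <= 2))
    expect_gte(m$inertia, 0)
    # local optimality: assigned centroid is the Euclidean-nearest
    U <- bl$X$vectors / sqrt(rowSums(bl$X$vectors^2))
    d2 <- outer(rowSums(U^2), rowSums(m$centroids^2), "+") - 2 * U %*% t(m$centroids)
    expect_identical(unname(m$assignment), max.col(-d2, ties.method = "first"))
  }
})

test_that("elbow selection finds the generating cluster count and honors the tie rule", {
  bl <- blob_embeddings(n = 150, k = 5, d = 8, seed = 6)
  sel <- select_k_elbow(bl$X, 2:12, seed = 7)
  expect_equal(sel$k, 5)
  expect_identical(sel$table$k, 2:12)

  expect_error(select_k_elbow(bl$X, 2:3, seed = 1), class = "credlift_cluster_error")

  # exactly linear inertia: no elbow, all chord distances zero, smallest k wins
  lin <- credlift:::chord_distances(2:8, seq(70, 10, by = -10))
  expect_true(all(abs(lin) < 1e-12))

  # single compact blob: flat curve, small k expected (pinned regression value)
  single <- blob_embeddings(n = 80, k = 1, d = 6, seed = 8, spread = 1)
  flat <- select_k_elbow(single$X, 2:10, seed = 9)
  expect_lte(flat$k, 4)
})

test_that("pivots are the most central sentences, disjoint across clusters", {
  model <- structure(list(
    k = 2L,
    centroids = diag(2),
    assignment = c(a = 1L, b = 1L, c = 1L, d = 2L),
    distance = c(a = 0.1, b = 0.3, c = 0.2, d = 0.05),
    inertia = 0.1, seed = 1L
  ), class = "cluster_model")
  pv <- suppressWarnings(pivots(model, 2))
  expect_identical(pv[["1"]], c("a", "c"))
  expect_identical(pv[["2"]], "d")                 # cluster smaller than m
  pv5 <- suppressWarnings(pivots(model, 5))
  expect_identical(pv5[["1"]], c("a", "c", "b"))   # truncation returns all

  # random model: disjointness and membership, |union| <= k*m
  bl <- blob_embeddings(n = 90, k = 3, d = 5, seed = 10)
  m <- fit_kmeans(bl$X, 3, seed = 10)
  pv <- pivots(m, 4)
  all_ids <- unlist(pv)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_lte(length(all_ids), 3 * 4)
  for (j in 1:3) expect_true(all(m$assignment[pv[[as.character(j)]]] == j))
})

test_that("a large initial annotation budget triggers the 15% warning", {
  bl <- blob_embeddings(n = 40, k = 2, d = 4, seed = 11)
  m <- fit_kmeans(bl$X, 2, seed = 11)
  expect_warning(pivots(m, 10), class = "credlift_pivot_fraction_warning")
  expect_silent(pivots(m, 3))  # 6/40 = 15% exactly, not exceeded
})
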