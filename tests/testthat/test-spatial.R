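test_that("straight-line COM distance matches the formula", {
  expect_equal(com_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(com_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  for (i in 1:10) {
    p <- rnorm(3, sd = 1e4); q <- rnorm(3, sd = 1e4)
    expect_equal(com_distance(p, q),
                 sqrt((q[1] - p[1])^2 + (q[2] - p[2])^2 + (q[3] - p[3])^2))
  }
  expect_error(com_distance(c(Inf, 0, 0), c(0, 0, 0)), "finite")
})

test_that("displacement from centre converts nm to um and checks frames", {
  expect_equal(displacement_from_center(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(displacement_from_center(c(2500, 0, 0), c(0, 0, 0)), 2.5)
  expect_error(displacement_from_center(c(0, 0, 0), c(0, 0, 0),
                                        frame = list("volA", "volB")),
               "different coordinate frames")
})

test_that("distance matrix equals the O(n^2) loop and its invariants hold", {
  set.seed(4)
  pts <- matrix(rnorm(30, sd = 1000), 10, 3)
  dm <- distance_matrix(pts, object_ids = 1:10)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    brute[i, j] <- sqrt(sum((pts[i, ] - pts[j, ])^2))
  expect_equal(unclass(dm), brute, ignore_attr = TRUE)
  expect_equal(dm, t(dm), ignore_attr = TRUE)
  expect_true(all(diag(dm) == 0))
  ## triangle inequality
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  expect_error(distance_matrix(pts[1, , drop = FALSE]), "at least 2")
})

test_that("distance matrix commutes with relabelling", {
  set.seed(5)
  pts <- matrix(rnorm(24, sd = 500), 8, 3)
  perm <- sample(8)
  dm <- unclass(distance_matrix(pts))
  dmp <- unclass(distance_matrix(pts[perm, ]))
  expect_equal(dmp, dm[perm, perm], ignore_attr = TRUE)
})

test_that("radial ranking numbers chromosomes by descending volume", {
  ch <- data.frame(object_id = 1:3, volume_um3 = c(9, 5, 7),
                   com_x_nm = c(0, 3000, 0), com_y_nm = 0, com_z_nm = 0)
  rr <- radial_ranking(ch, c(0, 0, 0))
  expect_equal(rr$object_id, c(1L, 3L, 2L))
  expect_equal(rr$rank, 1:3)
  expect_equal(rr$distance_from_center_nm[3], 3000)
  one <- radial_ranking(ch[1, ], c(0, 0, 0))
  expect_equal(nrow(one), 1)
  expect_equal(one$rank, 1)
})

test_that("mutual-kNN network equals exhaustive enumeration on small n", {
  set.seed(6)
  for (trial in 1:5) {
    n <- sample(4:10, 1)
    pts <- matrix(rnorm(3 * n, sd = 100), n, 3)
    k <- sample(1:(n - 2), 1)
    dm <- distance_matrix(pts, object_ids = seq_len(n))
    g <- build_network(dm, k = k)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    ## oracle: enumerate each node's k nearest, edge iff mutual
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      nn_i <- order(dm[i, -i])[seq_len(k)]
      nn_i <- (seq_len(n)[-i])[nn_i]
      nn_j <- order(dm[j, -j])[seq_len(k)]
      nn_j <- (seq_len(n)[-j])[nn_j]
      expect_equal(adj[i, j] == 1, (j %in% nn_i) && (i %in% nn_j))
    }
    expect_equal(adj, t(adj))
    expect_true(all(igraph::degree(g) <= k))
  }
})

test_that("network edge sets grow monotonically in k", {
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 100), 10, 3)
  dm <- distance_matrix(pts, object_ids = 1:10)
  prev <- character(0)
  for (k in 1:6) {
    g <- build_network(dm, k = k)
    ed <- apply(igraph::as_edgelist(g), 1, function(r)
      paste(sort(r), collapse = "-"))
    expect_true(all(prev %in% ed))
    prev <- ed
  }
})

test_that("two points with k = 1 give a single edge; k >= n errors", {
  dm <- distance_matrix(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE),
                        object_ids = 1:2)
  g <- build_network(dm, k = 1)
  expect_equal(igraph::ecount(g), 1)
  expect_error(build_network(dm, k = 2), "smaller")
})

test_that("silhouette-selected K recovers planted blobs with pure labels", {
  b3 <- gaussian_blobs(3, 20, sep_sd = 40, seed = 11)
  cl <- kmeans_silhouette(b3$points, seed = 11)
  expect_equal(cl$k, 3)
  expect_equal(label_purity(cl$labels, b3$labels), 1)
  b2 <- gaussian_blobs(2, 20, sep_sd = 40, seed = 12)
  expect_equal(kmeans_silhouette(b2$points, seed = 12)$k, 2)
  expect_error(kmeans_silhouette(matrix(0, 2, 3), seed = 1), "at least 3")
  expect_error(kmeans_silhouette(matrix(1, 5, 3), seed = 1), "degenerate")
})

test_that("k-means result is deterministic for a fixed seed", {
  b <- gaussian_blobs(3, 15, sep_sd = 30, seed = 13)
  c1 <- kmeans_silhouette(b$points, seed = 99)
  c2 <- kmeans_silhouette(b$points, seed = 99)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$silhouette, c2$silhouette)
})

test_that("BIC-selected mixture recovers separated components", {
  b2 <- gaussian_blobs(2, 25, sep_sd = 40, seed = 14)
  g <- gmm_cluster(b2$points, max_components = 5, seed = 14)
  expect_equal(g$k, 2)
  expect_equal(label_purity(g$labels, b2$labels), 1)
  g1 <- gmm_cluster(b2$points, max_components = 1, seed = 14)
  expect_equal(g1$k, 1)
  expect_true(all(g1$labels == 1))
})

test_that("GMM reports the cluster containing the sex chromosomes", {
  b2 <- gaussian_blobs(2, 20, sep_sd = 50, seed = 15)
  rownames(b2$points) <- paste0("chr", seq_len(nrow(b2$points)))
  ## place "X" and "Y" inside blob 1
  g <- gmm_cluster(b2$points, max_components = 3, seed = 15,
                   sex_ids = c("chr1", "chr2"))
  expect_true(all(c("chr1", "chr2") %in% g$sex_cluster_members))
  ## co-members of the sex cluster are majority blob-1 points
  mem_idx <- match(g$sex_cluster_members, rownames(b2$points))
  expect_gt(mean(b2$labels[mem_idx] == 1), 0.9)
})

test_that("within-cluster nearest neighbour equals brute force", {
  pts <- matrix(c(0, 0, 0, 3000, 0, 0, 0, 4000, 0), 3, 3, byrow = TRUE)
  nn <- nn_within_clusters(pts, c(1, 1, 2))
  expect_equal(nn[1:2], c(3, 3))           # um
  expect_true(is.na(nn[3]))                # singleton flagged undefined
  set.seed(16)
  pts2 <- matrix(rnorm(60, sd = 2000), 20, 3)
  lab <- sample(1:3, 20, replace = TRUE)
  nn2 <- nn_within_clusters(pts2, lab)
  for (i in 1:20) {
    same <- setdiff(which(lab == lab[i]), i)
    if (!length(same)) expect_true(is.na(nn2[i]))
    else expect_equal(nn2[i],
                      min(sapply(same, function(j)
                        sqrt(sum((pts2[i, ] - pts2[j, ])^2)))) / 1000)
  }
})
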