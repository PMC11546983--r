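# Shared small fixtures ------------------------------------------------------

two_blob_features <- function(n1 = 10, n2 = 10, sep = 20, sd = 0.5,
                              seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * 2, 0, sd), ncol = 2),
             matrix(rnorm(n2 * 2, sep, sd), ncol = 2))
  list(x = x, truth = rep(1:2, c(n1, n2)))
}

block_distance <- function(n1 = 6, n2 = 6, between = 0.1) {
  d <- matrix(between, n1 + n2, n1 + n2)
  d[1:n1, 1:n1] <- 0
  d[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 0
  diag(d) <- 0
  d
}

test_that("k-means recovers planted blobs and honours edge cases", {
  blobs <- two_blob_features()
  res <- cluster_kmeans(blobs$x, 2, seed = 1)
  expect_s3_class(res, "cluster_result")
  expect_true(same_partition(res$labels, blobs$truth))
  expect_equal(res$k_found, 2L)

  x <- matrix(c(0, 1, 5, 6, 10, 11), ncol = 1)
  all_own <- cluster_kmeans(x, 6, seed = 1)
  expect_equal(all_own$sse, 0)
  expect_equal(all_own$k_found, 6L)

  one <- cluster_kmeans(x, 1, seed = 1)
  expect_equal(unname(one$centers[1, 1]), mean(x))
  expect_error(cluster_kmeans(x, 7), "between")
})

test_that("k-means refinement does not increase the SSE", {
  blobs <- two_blob_features(sd = 3)
  coarse <- cluster_kmeans(blobs$x, 3, seed = 2, n_init = 1, iter_max = 1)
  refined <- cluster_kmeans(blobs$x, 3, seed = 2, n_init = 1,
                            iter_max = 100)
  expect_lte(refined$sse, coarse$sse + 1e-12)
  multi <- cluster_kmeans(blobs$x, 3, seed = 2, n_init = 20)
  expect_lte(multi$sse, refined$sse + 1e-12)
})

test_that("complete linkage recovers blocks and matches the merge oracle", {
  d <- block_distance()
  res <- cluster_hclust(d, 2)
  expect_true(same_partition(res$labels, rep(1:2, each = 6)))

  chain <- matrix(c(0, 1, 4, 5,
                    1, 0, 3, 4,
                    4, 3, 0, 1,
                    5, 4, 1, 0), 4, 4)
  expect_true(same_partition(cluster_hclust(chain, 2)$labels,
                             c(1, 1, 2, 2)))

  expect_equal(cluster_hclust(chain, 4)$k_found, 4L)

  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    x <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(x))
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(cluster_hclust(d, k)$labels,
                               oracle_complete_linkage(d, k)))
  }
})

test_that("Brunet NMF clusters block structure with non-increasing divergence", {
  v <- rbind(cbind(matrix(5, 4, 3), matrix(0, 4, 2)),
             cbind(matrix(0, 4, 3), matrix(7, 4, 2)))
  res <- cluster_nmf(v, 2, nrun = 5, seed = 3, trace = TRUE)
  expect_true(same_partition(res$labels, rep(1:2, each = 4)))
  expect_true(all(diff(res$trace) <= 1e-8))

  expect_equal(cluster_nmf(v, 1, nrun = 2, seed = 3)$k_found, 1L)
  expect_error(cluster_nmf(-v, 2), "non-negative")
  expect_error(cluster_nmf(v, 5), "rank")

  # distance-matrix input: two zero-diagonal blocks separate by rank 2
  d <- block_distance(5, 5, between = 0.2)
  res <- cluster_nmf(d, 2, nrun = 10, seed = 4)
  expect_true(same_partition(res$labels, rep(1:2, each = 5)))
})

test_that("DBSCAN finds dense groups, noise, and border points", {
  d <- block_distance(25, 25, between = 5)   # coincident points, 10x eps
  res <- cluster_dbscan(d, eps = 0.5, min_pts = 20)
  expect_equal(res$k_found, 2L)
  expect_equal(sum(res$labels == 0L), 0L)
  expect_true(same_partition(res$labels, rep(1:2, each = 25)))

  far <- as.matrix(dist(matrix(c(0, 10, 20, 30), ncol = 1)))
  res <- cluster_dbscan(far, eps = 1, min_pts = 2)
  expect_equal(res$k_found, 0L)
  expect_true(all(res$labels == 0L))

  # 1-D: points 0,0.5,1 are a core cluster (min_pts 3 within eps 1);
  # border point 1.9 is reachable only from the core at 1
  x <- matrix(c(0, 0.5, 1, 1.9, 5), ncol = 1)
  d <- as.matrix(dist(x))
  res <- cluster_dbscan(d, eps = 1, min_pts = 3)
  expect_equal(res$labels[1:4], rep(1L, 4))
  expect_equal(res$labels[5], 0L)
})

test_that("affinity propagation finds block structure without a preset k", {
  s <- matrix(0.1, 6, 6)
  s[1:3, 1:3] <- 0.9
  s[4:6, 4:6] <- 0.9
  res <- cluster_ap(s, seed = 1)
  expect_equal(res$k_found, 2L)
  expect_true(same_partition(res$labels, rep(1:2, each = 3)))
  expect_true(res$converged)

  expect_equal(cluster_ap(matrix(1, 1, 1))$k_found, 1L)

  # label equivariance under permutation of the similarity matrix
  perm <- c(4, 5, 6, 1, 2, 3)
  res_p <- cluster_ap(s[perm, perm], seed = 1)
  expect_true(same_partition(res_p$labels, res$labels[perm]))
})

test_that("consensus aligns labels, votes, and measures agreement", {
  base <- rep(1:2, each = 5)
  mk <- function(labels, alg = "kmeans")
    crypticscan:::new_cluster_result(alg, labels)
  res <- list(mk(base), mk(base, "hclust_complete"), mk(3 - base, "nmf"),
              mk(base, "dbscan"), mk(c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1), "ap"))
  cons <- consensus_partition(res)
  expect_true(cons$unanimous)            # permuted ids are the same partition
  expect_true(same_partition(cons$consensus_labels, base))
  expect_true(all(cons$agreement == 1))

  flipped <- base; flipped[1] <- 2
  cons2 <- consensus_partition(list(mk(base), mk(base, "hclust_complete"),
                                    mk(base, "nmf"), mk(flipped, "ap")))
  expect_false(cons2$unanimous)
  expect_true(same_partition(cons2$consensus_labels, base))

  # noise points cast no vote but still receive the majority label
  noisy <- base; noisy[10] <- 0L
  cons3 <- consensus_partition(list(mk(base), mk(base, "hclust_complete"),
                                    mk(noisy, "dbscan")))
  expect_true(same_partition(cons3$consensus_labels, base))

  expect_error(consensus_partition(list(mk(base), mk(base[-1]))),
               "different")
})
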