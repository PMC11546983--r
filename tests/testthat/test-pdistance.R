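test_that("p_distance applies pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGA"), list(distance = 0.25, n_valid = 4L))
  expect_equal(p_distance("AC-T", "ACGT"), list(distance = 0, n_valid = 3L))
  expect_equal(p_distance("A-CN", "ATCG"), list(distance = 0, n_valid = 2L))
  expect_error(p_distance("----", "ACGT"), "no overlapping")
  expect_error(p_distance("ACG", "ACGT"), "equal")
})

test_that("p_distance is symmetric, zero on self, and matches the loop oracle", {
  set.seed(11)
  for (i in 1:50) {
    a <- rand_seq(20, gap_prob = 0.1, amb_prob = 0.1)
    b <- rand_seq(20, gap_prob = 0.1, amb_prob = 0.1)
    got <- tryCatch(p_distance(a, b), error = function(e) NULL)
    want <- oracle_p_distance(a, b)
    if (is.null(got)) {
      expect_identical(want$n_valid, 0L)
    } else {
      expect_identical(got$distance, want$distance)
      expect_identical(got$n_valid, want$n_valid)
      expect_identical(p_distance(b, a)$distance, got$distance)
    }
    if (grepl("[ACGT]", a)) expect_equal(p_distance(a, a)$distance, 0)
  }
})

test_that("distance_matrix reproduces per-pair p-distances", {
  aln <- dna_alignment(c("a", "b", "c"), c("ACGT", "ACGA", "TCGA"))
  dm <- distance_matrix(aln)
  expect_equal(dm$d["a", "b"], 0.25)
  expect_equal(dm$d["a", "c"], 0.5)
  expect_equal(dm$d["b", "c"], 0.25)
  expect_equal(diag(dm$d), c(a = 0, b = 0, c = 0))

  aln3 <- dna_alignment(c("x", "y", "z"), rep("ACGTACGT", 3))
  expect_true(all(distance_matrix(aln3)$d == 0))

  set.seed(21)
  aln <- rand_alignment(10, 50, gap_prob = 0.08, amb_prob = 0.08)
  dm <- distance_matrix(aln)
  expect_true(isSymmetric(dm$d))
  for (i in 1:9) for (j in (i + 1):10) {
    want <- oracle_p_distance(aln$seqs[i], aln$seqs[j])
    expect_equal(dm$d[i, j], want$distance)
    expect_equal(unname(dm$n_valid[i, j]), want$n_valid)
  }
})

test_that("distance_matrix agrees with ape's pairwise-deletion raw distance", {
  set.seed(31)
  aln <- rand_alignment(12, 80, gap_prob = 0.05, amb_prob = 0)
  dm <- distance_matrix(aln)
  bin <- ape::as.DNAbin(strsplit(tolower(aln$seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                 pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(ref), tolerance = 1e-12)
})

test_that("min-max scaling maps extremes to 0 and 1 and preserves order", {
  expect_equal(scale_distances(c(0.02, 0.04, 0.06))$values, c(0, 0.5, 1))
  expect_equal(scale_distances(0.3)$values, 0)
  expect_equal(scale_distances(c(1, 2, 4))$values, c(0, 1 / 3, 1))
  expect_error(scale_distances(numeric(0)))
  set.seed(41)
  v <- runif(30)
  s <- scale_distances(v)
  expect_true(all(s$values >= 0 & s$values <= 1))
  expect_identical(order(s$values), order(v))
})

test_that("group distance sets have the right cardinalities and means", {
  set.seed(51)
  aln <- rand_alignment(22, 40, gap_prob = 0, amb_prob = 0)
  dm <- distance_matrix(aln)

  g18 <- group_distance_sets(dm, rep(c("A", "B"), c(18, 4)))
  expect_length(g18$within$A, 153)       # 18 members -> 18*17/2 unique pairs
  expect_length(g18$within$B, 6)
  expect_length(g18$between[["A|B"]], 72)
  expect_equal(g18$averages[["A"]], mean(g18$within$A))
  # count conservation: all pairs are either within or between
  total <- sum(lengths(g18$within)) + sum(lengths(g18$between))
  expect_equal(total, 22 * 21 / 2)

  # singleton groups produce only between-lists
  gs <- group_distance_sets(dm, c("solo", rep("A", 18), rep("B", 3)))
  expect_length(gs$between[["A|solo"]], 18)
  expect_false("solo" %in% names(gs$within))

  aln2 <- dna_alignment(c("p", "q"), c("AAAAAAAAAA", "AGAAAAAAAA"))
  g2 <- group_distance_sets(distance_matrix(aln2), c("x", "y"))
  expect_equal(g2$between[["x|y"]], 0.1)
  expect_equal(unname(g2$averages["x|y"]), 0.1)

  expect_error(group_distance_sets(dm, c(s01 = "A")), "label")
})

test_that("pairwise similarity is 1 - d and order-reversing", {
  set.seed(61)
  aln <- rand_alignment(8, 40)
  dm <- distance_matrix(aln)
  s <- pairwise_similarity(dm)
  expect_equal(unname(diag(s)), rep(1, 8))
  expect_equal(s, 1 - dm$d)
  ord_d <- order(dm$d[1, -1])
  ord_s <- order(s[1, -1], decreasing = TRUE)
  expect_identical(ord_d, ord_s)
})

test_that("distance TSV export round-trips", {
  aln <- dna_alignment(c("a", "b", "c"), c("ACGT", "ACGA", "TCGA"))
  dm <- distance_matrix(aln)
  sq <- tempfile(fileext = ".tsv"); lg <- tempfile(fileext = ".tsv")
  write_distance_tsv(dm, sq)
  write_distance_tsv(dm, lg, long = TRUE)
  back <- as.matrix(read.delim(sq, row.names = 1))
  expect_equal(unname(back), unname(dm$d))
  long <- read.delim(lg)
  expect_equal(nrow(long), 3)
  expect_equal(long$distance[long$id_a == "a" & long$id_b == "c"], 0.5)
})
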