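# Small separable fixture: a few fixed diagnostic columns among random
# noise columns, mimicking diagnostic sites on an encoded alignment.
separable_encoding <- function(n1 = 15, n2 = 15, L = 30, ndiag = 5,
                               seed = 17) {
  set.seed(seed)
  x <- matrix(sample(1:4, (n1 + n2) * L, replace = TRUE), n1 + n2, L)
  for (j in seq_len(ndiag)) x[, j] <- rep(c(1L, 4L), c(n1, n2))
  list(x = x, y = factor(rep(c("ref", "new"), c(n1, n2)),
                         levels = c("ref", "new")))
}

test_that("confusion metrics follow the precision/recall/F1 definitions", {
  m <- metrics_from_confusion(10, 0, 0, 10)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  m <- metrics_from_confusion(2, 2, 2, 0)
  expect_equal(c(m$precision, m$recall, m$f1), c(0.5, 0.5, 0.5))
  m <- metrics_from_confusion(0, 5, 3, 2)
  expect_equal(c(m$precision, m$recall, m$f1), c(0, 0, 0))
  expect_warning(m <- metrics_from_confusion(0, 0, 0, 0), "zero")
  expect_equal(m$f1, 0)
  expect_error(metrics_from_confusion(-1, 0, 0, 0))
})

test_that("roc_auc equals the pair-counting oracle and pROC", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")

  set.seed(19)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(runif(n), 2)          # induce some ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    got <- roc_auc(scores, labels)
    expect_equal(got, oracle_auc(scores, labels))
    ref <- suppressMessages(pROC::auc(labels, scores,
                                      direction = "<", quiet = TRUE))
    expect_equal(got, as.numeric(ref))
  }
})

test_that("all three models separate linearly separable encodings", {
  fix <- separable_encoding()
  bundle <- train_models(fix$x, fix$y, seed = 1, ntree = 100, hidden = 30,
                         epochs = 400)
  prob <- predict(bundle, fix$x)
  for (m in c("rf", "svm", "mlp"))
    expect_equal(roc_auc(prob[[m]], fix$y), 1)
  expect_error(train_models(fix$x, factor(rep("a", 30))), "two classes")
})

test_that("permuted labels drive cross-validated AUC to chance", {
  sim <- simulate_alignment(sim_config(length = 200,
                                       group_sizes = c(20, 15), seed = 23))
  x <- encode_ordinal(sim$alignment)
  set.seed(29)
  y_perm <- sample(factor(sim$true_labels))
  cv <- cross_validate(x, y_perm, folds = 5, seed = 31, ntree = 100,
                       hidden = 20, epochs = 50)
  for (m in c("rf", "svm", "mlp"))
    expect_lt(abs(cv$mean_auc[[m]] - 0.5), 0.25)
})

test_that("cross-validation partitions samples once each, stratified", {
  fix <- separable_encoding()
  cv <- cross_validate(fix$x, fix$y, folds = 5, seed = 7, ntree = 100,
                       hidden = 30, epochs = 400)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(as.vector(table(cv$fold_assignment)), rep(6, 5))
  # stratification: every fold holds both classes in proportion
  for (f in 1:5)
    expect_equal(as.vector(table(fix$y[cv$fold_assignment == f])), c(3, 3))
  # confusion counts sum to n per model
  for (m in c("rf", "svm", "mlp"))
    expect_equal(sum(cv$confusion[[m]]), 30)
  # separable data: perfect and stable
  expect_equal(unname(cv$mean_auc), rep(1, 3))
  expect_equal(unname(cv$sd_auc), rep(0, 3))
})

test_that("cross-validation is bit-reproducible under a fixed seed", {
  fix <- separable_encoding()
  a <- cross_validate(fix$x, fix$y, folds = 5, seed = 11, ntree = 50,
                      hidden = 10, epochs = 30)
  b <- cross_validate(fix$x, fix$y, folds = 5, seed = 11, ntree = 50,
                      hidden = 10, epochs = 30)
  expect_identical(a$mean_auc, b$mean_auc)
  expect_identical(a$per_fold, b$per_fold)
  expect_identical(a$confusion, b$confusion)
})

test_that("importance concentrates on diagnostic columns and normalises", {
  n1 <- 10; n2 <- 10
  y <- factor(rep(c("a", "b"), c(n1, n2)))
  x <- matrix(2L, n1 + n2, 8)             # constant background
  x[, 3] <- rep(c(1L, 4L), c(n1, n2))     # single informative column
  imp <- feature_importance(x, y, seed = 1, ntree = 100)
  expect_equal(imp$importance[3], 1)
  expect_equal(imp$importance[-3], rep(0, 7))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)

  expect_warning(imp0 <- feature_importance(matrix(1L, 10, 4),
                                            factor(rep(c("a", "b"), 5)),
                                            seed = 1, ntree = 20),
                 "constant")
  expect_equal(imp0$importance, rep(0, 4))

  # duplicating the diagnostic column splits its mass but keeps the total
  x2 <- cbind(x, x[, 3])
  imp2 <- feature_importance(x2, y, seed = 1, ntree = 200)
  expect_equal(imp2$importance[3] + imp2$importance[9], 1,
               tolerance = 1e-9)
})

test_that("key sites apply strict thresholds sorted by importance", {
  prof <- structure(list(importance = c(0, 0.5, 0.5),
                         column_index = 1:3),
                    class = "importance_profile")
  ks <- key_sites(prof, c(0, 0.1))
  expect_equal(ks[["0"]]$count, 2)
  expect_setequal(ks[["0"]]$columns, c(2, 3))

  prof$importance <- c(0.05, 0.15, 0.8)
  ks <- key_sites(prof, 0.1)
  expect_equal(ks[["0.1"]]$count, 2)
  expect_equal(ks[["0.1"]]$columns, c(3, 2))

  prof$importance <- rep(0, 3)
  expect_equal(key_sites(prof, 0)[["0"]]$count, 0)
})

test_that("logo data reports per-column base frequencies plus importance", {
  aln <- dna_alignment(c("a", "b", "c", "d"),
                       c("AAT-", "AATC", "ATTC", "ATNC"))
  prof <- structure(list(importance = c(0.7, 0.3, 0, 0),
                         column_index = 1:4),
                    class = "importance_profile")
  ld <- logo_data(aln, prof)
  expect_equal(ld$A[1], 1)
  expect_equal(ld$A[2], 0.5)
  expect_equal(ld$T[2], 0.5)
  expect_equal(ld$gap[4], 0.25)
  expect_equal(ld$gap[3], 0.25)            # N counts as the missing sink
  expect_equal(rowSums(ld[, c("A", "C", "G", "T", "gap")]),
               rep(1, 4), ignore_attr = TRUE)
  expect_equal(ld$importance, prof$importance)
  bad <- structure(list(importance = 0.5, column_index = 1),
                   class = "importance_profile")
  expect_error(logo_data(aln, bad), "length")
})
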