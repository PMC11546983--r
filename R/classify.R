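# Classifier bundle (random forest, SVM, multilayer perceptron) on
# ordinally encoded alignments: stratified cross-validation, confusion
# metrics, ROC/AUC, per-site importance and key-site summaries.

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, F1 their harmonic mean;
#' zero-denominator cases are defined as 0.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return Object of class `ml_metrics`: the counts plus `precision`,
#'   `recall`, `f1`.
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (all(counts == 0)) warning("all confusion counts are zero")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1),
            class = "ml_metrics")
}

#' @export
print.ml_metrics <- function(x, ...) {
  cat(sprintf("TP %d FP %d FN %d TN %d | precision %.3f recall %.3f f1 %.3f",
              x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f1))
  if (!is.null(x$auc)) cat(sprintf(" auc %.3f", x$auc))
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation: the probability that a
#' random positive scores above a random negative, ties counting one half.
#'
#' @param scores Numeric score (class-1 probability) per sample.
#' @param labels Binary ground truth (logical, 0/1, or two-level factor;
#'   the second factor level is positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Internal: coerce labels to 0/1 integer; for factors the second level is
# the positive class.
as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(as.vector(labels)))
  if (length(u) > 2L) stop("labels must be binary")
  as.integer(as.vector(labels) == u[length(u)])
}

# ---- multilayer perceptron (single hidden layer, SGD on log-loss) -------

# Forward pass helpers; hidden layer is ReLU, output is a sigmoid.
mlp_fit <- function(x, y01, hidden = 100L, epochs = 200L, lr = 0.01,
                    l2 = 1e-4, batch = 16L, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  n <- nrow(xs); d <- ncol(xs)
  w1 <- matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden)
  b1 <- numeric(hidden)
  w2 <- matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1L)
  b2 <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      xb <- xs[idx, , drop = FALSE]
      yb <- y01[idx]
      z1 <- sweep(xb %*% w1, 2L, b1, "+")
      h <- pmax(z1, 0)
      p <- 1 / (1 + exp(-(h %*% w2 + b2)))
      delta <- (p - yb) / length(idx)            # d(log-loss)/d(logit)
      g_w2 <- crossprod(h, delta) + l2 * w2
      g_b2 <- sum(delta)
      dh <- (delta %*% t(w2)) * (z1 > 0)
      g_w1 <- crossprod(xb, dh) + l2 * w1
      g_b1 <- colSums(dh)
      w2 <- w2 - lr * g_w2; b2 <- b2 - lr * g_b2
      w1 <- w1 - lr * g_w1; b1 <- b1 - lr * g_b1
    }
  }
  structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, mu = mu, sd = sdv,
                 hidden = hidden, epochs = epochs, lr = lr, l2 = l2),
            class = "crypticscan_mlp")
}

#' @export
predict.crypticscan_mlp <- function(object, newdata, ...) {
  x <- sweep(sweep(as.matrix(newdata), 2L, object$mu), 2L, object$sd, "/")
  h <- pmax(sweep(x %*% object$w1, 2L, object$b1, "+"), 0)
  as.vector(1 / (1 + exp(-(h %*% object$w2 + object$b2))))
}

# -------------------------------------------------------------------------

#' Train the three classifiers
#'
#' Fits a random forest, an RBF-kernel support vector machine (with Platt
#' probability estimates) and a single-hidden-layer multilayer perceptron
#' trained by stochastic gradient descent on the log-loss, all on the same
#' encoded matrix. Every stochastic element is seeded.
#'
#' @param x Numeric matrix (samples x sites), e.g. from [encode_ordinal()].
#' @param y Two-level factor (second level = positive class), or binary
#'   vector, with at least two samples per class.
#' @param seed Integer seed.
#' @param ntree Random-forest tree count.
#' @param hidden,epochs MLP hidden-layer width and SGD epochs.
#' @return Object of class `species_classifiers` with elements `rf`, `svm`,
#'   `mlp`, `levels`, `positive`.
#' @export
train_models <- function(x, y, seed = 1L, ntree = 500L, hidden = 100L,
                         epochs = 200L) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else
    factor(as_binary(y), levels = c(0L, 1L))
  if (nlevels(y) != 2L) stop("y must contain exactly two classes")
  if (any(table(y) < 2L)) stop("need at least two samples per class")
  y01 <- as.integer(y) - 1L
  colnames(x) <- paste0("site", seq_len(ncol(x)))
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree)
  set.seed(seed + 1L)
  sv <- e1071::svm(x, y, kernel = "radial", probability = TRUE,
                   scale = FALSE)
  mlp <- mlp_fit(x, y01, hidden = hidden, epochs = epochs,
                 seed = seed + 2L)
  structure(list(rf = rf, svm = sv, mlp = mlp, levels = levels(y),
                 positive = levels(y)[2L], seed = seed),
            class = "species_classifiers")
}

#' @export
print.species_classifiers <- function(x, ...) {
  cat("Classifier bundle (rf, svm, mlp); positive class:", x$positive, "\n")
  invisible(x)
}

#' Positive-class probabilities from a classifier bundle
#'
#' @param object A [train_models()] bundle.
#' @param newdata Numeric matrix with the same columns as the training
#'   matrix.
#' @param ... Unused.
#' @return Data frame with columns `rf`, `svm`, `mlp` of positive-class
#'   probabilities.
#' @export
predict.species_classifiers <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  colnames(x) <- paste0("site", seq_len(ncol(x)))
  p_rf <- stats::predict(object$rf, x, type = "prob")[, object$positive]
  sv <- stats::predict(object$svm, x, probability = TRUE)
  p_sv <- attr(sv, "probabilities")[, object$positive]
  p_mlp <- stats::predict(object$mlp, x)
  data.frame(rf = unname(p_rf), svm = unname(p_sv), mlp = p_mlp)
}

# Internal: stratified fold assignment. Each class is shuffled and dealt
# round-robin, continuing the deal across classes so overall fold sizes
# differ by at most one.
stratified_folds <- function(y, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  offset <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (offset + seq_along(idx) - 1L) %% folds + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validation of the three classifiers
#'
#' Folds are stratified by class (an imbalanced 65/30 grouping can
#' otherwise produce single-class test sets). Each fold is held out once;
#' per-fold precision/recall/F1 (probability threshold 0.5) and AUC are
#' reported per model, together with the per-model mean and standard
#' deviation of the AUC and the summed confusion matrix.
#'
#' @param x Numeric matrix (samples x sites).
#' @param y Two-level factor or binary vector.
#' @param folds Number of folds.
#' @param seed Integer master seed (fold split and per-fold model seeds are
#'   derived from it).
#' @param ... Passed to [train_models()] (e.g. `ntree`, `epochs`).
#' @return Object of class `cv_report`: `folds`, `per_fold` (model ->
#'   fold -> `ml_metrics` with `$auc`), `mean_auc`, `sd_auc`, `mean_f1`,
#'   `confusion` (model -> 2x2 matrix), `fold_assignment`, `seed`.
#' @export
cross_validate <- function(x, y, folds = 5L, seed = 1L, ...) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else
    factor(as_binary(y), levels = c(0L, 1L))
  if (nrow(x) < folds) stop("fewer samples than folds")
  fold <- stratified_folds(y, folds, seed = seed)
  models <- c("rf", "svm", "mlp")
  per_fold <- stats::setNames(
    lapply(models, function(m) vector("list", folds)), models)
  confusion <- stats::setNames(lapply(models, function(m)
    matrix(0L, 2L, 2L, dimnames = list(predicted = rev(levels(y)),
                                       truth = rev(levels(y))))), models)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L)
      stop("fold ", f, " has single-class training data; ",
           "use stratified folds or another seed")
    bundle <- train_models(x[tr, , drop = FALSE], y[tr],
                           seed = seed + f, ...)
    prob <- predict(bundle, x[te, , drop = FALSE])
    truth <- y[te]
    pos <- levels(y)[2L]; neg <- levels(y)[1L]
    for (m in models) {
      p <- prob[[m]]
      pred <- ifelse(p >= 0.5, pos, neg)
      tp <- sum(pred == pos & truth == pos)
      fp <- sum(pred == pos & truth == neg)
      fn <- sum(pred == neg & truth == pos)
      tn <- sum(pred == neg & truth == neg)
      met <- metrics_from_confusion(tp, fp, fn, tn)
      met$auc <- roc_auc(p, truth)
      per_fold[[m]][[f]] <- met
      confusion[[m]] <- confusion[[m]] +
        matrix(c(tp, fn, fp, tn), 2L, 2L)
    }
  }
  mean_auc <- vapply(per_fold, function(l)
    mean(vapply(l, `[[`, numeric(1), "auc")), numeric(1))
  sd_auc <- vapply(per_fold, function(l)
    stats::sd(vapply(l, `[[`, numeric(1), "auc")), numeric(1))
  mean_f1 <- vapply(per_fold, function(l)
    mean(vapply(l, `[[`, numeric(1), "f1")), numeric(1))
  structure(list(folds = folds, per_fold = per_fold, mean_auc = mean_auc,
                 sd_auc = sd_auc, mean_f1 = mean_f1, confusion = confusion,
                 fold_assignment = fold, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$folds, x$seed))
  for (m in names(x$mean_auc))
    cat(sprintf("  %-4s mean AUC %.3f (sd %.3f), mean F1 %.3f\n", m,
                x$mean_auc[m], x$sd_auc[m], x$mean_f1[m]))
  invisible(x)
}

#' Per-site random-forest importance profile
#'
#' Fits a random forest on all samples (no held-out split) and returns the
#' per-column mean decrease in Gini impurity, normalised to sum to 1.
#'
#' @param x Numeric matrix (samples x alignment columns).
#' @param y Two-level factor or binary vector.
#' @param seed Integer seed.
#' @param ntree Tree count.
#' @return Object of class `importance_profile`: list with `importance`
#'   (numeric, sums to 1 unless all-zero) and `column_index` (1-based).
#' @export
feature_importance <- function(x, y, seed = 1L, ntree = 500L) {
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else
    factor(as_binary(y), levels = c(0L, 1L))
  colnames(x) <- paste0("site", seq_len(ncol(x)))
  variable <- apply(x, 2L, function(col) length(unique(col)) > 1L)
  if (!any(variable)) {
    warning("constant input: all importances are zero")
    return(structure(list(importance = rep(0, ncol(x)),
                          column_index = seq_len(ncol(x)), forest = NULL),
                     class = "importance_profile"))
  }
  set.seed(seed)
  rf <- randomForest::randomForest(x, y, ntree = ntree)
  imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
  total <- sum(imp)
  if (total == 0) {
    warning("no informative splits: all importances are zero")
  } else {
    imp <- imp / total
  }
  structure(list(importance = unname(imp),
                 column_index = seq_len(ncol(x)), forest = rf),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, ...) {
  top <- order(x$importance, decreasing = TRUE)[1:min(6L, length(x$importance))]
  cat(sprintf("Importance profile over %d columns; top sites: %s\n",
              length(x$importance),
              paste(sprintf("%d (%.3f)", x$column_index[top],
                            x$importance[top]), collapse = ", ")))
  invisible(x)
}

#' Key diagnostic sites above importance thresholds
#'
#' @param profile An [feature_importance()] profile.
#' @param thresholds Numeric thresholds; sites with importance strictly
#'   greater than each threshold are reported.
#' @return Named list (one entry per threshold) of `list(count, columns)`,
#'   columns 1-based and sorted by decreasing importance.
#' @export
key_sites <- function(profile, thresholds = c(0, 0.1)) {
  stopifnot(inherits(profile, "importance_profile"))
  out <- lapply(thresholds, function(th) {
    hit <- which(profile$importance > th)
    hit <- hit[order(profile$importance[hit], decreasing = TRUE)]
    list(count = length(hit), columns = profile$column_index[hit])
  })
  stats::setNames(out, as.character(thresholds))
}

#' Per-column base frequencies with the importance track
#'
#' Data behind a sequence logo: for every alignment column, the frequency
#' of A/C/G/T and of gap-or-ambiguous symbols among the sequences, plus the
#' site's importance weight.
#'
#' @param aln A [dna_alignment].
#' @param profile An [feature_importance()] profile of matching length.
#' @return Data frame with columns `column`, `A`, `C`, `G`, `T`, `gap`,
#'   `importance`; the five frequencies sum to 1 per row.
#' @export
logo_data <- function(aln, profile) {
  stopifnot(inherits(aln, "dna_alignment"),
            inherits(profile, "importance_profile"))
  if (length(profile$importance) != aln$length)
    stop("importance profile length does not match alignment columns")
  m <- as.matrix(aln)
  freq <- function(base) colMeans(m == base)
  out <- data.frame(column = seq_len(aln$length),
                    A = freq("A"), C = freq("C"), G = freq("G"),
                    T = freq("T"))
  out$gap <- 1 - out$A - out$C - out$G - out$T
  out$importance <- profile$importance
  rownames(out) <- NULL
  out
}
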