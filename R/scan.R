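# The central fitting function: alignment in, cryptic-species scan out.

#' Scan an alignment for cryptic species structure
#'
#' Runs the full delimitation procedure on one aligned locus:
#' pairwise-deletion p-distances; the validity curve (SSE/elbow, mean
#' silhouette, gap statistic) with data-driven choice of the cluster
#' number; five clustering algorithms (k-means, complete-linkage
#' hierarchical, Brunet NMF, DBSCAN on the min-max-scaled distances,
#' affinity propagation on 1 - d) combined into a consensus partition;
#' then, unless `classify = FALSE`, cross-validated random-forest, SVM and
#' MLP classifiers on the ordinal encoding with a per-site importance
#' profile and key diagnostic sites.
#'
#' The positive ("putative cryptic") class is the consensus cluster
#' containing `reference_id` when one is supplied (the cluster nearest a
#' reference specimen is the candidate species); otherwise the smallest
#' consensus cluster is flagged for review.
#'
#' @param aln A [dna_alignment] (or path to a FASTA file).
#' @param k Number of clusters; `NULL` (default) uses the validity-curve
#'   majority choice.
#' @param k_range Cluster counts evaluated for the validity curve.
#' @param seed Master integer seed; every stochastic stage derives its seed
#'   from it, making the scan fully reproducible.
#' @param reference_id Optional id whose consensus cluster defines the
#'   positive class.
#' @param group_labels Optional externally supplied two-group labelling
#'   (vector in alignment order, or named by id). When given, the
#'   classification stage uses it instead of the consensus clusters; the
#'   clustering and validity stages still run.
#' @param gap_b Monte-Carlo reference samples for the gap statistic.
#' @param nmf_nrun NMF random restarts (the full protocol value is 1000;
#'   50 is ample away from degenerate optima).
#' @param dbscan_eps,dbscan_min_pts DBSCAN radius (on 0-1 scaled distances)
#'   and minimum neighbourhood size.
#' @param folds Cross-validation folds.
#' @param classify Run the classification stage?
#' @param ntree,hidden,epochs Classifier hyperparameters (random-forest
#'   trees; MLP hidden width and SGD epochs).
#' @param key_thresholds Importance thresholds for [key_sites()].
#' @return Object of class `cryptic_scan`; see the elements `dm`,
#'   `validity`, `k`, `selection`, `clusterings`, `consensus`, `groups`,
#'   `cv`, `models`, `importance`, `key_sites`, `logo`.
#' @seealso [simulate_alignment()] to generate test data,
#'   [run_pipeline()] for the file-based interface.
#' @export
cryptic_scan <- function(aln, k = NULL, k_range = 1:8, seed = 1L,
                         reference_id = NULL, group_labels = NULL, gap_b = 100L,
                         nmf_nrun = 50L, dbscan_eps = 0.5,
                         dbscan_min_pts = 20L, folds = 5L,
                         classify = TRUE, ntree = 500L, hidden = 100L,
                         epochs = 200L, key_thresholds = c(0, 0.1)) {
  if (is.character(aln)) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "dna_alignment"))
  seed <- as.integer(seed)
  n <- length(aln$ids)

  dm <- distance_matrix(aln)
  scaled_d <- scale_distance_matrix(dm)
  sim <- pairwise_similarity(dm)

  validity <- validity_curve(dm$d, d = dm$d,
                             k_range = k_range[k_range <= n],
                             b = gap_b, seed = seed)
  selection <- choose_k(validity)
  if (is.null(k)) {
    k <- selection$k_best
    if (is.na(k)) {
      k <- selection$per_criterion[["silhouette"]]
      if (is.na(k)) stop("no usable cluster-number criterion; supply k")
    }
  }

  clusterings <- list(
    kmeans = cluster_kmeans(dm$d, k, seed = seed + 11L),
    hclust = cluster_hclust(dm, k),
    nmf = cluster_nmf(dm$d, rank = k, nrun = nmf_nrun, seed = seed + 12L),
    dbscan = cluster_dbscan(scaled_d, eps = dbscan_eps,
                            min_pts = dbscan_min_pts),
    ap = cluster_ap(sim, seed = seed + 13L))
  consensus <- consensus_partition(unname(clusterings))

  if (!is.null(group_labels)) {
    if (!is.null(names(group_labels))) group_labels <- group_labels[aln$ids]
    if (length(group_labels) != n || anyNA(group_labels))
      stop("group_labels must cover every sequence")
    labels <- match(group_labels, sort(unique(group_labels)))
  } else {
    labels <- consensus$consensus_labels
  }
  sizes <- table(labels)
  if (!is.null(reference_id)) {
    pos_cluster <- labels[match(reference_id, aln$ids)]
    if (is.na(pos_cluster)) stop("reference_id not found: ", reference_id)
  } else {
    pos_cluster <- as.integer(names(sizes)[which.min(sizes)])
  }
  group <- ifelse(labels == pos_cluster, "putative_cryptic", "reference")
  y <- factor(group, levels = c("reference", "putative_cryptic"))

  obj <- structure(
    list(alignment = aln, dm = dm, validity = validity,
         selection = selection, k = k, clusterings = clusterings,
         consensus = consensus, groups = y, positive_cluster = pos_cluster,
         reference_id = reference_id, seed = seed,
         group_distances = group_distance_sets(dm, as.character(y)),
         call = match.call()),
    class = "cryptic_scan")

  if (classify) {
    if (length(unique(y)) < 2L || any(table(y) < 2L)) {
      warning("consensus produced a class with fewer than two members; ",
              "classification stage skipped")
    } else {
      enc <- encode_ordinal(aln)
      obj$encoded <- enc
      obj$cv <- cross_validate(enc, y, folds = folds, seed = seed + 100L,
                               ntree = ntree, hidden = hidden,
                               epochs = epochs)
      obj$models <- train_models(enc, y, seed = seed + 200L, ntree = ntree,
                                 hidden = hidden, epochs = epochs)
      obj$importance <- feature_importance(enc, y, seed = seed + 300L,
                                           ntree = ntree)
      obj$key_sites <- key_sites(obj$importance,
                                 thresholds = key_thresholds)
      obj$logo <- logo_data(aln, obj$importance)
    }
  }
  obj
}

#' @export
print.cryptic_scan <- function(x, ...) {
  cat("Cryptic-species scan\n")
  cat(sprintf("  %d sequences x %d columns, master seed %d\n",
              length(x$alignment$ids), x$alignment$length, x$seed))
  pc <- x$selection$per_criterion
  cat(sprintf("  clusters k = %d (elbow %s, silhouette %s, gap %s)\n",
              x$k, pc["elbow"], pc["silhouette"], pc["gap"]))
  sizes <- table(x$consensus$consensus_labels)
  cat(sprintf("  consensus partition: [%s]%s\n",
              paste(sizes, collapse = "/"),
              if (x$consensus$unanimous) ", all five algorithms agree"
              else ""))
  cat(sprintf("  putative cryptic group: cluster %d (%d sequences)\n",
              x$positive_cluster, sum(x$groups == "putative_cryptic")))
  if (!is.null(x$cv)) {
    for (m in names(x$cv$mean_auc))
      cat(sprintf("  %-4s CV mean AUC %.3f (sd %.3f)\n", m,
                  x$cv$mean_auc[m], x$cv$sd_auc[m]))
    ks <- x$key_sites[["0.1"]]
    if (!is.null(ks))
      cat(sprintf("  key sites (importance > 0.1): %s\n",
                  paste(ks$columns, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.cryptic_scan <- function(object, ...) {
  gd <- object$group_distances
  out <- list(
    n = length(object$alignment$ids),
    length = object$alignment$length,
    k = object$k,
    per_criterion = object$selection$per_criterion,
    consensus_sizes = as.integer(table(object$consensus$consensus_labels)),
    unanimous = object$consensus$unanimous,
    agreement = object$consensus$agreement,
    mean_within = vapply(gd$within, mean, numeric(1)),
    mean_between = vapply(gd$between, mean, numeric(1)),
    mean_auc = object$cv$mean_auc, sd_auc = object$cv$sd_auc,
    mean_f1 = object$cv$mean_f1,
    key_sites = object$key_sites,
    validity = as.data.frame(object$validity))
  class(out) <- "summary.cryptic_scan"
  out
}

#' @export
print.summary.cryptic_scan <- function(x, ...) {
  cat(sprintf("Cryptic-species scan: %d sequences x %d columns\n",
              x$n, x$length))
  cat(sprintf("Chosen k = %d; consensus sizes [%s]%s\n", x$k,
              paste(x$consensus_sizes, collapse = "/"),
              if (x$unanimous) " (unanimous)" else ""))
  cat("Mean within-group p-distance:",
      paste(sprintf("%s %.4f", names(x$mean_within), x$mean_within),
            collapse = ", "), "\n")
  cat("Mean between-group p-distance:",
      paste(sprintf("%s %.4f", names(x$mean_between), x$mean_between),
            collapse = ", "), "\n")
  cat("Validity curve:\n")
  print(x$validity, row.names = FALSE, digits = 4)
  if (!is.null(x$mean_auc)) {
    cat("Cross-validated classifiers:\n")
    for (m in names(x$mean_auc))
      cat(sprintf("  %-4s AUC %.3f (sd %.3f), F1 %.3f\n", m, x$mean_auc[m],
                  x$sd_auc[m], x$mean_f1[m]))
    for (th in names(x$key_sites))
      cat(sprintf("  sites with importance > %s: %d\n", th,
                  x$key_sites[[th]]$count))
  }
  invisible(x)
}

#' Classify new aligned sequences against a fitted scan
#'
#' @param object A [cryptic_scan()] result with a classification stage.
#' @param newdata A [dna_alignment] with the same column count as the
#'   training alignment, or an encoded matrix.
#' @param ... Unused.
#' @return Data frame with the per-model positive-class probabilities and
#'   a majority-vote `predicted` group per sequence.
#' @export
predict.cryptic_scan <- function(object, newdata, ...) {
  if (is.null(object$models))
    stop("scan has no classification stage; rerun with classify = TRUE")
  x <- if (inherits(newdata, "dna_alignment")) {
    if (newdata$length != object$alignment$length)
      stop("newdata column count differs from the fitted alignment")
    encode_ordinal(newdata)
  } else {
    as.matrix(newdata)
  }
  prob <- predict(object$models, x)
  vote <- rowMeans(prob >= 0.5)
  prob$predicted <- ifelse(vote > 0.5, "putative_cryptic", "reference")
  if (!is.null(rownames(x))) rownames(prob) <- rownames(x)
  prob
}

#' Plot a fitted scan
#'
#' Four panels: SSE elbow curve, mean silhouette, gap statistic with
#' 1-standard-error bars, and the per-site importance profile (when the
#' classification stage ran; otherwise a p-distance heatmap).
#'
#' @param x A [cryptic_scan()] result.
#' @param ... Unused.
#' @export
plot.cryptic_scan <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  v <- x$validity
  plot(v$k_values, v$sse, type = "b", xlab = "k", ylab = "SSE",
       main = "Elbow")
  graphics::abline(v = x$k, lty = 2, col = "grey40")
  plot(v$k_values, v$mean_silhouette, type = "b", xlab = "k",
       ylab = "mean silhouette", main = "Silhouette")
  graphics::abline(v = x$k, lty = 2, col = "grey40")
  plot(v$k_values, v$gap, type = "b", xlab = "k", ylab = "gap",
       main = sprintf("Gap statistic (B = %d)", v$b_samples),
       ylim = range(c(v$gap - v$gap_se, v$gap + v$gap_se)))
  graphics::arrows(v$k_values, v$gap - v$gap_se, v$k_values,
                   v$gap + v$gap_se, angle = 90, code = 3, length = 0.03)
  graphics::abline(v = x$k, lty = 2, col = "grey40")
  if (!is.null(x$importance)) {
    plot(x$importance$column_index, x$importance$importance, type = "h",
         xlab = "alignment column", ylab = "importance",
         main = "Random-forest site importance")
  } else {
    graphics::image(x$dm$d, axes = FALSE, main = "p-distance matrix",
                    col = grDevices::hcl.colors(64, "Reds", rev = TRUE))
  }
  invisible(x)
}
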