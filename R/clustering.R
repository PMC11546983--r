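# Five clustering routes over the p-distance matrix, and their consensus.
#
# k-means and complete-linkage hierarchical clustering are delegated to
# stats; DBSCAN, affinity propagation and Brunet NMF are implemented here
# (small-n, matrix-vectorised). Cluster labels are integers 1..k; 0 marks
# DBSCAN noise. Feature spaces: hierarchical and DBSCAN consume the
# p-distance matrix as a precomputed metric; k-means and NMF consume its
# rows (each sequence described by its distance profile); affinity
# propagation consumes pairwise similarity (1 - d).

new_cluster_result <- function(algorithm, labels, params = list(),
                               seed = NULL, converged = TRUE) {
  labels <- as.integer(labels)
  pos <- sort(unique(labels[labels > 0L]))
  labels[labels > 0L] <- match(labels[labels > 0L], pos)
  structure(list(algorithm = algorithm, labels = labels,
                 k_found = length(pos), params = params, seed = seed,
                 converged = converged),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- table(x$labels[x$labels > 0L])
  cat(sprintf("%s: %d cluster(s) [%s]%s\n", x$algorithm, x$k_found,
              paste(sizes, collapse = "/"),
              if (any(x$labels == 0L))
                sprintf(", %d noise", sum(x$labels == 0L)) else ""))
  invisible(x)
}

#' k-means clustering of distance profiles
#'
#' Lloyd's algorithm via [stats::kmeans()], best of `n_init` random
#' initialisations by total within-cluster sum of squares.
#'
#' @param features Numeric matrix, one row per sequence (typically the rows
#'   of the p-distance matrix).
#' @param k Number of clusters (1..n).
#' @param seed Integer seed for the initialisations (`NULL` = leave RNG).
#' @param n_init Number of random restarts.
#' @param iter_max Maximum Lloyd iterations.
#' @return A `cluster_result`.
#' @export
cluster_kmeans <- function(features, k, seed = NULL, n_init = 10L,
                           iter_max = 100L) {
  features <- as.matrix(features)
  if (k < 1L || k > nrow(features))
    stop("k must be between 1 and the number of sequences")
  if (!is.null(seed)) set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(features, centers = k, nstart = n_init,
                  iter.max = iter_max, algorithm = "Lloyd"))
  res <- new_cluster_result("kmeans", km$cluster,
                            params = list(k = k, n_init = n_init),
                            seed = seed)
  res$sse <- km$tot.withinss
  res$centers <- km$centers
  res
}

#' Complete-linkage hierarchical clustering of a p-distance matrix
#'
#' @param dm A [distance_matrix()] result (or square distance matrix).
#' @param k Number of clusters to cut the dendrogram into.
#' @return A `cluster_result`; the `hclust` tree is attached as `$tree`.
#' @export
cluster_hclust <- function(dm, k) {
  d <- if (inherits(dm, "pdist_matrix")) dm$d else as.matrix(dm)
  if (k < 1L || k > nrow(d))
    stop("k must be between 1 and the number of sequences")
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  res <- new_cluster_result("hclust_complete", stats::cutree(tree, k = k),
                            params = list(k = k, method = "complete"))
  res$tree <- tree
  res
}

# Internal: KL divergence D(x || wh), with 0 log 0 = 0.
kl_divergence <- function(x, wh) {
  pos <- x > 0
  sum(x[pos] * log(x[pos] / wh[pos])) - sum(x) + sum(wh)
}

#' Brunet NMF clustering
#'
#' Non-negative matrix factorisation `x ~ W H` by Brunet's multiplicative
#' updates for the Kullback-Leibler divergence, keeping the best of `nrun`
#' random restarts (lowest final divergence). Each row is assigned to the
#' basis component with the largest coefficient in `W`.
#'
#' @param x Non-negative numeric matrix (e.g. the p-distance matrix).
#' @param rank Factorisation rank (number of clusters), `< min(dim(x))`.
#' @param nrun Number of random restarts. The full protocol uses 1000;
#'   reduce for quick runs — restarts only matter near degenerate optima.
#' @param seed Integer seed.
#' @param max_iter,tol Update-loop cap and relative divergence tolerance
#'   (checked every 10 iterations).
#' @param trace If `TRUE`, attach the divergence trace of the best run.
#' @return A `cluster_result` with `$divergence` (and `$trace` if requested).
#' @export
cluster_nmf <- function(x, rank, nrun = 1000L, seed = NULL, max_iter = 2000L,
                        tol = 1e-5, trace = FALSE) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("NMF input must be non-negative")
  if (rank < 1L || rank >= min(dim(x)))
    stop("rank must be in 1 .. min(dim(x)) - 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); m <- ncol(x); eps <- .Machine$double.eps
  best <- NULL
  for (run in seq_len(nrun)) {
    w <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
    h <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)
    div_prev <- Inf; tr <- numeric(0)
    for (it in seq_len(max_iter)) {
      wh <- w %*% h + eps
      h <- h * (crossprod(w, x / wh)) / (colSums(w) + eps)
      wh <- w %*% h + eps
      w <- w * ((x / wh) %*% t(h)) / rep(rowSums(h) + eps, each = n)
      if (it %% 10L == 0L || it == max_iter) {
        div <- kl_divergence(x, w %*% h + eps)
        if (trace) tr <- c(tr, div)
        if (is.finite(div_prev) &&
            div_prev - div < tol * max(abs(div_prev), 1)) break
        div_prev <- div
      }
    }
    div <- kl_divergence(x, w %*% h + eps)
    if (is.null(best) || div < best$div)
      best <- list(div = div, w = w, trace = tr)
  }
  labels <- max.col(best$w, ties.method = "first")
  res <- new_cluster_result("nmf_brunet", labels,
                            params = list(rank = rank, nrun = nrun),
                            seed = seed)
  res$divergence <- best$div
  if (trace) res$trace <- best$trace
  res
}

#' DBSCAN on a precomputed distance matrix
#'
#' Density-based clustering. A point is a core point when at least
#' `min_pts` points (itself included) lie within distance `eps`; clusters
#' are the reachability closures of core points, and unreachable non-core
#' points are noise (label 0). The default radius 0.5 assumes distances
#' min-max scaled to 0-1 (see [scale_distance_matrix] use in
#' [cryptic_scan()]); raw control-region p-distances rarely exceed ~0.1.
#'
#' @param dm A [distance_matrix()] result or square distance matrix.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point, self
#'   included.
#' @return A `cluster_result` (label 0 = noise).
#' @export
cluster_dbscan <- function(dm, eps = 0.5, min_pts = 20L) {
  d <- if (inherits(dm, "pdist_matrix")) dm$d else as.matrix(dm)
  if (eps <= 0) stop("eps must be positive")
  if (min_pts < 1L) stop("min_pts must be at least 1")
  n <- nrow(d)
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      nbrs <- which(nb[j, ])
      fresh <- nbrs[labels[nbrs] == 0L]
      labels[fresh] <- cl
      queue <- c(queue, fresh[core[fresh]])
    }
  }
  new_cluster_result("dbscan", labels,
                     params = list(eps = eps, min_pts = min_pts))
}

#' Affinity propagation on a similarity matrix
#'
#' Frey-Dueck responsibility/availability message passing. The shared
#' preference (self-similarity) defaults to the median off-diagonal
#' similarity, so the number of clusters emerges from the data. A tiny
#' seeded jitter breaks exact symmetry ties, as reference implementations
#' do.
#'
#' @param similarity Square similarity matrix (e.g. [pairwise_similarity()]).
#' @param damping Message damping factor in (0.5, 1).
#' @param max_iter Maximum iterations.
#' @param conv_iter Iterations of unchanged exemplar set declaring
#'   convergence.
#' @param preference Optional scalar or per-point preference.
#' @param seed Integer seed for the jitter.
#' @return A `cluster_result`; `$converged` is `FALSE` when the exemplar set
#'   never stabilised, `$exemplars` holds the exemplar indices.
#' @export
cluster_ap <- function(similarity, damping = 0.9, max_iter = 1000L,
                       conv_iter = 100L, preference = NULL, seed = NULL) {
  s <- as.matrix(similarity)
  n <- nrow(s)
  if (n != ncol(s)) stop("similarity matrix must be square")
  if (n == 1L) {
    res <- new_cluster_result("affinity_propagation", 1L, seed = seed)
    res$exemplars <- 1L
    return(res)
  }
  off <- s[row(s) != col(s)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(s) <- preference
  if (!is.null(seed)) set.seed(seed)
  scale <- diff(range(s)) + .Machine$double.eps
  s <- s + 1e-12 * scale * matrix(stats::rnorm(n * n), n, n)
  r <- a <- matrix(0, n, n)
  ex_prev <- rep(NA, n); stable <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    as_mat <- a + s
    top <- max.col(as_mat, ties.method = "first")
    m1 <- as_mat[cbind(seq_len(n), top)]
    as_mat[cbind(seq_len(n), top)] <- -Inf
    m2 <- as_mat[cbind(seq_len(n), max.col(as_mat, ties.method = "first"))]
    r_new <- s - m1
    r_new[cbind(seq_len(n), top)] <- s[cbind(seq_len(n), top)] - m2
    r <- damping * r + (1 - damping) * r_new
    rp <- pmax(r, 0); diag(rp) <- diag(r)
    cs <- colSums(rp)
    a_new <- pmin(matrix(cs, n, n, byrow = TRUE) - rp, 0)
    diag(a_new) <- cs - diag(r)
    a <- damping * a + (1 - damping) * a_new
    ex <- diag(a) + diag(r) > 0
    if (identical(ex, ex_prev)) stable <- stable + 1L else stable <- 0L
    ex_prev <- ex
    if (stable >= conv_iter && any(ex)) { converged <- TRUE; break }
  }
  exemplars <- which(diag(a) + diag(r) > 0)
  if (length(exemplars) == 0L)
    exemplars <- which.max(diag(a) + diag(r))
  assign <- exemplars[max.col(s[, exemplars, drop = FALSE],
                              ties.method = "first")]
  assign[exemplars] <- exemplars
  # re-assign members to the final exemplar set once more for stability
  labels <- match(assign, sort(unique(assign)))
  res <- new_cluster_result("affinity_propagation", labels,
                            params = list(damping = damping,
                                          preference = preference),
                            seed = seed, converged = converged)
  res$exemplars <- sort(unique(assign))
  res
}

# Internal: ARI between two labelings, ignoring points flagged noise (0)
# in either.
ari_pair <- function(a, b) {
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(NA_real_)
  if (length(unique(a)) == 1L && length(unique(b)) == 1L) return(1)
  mclust::adjustedRandIndex(a, b)
}

# Internal: relabel 'labels' to maximise overlap with 'ref'. Exact over all
# assignments for up to 7 cluster ids, greedy beyond. Noise (0) is left
# untouched; surplus clusters keep fresh ids above those of 'ref'.
align_labels <- function(labels, ref) {
  ks <- sort(unique(labels[labels > 0L]))
  kr <- sort(unique(ref[ref > 0L]))
  if (length(ks) == 0L) return(labels)
  ov <- outer(ks, kr,
              Vectorize(function(a, b) sum(labels == a & ref == b)))
  mapping <- rep(NA_integer_, length(ks))
  if (length(ks) <= 7L && length(kr) <= 7L) {
    # exact: enumerate injective assignments of the smaller side
    if (length(ks) <= length(kr)) {
      perms <- perm_enum(length(kr), length(ks))
      scores <- vapply(seq_len(nrow(perms)), function(i)
        sum(ov[cbind(seq_along(ks), perms[i, ])]), numeric(1))
      mapping <- kr[perms[which.max(scores), ]]
    } else {
      perms <- perm_enum(length(ks), length(kr))
      scores <- vapply(seq_len(nrow(perms)), function(i)
        sum(ov[cbind(perms[i, ], seq_along(kr))]), numeric(1))
      mapping[perms[which.max(scores), ]] <- kr
    }
  } else {
    o <- ov
    repeat {
      if (all(is.na(o)) || max(o, na.rm = TRUE) < 0) break
      idx <- which(o == max(o, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      mapping[idx[1L]] <- kr[idx[2L]]
      o[idx[1L], ] <- NA; o[, idx[2L]] <- NA
      if (all(is.na(o))) break
    }
  }
  nxt <- max(kr, 0L)
  for (i in seq_along(mapping)) if (is.na(mapping[i])) {
    nxt <- nxt + 1L
    mapping[i] <- nxt
  }
  out <- labels
  for (i in seq_along(ks)) out[labels == ks[i]] <- mapping[i]
  out
}

# Internal: all injective index tuples of length 'take' from 1..n, as rows.
perm_enum <- function(n, take) {
  if (take == 0L) return(matrix(integer(0), 1L, 0L))
  out <- matrix(seq_len(n), ncol = 1L)
  for (step in seq_len(take - 1L)) {
    out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
      rest <- setdiff(seq_len(n), out[i, ])
      cbind(matrix(out[i, ], length(rest), step, byrow = TRUE), rest)
    }))
  }
  unname(out)
}

#' Consensus over several cluster results
#'
#' Aligns every partition's labels to a reference (the complete-linkage
#' result when present, else the first) by maximal overlap, then takes a
#' per-sequence majority vote. DBSCAN noise points cast no vote. Sequences
#' with no majority are flagged ambiguous and resolved by the reference
#' partition, which is deterministic given the distance matrix. Agreement
#' between partitions is the pairwise adjusted Rand index, computed over
#' points that are noise in neither.
#'
#' @param results List of `cluster_result` objects over the same sequences.
#' @return Object of class `consensus_result`: `per_algorithm`, `agreement`
#'   (ARI matrix), `consensus_labels`, `unanimous` (all pairwise ARI == 1),
#'   `ambiguous` (indices resolved by the reference).
#' @export
consensus_partition <- function(results) {
  if (length(results) < 2L) stop("need at least two cluster results")
  ns <- vapply(results, function(r) length(r$labels), integer(1))
  if (length(unique(ns)) != 1L)
    stop("cluster results cover different sequence sets")
  n <- ns[1L]
  algs <- vapply(results, `[[`, character(1), "algorithm")
  ref_i <- match("hclust_complete", algs)
  if (is.na(ref_i)) ref_i <- 1L
  ref <- results[[ref_i]]$labels
  aligned <- vapply(results, function(r) align_labels(r$labels, ref),
                    integer(n))
  agreement <- diag(1, length(results))
  for (i in seq_along(results)) for (j in seq_along(results)) {
    if (j <= i) next
    agreement[i, j] <- agreement[j, i] <-
      ari_pair(results[[i]]$labels, results[[j]]$labels)
  }
  dimnames(agreement) <- list(algs, algs)
  consensus <- integer(n); ambiguous <- integer(0)
  for (i in seq_len(n)) {
    votes <- aligned[i, ]
    votes <- votes[votes > 0L]
    if (length(votes) == 0L) { consensus[i] <- ref[i]; next }
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1L && max(tab) > length(votes) / 2) {
      consensus[i] <- winners
    } else if (length(winners) == 1L) {
      consensus[i] <- winners
    } else {
      ambiguous <- c(ambiguous, i)
      consensus[i] <- if (ref[i] %in% winners) ref[i] else winners[1L]
    }
  }
  pos <- sort(unique(consensus[consensus > 0L]))
  consensus[consensus > 0L] <- match(consensus[consensus > 0L], pos)
  structure(list(per_algorithm = results, agreement = agreement,
                 consensus_labels = consensus,
                 unanimous = isTRUE(all(agreement[upper.tri(agreement)] == 1)),
                 ambiguous = ambiguous),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  sizes <- table(x$consensus_labels)
  cat(sprintf("Consensus of %d algorithms: %d cluster(s) [%s]%s\n",
              length(x$per_algorithm), length(sizes),
              paste(sizes, collapse = "/"),
              if (x$unanimous) ", unanimous" else ""))
  if (length(x$ambiguous))
    cat("  ambiguous sequences:", paste(x$ambiguous, collapse = ", "), "\n")
  invisible(x)
}
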