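# Cluster-number selection: SSE/elbow, average silhouette, gap statistic.

#' Within-cluster sum of squared errors
#'
#' `SSE = sum_i sum_{p in C_i} ||p - m_i||^2` where `m_i` is the centroid of
#' cluster `C_i`.
#'
#' @param features Numeric matrix, one row per point.
#' @param labels Integer cluster label per row (every label >= 1 present).
#' @return Scalar SSE.
#' @export
cluster_sse <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("every row must be labelled")
  if (any(labels < 1L)) stop("labels must be positive integers")
  total <- 0
  for (g in unique(labels)) {
    sub <- features[labels == g, , drop = FALSE]
    ctr <- colMeans(sub)
    total <- total + sum(sweep(sub, 2L, ctr)^2)
  }
  total
}

#' Silhouette widths from a distance matrix
#'
#' For point i in cluster C: `a_i` is its mean distance to the other members
#' of C, `b_i` the smallest mean distance to any other cluster, and
#' `s_i = (b_i - a_i)/max(a_i, b_i)`. Points in singleton clusters get
#' `s_i = 0` by the standard convention.
#'
#' @param d Square distance matrix, `dist`, or [distance_matrix()] result.
#' @param labels Integer cluster label per point; at least two clusters.
#' @return List with `widths` (per-point s_i) and `mean`.
#' @export
silhouette_widths <- function(d, labels) {
  d <- if (inherits(d, "pdist_matrix")) d$d else as.matrix(d)
  labels <- as.integer(labels)
  n <- nrow(d)
  if (length(labels) != n) stop("every point must be labelled")
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L)
    stop("silhouette undefined for a single cluster")
  sizes <- table(factor(labels, levels = clusters))
  # n x k matrix of summed distances from each point to each cluster
  sums <- vapply(clusters,
                 function(g) rowSums(d[, labels == g, drop = FALSE]),
                 numeric(n))
  own <- match(labels, clusters)
  s <- numeric(n)
  for (i in seq_len(n)) {
    m <- sizes[own[i]]
    if (m == 1L) { s[i] <- 0; next }
    a_i <- sums[i, own[i]] / (m - 1L)
    b_i <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  list(widths = s, mean = mean(s))
}

#' Gap statistic over a range of cluster counts
#'
#' `gap(k) = mean_b log W_k(ref_b) - log W_k(data)`, with `W_k` the k-means
#' within-cluster SSE and reference datasets drawn uniformly over each
#' feature's observed range. The standard error is `sd_b * sqrt(1 + 1/b)`.
#'
#' @param features Numeric matrix.
#' @param k_range Integer vector of cluster counts.
#' @param b Number of Monte-Carlo reference samples. The full protocol uses
#'   1000; 100 gives standard errors adequate for the 1-SE rule.
#' @param seed Integer seed.
#' @param n_init k-means restarts per fit.
#' @return List with `k_values`, `gap`, `gap_se`, `log_w`, `b_samples`.
#' @export
gap_statistic <- function(features, k_range, b = 100L, seed = NULL,
                          n_init = 10L) {
  features <- as.matrix(features)
  if (b < 1L) stop("b must be at least 1")
  rng <- apply(features, 2L, range)
  if (all(rng[1L, ] == rng[2L, ]))
    stop("degenerate data: all rows identical")
  if (!is.null(seed)) set.seed(seed)
  w_k <- function(x, k) {
    if (k == 1L) return(sum(sweep(x, 2L, colMeans(x))^2))
    suppressWarnings(stats::kmeans(x, centers = k, nstart = n_init,
                                   iter.max = 100L,
                                   algorithm = "Lloyd"))$tot.withinss
  }
  log_w <- vapply(k_range, function(k)
    log(max(w_k(features, k), 1e-300)), numeric(1))
  log_w_ref <- matrix(NA_real_, b, length(k_range))
  n <- nrow(features); m <- ncol(features)
  for (j in seq_len(b)) {
    ref <- vapply(seq_len(m),
                  function(c) stats::runif(n, rng[1L, c], rng[2L, c]),
                  numeric(n))
    log_w_ref[j, ] <- vapply(k_range, function(k)
      log(max(w_k(ref, k), 1e-300)), numeric(1))
  }
  gap <- colMeans(log_w_ref) - log_w
  gap_se <- if (b == 1L) rep(0, length(k_range))
            else apply(log_w_ref, 2L, stats::sd) * sqrt(1 + 1 / b)
  list(k_values = as.integer(k_range), gap = gap, gap_se = gap_se,
       log_w = log_w, b_samples = as.integer(b))
}

#' Validity curve: SSE, mean silhouette and gap statistic versus k
#'
#' Fits seeded k-means at every k over the distance-profile features and
#' evaluates the three cluster-number criteria on the same partitions.
#'
#' @param features Numeric matrix (typically rows of the p-distance matrix).
#' @param d Distance matrix for the silhouette (defaults to Euclidean
#'   distances between feature rows when `NULL`).
#' @param k_range Cluster counts to evaluate (include k = 1 for the elbow).
#' @param b Monte-Carlo reference samples for the gap statistic.
#' @param seed Integer seed.
#' @param n_init k-means restarts.
#' @return Object of class `validity_curve`: `k_values`, `sse`,
#'   `mean_silhouette` (NA at k = 1), `gap`, `gap_se`, `b_samples`.
#' @export
validity_curve <- function(features, d = NULL, k_range = 1:8, b = 100L,
                           seed = NULL, n_init = 10L) {
  features <- as.matrix(features)
  if (is.null(d)) d <- as.matrix(stats::dist(features))
  d <- if (inherits(d, "pdist_matrix")) d$d else as.matrix(d)
  k_range <- sort(unique(as.integer(k_range)))
  n_distinct <- nrow(unique(features))
  if (max(k_range) > n_distinct) {
    warning("restricting k_range to the ", n_distinct,
            " distinct feature rows")
    k_range <- k_range[k_range <= n_distinct]
  }
  sse <- sil <- rep(NA_real_, length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- cluster_kmeans(features, k, seed = seed, n_init = n_init)
    sse[i] <- km$sse
    sil[i] <- if (k >= 2L && km$k_found >= 2L)
      silhouette_widths(d, km$labels)$mean else NA_real_
  }
  gp <- gap_statistic(features, k_range, b = b, seed = seed,
                      n_init = n_init)
  structure(list(k_values = k_range, sse = sse, mean_silhouette = sil,
                 gap = gp$gap, gap_se = gp$gap_se,
                 b_samples = gp$b_samples),
            class = "validity_curve")
}

#' @export
print.validity_curve <- function(x, ...) {
  tab <- data.frame(k = x$k_values, sse = x$sse,
                    mean_silhouette = x$mean_silhouette,
                    gap = x$gap, gap_se = x$gap_se)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.validity_curve <- function(x, ...) {
  data.frame(k = x$k_values, sse = x$sse,
             mean_silhouette = x$mean_silhouette,
             gap = x$gap, gap_se = x$gap_se)
}

#' Choose the number of clusters from a validity curve
#'
#' Elbow: the k maximising the second forward difference of the SSE curve
#' on the log scale (relative curvature; SSE spans orders of magnitude
#' across k, and the absolute second difference is dominated by the k = 1
#' term whenever the first drop is large). Flat curves leave it undefined. Silhouette:
#' argmax of the mean silhouette. Gap: the smallest k with
#' `gap(k) >= gap(k+1) - se(k+1)` (1-SE rule). `k_best` is the majority of
#' the three, ties resolved in favour of the elbow.
#'
#' @param curve A [validity_curve()] result.
#' @return List with `k_best` and `per_criterion` (named integer vector
#'   `elbow`, `silhouette`, `gap`; NA when undefined) and `unanimous`.
#' @export
choose_k <- function(curve) {
  ks <- curve$k_values
  if (length(ks) < 3L) stop("need at least three k values")
  lsse <- log(pmax(curve$sse, 1e-12))
  sec <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1L))
    sec[i] <- lsse[i - 1L] - 2 * lsse[i] + lsse[i + 1L]
  elbow <- if (all(is.na(sec)) || diff(range(curve$sse)) == 0)
    NA_integer_ else ks[which.max(sec)]
  sil <- if (all(is.na(curve$mean_silhouette))) NA_integer_
         else ks[which.max(curve$mean_silhouette)]
  gap <- NA_integer_
  for (i in seq_len(length(ks) - 1L)) {
    if (!is.na(curve$gap[i]) &&
        curve$gap[i] >= curve$gap[i + 1L] - curve$gap_se[i + 1L]) {
      gap <- ks[i]
      break
    }
  }
  per <- c(elbow = elbow, silhouette = sil, gap = gap)
  votes <- per[!is.na(per)]
  k_best <- if (length(votes) == 0L) {
    NA_integer_
  } else {
    tab <- table(votes)
    winners <- as.integer(names(tab)[tab == max(tab)])
    if (length(winners) == 1L) winners
    else if (!is.na(elbow) && elbow %in% winners) elbow
    else winners[1L]
  }
  list(k_best = k_best, per_criterion = per,
       unanimous = length(unique(per[!is.na(per)])) == 1L &&
         !anyNA(per))
}
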