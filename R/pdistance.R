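# Pairwise-deletion p-distances, min-max scaling, and intra-/inter-group
# distance summaries.

#' p-distance between two aligned sequences (pairwise deletion)
#'
#' The p-distance is the proportion of differing nucleotide sites over the
#' sites compared. Columns where either sequence carries a gap or an
#' ambiguous base (anything outside A/C/G/T) are removed for that pair
#' before counting, i.e. the pairwise-deletion option of standard distance
#' software.
#'
#' @param seq_a,seq_b Aligned sequence strings of equal length.
#' @return A list with `distance` (proportion in \[0, 1\]) and `n_valid`
#'   (number of sites compared).
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- toupper(strsplit(as.character(seq_a), "")[[1L]])
  b <- toupper(strsplit(as.character(seq_b), "")[[1L]])
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n_valid <- sum(ok)
  if (n_valid == 0L)
    stop("p-distance undefined: no overlapping unambiguous sites")
  list(distance = sum(a[ok] != b[ok]) / n_valid, n_valid = n_valid)
}

#' Pairwise p-distance matrix for an alignment
#'
#' Computes all pairwise p-distances with pairwise deletion. Implemented by
#' cross-products of per-base indicator matrices, so the full matrix for a
#' ~100 x ~750 alignment is immediate.
#'
#' @param aln A [dna_alignment] with at least two sequences.
#' @return An object of class `pdist_matrix`: list with `ids`, `d` (symmetric
#'   p-distance matrix, zero diagonal) and `n_valid` (sites compared per
#'   pair).
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences")
  m <- aln_codes(aln)
  valid <- (m > 0L) * 1
  n_valid <- tcrossprod(valid)
  matches <- matrix(0, n, n)
  for (b in 1:4) matches <- matches + tcrossprod((m == b) * 1)
  off <- row(n_valid) != col(n_valid)
  if (any(n_valid[off] == 0)) {
    bad <- which(n_valid == 0 & off, arr.ind = TRUE)[1L, ]
    stop("p-distance undefined for pair ", aln$ids[bad[1L]], " / ",
         aln$ids[bad[2L]], ": no overlapping unambiguous sites")
  }
  d <- 1 - matches / n_valid
  diag(d) <- 0
  d[d < 0] <- 0
  dimnames(d) <- dimnames(n_valid) <- list(aln$ids, aln$ids)
  structure(list(ids = aln$ids, d = d, n_valid = n_valid),
            class = "pdist_matrix")
}

#' @export
print.pdist_matrix <- function(x, ...) {
  off <- x$d[row(x$d) != col(x$d)]
  cat(sprintf("p-distance matrix: %d sequences (%d pairs), range %.4f-%.4f\n",
              length(x$ids), length(off) / 2, min(off), max(off)))
  invisible(x)
}

#' @export
as.matrix.pdist_matrix <- function(x, ...) x$d

#' @export
as.dist.pdist_matrix <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$d, diag = diag, upper = upper)

#' Min-max scaling of distances into 0-1
#'
#' Each value `v` maps to `(v - min)/(max - min)` over the observed extremes.
#' A constant vector (max == min) carries no contrast and maps to all zeros.
#'
#' @param values Numeric vector of distances (at least one value).
#' @return List with `values` (scaled), `min_raw`, `max_raw`.
#' @export
scale_distances <- function(values) {
  if (length(values) == 0L) stop("no values to scale")
  lo <- min(values); hi <- max(values)
  scaled <- if (hi > lo) (values - lo) / (hi - lo) else rep(0, length(values))
  list(values = scaled, min_raw = lo, max_raw = hi)
}

# Internal: min-max scale the off-diagonal entries of a distance matrix,
# keeping a zero diagonal. Used ahead of DBSCAN, whose radius is specified
# on the 0-1 scale.
scale_distance_matrix <- function(dm) {
  d <- as.matrix(dm)
  off <- row(d) != col(d)
  sc <- scale_distances(d[off])
  d[off] <- sc$values
  diag(d) <- 0
  d
}

#' Within- and between-group p-distance sets
#'
#' Splits the unique pairwise distances into within-group lists (one per
#' group; a group of m members yields m(m-1)/2 values) and between-group
#' lists (one per unordered group pair), with the arithmetic mean of each
#' list. Singleton groups produce only between-group entries.
#'
#' @param dm A [distance_matrix()] result.
#' @param labels Group label per sequence: either a vector in `dm$ids` order
#'   or a named vector covering every id.
#' @return Object of class `group_pdist`: list with `within`, `between`
#'   (named lists of numeric vectors; between keys are `"A|B"`) and
#'   `averages` (named numeric vector over the same keys).
#' @export
group_distance_sets <- function(dm, labels) {
  stopifnot(inherits(dm, "pdist_matrix"))
  ids <- dm$ids
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("no label for ids: ", paste(missing, collapse = ", "))
    extra <- setdiff(names(labels), ids)
    if (length(extra))
      stop("labelled ids absent from distance matrix: ",
           paste(extra, collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("'labels' must cover every id in the distance matrix")
  }
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  within <- list(); between <- list()
  for (gi in seq_along(groups)) {
    a <- which(labels == groups[gi])
    if (length(a) >= 2L) {
      sub <- dm$d[a, a]
      within[[groups[gi]]] <- sub[upper.tri(sub)]
    }
    for (gj in seq_along(groups)) {
      if (gj <= gi) next
      b <- which(labels == groups[gj])
      key <- paste(groups[gi], groups[gj], sep = "|")
      between[[key]] <- as.vector(dm$d[a, b])
    }
  }
  averages <- vapply(c(within, between), mean, numeric(1))
  structure(list(within = within, between = between, averages = averages),
            class = "group_pdist")
}

#' @export
print.group_pdist <- function(x, ...) {
  cat("Group p-distance summary\n")
  for (g in names(x$within))
    cat(sprintf("  within %-12s n=%4d  mean %.4f\n", g,
                length(x$within[[g]]), mean(x$within[[g]])))
  for (g in names(x$between))
    cat(sprintf("  between %-11s n=%4d  mean %.4f\n", g,
                length(x$between[[g]]), mean(x$between[[g]])))
  invisible(x)
}

#' Pairwise similarity matrix
#'
#' Similarity is defined as `1 - p`, a monotone decreasing transform of the
#' p-distance that preserves the 0-1 range; the diagonal is 1.
#'
#' @param dm A [distance_matrix()] result.
#' @return Symmetric numeric similarity matrix.
#' @export
pairwise_similarity <- function(dm) {
  stopifnot(inherits(dm, "pdist_matrix"))
  s <- 1 - dm$d
  diag(s) <- 1
  s
}

#' Export a distance matrix as TSV
#'
#' @param dm A [distance_matrix()] result.
#' @param path Output path.
#' @param long If `TRUE`, write the long format
#'   `(id_a, id_b, distance, n_valid)` over unique pairs instead of the
#'   square matrix.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path, long = FALSE) {
  stopifnot(inherits(dm, "pdist_matrix"))
  if (long) {
    idx <- which(upper.tri(dm$d), arr.ind = TRUE)
    tab <- data.frame(id_a = dm$ids[idx[, 1L]], id_b = dm$ids[idx[, 2L]],
                      distance = dm$d[idx], n_valid = dm$n_valid[idx])
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
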