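# Independent brute-force oracles, deliberately naive: plain loops over
# columns, points and pairs. They share no code with the implementation.

oracle_p_distance <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  diff <- 0L; valid <- 0L
  for (i in seq_along(a)) {
    ok_a <- a[i] %in% c("A", "C", "G", "T")
    ok_b <- b[i] %in% c("A", "C", "G", "T")
    if (ok_a && ok_b) {
      valid <- valid + 1L
      if (a[i] != b[i]) diff <- diff + 1L
    }
  }
  list(distance = diff / valid, n_valid = valid)
}

oracle_sse <- function(x, labels) {
  x <- as.matrix(x)
  total <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    ctr <- colMeans(x[rows, , drop = FALSE])
    for (r in rows) total <- total + sum((x[r, ] - ctr)^2)
  }
  total
}

oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0L) { s[i] <- 0; next }
    a_i <- mean(d[i, mates])
    b_i <- Inf
    for (g in setdiff(unique(labels), own))
      b_i <- min(b_i, mean(d[i, labels == g]))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  s
}

oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  wins <- 0
  for (p in pos) for (q in neg) {
    if (scores[p] > scores[q]) wins <- wins + 1
    else if (scores[p] == scores[q]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Agglomerative complete linkage by full re-scan of all cluster pairs at
# every merge; returns labels for k clusters.
oracle_complete_linkage <- function(d, k) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      link <- max(d[clusters[[i]], clusters[[j]]])
      if (link < best_d) { best_d <- link; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(d))
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Random test-case builders -------------------------------------------------

rand_seq <- function(L, alphabet = c("A", "C", "G", "T"),
                     gap_prob = 0, amb_prob = 0) {
  s <- sample(alphabet, L, replace = TRUE)
  r <- runif(L)
  s[r < gap_prob] <- "-"
  s[r >= gap_prob & r < gap_prob + amb_prob] <- "N"
  paste(s, collapse = "")
}

rand_alignment <- function(n, L, gap_prob = 0.05, amb_prob = 0.05) {
  dna_alignment(sprintf("s%02d", seq_len(n)),
                vapply(seq_len(n),
                       function(i) rand_seq(L, gap_prob = gap_prob,
                                            amb_prob = amb_prob),
                       character(1)))
}

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

same_partition <- function(a, b) {
  isTRUE(all.equal(mclust::adjustedRandIndex(a, b), 1))
}
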