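# Seeded simulator of control-region-like alignments with planted group
# structure: a shared ancestor, one founder per group (between-group
# divergence), individuals mutated off their founder (within-group
# divergence), a handful of guaranteed diagnostic columns, and sparse gaps.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults mirror the shape of a two-group mitochondrial control-region
#' dataset: 733 aligned columns, unequal group sizes 65/30, low within-group
#' and distinctly higher between-group divergence, occasional gaps, and six
#' planted fixed-difference (diagnostic) columns.
#'
#' @param length Alignment columns.
#' @param group_sizes Integer vector of group sizes (all >= 1).
#' @param d_within Per-site substitution probability on each individual's
#'   branch from its group founder.
#' @param d_between Per-site substitution probability on each group
#'   founder's branch from the shared ancestor.
#' @param gap_rate Per-cell gap probability (planted columns excluded).
#' @param n_diagnostic Number of planted fixed inter-group difference
#'   columns (needs `length >= n_diagnostic`; at most 4 groups get
#'   guaranteed-distinct bases).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(length = 733L, group_sizes = c(65L, 30L),
                       d_within = 0.005, d_between = 0.05,
                       gap_rate = 0.005, n_diagnostic = 6L, seed = 1L) {
  length <- as.integer(length)
  group_sizes <- as.integer(group_sizes)
  n_diagnostic <- as.integer(n_diagnostic)
  if (length < 1L) stop("length must be positive")
  if (any(group_sizes < 1L)) stop("group sizes must all be >= 1")
  if (n_diagnostic < 0L || n_diagnostic > length)
    stop("n_diagnostic must be between 0 and the alignment length")
  if (n_diagnostic > 0L && length(group_sizes) > 4L)
    stop("diagnostic columns support at most 4 groups")
  if (d_within < 0 || d_between < 0 || d_within > 0.75 || d_between > 0.75)
    stop("divergence rates must be in [0, 0.75]")
  if (d_between > 0 && d_within >= d_between)
    stop("d_within must be below d_between (cryptic-species premise)")
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")
  structure(list(length = length, group_sizes = group_sizes,
                 d_within = d_within, d_between = d_between,
                 gap_rate = gap_rate, n_diagnostic = n_diagnostic,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Internal: mutate each site with probability p, uniformly to one of the
# three other bases.
mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  hit <- stats::runif(length(seq)) < p
  if (any(hit)) {
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(setdiff(BASES, b), 1L),
                       character(1))
  }
  seq
}

#' Simulate an alignment with planted group structure
#'
#' Draws a uniform-random ancestor sequence; derives one founder per group
#' by mutating each site with probability `d_between`; derives individuals
#' from their founder with per-site probability `d_within`; overwrites the
#' planted diagnostic columns with fixed, distinct, within-group-monomorphic
#' bases; and finally injects gaps at `gap_rate` outside the planted
#' columns.
#'
#' @param config A [sim_config()] (or arguments passed on to it).
#' @param ... When `config` is missing, forwarded to [sim_config()].
#' @return Object of class `sim_dataset`: `alignment` (a [dna_alignment]
#'   with labels), `true_labels`, `planted_sites` (1-based columns),
#'   `config`.
#' @export
simulate_alignment <- function(config = sim_config(...), ...) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$length
  g <- length(config$group_sizes)
  ancestor <- sample(BASES, L, replace = TRUE)
  founders <- lapply(seq_len(g), function(i)
    mutate_seq(ancestor, config$d_between))
  planted <- if (config$n_diagnostic > 0L)
    sort(sample.int(L, config$n_diagnostic)) else integer(0)
  if (length(planted)) {
    for (col in planted) {
      picks <- sample(BASES, g)          # distinct base per group
      for (i in seq_len(g)) founders[[i]][col] <- picks[i]
    }
  }
  ids <- character(0); seqs <- character(0); labels <- character(0)
  for (i in seq_len(g)) {
    gname <- paste0("group", i)
    for (j in seq_len(config$group_sizes[i])) {
      s <- mutate_seq(founders[[i]], config$d_within)
      if (length(planted)) s[planted] <- founders[[i]][planted]
      if (config$gap_rate > 0) {
        gaps <- stats::runif(L) < config$gap_rate
        gaps[planted] <- FALSE
        s[gaps] <- "-"
      }
      ids <- c(ids, sprintf("%s_%02d", gname, j))
      seqs <- c(seqs, paste(s, collapse = ""))
      labels <- c(labels, gname)
    }
  }
  structure(list(alignment = dna_alignment(ids, seqs, labels = labels),
                 true_labels = labels, planted_sites = planted,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(paste0("Simulated alignment: %d sequences (%s) x %d bp, ",
                     "%d diagnostic column(s), seed %d\n"),
              length(x$alignment$ids),
              paste(x$config$group_sizes, collapse = "/"),
              x$config$length, length(x$planted_sites), x$config$seed))
  invisible(x)
}

#' Expected within- and between-group p-distance for a configuration
#'
#' Under the site-independent uniform-alternative substitution model, an
#' edge with mutation probability p leaves a site unchanged in expectation
#' through the factor `(1 - 4p/3)` on the non-identity eigenvalue, so two
#' sequences separated by edges `p1, ..., pk` differ at a site with
#' probability `(3/4)(1 - prod(1 - 4 p_i/3))`. Within a group the path is
#' two `d_within` edges; between groups it is two `d_within` and two
#' `d_between` edges, and the planted diagnostic columns always differ.
#' Planted columns are within-group monomorphic, diluting the within
#' expectation by `(L - n_diagnostic)/L`.
#'
#' @param config A [sim_config()].
#' @return List with `within` and `between` expected p-distances.
#' @export
expected_pdistance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  e <- function(p) 1 - 4 * p / 3
  p_path <- function(edges) 0.75 * (1 - prod(vapply(edges, e, numeric(1))))
  L <- config$length; nd <- config$n_diagnostic
  w <- config$d_within; b <- config$d_between
  within <- p_path(c(w, w)) * (L - nd) / L
  between <- (p_path(c(w, b, b, w)) * (L - nd) + nd) / L
  list(within = within, between = between)
}

#' Write a simulated dataset to disk
#'
#' Writes the FASTA alignment, an `id<TAB>label` table, the planted-site
#' list and the configuration as JSON.
#'
#' @param sim A [simulate_alignment()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, paste0(prefix, ".fasta")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    planted = file.path(dir, paste0(prefix, "_planted_sites.tsv")),
    config = file.path(dir, paste0(prefix, "_config.json")))
  write_fasta(sim$alignment, paths["fasta"])
  utils::write.table(
    data.frame(id = sim$alignment$ids, label = sim$true_labels),
    paths["labels"], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(column = sim$planted_sites),
                     paths["planted"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
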