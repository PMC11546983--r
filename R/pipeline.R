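# File-based pipeline: read inputs, run the scan stage by stage, write
# tabular reports and a reproducibility manifest.

PIPELINE_STAGES <- c("pdist", "validity", "cluster", "classify",
                     "importance", "report")

#' Run the delimitation pipeline on a FASTA file
#'
#' Thin file-based orchestration over [cryptic_scan()]: reads the
#' alignment, runs the requested stages in dependency order, and writes
#' tab-separated reports plus a JSON manifest (package version, seed,
#' parameters, input checksum) from which any run can be reconstructed.
#' Outputs are pure functions of the inputs and the seed; a rerun with the
#' same configuration reproduces them byte for byte.
#'
#' @param input Path to an aligned FASTA file.
#' @param output_dir Directory for the reports (created if needed).
#' @param stages Subset of `r paste(PIPELINE_STAGES, collapse = ", ")`;
#'   later stages pull in the computation (not the files) of earlier ones.
#' @param labels Optional `id<TAB>label` file; when given, the
#'   classification stage uses these labels instead of the consensus
#'   clusters.
#' @param seed Master seed.
#' @param ... Passed to [cryptic_scan()] (e.g. `k`, `k_range`,
#'   `reference_id`, `gap_b`, `nmf_nrun`).
#' @return Invisibly, a list with the fitted `scan` object and the written
#'   `paths`.
#' @export
run_pipeline <- function(input, output_dir, stages = PIPELINE_STAGES,
                         labels = NULL, seed = 1L, ...) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- read_alignment(input, labels = labels)
  paths <- character(0)
  need_cluster <- any(c("cluster", "classify", "importance", "report")
                      %in% stages)
  need_validity <- need_cluster || "validity" %in% stages
  classify <- any(c("classify", "importance", "report") %in% stages)

  if (need_validity) {
    scan <- cryptic_scan(aln, seed = seed, classify = classify,
                         group_labels = aln$labels, ...)
  } else {
    scan <- NULL
  }
  dm <- if (is.null(scan)) distance_matrix(aln) else scan$dm

  if ("pdist" %in% stages) {
    p1 <- file.path(output_dir, "pdist_matrix.tsv")
    p2 <- file.path(output_dir, "pdist_long.tsv")
    write_distance_tsv(dm, p1)
    write_distance_tsv(dm, p2, long = TRUE)
    paths <- c(paths, pdist_matrix = p1, pdist_long = p2)
  }
  if ("validity" %in% stages && !is.null(scan)) {
    p <- file.path(output_dir, "validity_curve.tsv")
    utils::write.table(as.data.frame(scan$validity), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, validity = p)
  }
  if ("cluster" %in% stages && !is.null(scan)) {
    tab <- data.frame(id = aln$ids)
    for (nm in names(scan$clusterings))
      tab[[nm]] <- scan$clusterings[[nm]]$labels
    tab$consensus <- scan$consensus$consensus_labels
    p <- file.path(output_dir, "clusters.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, clusters = p)
  }
  if ("classify" %in% stages && !is.null(scan$cv)) {
    p <- file.path(output_dir, "cv_report.json")
    rep <- list(
      folds = scan$cv$folds, seed = scan$cv$seed,
      mean_auc = as.list(scan$cv$mean_auc),
      sd_auc = as.list(scan$cv$sd_auc),
      mean_f1 = as.list(scan$cv$mean_f1),
      confusion = lapply(scan$cv$confusion, function(m)
        as.data.frame(as.table(m))),
      per_fold = lapply(scan$cv$per_fold, function(folds)
        lapply(folds, unclass)))
    jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, cv_report = p)
  }
  if ("importance" %in% stages && !is.null(scan$importance)) {
    p <- file.path(output_dir, "importance.tsv")
    utils::write.table(
      data.frame(column = scan$importance$column_index,
                 importance = scan$importance$importance),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, importance = p)
    p2 <- file.path(output_dir, "logo_data.tsv")
    utils::write.table(scan$logo, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, logo = p2)
  }
  if ("report" %in% stages) {
    p <- file.path(output_dir, "manifest.json")
    manifest <- list(
      package = "crypticscan",
      version = as.character(utils::packageVersion("crypticscan")),
      seed = seed,
      input = basename(input),
      input_md5 = unname(tools::md5sum(input)),
      n_sequences = length(aln$ids),
      n_columns = aln$length,
      stages = stages,
      params = lapply(list(...), function(x)
        if (is.function(x)) deparse(x) else x),
      chosen_k = if (!is.null(scan)) scan$k else NULL,
      consensus_sizes = if (!is.null(scan))
        as.integer(table(scan$consensus$consensus_labels)) else NULL,
      outputs = as.list(stats::setNames(basename(paths), names(paths))))
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    paths <- c(paths, manifest = p)
  }
  invisible(list(scan = scan, paths = paths))
}
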