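# Aligned-sequence container, FASTA I/O and ordinal encoding.

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct an aligned-sequence set
#'
#' A `dna_alignment` holds equal-length DNA sequences (uppercase, gaps as
#' `-`, IUPAC ambiguity codes allowed) with unique identifiers and an
#' optional per-sequence group label.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (one string each), same
#'   length as `ids`. Case is folded to upper and `U` is mapped to `T`.
#' @param labels Optional character vector of group labels per sequence.
#' @return An object of class `dna_alignment` with elements `ids`, `seqs`,
#'   `length` (alignment columns) and `labels`.
#' @export
dna_alignment <- function(ids, seqs, labels = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop("'ids' and 'seqs' must have the same length")
  if (length(seqs) == 0L) stop("alignment is empty")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences are not aligned (unequal lengths): ",
         paste(ids[nchar(seqs) != len[1L]], collapse = ", "))
  if (len == 0L) stop("alignment has zero columns")
  cls <- paste(c(setdiff(ALN_ALPHABET, "-"), "-"), collapse = "")
  bad <- !grepl(sprintf("^[%s]*$", cls), seqs)
  if (any(bad))
    stop("unexpected characters in sequences: ", paste(ids[bad], collapse = ", "))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(ids))
      stop("'labels' must match the number of sequences")
  }
  structure(list(ids = ids, seqs = seqs, length = len, labels = labels),
            class = "dna_alignment")
}

#' Read an aligned FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Case is folded to upper and `U` is mapped to `T`. Ragged (unaligned)
#' input, duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file containing one alignment.
#' @param labels Optional path to a two-column tab-separated file
#'   (`id<TAB>label`, no header) assigning a group label to every id.
#' @return A [dna_alignment].
#' @export
read_alignment <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  aln <- dna_alignment(ids, as.character(set))
  if (!is.null(labels)) {
    lab <- read_labels(labels)
    missing <- setdiff(aln$ids, names(lab))
    if (length(missing))
      stop("no label for ids: ", paste(missing, collapse = ", "))
    aln$labels <- unname(lab[aln$ids])
  }
  aln
}

#' Read a two-column id/label table
#'
#' @param path Tab-separated file with columns `id` and `label`, no header.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label file must have two tab-separated columns")
  if (anyDuplicated(tab[[1L]])) stop("duplicate ids in label file")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write an alignment to FASTA
#'
#' @param aln A [dna_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  set <- Biostrings::BStringSet(stats::setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("Alignment of", length(x$ids), "sequences x", x$length, "columns\n")
  if (!is.null(x$labels))
    cat("Groups:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                 table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.dna_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

#' Ordinal encoding of an alignment
#'
#' Maps bases to integers for the clustering/classification stages:
#' A = 1, T = 2, C = 3, G = 4, gap = 0. Ambiguity codes (N and other IUPAC
#' symbols) carry no usable ordinal rank and are encoded 0, the same sink as
#' gaps.
#'
#' @param aln A [dna_alignment].
#' @return Integer matrix (sequences x columns, entries in 0..4) with
#'   rownames set to sequence ids and an attribute `column_map` giving the
#'   1-based alignment column of each matrix column.
#' @export
encode_ordinal <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  chars <- as.matrix(aln)
  codes <- c(A = 1L, T = 2L, C = 3L, G = 4L)
  m <- matrix(unname(codes[chars]), nrow = nrow(chars))
  m[is.na(m)] <- 0L
  rownames(m) <- aln$ids
  attr(m, "column_map") <- seq_len(ncol(m))
  m
}

# Internal: A=1,C=2,G=3,T=4, everything else (gap/ambiguity) 0.
# Distinct from encode_ordinal; used for distance computation where 0 marks
# a site excluded by pairwise deletion.
aln_codes <- function(aln) {
  chars <- as.matrix(aln)
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(unname(codes[chars]), nrow = nrow(chars))
  m[is.na(m)] <- 0L
  rownames(m) <- aln$ids
  m
}
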