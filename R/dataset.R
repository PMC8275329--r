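#' In-memory dataset of candidate bound regions
#'
#' Bundles region sequences with strand-specific binarized 5'-end read
#' indicators (and optionally the raw counts they were derived from) into the
#' container consumed by the sampler, the prediction functions and the output
#' writers. Datasets built from genomic files come out of [extract_regions()]
#' + [load_counts()] + [binarize()]; synthetic datasets come from
#' [generate_dataset()]. Reverse-complement augmentation ([augment_revcomp()])
#' must be applied before model fitting.
#'
#' @param seqs character vector of region sequences over `A,C,G,T,N`.
#' @param binary_pos,binary_neg lists of 0/1 integer vectors, one per region,
#'   each the same length as its sequence: presence of a read 5' end at that
#'   position on the positive / negative strand.
#' @param counts_pos,counts_neg optional lists of non-negative count vectors
#'   (kept so [binarize()] can be re-run at a different threshold).
#' @param regions optional `data.frame` with one row per region and columns
#'   `id, chrom, start, end, summit` (0-based half-open genomic coordinates).
#'   Defaults to synthetic placeholders.
#' @param binarize_threshold threshold used to produce the binary vectors
#'   (`NA` if they were generated directly).
#' @return An object of class `exo_dataset`: a list with elements `seqs`,
#'   `binary_pos`, `binary_neg`, `counts_pos`, `counts_neg`, `regions`,
#'   `n_original`, `augmented`, `binarize_threshold`.
#' @export
exo_dataset <- function(seqs, binary_pos = NULL, binary_neg = NULL,
                        counts_pos = NULL, counts_neg = NULL,
                        regions = NULL, binarize_threshold = NA_real_) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n == 0L) stop("empty dataset: no regions")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("sequence alphabet must be {A,C,G,T,N}; offending region ", which(bad)[1])
  lens <- nchar(seqs)
  zero_bits <- function() lapply(lens, function(L) integer(L))
  if (is.null(binary_pos)) binary_pos <- zero_bits()
  if (is.null(binary_neg)) binary_neg <- zero_bits()
  chk <- function(x, nm, binary = TRUE) {
    if (length(x) != n) stop(nm, " must have one vector per region")
    for (i in seq_len(n)) {
      v <- x[[i]]
      if (length(v) != lens[i]) stop(nm, "[[", i, "]] length != sequence length")
      if (any(v < 0)) stop("negative values in ", nm)
      if (binary && any(v > 1)) stop(nm, " must be 0/1")
    }
    lapply(x, as.integer)
  }
  binary_pos <- chk(binary_pos, "binary_pos")
  binary_neg <- chk(binary_neg, "binary_neg")
  if (!is.null(counts_pos)) counts_pos <- chk(counts_pos, "counts_pos", binary = FALSE)
  if (!is.null(counts_neg)) counts_neg <- chk(counts_neg, "counts_neg", binary = FALSE)
  if (is.null(regions)) {
    regions <- data.frame(
      id = paste0("region_", seq_len(n)), chrom = "synthetic",
      start = (seq_len(n) - 1L) * (max(lens) + 20L),
      end = (seq_len(n) - 1L) * (max(lens) + 20L) + lens,
      summit = (seq_len(n) - 1L) * (max(lens) + 20L) + lens %/% 2L,
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(regions) == n)
  regions$is_revcomp <- FALSE
  regions$partner <- NA_integer_
  structure(list(seqs = seqs, binary_pos = binary_pos, binary_neg = binary_neg,
                 counts_pos = counts_pos, counts_neg = counts_neg,
                 regions = regions, n_original = n, augmented = FALSE,
                 binarize_threshold = binarize_threshold),
            class = "exo_dataset")
}

#' @export
print.exo_dataset <- function(x, ...) {
  cat("exo_dataset:", length(x$seqs), "datapoints",
      if (x$augmented) sprintf("(%d regions, RC-augmented)", x$n_original) else "(not augmented)",
      "\n  lengths:", paste(range(nchar(x$seqs)), collapse = "-"),
      "bp; binarize threshold:", x$binarize_threshold, "\n")
  invisible(x)
}

n_datapoints <- function(ds) length(ds$seqs)

BASES <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string (N-preserving)
#' @param x character vector of sequences over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## integer encoding A=1 C=2 G=3 T=4 N=5
encode_seq <- function(s) match(strsplit(s, "")[[1]], BASES)

#' Append reverse-complement copies to a dataset
#'
#' For each region appends a copy with the sequence reverse-complemented and
#' the strand read vectors swapped and reversed (`binary_pos` of the copy is
#' the reversed `binary_neg` of the original, and vice versa), so motifs on
#' either strand can be captured by one PWM. Copies are stored after all
#' originals; partner links are set both ways.
#'
#' @param dataset an [exo_dataset()].
#' @return The augmented dataset with `2 * n_original` datapoints.
#' @export
augment_revcomp <- function(dataset) {
  stopifnot(inherits(dataset, "exo_dataset"))
  if (isTRUE(dataset$augmented)) stop("dataset is already reverse-complement augmented")
  n <- dataset$n_original
  rc_seq <- revcomp(dataset$seqs)
  rc_bp <- lapply(dataset$binary_neg, rev)
  rc_bn <- lapply(dataset$binary_pos, rev)
  dataset$seqs <- c(dataset$seqs, rc_seq)
  dataset$binary_pos <- c(dataset$binary_pos, rc_bp)
  dataset$binary_neg <- c(dataset$binary_neg, rc_bn)
  if (!is.null(dataset$counts_pos)) {
    dataset$counts_pos <- c(dataset$counts_pos, lapply(dataset$counts_neg, rev))
    dataset$counts_neg <- c(dataset$counts_neg[seq_len(n)],
                            lapply(dataset$counts_pos[seq_len(n)], rev))
  }
  rc_regions <- dataset$regions
  rc_regions$id <- paste0(rc_regions$id, "_rc")
  rc_regions$is_revcomp <- TRUE
  rc_regions$partner <- seq_len(n)
  dataset$regions$partner <- n + seq_len(n)
  dataset$regions <- rbind(dataset$regions, rc_regions)
  rownames(dataset$regions) <- NULL
  dataset$augmented <- TRUE
  dataset
}
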