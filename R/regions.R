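#' Extract fixed-width regions around peak summits from a genome
#'
#' Builds the candidate bound windows the model is trained on: a
#' `2 * flank` bp window centred on each summit. Soft-masked (lowercase)
#' bases in the genome are treated as repeats and converted to `N`; regions
#' with fewer than `min_informative` non-`N` bases are dropped, as are
#' regions truncated by a chromosome edge and regions overlapping a
#' previously accepted one (first-come precedence in input order).
#'
#' @param peaks BED-like input: either a file path (>= 3 tab-separated
#'   columns, 0-based half-open) or a `data.frame` whose first three columns
#'   are chrom/start/end (column 4, if present, is the region id). A
#'   single-base record is taken as the summit itself; otherwise the summit
#'   is the interval midpoint, unless `summit_col` names/indexes a column
#'   holding a summit offset relative to `start`.
#' @param genome FASTA file path or a named `Biostrings::DNAStringSet`.
#'   Lowercase letters are honoured as soft-masking.
#' @param flank half-window size in bp (default 120, i.e. 240 bp windows).
#' @param min_informative minimum number of non-`N` bases required to keep a
#'   region (default 100).
#' @param summit_col optional column index/name in `peaks` giving the summit
#'   offset from `start`.
#' @return A `data.frame` of accepted regions with columns
#'   `id, chrom, start, end, summit, sequence` (0-based half-open; the
#'   window is `[summit - flank, summit + flank)`).
#' @export
extract_regions <- function(peaks, genome, flank = 120L, min_informative = 100L,
                            summit_col = NULL) {
  stopifnot(flank > 0)
  flank <- as.integer(flank)
  pk <- read_peaks(peaks, summit_col)
  gen <- load_genome(genome)
  glens <- setNames(Biostrings::width(gen), names(gen))
  missing_chrom <- setdiff(unique(pk$chrom), names(gen))
  if (length(missing_chrom))
    stop("chromosome(s) absent from genome: ", paste(missing_chrom, collapse = ", "))

  start <- pk$summit - flank          # 0-based
  end <- pk$summit + flank            # half-open
  keep <- rep(TRUE, nrow(pk))
  trunc <- start < 0L | end > glens[pk$chrom]
  if (any(trunc)) {
    warning(sum(trunc), " region(s) truncated by a chromosome edge were dropped")
    keep[trunc] <- FALSE
  }
  ## overlap filter, first-come precedence by input order
  accepted <- list()
  for (i in which(keep)) {
    prev <- accepted[[pk$chrom[i]]]
    if (!is.null(prev) && any(start[i] < prev[, 2L] & end[i] > prev[, 1L])) {
      keep[i] <- FALSE
    } else {
      accepted[[pk$chrom[i]]] <- rbind(prev, c(start[i], end[i]))
    }
  }
  idx <- which(keep)
  if (!length(idx)) stop("no regions survived extraction")
  seqs <- as.character(Biostrings::subseq(gen[pk$chrom[idx]],
                                          start = start[idx] + 1L, end = end[idx]))
  ## soft-masked (lowercase) and ambiguous bases -> N
  seqs <- gsub("[^ACGT]", "N", chartr("acgtn", "NNNNN", seqs))
  informative <- nchar(gsub("N", "", seqs))
  low <- informative < min_informative
  if (any(low)) {
    message(sum(low), " region(s) dropped with < ", min_informative, " non-repetitive bases")
    idx <- idx[!low]; seqs <- seqs[!low]
  }
  if (!length(idx)) stop("no regions survived the repeat filter")
  data.frame(id = pk$id[idx], chrom = pk$chrom[idx],
             start = start[idx], end = end[idx], summit = pk$summit[idx],
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

read_peaks <- function(peaks, summit_col = NULL) {
  if (is.character(peaks) && length(peaks) == 1L) {
    peaks <- read.table(peaks, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(peaks), ncol(peaks) >= 3L)
  chrom <- as.character(peaks[[1L]])
  start <- as.integer(peaks[[2L]])
  end <- as.integer(peaks[[3L]])
  if (any(end <= start)) stop("malformed peak intervals (end <= start)")
  id <- if (ncol(peaks) >= 4L && !is.numeric(peaks[[4L]])) as.character(peaks[[4L]])
        else paste0("peak_", seq_along(chrom))
  if (!is.null(summit_col)) {
    summit <- start + as.integer(peaks[[summit_col]])
  } else {
    summit <- ifelse(end - start == 1L, start, start + (end - start) %/% 2L)
  }
  data.frame(id = id, chrom = chrom, start = start, end = end,
             summit = as.integer(summit), stringsAsFactors = FALSE)
}

load_genome <- function(genome) {
  if (inherits(genome, c("DNAStringSet", "BStringSet"))) return(genome)
  if (is.character(genome) && length(genome) == 1L) {
    ## BStringSet preserves case, i.e. soft-masking
    gen <- Biostrings::readBStringSet(genome)
    names(gen) <- sub("\\s.*$", "", names(gen))
    return(gen)
  }
  stop("genome must be a FASTA path or a DNAStringSet/BStringSet")
}

#' Assemble a dataset from extracted regions and read tracks
#'
#' Convenience wrapper chaining [load_counts()], [binarize()] and dataset
#' construction from the output of [extract_regions()].
#'
#' @param regions output of [extract_regions()].
#' @param track_pos,track_neg per-strand signal files (bedGraph/bigWig) or
#'   GRanges with a `score` column.
#' @param threshold binarization threshold; `NULL` uses the pooled median of
#'   positive counts.
#' @param ... passed to [load_counts()] (controls, scale).
#' @return An unaugmented [exo_dataset()].
#' @export
build_dataset <- function(regions, track_pos, track_neg, threshold = NULL, ...) {
  counts <- load_counts(track_pos, track_neg, regions, ...)
  bin <- binarize(counts, threshold = threshold)
  exo_dataset(seqs = regions$sequence,
              binary_pos = bin$binary_pos, binary_neg = bin$binary_neg,
              counts_pos = counts$counts_pos, counts_neg = counts$counts_neg,
              regions = regions[, c("id", "chrom", "start", "end", "summit")],
              binarize_threshold = bin$threshold)
}
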