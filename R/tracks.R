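#' Load per-region strand-specific 5'-end counts
#'
#' Extracts per-base counts in region-local coordinates from genome-wide
#' signal tracks (bedGraph or bigWig, one per strand), optionally subtracting
#' a scaled control: `count := max(0, treatment - scale * control)` per
#' position. The default scale is the library-size ratio
#' `sum(treatment) / sum(control)` over the whole track.
#'
#' @param track_pos,track_neg positive/negative strand treatment tracks: file
#'   paths understood by `rtracklayer::import` or `GRanges` with a numeric
#'   `score` column. All values must be non-negative.
#' @param regions `data.frame` with `chrom, start, end` (0-based half-open),
#'   e.g. from [extract_regions()].
#' @param control_pos,control_neg optional control tracks.
#' @param scale control scaling factor; `NULL` (default) uses the
#'   library-size ratio.
#' @return list with `counts_pos`, `counts_neg` (lists of integer-valued
#'   vectors in region coordinates) and the `scale` used (`NA` without
#'   control).
#' @export
load_counts <- function(track_pos, track_neg, regions,
                        control_pos = NULL, control_neg = NULL, scale = NULL) {
  tp <- track_coverage(track_pos)
  tn <- track_coverage(track_neg)
  have_ctrl <- !is.null(control_pos) || !is.null(control_neg)
  if (have_ctrl) {
    if (is.null(control_pos) || is.null(control_neg))
      stop("supply control tracks for both strands or neither")
    cp <- track_coverage(control_pos)
    cn <- track_coverage(control_neg)
    if (is.null(scale)) {
      tot_t <- sum(vapply(tp, function(r) sum(as.numeric(r)), 0)) +
               sum(vapply(tn, function(r) sum(as.numeric(r)), 0))
      tot_c <- sum(vapply(cp, function(r) sum(as.numeric(r)), 0)) +
               sum(vapply(cn, function(r) sum(as.numeric(r)), 0))
      scale <- if (tot_c > 0) tot_t / tot_c else 0
    }
  }
  pull <- function(cov, chrom, start, end) {
    L <- end - start
    r <- cov[[chrom]]
    if (is.null(r)) return(NULL)
    if (end > length(r)) {                       # track shorter than region
      v <- rep(0, L)
      avail <- max(0L, length(r) - start)
      if (avail > 0) v[seq_len(avail)] <- as.numeric(r[(start + 1L):min(end, length(r))])
      return(v)
    }
    as.numeric(r[(start + 1L):end])
  }
  miss_warned <- character(0)
  one_region <- function(i, treat, ctrl) {
    v <- pull(treat, regions$chrom[i], regions$start[i], regions$end[i])
    if (is.null(v)) {
      if (!(regions$chrom[i] %in% miss_warned)) {
        warning("chromosome ", regions$chrom[i],
                " missing from a signal track; counts set to 0")
        miss_warned <<- c(miss_warned, regions$chrom[i])
      }
      v <- rep(0, regions$end[i] - regions$start[i])
    }
    if (have_ctrl) {
      cv <- pull(ctrl, regions$chrom[i], regions$start[i], regions$end[i])
      if (is.null(cv)) cv <- rep(0, length(v))
      v <- pmax(0, v - scale * cv)
    }
    v
  }
  n <- nrow(regions)
  counts_pos <- lapply(seq_len(n), one_region, treat = tp,
                       ctrl = if (have_ctrl) cp else NULL)
  counts_neg <- lapply(seq_len(n), one_region, treat = tn,
                       ctrl = if (have_ctrl) cn else NULL)
  list(counts_pos = counts_pos, counts_neg = counts_neg,
       scale = if (have_ctrl) scale else NA_real_)
}

## genome-wide coverage (simple list of per-chromosome Rle) from a track
track_coverage <- function(track) {
  if (is.character(track) && length(track) == 1L) {
    track <- rtracklayer::import(track)
  }
  if (!inherits(track, "GRanges")) stop("track must be a file path or GRanges")
  sc <- track$score
  if (is.null(sc)) stop("signal track has no score column")
  if (any(sc < 0)) stop("negative values in signal track")
  cov <- GenomicRanges::coverage(track, weight = "score")
  as.list(cov)
}

#' Binarize read counts at a threshold
#'
#' A position carries a read indicator of 1 iff its count is strictly greater
#' than the threshold. The default threshold is the median of all strictly
#' positive counts pooled over both strands and all regions, so the upper
#' half of the nonzero signal is marked.
#'
#' @param counts list with `counts_pos` and `counts_neg` (as from
#'   [load_counts()]), or an [exo_dataset()] carrying counts.
#' @param threshold numeric threshold; `NULL` for the pooled-median default.
#' @return For a counts list: list with `binary_pos`, `binary_neg` and the
#'   `threshold` used. For a dataset: the dataset with binaries and
#'   `binarize_threshold` replaced.
#' @export
binarize <- function(counts, threshold = NULL) {
  is_ds <- inherits(counts, "exo_dataset")
  cp <- if (is_ds) counts$counts_pos else counts$counts_pos
  cn <- if (is_ds) counts$counts_neg else counts$counts_neg
  if (is.null(cp) || is.null(cn)) stop("no counts to binarize")
  pooled <- c(unlist(cp, use.names = FALSE), unlist(cn, use.names = FALSE))
  if (is.null(threshold)) {
    pos <- pooled[pooled > 0]
    if (!length(pos)) {
      warning("all read counts are zero; threshold set to 0")
      threshold <- 0
    } else threshold <- median(pos)
  }
  bp <- lapply(cp, function(v) as.integer(v > threshold))
  bn <- lapply(cn, function(v) as.integer(v > threshold))
  if (is_ds) {
    counts$binary_pos <- bp
    counts$binary_neg <- bn
    counts$binarize_threshold <- threshold
    counts
  } else {
    list(binary_pos = bp, binary_neg = bn, threshold = threshold)
  }
}
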