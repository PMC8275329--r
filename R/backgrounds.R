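#' Fit background models for sequence and reads
#'
#' The sequence background is a 2nd-order Markov chain with add-one
#' smoothing, estimated from all (RC-augmented) sequences, with lower-order
#' fallbacks used at sequence starts and next to `N`s. Training on the
#' augmented set makes it strand-symmetric by construction. The read
#' background is a per-strand Bernoulli rate over all binarized positions,
#' add-one smoothed on both outcomes.
#'
#' @param dataset an augmented, binarized [exo_dataset()].
#' @return list with elements `seq` (class `exo_bg_seq`: `p0` length-4,
#'   `p1` 4x4, `p2` 16x4 conditional probability tables) and `read`
#'   (class `exo_bg_read`: `p_pos`, `p_neg`).
#' @export
fit_backgrounds <- function(dataset) {
  stopifnot(inherits(dataset, "exo_dataset"))
  if (n_datapoints(dataset) == 0L) stop("empty dataset")
  enc <- lapply(dataset$seqs, encode_seq)
  c0 <- numeric(4); c1 <- matrix(0, 4, 4); c2 <- matrix(0, 16, 4)
  for (s in enc) {
    L <- length(s)
    ok <- s <= 4L
    c0 <- c0 + tabulate(s[ok], 4L)
    if (L >= 2L) {
      i <- which(ok[-L] & ok[-1L])
      if (length(i)) {
        t1 <- tabulate((s[i] - 1L) * 4L + s[i + 1L], 16L)
        c1 <- c1 + matrix(t1, 4, 4, byrow = TRUE)
      }
    }
    if (L >= 3L) {
      j <- which(ok[1:(L - 2L)] & ok[2:(L - 1L)] & ok[3:L])
      if (length(j)) {
        ctx <- (s[j] - 1L) * 4L + s[j + 1L]       # 1..16
        t2 <- tabulate((ctx - 1L) * 4L + s[j + 2L], 64L)
        c2 <- c2 + matrix(t2, 16, 4, byrow = TRUE)
      }
    }
  }
  norm <- function(m) (m + 1) / (rowSums(m) + 4)
  bg_seq <- structure(list(p0 = (c0 + 1) / (sum(c0) + 4),
                           p1 = norm(c1), p2 = norm(c2)),
                      class = "exo_bg_seq")
  bpos <- unlist(dataset$binary_pos, use.names = FALSE)
  bneg <- unlist(dataset$binary_neg, use.names = FALSE)
  bg_read <- structure(list(p_pos = (sum(bpos) + 1) / (length(bpos) + 2),
                            p_neg = (sum(bneg) + 1) / (length(bneg) + 2)),
                       class = "exo_bg_read")
  list(seq = bg_seq, read = bg_read)
}

## per-position log background probability of an encoded sequence (1..4, 5=N)
## order-2 where the two preceding bases exist and are unambiguous, with
## order-1/order-0 fallback; N positions emit uniformly at 1/4
bg_seq_logp <- function(bg, s) {
  L <- length(s)
  out <- numeric(L)
  isN <- s == 5L
  ## order 0 by default
  out[!isN] <- log(bg$p0[s[!isN]])
  out[isN] <- log(0.25)
  if (L >= 2L) {
    j <- 2:L
    ok1 <- !isN[j] & !isN[j - 1L]
    jj <- j[ok1]
    out[jj] <- log(bg$p1[cbind(s[jj - 1L], s[jj])])
  }
  if (L >= 3L) {
    j <- 3:L
    ok2 <- !isN[j] & !isN[j - 1L] & !isN[j - 2L]
    jj <- j[ok2]
    out[jj] <- log(bg$p2[cbind((s[jj - 2L] - 1L) * 4L + s[jj - 1L], s[jj])])
  }
  out
}

## per-position log background probability of a binary read vector
bg_read_logp <- function(p, bits) {
  ifelse(bits == 1L, log(p), log1p(-p))
}
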