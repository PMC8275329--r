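#' Log-likelihood ratio of a motif site against the sequence background
#'
#' Log of the PWM probability of the site string starting at `z` minus the
#' log background probability of the same string under the 2nd-order chain,
#' conditioned on the actual bases preceding `z` (lower order at sequence
#' starts). Bases outside the site cancel between the two models, so the
#' ratio depends only on the site string and its immediate left context.
#'
#' @param seq sequence (character string or integer encoding 1..4, 5 = N).
#' @param z 1-based motif start position.
#' @param pwm 4 x w matrix of column distributions over A,C,G,T.
#' @param bg an `exo_bg_seq` background from [fit_backgrounds()].
#' @return The log ratio, or `-Inf` for an invalid site (out of bounds or
#'   containing `N`).
#' @export
seq_loglik_ratio <- function(seq, z, pwm, bg) {
  s <- if (is.character(seq)) encode_seq(seq) else as.integer(seq)
  w <- ncol(pwm)
  L <- length(s)
  if (z < 1L || z + w - 1L > L) return(-Inf)
  site <- s[z:(z + w - 1L)]
  if (any(site == 5L)) return(-Inf)
  lp <- sum(log(pwm[cbind(site, seq_len(w))]))
  lbg <- sum(bg_seq_logp(bg, s)[z:(z + w - 1L)])
  lp - lbg
}

#' Log-likelihood ratio of a read window against the read background
#'
#' Sum over the window positions of the log Bernoulli probability of the
#' observed 0/1 indicator under the mode's window parameters minus the log
#' probability under the per-strand background rate. The window starts at
#' `z + tau`.
#'
#' @param bits 0/1 integer vector for one strand.
#' @param z 1-based motif start position.
#' @param tau signed window offset (window start = `z + tau`).
#' @param bern vector of window Bernoulli success probabilities.
#' @param bg_p background per-position read probability for this strand.
#' @return The log ratio, or `-Inf` for a window falling outside the region.
#' @export
reads_loglik_ratio <- function(bits, z, tau, bern, bg_p) {
  ws <- length(bern)
  a <- z + tau
  if (a < 1L || a + ws - 1L > length(bits)) return(-Inf)
  r <- bits[a:(a + ws - 1L)]
  sum(ifelse(r == 1L, log(bern), log1p(-bern))) - sum(bg_read_logp(bg_p, r))
}

#' Joint log-likelihood ratio of one datapoint under one mode
#'
#' Sequence and the two strand read components are conditionally independent
#' given the mode, so the joint log ratio is the sum of [seq_loglik_ratio()]
#' and the two [reads_loglik_ratio()] terms, plus the log mixture weight.
#'
#' @param dataset an [exo_dataset()].
#' @param i datapoint index.
#' @param mode a single mode's parameter list with elements `pwm`,
#'   `bern_pos`, `bern_neg`, `tau_pos`, `tau_neg` (as stored in an
#'   [fit_modes()] model).
#' @param z 1-based motif start position.
#' @param gamma_k mixture weight of the mode.
#' @param bg backgrounds from [fit_backgrounds()].
#' @return The joint log ratio (`-Inf` when any placement is invalid).
#' @export
datapoint_loglik <- function(dataset, i, mode, z, gamma_k, bg) {
  seq_loglik_ratio(dataset$seqs[i], z, mode$pwm, bg$seq) +
    reads_loglik_ratio(dataset$binary_pos[[i]], z, mode$tau_pos, mode$bern_pos,
                       bg$read$p_pos) +
    reads_loglik_ratio(dataset$binary_neg[[i]], z, mode$tau_neg, mode$bern_neg,
                       bg$read$p_neg) +
    log(gamma_k)
}

## valid motif placements for length-L region given mode geometry:
## motif fits, site has no N, both read windows fit
valid_placements <- function(s, w, tau_pos, tau_neg, wwin, require_windows = TRUE) {
  L <- length(s)
  if (L < w) return(integer(0))
  z <- seq_len(L - w + 1L)
  nN <- cumsum(c(0L, as.integer(s == 5L)))
  ok <- (nN[z + w] - nN[z]) == 0L
  if (require_windows) {
    ok <- ok & (z + tau_pos >= 1L) & (z + tau_pos + wwin - 1L <= L) &
               (z + tau_neg >= 1L) & (z + tau_neg + wwin - 1L <= L)
  }
  z[ok]
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}
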