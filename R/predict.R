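## per-mode marginal log terms for one datapoint under a fitted model:
## log gamma_k + log mean over valid placements of the likelihood ratio,
## with the sequence and/or read factors included per `component`
mode_terms <- function(fitted, s, bp, bn, component = "full") {
  L <- length(s)
  use_seq <- component %in% c("full", "seq")
  use_reads <- component %in% c("full", "reads")
  bgv <- if (use_seq) bg_seq_logp(fitted$bg_seq, s) else NULL
  prefs <- if (use_seq) cumsum(c(0, bgv)) else NULL
  prefp <- if (use_reads) cumsum(c(0, bg_read_logp(fitted$bg_read$p_pos, bp))) else NULL
  prefn <- if (use_reads) cumsum(c(0, bg_read_logp(fitted$bg_read$p_neg, bn))) else NULL
  ww <- fitted$window_width
  out <- vapply(seq_len(fitted$m), function(k) {
    mo <- fitted$modes[[k]]
    if (fitted$gamma[k] <= 0) return(-Inf)
    zv <- valid_placements(s, mo$w, mo$tau_pos, mo$tau_neg, ww,
                           require_windows = (component != "seq"))
    if (!length(zv)) return(-Inf)
    term <- numeric(length(zv))
    if (use_seq) {
      lpw <- log(mo$pwm)
      for (a in seq_len(mo$w)) term <- term + lpw[cbind(s[zv + a - 1L], a)]
      term <- term - (prefs[zv + mo$w] - prefs[zv])
    }
    if (use_reads) {
      l1p <- log(mo$bern_pos); l0p <- log1p(-mo$bern_pos)
      l1n <- log(mo$bern_neg); l0n <- log1p(-mo$bern_neg)
      zp <- zv + mo$tau_pos; zn <- zv + mo$tau_neg
      for (a in seq_len(ww)) {
        term <- term + ifelse(bp[zp + a - 1L] == 1L, l1p[a], l0p[a])
        term <- term + ifelse(bn[zn + a - 1L] == 1L, l1n[a], l0n[a])
      }
      term <- term - (prefp[zp + ww] - prefp[zp]) - (prefn[zn + ww] - prefn[zn])
    }
    log(fitted$gamma[k]) + logsumexp(term) - log(length(zv))
  }, 0)
  ## background constant of the components used (turns ratios into likelihoods)
  const <- 0
  if (use_seq) const <- const + sum(bgv)
  if (use_reads) const <- const + sum(bg_read_logp(fitted$bg_read$p_pos, bp)) +
                                  sum(bg_read_logp(fitted$bg_read$p_neg, bn))
  list(terms = out, const = const)
}

get_point <- function(dataset, i) {
  list(s = encode_seq(dataset$seqs[i]), bp = dataset$binary_pos[[i]],
       bn = dataset$binary_neg[[i]])
}

#' Posterior distribution over binding modes for one datapoint
#'
#' Marginalizes the motif position over all valid placements (uniform
#' positional prior over the feasible positions) and normalizes over modes.
#' `component` selects which factors of the joint are used: the full model,
#' the sequence factor only, or the read factors only.
#'
#' @param dataset an [exo_dataset()].
#' @param i datapoint index (any copy, original or reverse-complement).
#' @param fitted an `exo_model` from [fit_modes()].
#' @param component `"full"`, `"seq"` or `"reads"`.
#' @return list of class `exo_posterior`: `posterior` (length-m, sums to 1),
#'   `mode` (argmax), `z` (argmax placement under the argmax mode),
#'   `component`.
#' @export
mode_posterior <- function(dataset, i, fitted, component = c("full", "seq", "reads")) {
  component <- match.arg(component)
  pt <- get_point(dataset, i)
  mt <- mode_terms(fitted, pt$s, pt$bp, pt$bn, component)
  if (all(!is.finite(mt$terms)))
    stop("datapoint ", i, " is shorter than every mode's footprint span")
  tot <- logsumexp(mt$terms)
  post <- exp(mt$terms - tot)
  kbest <- which.max(mt$terms)
  zbest <- map_z(fitted, pt, kbest, component)
  structure(list(posterior = post, mode = kbest, z = zbest,
                 component = component), class = "exo_posterior")
}

## argmax placement of mode k for one datapoint
map_z <- function(fitted, pt, k, component = "full") {
  mo <- fitted$modes[[k]]
  zv <- valid_placements(pt$s, mo$w, mo$tau_pos, mo$tau_neg, fitted$window_width,
                         require_windows = (component != "seq"))
  if (!length(zv)) return(NA_integer_)
  lpw <- log(mo$pwm)
  term <- numeric(length(zv))
  if (component %in% c("full", "seq"))
    for (a in seq_len(mo$w)) term <- term + lpw[cbind(pt$s[zv + a - 1L], a)]
  if (component %in% c("full", "reads")) {
    l1p <- log(mo$bern_pos); l0p <- log1p(-mo$bern_pos)
    l1n <- log(mo$bern_neg); l0n <- log1p(-mo$bern_neg)
    for (a in seq_len(fitted$window_width)) {
      term <- term + ifelse(pt$bp[zv + mo$tau_pos + a - 1L] == 1L, l1p[a], l0p[a])
      term <- term + ifelse(pt$bn[zv + mo$tau_neg + a - 1L] == 1L, l1n[a], l0n[a])
    }
  }
  ## subtract the background of what the site/windows cover so the argmax
  ## matches the placement-wise ratio used everywhere else
  bgv <- bg_seq_logp(fitted$bg_seq, pt$s)
  prefs <- cumsum(c(0, bgv))
  if (component %in% c("full", "seq")) term <- term - (prefs[zv + mo$w] - prefs[zv])
  if (component %in% c("full", "reads")) {
    prefp <- cumsum(c(0, bg_read_logp(fitted$bg_read$p_pos, pt$bp)))
    prefn <- cumsum(c(0, bg_read_logp(fitted$bg_read$p_neg, pt$bn)))
    zp <- zv + mo$tau_pos; zn <- zv + mo$tau_neg
    term <- term - (prefp[zp + fitted$window_width] - prefp[zp]) -
                   (prefn[zn + fitted$window_width] - prefn[zn])
  }
  zv[which.max(term)]
}

#' Marginal log-likelihood of a datapoint under a fitted model
#'
#' Log probability of the datapoint with the mode and the motif position
#' marginalized out (positions taken uniform over valid placements),
#' computed stably in log space.
#'
#' @inheritParams mode_posterior
#' @return log marginal likelihood (a single number).
#' @export
marginal_loglik <- function(dataset, i, fitted, component = c("full", "seq", "reads")) {
  component <- match.arg(component)
  pt <- get_point(dataset, i)
  mt <- mode_terms(fitted, pt$s, pt$bp, pt$bn, component)
  mt$const + logsumexp(mt$terms)
}

#' Two-model log-odds score of a datapoint
#'
#' `S(D) = log P(D | model_a) - log P(D | model_b)`; positive values favor
#' model a. Used for classifying datapoints between two fitted models.
#'
#' @inheritParams mode_posterior
#' @param fitted_a,fitted_b two `exo_model`s.
#' @return the log-odds score.
#' @export
log_odds <- function(dataset, i, fitted_a, fitted_b,
                     component = c("full", "seq", "reads")) {
  component <- match.arg(component)
  marginal_loglik(dataset, i, fitted_a, component) -
    marginal_loglik(dataset, i, fitted_b, component)
}

#' Mode confusion matrix
#'
#' Entry (u, v) is the mean posterior probability of mode v among datapoints
#' assigned to mode u, computable from the full model or from the sequence /
#' read components alone. Rows sum to 1; an empty mode yields a row of NaN.
#'
#' @inheritParams mode_posterior
#' @param assignments data.frame with columns `index` (datapoint index into
#'   `dataset`) and `mode`; defaults to the fit's own assignments (the
#'   orientation chosen during sampling).
#' @return m x m numeric matrix.
#' @export
confusion_matrix <- function(dataset, fitted, component = c("full", "seq", "reads"),
                             assignments = NULL) {
  component <- match.arg(component)
  if (is.null(assignments)) {
    st <- fitted$state
    npair <- length(st$I)
    assignments <- data.frame(index = ifelse(st$O == 0L, seq_len(npair),
                                             seq_len(npair) + npair),
                              mode = st$I)
  }
  m <- fitted$m
  post <- t(vapply(assignments$index, function(i)
    mode_posterior(dataset, i, fitted, component)$posterior, numeric(m)))
  if (m == 1L) post <- matrix(post, ncol = 1L)
  cm <- matrix(NaN, m, m)
  for (u in seq_len(m)) {
    rows <- assignments$mode == u
    if (!any(rows)) {
      warning("no datapoints assigned to mode ", u, "; confusion row is NaN")
      next
    }
    cm[u, ] <- colMeans(post[rows, , drop = FALSE])
  }
  cm
}

#' Resolve the reported orientation of each region
#'
#' Each original region and its reverse-complement copy are scored by their
#' marginal likelihood; the better orientation is reported (ties go to the
#' forward strand), with the motif call mapped back to forward-genome
#' coordinates.
#'
#' @param dataset augmented [exo_dataset()].
#' @param fitted an `exo_model`.
#' @return data.frame with one row per original region: `region, chrom,
#'   start, end` (genomic 0-based half-open motif site), `strand`, `mode`,
#'   `posterior` (posterior of the called mode), `loglik`, `z` (local
#'   placement in the chosen copy) and `site_seq` (site string in motif
#'   orientation).
#' @export
resolve_orientation <- function(dataset, fitted) {
  if (!isTRUE(dataset$augmented)) stop("dataset must be augmented")
  npair <- dataset$n_original
  out <- vector("list", npair)
  for (i in seq_len(npair)) {
    ll_f <- marginal_loglik(dataset, i, fitted)
    ll_r <- marginal_loglik(dataset, i + npair, fitted)
    use_rc <- ll_r > ll_f
    idx <- if (use_rc) i + npair else i
    mp <- mode_posterior(dataset, idx, fitted)
    mo <- fitted$modes[[mp$mode]]
    reg <- dataset$regions[i, ]
    z <- mp$z
    if (use_rc) {
      gstart <- reg$end - (z - 1L) - mo$w
    } else {
      gstart <- reg$start + (z - 1L)
    }
    out[[i]] <- data.frame(
      region = reg$id, chrom = reg$chrom,
      start = gstart, end = gstart + mo$w,
      strand = if (use_rc) "-" else "+",
      mode = mp$mode, posterior = mp$posterior[mp$mode],
      loglik = max(ll_f, ll_r), z = z,
      site_seq = substr(dataset$seqs[idx], z, z + mo$w - 1L),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Area under the ROC curve for a score vector
#'
#' Exact rank-based (Mann-Whitney) AUC of `scores` for separating the
#' positive class, a convenience for benchmarking [log_odds()] classifiers.
#'
#' @param scores numeric scores, larger favoring the positive class.
#' @param labels logical or 0/1 vector marking positives.
#' @return AUC in `[0, 1]`.
#' @export
classification_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("need both classes to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}
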