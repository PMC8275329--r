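#' Prior hyperparameters for the collapsed sampler
#'
#' Conjugate, non-informative by default: Jeffreys-style 0.5 pseudocounts for
#' PWM columns (symmetric Dirichlet) and window Bernoullis (Beta), and a
#' symmetric Dirichlet(1) over mode weights.
#'
#' @param alpha Dirichlet concentration per base for PWM columns.
#' @param beta_a,beta_b Beta prior for window Bernoulli probabilities.
#' @param delta Dirichlet concentration per mode for the mixture weights.
#' @return list of class `exo_priors`.
#' @export
mode_priors <- function(alpha = 0.5, beta_a = 0.5, beta_b = 0.5, delta = 1) {
  stopifnot(alpha > 0, beta_a > 0, beta_b > 0, delta > 0)
  structure(list(alpha = alpha, beta_a = beta_a, beta_b = beta_b, delta = delta),
            class = "exo_priors")
}

#' Sampler configuration
#'
#' @param window_width read-window width in bp per strand (default 5).
#' @param init_width initial motif width.
#' @param w_min,w_max bounds for the sampled motif width.
#' @param max_offset how far (bp) a read window may start beyond the motif
#'   boundaries; the offset grids are `tau+ in [-max_offset - window_width,
#'   w - 1]` and `tau- in [-window_width + 1, w + max_offset]`.
#' @param restarts independent chains per mode count; best posterior wins.
#' @param stop_mult stop a chain after `stop_mult * n` consecutive
#'   single-variable updates without a new best score (`n` = datapoints).
#' @param warm_sweeps number of initial sweeps during which the membership
#'   term of the sampling weights is flattened (large effective Dirichlet
#'   pseudo-count), letting weak or empty modes re-acquire datapoints before
#'   the rich-get-richer membership prior takes hold; the score and the
#'   hill climb always use the true prior.
#' @param max_sweeps hard cap on sweeps per chain.
#' @param max_passes hard cap on hill-climbing passes.
#' @param tol minimal score improvement counted as an improvement.
#' @return list of class `exo_config`.
#' @export
sampler_config <- function(window_width = 5L, init_width = 12L, w_min = 5L,
                           w_max = 50L, max_offset = 25L, restarts = 3L,
                           stop_mult = 5L, warm_sweeps = 10L, max_sweeps = 1000L,
                           max_passes = 200L, tol = 1e-9) {
  stopifnot(window_width >= 1, w_min >= 2, w_max >= w_min,
            init_width >= w_min, init_width <= w_max, restarts >= 1)
  structure(list(window_width = as.integer(window_width),
                 init_width = as.integer(init_width),
                 w_min = as.integer(w_min), w_max = as.integer(w_max),
                 max_offset = as.integer(max_offset),
                 restarts = as.integer(restarts),
                 stop_mult = as.integer(stop_mult),
                 warm_sweeps = as.integer(warm_sweeps),
                 max_sweeps = as.integer(max_sweeps),
                 max_passes = as.integer(max_passes), tol = tol),
            class = "exo_config")
}

## merge priors into the flat list the C++ side consumes
cpp_cfg <- function(config, priors) {
  c(unclass(config), unclass(priors))
}

## flatten an augmented dataset + backgrounds into the arrays the C++
## sampler consumes (prefix sums of per-position background log-probs)
sampler_data <- function(dataset, bg) {
  stopifnot(inherits(dataset, "exo_dataset"))
  if (!isTRUE(dataset$augmented))
    stop("dataset must be reverse-complement augmented before sampling")
  nc <- n_datapoints(dataset)
  npair <- dataset$n_original
  enc <- lapply(dataset$seqs, encode_seq)
  lens <- lengths(enc)
  off <- c(0L, cumsum(lens))
  off2 <- c(0L, cumsum(lens + 1L))
  pref <- function(v) cumsum(c(0, v))
  pseq <- unlist(lapply(enc, function(s) pref(bg_seq_logp(bg$seq, s))), use.names = FALSE)
  ppos <- unlist(lapply(dataset$binary_pos,
                        function(b) pref(bg_read_logp(bg$read$p_pos, b))), use.names = FALSE)
  pneg <- unlist(lapply(dataset$binary_neg,
                        function(b) pref(bg_read_logp(bg$read$p_neg, b))), use.names = FALSE)
  nN <- unlist(lapply(enc, function(s) cumsum(c(0L, as.integer(s == 5L)))), use.names = FALSE)
  list(npair = npair, off = off, off2 = off2,
       seq = unlist(enc, use.names = FALSE) - 1L,
       rpos = unlist(dataset$binary_pos, use.names = FALSE),
       rneg = unlist(dataset$binary_neg, use.names = FALSE),
       pseq = pseq, ppos = ppos, pneg = pneg, nN = nN)
}

#' Initialize a sampler state
#'
#' Mode labels and orientations uniform at random, motif positions uniform
#' over valid placements; read windows start abutting the motif
#' (`tau+ = -window_width`, `tau- = init_width`).
#'
#' @param dataset augmented [exo_dataset()].
#' @param m number of modes.
#' @param config [sampler_config()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return list of class `exo_state` with elements `m`, `Z`, `O`, `I`
#'   (per original region: motif position, orientation 0/1, mode), and
#'   per-mode `w`, `tau_pos`, `tau_neg`.
#' @export
init_state <- function(dataset, m, config = sampler_config(), seed = NULL) {
  stopifnot(m >= 1)
  if (!isTRUE(dataset$augmented)) stop("dataset must be augmented")
  if (!is.null(seed)) set.seed(seed)
  npair <- dataset$n_original
  w0 <- config$init_width
  tp <- -config$window_width
  tn <- w0
  enc <- lapply(dataset$seqs, encode_seq)
  O <- integer(npair); Z <- integer(npair)
  I <- if (m == 1L) rep(1L, npair) else sample.int(m, npair, replace = TRUE)
  for (i in seq_len(npair)) {
    o <- sample(c(0L, 1L), 1L)
    for (try_o in c(o, 1L - o)) {
      s <- enc[[if (try_o == 0L) i else i + npair]]
      vz <- valid_placements(s, w0, tp, tn, config$window_width)
      if (length(vz)) { O[i] <- try_o; Z[i] <- vz[sample.int(length(vz), 1L)]; break }
      Z[i] <- 0L
    }
    if (Z[i] == 0L)
      stop("region ", dataset$regions$id[i],
           " has no valid motif placement at init_width ", w0)
  }
  structure(list(m = as.integer(m), Z = Z, O = O, I = as.integer(I),
                 w = rep(as.integer(w0), m),
                 tau_pos = rep(as.integer(tp), m),
                 tau_neg = rep(as.integer(tn), m)),
            class = "exo_state")
}

as_state <- function(x) { class(x) <- "exo_state"; x }

#' Run one collapsed Gibbs chain
#'
#' Sweeps over all regions sampling (motif position, orientation, mode)
#' jointly from the collapsed predictive, then samples the read-window
#' offsets (both strands, every mode) and proposes +/-1 bp motif edge moves.
#' The chain stops once `stop_mult * n` consecutive single-variable updates
#' fail to improve the best collapsed posterior score (`n` = datapoints,
#' i.e. the RC-augmented count), and returns the best-scoring state visited.
#'
#' @inheritParams init_state
#' @param priors [mode_priors()].
#' @param seed integer seed (also seeds the initialization).
#' @param bg backgrounds from [fit_backgrounds()]; computed if `NULL`.
#' @param init optional starting `exo_state` (skips [init_state()]).
#' @param record_trace keep the per-update score trace.
#' @return list of class `exo_chain`: `best_state`, `best_score`,
#'   `final_state`, `final_score`, `trace`, `sweeps`, `updates`, `seed`.
#' @export
run_chain <- function(dataset, m, priors = mode_priors(),
                      config = sampler_config(), seed = 1L, bg = NULL,
                      init = NULL, record_trace = TRUE) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  data <- sampler_data(dataset, bg)
  set.seed(seed)
  if (is.null(init)) init <- init_state(dataset, m, config)
  res <- cg_run_chain(data, unclass(init), cpp_cfg(config, priors), record_trace)
  res$best_state <- as_state(res$best_state)
  res$final_state <- as_state(res$final_state)
  res$seed <- seed
  class(res) <- "exo_chain"
  res
}

#' Deterministic hill climb from a sampled state
#'
#' Repeatedly sets each variable (per-region placement/orientation/mode
#' jointly; each window offset; each motif edge move) to the argmax of its
#' collapsed conditional until a full pass makes no change. The score never
#' decreases.
#'
#' @param state an `exo_state` (typically `chain$best_state`).
#' @inheritParams run_chain
#' @return list with the climbed `state`, its `score`, `passes` and `moves`.
#' @export
hill_climb <- function(state, dataset, priors = mode_priors(),
                       config = sampler_config(), bg = NULL) {
  if (inherits(state, "exo_chain")) state <- state$best_state
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  res <- cg_hill_climb(sampler_data(dataset, bg), unclass(state),
                       cpp_cfg(config, priors))
  res$state <- as_state(res$state)
  res
}

#' Collapsed posterior score of a state
#'
#' Exact closed form of the marginalized joint: Dirichlet-multinomial
#' marginals for every PWM column and for the mode memberships,
#' Beta-Bernoulli marginals for every window position, and background terms
#' for everything outside sites and windows.
#'
#' @inheritParams hill_climb
#' @return log collapsed posterior score (a single number).
#' @export
score_state <- function(state, dataset, priors = mode_priors(),
                        config = sampler_config(), bg = NULL) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  cg_score(sampler_data(dataset, bg), unclass(state), cpp_cfg(config, priors))
}

#' Gibbs conditionals (diagnostics / verification)
#'
#' Return the exact collapsed conditional used by the sampler for one
#' variable, as log-weights over the candidate grid: `conditional_zi` for
#' region `i`'s joint (mode, orientation, position), `conditional_tau` for a
#' mode's window offset on one strand, `conditional_width` for the five
#' motif edge moves (stay / grow or shrink at either edge).
#'
#' @inheritParams hill_climb
#' @param i region (pair) index for `conditional_zi`.
#' @param k mode index.
#' @param strand `"pos"` or `"neg"`.
#' @return data.frame of candidates and unnormalized log weights.
#' @export
conditional_zi <- function(state, dataset, i, priors = mode_priors(),
                           config = sampler_config(), bg = NULL) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  cg_zi_weights(sampler_data(dataset, bg), unclass(state),
                cpp_cfg(config, priors), as.integer(i))
}

#' @rdname conditional_zi
#' @export
conditional_tau <- function(state, dataset, k, strand = c("pos", "neg"),
                            priors = mode_priors(), config = sampler_config(),
                            bg = NULL) {
  strand <- match.arg(strand)
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  res <- cg_tau_weights(sampler_data(dataset, bg), unclass(state),
                        cpp_cfg(config, priors), as.integer(k),
                        if (strand == "pos") 0L else 1L)
  data.frame(tau = res$tau, logw = res$logw)
}

#' @rdname conditional_zi
#' @export
conditional_width <- function(state, dataset, k, priors = mode_priors(),
                              config = sampler_config(), bg = NULL) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  res <- cg_width_weights(sampler_data(dataset, bg), unclass(state),
                          cpp_cfg(config, priors), as.integer(k))
  data.frame(dw = res$dw, shift = res$shift, logw = res$logw)
}

#' Count-integrity audit
#'
#' Runs a random sequence of incremental sampler updates and returns both the
#' incrementally maintained sufficient statistics and a from-scratch recount
#' of the final state; the two must agree exactly.
#'
#' @inheritParams hill_climb
#' @param n_updates number of random updates.
#' @param seed RNG seed.
#' @return list with `state`, `incremental`, `recount` and the two scores.
#' @export
audit_updates <- function(state, dataset, n_updates = 1000L,
                          priors = mode_priors(), config = sampler_config(),
                          bg = NULL, seed = 1L) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  set.seed(seed)
  cg_random_updates(sampler_data(dataset, bg), unclass(state),
                    cpp_cfg(config, priors), as.integer(n_updates))
}

#' MAP parameter estimates from a sampler state
#'
#' Posterior-mean point estimates under the conjugate priors: PWM columns
#' `(counts + alpha) / (n_k + 4 alpha)`, window Bernoullis
#' `(ones + a) / (n_k + a + b)`, mixture weights
#' `(n_k + delta) / (n + m delta)`. Empty modes receive prior-predictive
#' parameters with a warning.
#'
#' @inheritParams hill_climb
#' @return An object of class `exo_model`; see [fit_modes()].
#' @export
estimate_parameters <- function(state, dataset, priors = mode_priors(),
                                config = sampler_config(), bg = NULL) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  data <- sampler_data(dataset, bg)
  cc <- cg_counts(data, unclass(state), cpp_cfg(config, priors))
  m <- state$m
  npair <- dataset$n_original
  al <- priors$alpha; a0 <- priors$beta_a; b0 <- priors$beta_b; de <- priors$delta
  modes <- vector("list", m)
  for (k in seq_len(m)) {
    nk <- cc$nk[k]
    if (nk == 0L) warning("mode ", k, " is empty; prior-predictive parameters reported")
    pwm <- (cc$pwm_counts[[k]] + al) / (nk + 4 * al)
    rownames(pwm) <- BASES[1:4]
    modes[[k]] <- list(
      w = state$w[k], pwm = pwm,
      bern_pos = (cc$win_pos[[k]] + a0) / (nk + a0 + b0),
      bern_neg = (cc$win_neg[[k]] + a0) / (nk + a0 + b0),
      tau_pos = state$tau_pos[k], tau_neg = state$tau_neg[k],
      n_members = nk)
  }
  gamma <- (cc$nk + de) / (npair + m * de)
  logpost <- cg_score(data, unclass(state), cpp_cfg(config, priors))
  assignments <- data.frame(
    region = dataset$regions$id[seq_len(npair)],
    mode = state$I, orientation = ifelse(state$O == 0L, "+", "-"),
    z = state$Z, stringsAsFactors = FALSE)
  structure(list(m = m, modes = modes, gamma = gamma,
                 window_width = config$window_width,
                 bg_seq = bg$seq, bg_read = bg$read,
                 priors = priors, logpost = logpost,
                 n_data = n_datapoints(dataset),
                 binarize_threshold = dataset$binarize_threshold,
                 assignments = assignments, state = unclass(state)),
            class = "exo_model")
}

#' @export
print.exo_model <- function(x, ...) {
  cat("exo_model with", x$m, "binding mode(s); log posterior", format(x$logpost), "\n")
  for (k in seq_len(x$m)) {
    mo <- x$modes[[k]]
    cons <- paste(BASES[apply(mo$pwm, 2, which.max)], collapse = "")
    cat(sprintf("  mode %d: w=%d  gamma=%.3f  tau+=%d tau-=%d  consensus %s  (n=%d)\n",
                k, mo$w, x$gamma[k], mo$tau_pos, mo$tau_neg, cons, mo$n_members))
  }
  invisible(x)
}

#' Fit a binding-mode model with a fixed number of modes
#'
#' Runs `restarts` independent collapsed Gibbs chains, hill-climbs the best
#' state, and reports MAP point estimates of all mode parameters.
#'
#' @inheritParams run_chain
#' @return An `exo_model` carrying, per mode, the PWM, the strand window
#'   Bernoulli vectors and offsets and width; the mixture weights; the
#'   backgrounds; the collapsed posterior score `logpost`; and the final
#'   per-region assignments.
#' @export
fit_modes <- function(dataset, m, priors = mode_priors(),
                      config = sampler_config(), seed = 1L, bg = NULL) {
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    chain_seed <- as.integer(seed) + 7919L * (r - 1L)
    ch <- run_chain(dataset, m, priors, config, seed = chain_seed, bg = bg,
                    record_trace = FALSE)
    if (is.null(best) || ch$best_score > best$best_score) {
      best <- ch; best_seed <- chain_seed
    }
  }
  hc <- hill_climb(best$best_state, dataset, priors, config, bg = bg)
  fit <- estimate_parameters(hc$state, dataset, priors, config, bg = bg)
  fit$seed <- best_seed
  fit
}
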