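# Independent reference implementations used to verify the sampler and the
# prediction machinery. Everything here is deliberately written as plain,
# slow R (explicit loops, no prefix sums, no shared code with the package
# internals beyond public constructors), evaluating the closed-form
# collapsed marginals and brute-force enumerations directly.

or_encode <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T", "N"))

## per-position log background probability under the 2nd-order chain with
## lower-order fallback; N emits 1/4
or_bg_vec <- function(bg, s) {
  L <- length(s)
  out <- numeric(L)
  for (j in seq_len(L)) {
    if (s[j] == 5L) { out[j] <- log(0.25); next }
    if (j >= 3L && s[j - 1L] <= 4L && s[j - 2L] <= 4L) {
      out[j] <- log(bg$seq$p2[(s[j - 2L] - 1L) * 4L + s[j - 1L], s[j]])
    } else if (j >= 2L && s[j - 1L] <= 4L) {
      out[j] <- log(bg$seq$p1[s[j - 1L], s[j]])
    } else {
      out[j] <- log(bg$seq$p0[s[j]])
    }
  }
  out
}

or_lp_bits <- function(p, bits) {
  tot <- 0
  for (b in bits) tot <- tot + if (b == 1L) log(p) else log(1 - p)
  tot
}

or_logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

or_tv <- function(p, q) 0.5 * sum(abs(p - q))

## exact closed-form collapsed posterior score of a full configuration:
## Dirichlet-multinomial marginals per PWM column and for memberships,
## Beta-Bernoulli marginals per window position, background elsewhere
oracle_score <- function(ds, st, bg, priors = mode_priors(), wwin = 5L) {
  npair <- ds$n_original
  al <- priors$alpha; a0 <- priors$beta_a; b0 <- priors$beta_b; de <- priors$delta
  enc <- lapply(ds$seqs, or_encode)
  bgv <- lapply(enc, function(s) or_bg_vec(bg, s))
  total <- 0
  for (c in seq_along(enc)) {
    total <- total + sum(bgv[[c]]) +
      or_lp_bits(bg$read$p_pos, ds$binary_pos[[c]]) +
      or_lp_bits(bg$read$p_neg, ds$binary_neg[[c]])
  }
  for (k in seq_len(st$m)) {
    mem <- which(st$I == k)
    nk <- length(mem)
    w <- st$w[k]
    cnt <- matrix(0L, 4L, w)
    ones_p <- integer(wwin); ones_n <- integer(wwin)
    for (i in mem) {
      c <- if (st$O[i] == 0L) i else i + npair
      z <- st$Z[i]
      for (a in seq_len(w)) cnt[enc[[c]][z + a - 1L], a] <- cnt[enc[[c]][z + a - 1L], a] + 1L
      total <- total - sum(bgv[[c]][z:(z + w - 1L)])
      zp <- z + st$tau_pos[k]; zn <- z + st$tau_neg[k]
      bp <- ds$binary_pos[[c]][zp:(zp + wwin - 1L)]
      bn <- ds$binary_neg[[c]][zn:(zn + wwin - 1L)]
      ones_p <- ones_p + bp; ones_n <- ones_n + bn
      total <- total - or_lp_bits(bg$read$p_pos, bp) - or_lp_bits(bg$read$p_neg, bn)
    }
    for (a in seq_len(w)) {
      total <- total + lgamma(4 * al) - lgamma(nk + 4 * al)
      for (b in 1:4) total <- total + lgamma(cnt[b, a] + al) - lgamma(al)
    }
    for (a in seq_len(wwin)) {
      total <- total + lgamma(a0 + b0) - lgamma(nk + a0 + b0) +
        lgamma(ones_p[a] + a0) - lgamma(a0) + lgamma(nk - ones_p[a] + b0) - lgamma(b0)
      total <- total + lgamma(a0 + b0) - lgamma(nk + a0 + b0) +
        lgamma(ones_n[a] + a0) - lgamma(a0) + lgamma(nk - ones_n[a] + b0) - lgamma(b0)
    }
  }
  total <- total + lgamma(st$m * de) - lgamma(npair + st$m * de)
  for (k in seq_len(st$m)) total <- total + lgamma(sum(st$I == k) + de) - lgamma(de)
  total
}

or_valid <- function(s, w, tp, tn, wwin, bits_len = length(s)) {
  L <- length(s)
  keep <- integer(0)
  for (z in seq_len(max(0L, L - w + 1L))) {
    if (any(s[z:(z + w - 1L)] == 5L)) next
    if (z + tp < 1L || z + tp + wwin - 1L > L) next
    if (z + tn < 1L || z + tn + wwin - 1L > L) next
    keep <- c(keep, z)
  }
  keep
}

## enumerated conditional over (mode, orientation, position) of pair i:
## score every full configuration and normalize
oracle_zi_conditional <- function(ds, st, i, bg, priors = mode_priors(), wwin = 5L) {
  npair <- ds$n_original
  enc <- lapply(ds$seqs, or_encode)
  rows <- list()
  for (k in seq_len(st$m)) for (o in 0:1) {
    c <- if (o == 0L) i else i + npair
    for (z in or_valid(enc[[c]], st$w[k], st$tau_pos[k], st$tau_neg[k], wwin)) {
      st2 <- st; st2$I[i] <- k; st2$O[i] <- o; st2$Z[i] <- z
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, o = o, z = z,
                   logw = oracle_score(ds, st2, bg, priors, wwin))
    }
  }
  do.call(rbind, rows)
}

oracle_tau_conditional <- function(ds, st, k, strand, bg, priors = mode_priors(),
                                   wwin = 5L, max_offset = 25L) {
  npair <- ds$n_original
  mem <- which(st$I == k)
  if (strand == "pos") { lo <- -max_offset - wwin; hi <- st$w[k] - 1L }
  else { lo <- -wwin + 1L; hi <- st$w[k] + max_offset }
  rows <- list()
  for (tau in lo:hi) {
    ok <- TRUE
    for (i in mem) {
      c <- if (st$O[i] == 0L) i else i + npair
      L <- nchar(ds$seqs[c])
      if (st$Z[i] + tau < 1L || st$Z[i] + tau + wwin - 1L > L) { ok <- FALSE; break }
    }
    if (!ok) next
    st2 <- st
    if (strand == "pos") st2$tau_pos[k] <- tau else st2$tau_neg[k] <- tau
    rows[[length(rows) + 1L]] <-
      data.frame(tau = tau, logw = oracle_score(ds, st2, bg, priors, wwin))
  }
  do.call(rbind, rows)
}

oracle_width_conditional <- function(ds, st, k, bg, priors = mode_priors(),
                                     wwin = 5L, w_min = 5L, w_max = 50L,
                                     max_offset = 25L) {
  npair <- ds$n_original
  enc <- lapply(ds$seqs, or_encode)
  mem <- which(st$I == k)
  cand <- list(c(0L, 0L), c(1L, -1L), c(1L, 0L), c(-1L, 1L), c(-1L, 0L))
  rows <- list()
  for (cc in cand) {
    dw <- cc[1L]; sh <- cc[2L]
    wn <- st$w[k] + dw
    if (wn < w_min || wn > w_max) next
    tpn <- st$tau_pos[k] - sh; tnn <- st$tau_neg[k] - sh
    if (tpn < -max_offset - wwin || tpn > wn - 1L) next
    if (tnn < -wwin + 1L || tnn > wn + max_offset) next
    ok <- TRUE
    for (i in mem) {
      c <- if (st$O[i] == 0L) i else i + npair
      zn <- st$Z[i] + sh
      if (zn < 1L || zn + wn - 1L > length(enc[[c]]) ||
          any(enc[[c]][zn:(zn + wn - 1L)] == 5L)) { ok <- FALSE; break }
    }
    if (!ok) next
    st2 <- st
    st2$w[k] <- wn; st2$tau_pos[k] <- tpn; st2$tau_neg[k] <- tnn
    st2$Z[mem] <- st2$Z[mem] + sh
    rows[[length(rows) + 1L]] <-
      data.frame(dw = dw, shift = sh, logw = oracle_score(ds, st2, bg, priors, wwin))
  }
  do.call(rbind, rows)
}

## brute-force marginal likelihood of datapoint `i` under a fitted model:
## direct product over every position for every (mode, placement)
oracle_marglik <- function(ds, i, fit, component = "full") {
  s <- or_encode(ds$seqs[i])
  bp <- ds$binary_pos[[i]]; bn <- ds$binary_neg[[i]]
  L <- length(s)
  bgv <- or_bg_vec(list(seq = fit$bg_seq), s)
  use_seq <- component %in% c("full", "seq")
  use_reads <- component %in% c("full", "reads")
  ww <- fit$window_width
  per_mode <- numeric(fit$m)
  for (k in seq_len(fit$m)) {
    mo <- fit$modes[[k]]
    zv <- if (component == "seq") {
      z <- integer(0)
      for (zz in seq_len(max(0L, L - mo$w + 1L)))
        if (!any(s[zz:(zz + mo$w - 1L)] == 5L)) z <- c(z, zz)
      z
    } else or_valid(s, mo$w, mo$tau_pos, mo$tau_neg, ww)
    if (!length(zv) || fit$gamma[k] <= 0) { per_mode[k] <- -Inf; next }
    terms <- numeric(length(zv))
    for (t in seq_along(zv)) {
      z <- zv[t]
      lp <- 0
      if (use_seq) {
        for (j in seq_len(L)) {
          lp <- lp + if (j >= z && j <= z + mo$w - 1L)
            log(mo$pwm[s[j], j - z + 1L]) else bgv[j]
        }
      }
      if (use_reads) {
        zp <- z + mo$tau_pos; zn <- z + mo$tau_neg
        for (j in seq_len(L)) {
          lp <- lp + if (j >= zp && j <= zp + ww - 1L) {
            if (bp[j] == 1L) log(mo$bern_pos[j - zp + 1L]) else log(1 - mo$bern_pos[j - zp + 1L])
          } else {
            if (bp[j] == 1L) log(fit$bg_read$p_pos) else log(1 - fit$bg_read$p_pos)
          }
          lp <- lp + if (j >= zn && j <= zn + ww - 1L) {
            if (bn[j] == 1L) log(mo$bern_neg[j - zn + 1L]) else log(1 - mo$bern_neg[j - zn + 1L])
          } else {
            if (bn[j] == 1L) log(fit$bg_read$p_neg) else log(1 - fit$bg_read$p_neg)
          }
        }
      }
      terms[t] <- lp - log(length(zv))
    }
    per_mode[k] <- log(fit$gamma[k]) + or_logsumexp(terms)
  }
  list(per_mode = per_mode, total = or_logsumexp(per_mode))
}

## ---- shared fixtures ------------------------------------------------------

## tiny augmented dataset from explicit sequences/bits
toy_dataset <- function(seqs, bpos = NULL, bneg = NULL, augment = TRUE) {
  ds <- exo_dataset(seqs, bpos, bneg)
  if (augment) ds <- augment_revcomp(ds)
  ds
}

## uniform background (so likelihood ratios have closed hand-computable forms)
uniform_bg <- function(read_p = 0.5) {
  list(seq = structure(list(p0 = rep(0.25, 4), p1 = matrix(0.25, 4, 4),
                            p2 = matrix(0.25, 16, 4)), class = "exo_bg_seq"),
       read = structure(list(p_pos = read_p, p_neg = read_p),
                        class = "exo_bg_read"))
}

## small well-separated two-mode generator shared by several tests
two_mode_gen <- function(n = 60, L = 80, seed = 11, rc_prob = 0.5) {
  generate_dataset(list(
    mode_spec("TTGACGTCAA", strength = 0.95, tau_pos = -8L, tau_neg = 12L,
              proportion = 0.5, label = "cre",
              footprint_pos = rep(0.9, 5), footprint_neg = rep(0.9, 5)),
    mode_spec("GGGACTTTCC", strength = 0.95, tau_pos = -6L, tau_neg = 14L,
              proportion = 0.5, label = "nfkb",
              footprint_pos = rep(0.9, 5), footprint_neg = rep(0.9, 5))),
    n = n, L = L, bg_gc = 0.4, bg_read_p = 0.05, rc_prob = rc_prob, seed = seed)
}

## label agreement between fitted assignments and planted truth under the
## best mode bijection (computed by brute force over permutations)
best_agreement <- function(pred, truth, m) {
  best <- 0
  for (p in combinat_perms(m)) {
    agree <- mean(p[pred] == truth)
    if (!is.na(agree) && agree > best) best <- agree
  }
  best
}

combinat_perms <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (j in seq_len(m)) {
    for (sub in combinat_perms(m - 1L)) {
      rest <- setdiff(seq_len(m), j)
      out[[length(out) + 1L]] <- c(j, rest[sub])
    }
  }
  out
}
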