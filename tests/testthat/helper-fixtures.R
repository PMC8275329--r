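# Shared fixture builders for the sampler and acceptance suites.

## small planted two-mode dataset (3 bp read windows) for enumeration tests
small_fixture <- function(n = 3, L = 20, seed = 4,
                          tau_a = c(-4L, 7L), tau_b = c(-3L, 8L)) {
  generate_dataset(list(
    mode_spec("ACGCGT", strength = 0.95, tau_pos = tau_a[1], tau_neg = tau_a[2],
              proportion = 0.5, label = "a",
              footprint_pos = rep(0.9, 3), footprint_neg = rep(0.9, 3)),
    mode_spec("TGGATC", strength = 0.95, tau_pos = tau_b[1], tau_neg = tau_b[2],
              proportion = 0.5, label = "b",
              footprint_pos = rep(0.9, 3), footprint_neg = rep(0.9, 3))),
    n = n, L = L, bg_gc = 0.5, bg_read_p = 0.1, window_width = 3L, seed = seed)
}

small_cfg <- sampler_config(window_width = 3L, init_width = 6L, w_min = 5L,
                            max_offset = 10L)

## truth-aligned state for a generated dataset (all regions assigned to
## their planted mode at the planted placement/orientation)
truth_state <- function(gen, m = length(gen$specs)) {
  tr <- gen$truth
  n <- nrow(tr)
  w <- vapply(gen$specs, function(sp) sp$w, 0L)
  Z <- integer(n); O <- integer(n); I <- integer(n)
  for (i in seq_len(n)) {
    k <- max(1L, tr$mode[i])
    I[i] <- k
    if (tr$mode[i] == 0L) { O[i] <- 0L; Z[i] <- 1L - gen$specs[[k]]$tau_pos; next }
    if (tr$orientation[i] == "+") { O[i] <- 0L; Z[i] <- tr$z[i] }
    else { O[i] <- 1L; Z[i] <- tr$z[i] }   # motif frame is the RC copy
  }
  structure(list(m = as.integer(m), Z = Z, O = O, I = I,
                 w = w[seq_len(m)],
                 tau_pos = vapply(gen$specs[seq_len(m)], function(sp) sp$tau_pos, 0L),
                 tau_neg = vapply(gen$specs[seq_len(m)], function(sp) sp$tau_neg, 0L)),
            class = "exo_state")
}

## mirrored configuration: the equivalent state describing every mode in the
## opposite orientation frame
mirror_state <- function(st, ds, wwin = 5L) {
  L <- nchar(ds$seqs[1])
  out <- st
  out$O <- 1L - st$O
  out$Z <- L - st$Z - st$w[st$I] + 2L
  out$tau_pos <- st$w - st$tau_neg - wwin
  out$tau_neg <- st$w - st$tau_pos - wwin
  out
}
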