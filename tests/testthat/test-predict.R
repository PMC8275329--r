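# Mode posteriors, marginal likelihoods, confusion matrices, log-odds
# classification and orientation resolution.

fitted_two_modes <- function(n = 120, L = 80, seed = 3) {
  gen <- two_mode_gen(n = n, L = L, seed = seed)
  ds <- augment_revcomp(gen$dataset)
  fit <- fit_modes(ds, 2, config = sampler_config(init_width = 10L, restarts = 2L),
                   seed = 7)
  list(gen = gen, ds = ds, fit = fit)
}

test_that("posteriors normalize, and components ignore the data they drop", {
  fx <- fitted_two_modes()
  ds <- fx$ds
  for (i in c(1, 5, 130)) for (comp in c("full", "seq", "reads")) {
    mp <- mode_posterior(ds, i, fx$fit, comp)
    expect_equal(sum(mp$posterior), 1, tolerance = 1e-9)
  }
  ## zeroing the reads leaves seq-only results unchanged, and vice versa
  ds_zero <- ds
  ds_zero$binary_pos <- lapply(ds$binary_pos, function(b) b * 0L)
  ds_zero$binary_neg <- lapply(ds$binary_neg, function(b) b * 0L)
  ds_shuf <- ds
  set.seed(4)
  ds_shuf$seqs <- vapply(nchar(ds$seqs), function(L)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), "")
  for (i in c(2, 7)) {
    expect_equal(mode_posterior(ds, i, fx$fit, "seq")$posterior,
                 mode_posterior(ds_zero, i, fx$fit, "seq")$posterior)
    expect_equal(marginal_loglik(ds, i, fx$fit, "seq"),
                 marginal_loglik(ds_zero, i, fx$fit, "seq"))
    expect_equal(mode_posterior(ds, i, fx$fit, "reads")$posterior,
                 mode_posterior(ds_shuf, i, fx$fit, "reads")$posterior)
  }
  ## m = 1 forces a degenerate posterior
  fit1 <- fit_modes(fx$ds, 1, config = sampler_config(init_width = 10L,
                                                      restarts = 1L), seed = 1)
  expect_equal(mode_posterior(ds, 3, fit1)$posterior, 1)
})

test_that("marginal likelihood matches brute-force enumeration", {
  gen <- two_mode_gen(n = 8, L = 30, seed = 21)
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  fit <- structure(list(
    m = 2L,
    modes = lapply(gen$specs, function(sp) list(
      w = sp$w, pwm = sp$pwm, bern_pos = sp$footprint_pos,
      bern_neg = sp$footprint_neg, tau_pos = sp$tau_pos, tau_neg = sp$tau_neg)),
    gamma = c(0.6, 0.4), window_width = 5L,
    bg_seq = bg$seq, bg_read = bg$read), class = "exo_model")
  for (i in c(1, 4, 11)) for (comp in c("full", "seq", "reads")) {
    want <- oracle_marglik(ds, i, fit, comp)
    expect_equal(marginal_loglik(ds, i, fit, comp), want$total, tolerance = 1e-9)
    mp <- mode_posterior(ds, i, fit, comp)
    expect_equal(mp$posterior,
                 exp(want$per_mode - or_logsumexp(want$per_mode)),
                 tolerance = 1e-9)
  }
  ## a mode with zero weight contributes nothing
  fit0 <- fit
  fit0$m <- 3L
  fit0$modes <- c(fit$modes, fit$modes[1])
  fit0$gamma <- c(fit$gamma, 0)
  expect_equal(marginal_loglik(ds, 2, fit0), marginal_loglik(ds, 2, fit))
  ## strengthening the site match raises the marginal monotonically: a
  ## single-placement region under a uniform background isolates the site
  ## term, so every consensus substitution must raise the marginal
  sp <- gen$specs[[1]]
  cons <- strsplit("TTGACGTCAA", "")[[1]]
  start <- chartr("ACGT", "TGCA", cons)   # differs from consensus everywhere
  fit1 <- fit
  fit1$m <- 1L; fit1$modes <- fit$modes[1]; fit1$gamma <- 1
  fit1$bg_seq <- uniform_bg()$seq; fit1$bg_read <- uniform_bg(0.1)$read
  ds2 <- exo_dataset(paste(start, collapse = ""))
  ll <- numeric(sp$w + 1)
  ll[1] <- marginal_loglik(ds2, 1, fit1, "seq")
  base_seq <- start
  for (a in seq_len(sp$w)) {
    base_seq[a] <- cons[a]
    ds2 <- exo_dataset(paste(base_seq, collapse = ""))
    ll[a + 1] <- marginal_loglik(ds2, 1, fit1, "seq")
  }
  expect_true(all(diff(ll) > 0))
})

test_that("confusion matrices have unit rows and a dominant diagonal", {
  fx <- fitted_two_modes(n = 80, L = 80, seed = 9)
  cm <- confusion_matrix(fx$ds, fx$fit)
  expect_equal(rowSums(cm), c(1, 1), tolerance = 1e-9)
  expect_gt(min(diag(cm)), 0.8)
  ## sequence-only confusion is also normalized
  cm_seq <- confusion_matrix(fx$ds, fx$fit, "seq")
  expect_equal(rowSums(cm_seq), c(1, 1), tolerance = 1e-9)
  ## m = 1 gives the 1x1 identity
  fit1 <- fit_modes(fx$ds, 1, config = sampler_config(init_width = 10L,
                                                      restarts = 1L), seed = 2)
  expect_equal(confusion_matrix(fx$ds, fit1), matrix(1, 1, 1))
  ## modes sharing a motif but differing in footprint: the full model
  ## separates them better than sequence alone
  gen <- generate_dataset(list(
    mode_spec("TTGACGTCAA", strength = 0.95, tau_pos = -9L, tau_neg = 12L,
              proportion = 0.5, label = "near"),
    mode_spec("TTGACGTCAA", strength = 0.95, tau_pos = -20L, tau_neg = 23L,
              proportion = 0.5, label = "far")),
    n = 120, L = 100, bg_read_p = 0.05, seed = 33)
  ds <- augment_revcomp(gen$dataset)
  st <- structure(list(m = 2L,
                       Z = ifelse(gen$truth$orientation == "+" | is.na(gen$truth$orientation),
                                  gen$truth$z, gen$truth$z),
                       O = ifelse(gen$truth$orientation == "-", 1L, 0L),
                       I = pmax(1L, gen$truth$mode),
                       w = c(10L, 10L), tau_pos = c(-9L, -20L),
                       tau_neg = c(12L, 23L)), class = "exo_state")
  fit <- estimate_parameters(st, ds, config = sampler_config(init_width = 10L))
  cm_full <- confusion_matrix(ds, fit, "full")
  cm_seq2 <- confusion_matrix(ds, fit, "seq")
  expect_gt(min(diag(cm_full)), 0.8)
  expect_gt(min(diag(cm_full) - diag(cm_seq2)), 0)
})

test_that("log-odds scores are antisymmetric and zero at identity", {
  fx <- fitted_two_modes(n = 60, L = 80, seed = 13)
  fit_b <- fit_modes(fx$ds, 2, config = sampler_config(init_width = 10L,
                                                       restarts = 1L), seed = 99)
  for (i in c(1, 10)) {
    expect_equal(log_odds(fx$ds, i, fx$fit, fx$fit), 0)
    expect_equal(log_odds(fx$ds, i, fx$fit, fit_b),
                 -log_odds(fx$ds, i, fit_b, fx$fit))
  }
})

test_that("the rank AUC agrees with pROC and separates planted classes", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(40, 1), rnorm(60, 0))
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(classification_auc(scores, labels), want, tolerance = 1e-12)
  expect_error(classification_auc(scores, rep(TRUE, 100)), "both classes")
})

test_that("orientation is resolved to the planted strand and maps coordinates", {
  gen <- two_mode_gen(n = 60, L = 80, seed = 15)
  ds <- augment_revcomp(gen$dataset)
  st <- structure(list(m = 2L, Z = gen$truth$z,
                       O = ifelse(gen$truth$orientation == "-", 1L, 0L),
                       I = gen$truth$mode, w = c(10L, 10L),
                       tau_pos = c(-8L, -6L), tau_neg = c(12L, 14L)),
                  class = "exo_state")
  fit <- estimate_parameters(st, ds, config = sampler_config(init_width = 10L))
  calls <- resolve_orientation(ds, fit)
  ## exactly one call per original region
  expect_equal(nrow(calls), 60L)
  expect_equal(calls$region, ds$regions$id[1:60])
  ## strand calls match the planted orientation
  expect_gt(mean(calls$strand == gen$truth$orientation), 0.95)
  ## forward-mapped coordinates cover the planted site: re-extract the site
  ## string from the forward sequence and compare
  for (i in seq_len(20)) {
    sq <- substr(ds$seqs[i], calls$start[i] - ds$regions$start[i] + 1L,
                 calls$end[i] - ds$regions$start[i])
    if (calls$strand[i] == "-") sq <- revcomp(sq)
    expect_equal(sq, calls$site_seq[i])
  }
  ## a palindromic self-RC datapoint with symmetric reads ties -> forward
  pal <- exo_dataset("ACGCGTACGCGT",
                     binary_pos = list(c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L)),
                     binary_neg = list(c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L)))
  pal <- augment_revcomp(pal)
  ufit <- structure(list(m = 1L,
                         modes = list(list(w = 6L,
                                           pwm = matrix(0.25, 4, 6,
                                                        dimnames = list(c("A","C","G","T"), NULL)),
                                           bern_pos = rep(0.5, 2), bern_neg = rep(0.5, 2),
                                           tau_pos = -2L, tau_neg = 6L)),
                         gamma = 1, window_width = 2L,
                         bg_seq = uniform_bg()$seq, bg_read = uniform_bg()$read),
                    class = "exo_model")
  calls_p <- resolve_orientation(pal, ufit)
  expect_equal(calls_p$strand, "+")
})
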