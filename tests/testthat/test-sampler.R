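# Collapsed Gibbs sampler: conditionals against enumeration oracles,
# count integrity, chain behavior, hill climbing, parameter estimates.
# Fixture builders (small_fixture, truth_state, mirror_state, small_cfg)
# live in helper-fixtures.R.

test_that("initialization is deterministic and respects the mode count", {
  gen <- two_mode_gen(n = 12, L = 60, seed = 2)
  ds <- augment_revcomp(gen$dataset)
  s1 <- init_state(ds, 3, seed = 7)
  s2 <- init_state(ds, 3, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(init_state(ds, 1, seed = 1)$I == 1L))
  expect_true(all(s1$I %in% 1:3))
  ## no valid placement at init width -> error naming the region
  short <- augment_revcomp(exo_dataset("ACGTACGT"))
  expect_error(init_state(short, 1, sampler_config(init_width = 12), seed = 1),
               "region_1")
})

test_that("the (Z, O, I) conditional matches exhaustive enumeration", {
  gen <- small_fixture()
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  st <- truth_state(gen)
  got <- conditional_zi(st, ds, i = 2, config = small_cfg, bg = bg)
  want <- oracle_zi_conditional(ds, st, 2, bg, wwin = 3L)
  mg <- merge(got, want, by = c("k", "o", "z"), suffixes = c("_got", "_want"))
  expect_equal(nrow(mg), nrow(got))
  expect_equal(nrow(mg), nrow(want))
  p_got <- exp(mg$logw_got - or_logsumexp(mg$logw_got))
  p_want <- exp(mg$logw_want - or_logsumexp(mg$logw_want))
  expect_lt(or_tv(p_got, p_want), 1e-10)
  ## the collapsed weight is the marginal-likelihood ratio: weight
  ## differences equal full-configuration score differences exactly
  d_got <- mg$logw_got - mg$logw_got[1]
  d_want <- mg$logw_want - mg$logw_want[1]
  expect_equal(d_got, d_want, tolerance = 1e-9)
})

test_that("with no counts the collapsed weight reduces to the prior predictive", {
  ## a single pair, removed from the counts, under a uniform background:
  ## every valid candidate has identical weight (motif and window predictives
  ## both cancel against the background)
  ds <- toy_dataset("ACGTACGTACGTACGT", list(rep(0L, 16)), list(rep(0L, 16)))
  bg <- uniform_bg(0.5)
  st <- structure(list(m = 2L, Z = 6L, O = 0L, I = 1L, w = c(5L, 5L),
                       tau_pos = c(-3L, -3L), tau_neg = c(5L, 5L)),
                  class = "exo_state")
  cfg <- sampler_config(window_width = 3L, init_width = 5L, max_offset = 5L)
  wts <- conditional_zi(st, ds, 1, config = cfg, bg = bg)
  expect_gt(nrow(wts), 4)
  expect_lt(diff(range(wts$logw)), 1e-12)
})

test_that("uniform data gives a uniform placement conditional", {
  ds <- toy_dataset(c(strrep("A", 30), strrep("A", 30)),
                    list(rep(0L, 30), rep(0L, 30)),
                    list(rep(0L, 30), rep(0L, 30)))
  bg <- fit_backgrounds(ds)
  st <- structure(list(m = 1L, Z = c(8L, 8L), O = c(0L, 0L), I = c(1L, 1L),
                       w = 5L, tau_pos = -5L, tau_neg = 5L),
                  class = "exo_state")
  wts <- conditional_zi(st, ds, 1, config = sampler_config(init_width = 5L), bg = bg)
  for (o in 0:1) {
    lw <- wts$logw[wts$o == o]
    expect_gt(length(lw), 3)
    expect_lt(diff(range(lw)), 1e-10)
  }
})

test_that("a well-supported datapoint is assigned to its own mode", {
  gen <- two_mode_gen(n = 40, L = 80, seed = 19, rc_prob = 0)
  ds <- augment_revcomp(gen$dataset)
  st <- truth_state(gen)
  bg <- fit_backgrounds(ds)
  ## enumerated conditional for a mode-1 datapoint puts > 0.99 on mode 1
  i <- which(gen$truth$mode == 1L)[1]
  wts <- conditional_zi(st, ds, i, config = sampler_config(init_width = 10L), bg = bg)
  p <- exp(wts$logw - or_logsumexp(wts$logw))
  expect_gt(sum(p[wts$k == 1]), 0.99)
  ## and its planted placement dominates within the mode
  expect_equal(wts$z[which.max(wts$logw)], gen$truth$z[i])
})

test_that("tau conditionals match enumeration and recover planted offsets", {
  gen <- two_mode_gen(n = 100, L = 80, seed = 23)
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  st <- truth_state(gen)
  cfg <- sampler_config(init_width = 10L)
  ## exact match with the enumerated conditional on a small fixture
  gen_s <- small_fixture()
  ds_s <- augment_revcomp(gen_s$dataset)
  bg_s <- fit_backgrounds(ds_s)
  st_s <- truth_state(gen_s)
  for (strand in c("pos", "neg")) {
    got <- conditional_tau(st_s, ds_s, 1, strand, config = small_cfg, bg = bg_s)
    want <- oracle_tau_conditional(ds_s, st_s, 1, strand, bg_s, wwin = 3L,
                                   max_offset = 10L)
    expect_equal(got$tau, want$tau)
    p_got <- exp(got$logw - or_logsumexp(got$logw))
    p_want <- exp(want$logw - or_logsumexp(want$logw))
    expect_lt(or_tv(p_got, p_want), 1e-10)
  }
  ## planted offset dominates the enumerated conditional (tau+ = -8, 100 regions)
  got <- conditional_tau(st, ds, 1, "pos", config = cfg, bg = bg)
  p <- exp(got$logw - or_logsumexp(got$logw))
  expect_gt(p[got$tau == -8L], 0.99)
  ## uniform reads -> conditional uniform over valid offsets
  ds_u <- toy_dataset(c(strrep("ACGT", 10)), list(rep(0L, 40)), list(rep(0L, 40)))
  st_u <- structure(list(m = 1L, Z = 18L, O = 0L, I = 1L, w = 5L,
                         tau_pos = -5L, tau_neg = 5L), class = "exo_state")
  got_u <- conditional_tau(st_u, ds_u, 1, "pos",
                           config = sampler_config(init_width = 5L), bg = bg)
  expect_lt(diff(range(got_u$logw)), 1e-10)
})

test_that("width conditionals match enumeration and favor the planted width", {
  gen_s <- small_fixture()
  ds_s <- augment_revcomp(gen_s$dataset)
  bg_s <- fit_backgrounds(ds_s)
  st_s <- truth_state(gen_s)
  got <- conditional_width(st_s, ds_s, 1, config = small_cfg, bg = bg_s)
  want <- oracle_width_conditional(ds_s, st_s, 1, bg_s, wwin = 3L,
                                   w_min = 5L, max_offset = 10L)
  expect_equal(got$dw, want$dw)
  expect_equal(got$shift, want$shift)
  p_got <- exp(got$logw - or_logsumexp(got$logw))
  p_want <- exp(want$logw - or_logsumexp(want$logw))
  expect_lt(or_tv(p_got, p_want), 1e-10)

  ## planted width 10, current state truncated to w = 9: the right-extension
  ## recovers the missing informative column with probability > 0.9
  gen <- two_mode_gen(n = 120, L = 80, seed = 31)
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  st <- truth_state(gen)
  st$w <- c(9L, 9L)    # site covers planted columns 1..9
  got9 <- conditional_width(st, ds, 1, config = sampler_config(init_width = 9L),
                            bg = bg)
  p9 <- exp(got9$logw - or_logsumexp(got9$logw))
  expect_gt(p9[got9$dw == 1L & got9$shift == 0L], 0.9)

  ## at w_min shrink moves carry no probability (they are not proposed)
  st5 <- st; st5$w <- c(10L, 10L)
  cfg5 <- sampler_config(init_width = 10L, w_min = 10L)
  got5 <- conditional_width(st5, ds, 1, config = cfg5, bg = bg)
  expect_true(all(got5$dw >= 0L))
})

test_that("incremental counts survive a long random update sequence", {
  gen <- two_mode_gen(n = 25, L = 60, seed = 6)
  ds <- augment_revcomp(gen$dataset)
  st <- init_state(ds, 2, sampler_config(init_width = 8L), seed = 3)
  res <- audit_updates(st, ds, n_updates = 1000L,
                       config = sampler_config(init_width = 8L), seed = 5)
  expect_identical(res$incremental$pwm_counts, res$recount$pwm_counts)
  expect_identical(res$incremental$win_pos, res$recount$win_pos)
  expect_identical(res$incremental$win_neg, res$recount$win_neg)
  expect_identical(res$incremental$nk, res$recount$nk)
  expect_equal(res$incremental$bsite, res$recount$bsite, tolerance = 1e-9)
  expect_equal(res$incremental_score, res$recount_score, tolerance = 1e-8)
})

test_that("the collapsed score matches the closed-form oracle", {
  gen <- small_fixture(n = 3, L = 20, seed = 9)
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  st <- truth_state(gen)
  got <- score_state(st, ds, config = small_cfg, bg = bg)
  want <- oracle_score(ds, st, bg, wwin = 3L)
  expect_equal(got, want, tolerance = 1e-9)
  ## label-permutation invariance
  st2 <- st
  st2$I <- 3L - st$I
  st2$w <- rev(st$w); st2$tau_pos <- rev(st$tau_pos); st2$tau_neg <- rev(st$tau_neg)
  expect_equal(score_state(st2, ds, config = small_cfg, bg = bg), got,
               tolerance = 1e-9)
  ## mirror invariance (exact under a context-free background)
  ubg <- uniform_bg(0.2)
  stm <- mirror_state(st, ds, wwin = 3L)
  expect_equal(score_state(stm, ds, config = small_cfg, bg = ubg),
               score_state(st, ds, config = small_cfg, bg = ubg),
               tolerance = 1e-9)
})

test_that("mirrored configurations give mirror-equal conditionals", {
  gen <- small_fixture(n = 4, L = 20, seed = 14)
  ds <- augment_revcomp(gen$dataset)
  ubg <- uniform_bg(0.2)
  st <- truth_state(gen)
  stm <- mirror_state(st, ds, wwin = 3L)
  a <- conditional_zi(st, ds, 2, config = small_cfg, bg = ubg)
  b <- conditional_zi(stm, ds, 2, config = small_cfg, bg = ubg)
  ## candidate (k, o, z) in the original maps to (k, 1-o, L-z-w+2)
  L <- nchar(ds$seqs[1])
  b_key <- paste(b$k, 1L - b$o, L - b$z - stm$w[b$k] + 2L)
  a_key <- paste(a$k, a$o, a$z)
  expect_setequal(a_key, b_key)
  m <- match(a_key, b_key)
  expect_equal(a$logw, b$logw[m], tolerance = 1e-9)
})

test_that("chains are deterministic, keep a sane trace, and recover two modes", {
  gen <- two_mode_gen(n = 200, L = 100, seed = 27)
  ds <- augment_revcomp(gen$dataset)
  cfg <- sampler_config(init_width = 10L)
  ch1 <- run_chain(ds, 2, config = cfg, seed = 41)
  ch2 <- run_chain(ds, 2, config = cfg, seed = 41)
  expect_identical(ch1$trace, ch2$trace)
  expect_identical(unclass(ch1$best_state), unclass(ch2$best_state))
  ## the running maximum of the score trace is non-decreasing and tops out
  ## at the best score
  expect_true(all(diff(cummax(ch1$trace)) >= 0))
  expect_equal(max(ch1$trace), ch1$best_score)
  ## recovery: labels agree with the planted modes after matching
  fit <- fit_modes(ds, 2, config = cfg, seed = 41)
  calls <- resolve_orientation(ds, fit)
  agree <- best_agreement(calls$mode, gen$truth$mode, 2L)
  expect_gt(agree, 0.9)
  ## chains from a different seed land on an equivalent labeling
  fit3 <- fit_modes(ds, 2, config = cfg, seed = 91)
  calls3 <- resolve_orientation(ds, fit3)
  expect_gt(best_agreement(calls$mode, calls3$mode, 2L), 0.9)
})

test_that("hill climbing never lowers the score and finds the exhaustive optimum", {
  gen <- small_fixture(n = 3, L = 12, seed = 3,
                       tau_a = c(-3L, 4L), tau_b = c(-3L, 4L))
  ds <- augment_revcomp(gen$dataset)
  bg <- fit_backgrounds(ds)
  cfg <- sampler_config(window_width = 3L, init_width = 6L, w_min = 6L,
                        w_max = 6L, max_offset = 2L)
  ch <- run_chain(ds, 2, config = cfg, seed = 8, bg = bg)
  st0 <- ch$best_state
  s0 <- score_state(st0, ds, config = cfg, bg = bg)
  hc <- hill_climb(st0, ds, config = cfg, bg = bg)
  expect_gte(hc$score, s0 - 1e-9)
  ## a state already at a local maximum is returned unchanged
  hc2 <- hill_climb(hc$state, ds, config = cfg, bg = bg)
  expect_identical(unclass(hc2$state), unclass(hc$state))
  expect_equal(hc2$score, hc$score, tolerance = 1e-9)
  ## exhaustive search over all (Z, O, I) configurations at the climbed
  ## offsets: the climbed configuration attains the global maximum
  st <- hc$state
  cands <- lapply(1:3, function(i) {
    rows <- list()
    for (k in 1:2) for (o in 0:1) {
      s <- or_encode(ds$seqs[if (o == 0) i else i + 3])
      for (z in or_valid(s, st$w[k], st$tau_pos[k], st$tau_neg[k], 3L))
        rows[[length(rows) + 1L]] <- c(k, o, z)
    }
    rows
  })
  best <- -Inf
  for (c1 in cands[[1]]) for (c2 in cands[[2]]) for (c3 in cands[[3]]) {
    st2 <- st
    st2$I <- c(c1[1], c2[1], c3[1]); st2$O <- c(c1[2], c2[2], c3[2])
    st2$Z <- c(c1[3], c2[3], c3[3])
    sc <- oracle_score(ds, st2, bg, wwin = 3L)
    if (sc > best) best <- sc
  }
  expect_equal(hc$score, best, tolerance = 1e-9)
})

test_that("MAP estimates apply the posterior-mean formulas", {
  ## counts A:9, C:1, G:1, T:1 at a column with alpha = 0.5 -> 9.5/14
  gen <- two_mode_gen(n = 30, L = 60, seed = 17)
  ds <- augment_revcomp(gen$dataset)
  st <- truth_state(gen)
  cfg <- sampler_config(init_width = 10L)
  bg <- fit_backgrounds(ds)
  fit <- estimate_parameters(st, ds, config = cfg, bg = bg)
  cc <- exomodes:::cg_counts(exomodes:::sampler_data(ds, bg), unclass(st),
                             exomodes:::cpp_cfg(cfg, mode_priors()))
  for (k in 1:2) {
    nk <- cc$nk[k]
    expect_equal(fit$modes[[k]]$pwm,
                 (cc$pwm_counts[[k]] + 0.5) / (nk + 2), ignore_attr = TRUE)
    expect_equal(fit$modes[[k]]$bern_pos, (cc$win_pos[[k]] + 0.5) / (nk + 1))
    expect_equal(fit$gamma[k], (nk + 1) / (30 + 2))
  }
  expect_equal(sum(fit$gamma), 1, tolerance = 1e-12)
  ## a direct instance of the formula
  expect_equal((9 + 0.5) / (12 + 2), 9.5 / 14)
  ## empty mode: prior-predictive parameters and a warning
  st3 <- st; st3$m <- 3L
  st3$w <- c(st$w, 10L); st3$tau_pos <- c(st$tau_pos, -8L)
  st3$tau_neg <- c(st$tau_neg, 12L)
  expect_warning(fit3 <- estimate_parameters(st3, ds, config = cfg, bg = bg),
                 "empty")
  expect_equal(unname(fit3$modes[[3]]$pwm), matrix(0.25, 4, 10))
  expect_equal(fit3$modes[[3]]$bern_pos, rep(0.5, 5))
})
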