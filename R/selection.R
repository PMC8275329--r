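#' Number of free parameters of a fitted model
#'
#' Three parameters per PWM column, one per read-window position on each
#' strand, and two per mode for the window offsets:
#' `K = sum_k (3 w_k + w_k+ + w_k- + 2)`.
#'
#' @param fitted an `exo_model`.
#' @return integer K.
#' @export
count_free_parameters <- function(fitted) {
  stopifnot(inherits(fitted, "exo_model"))
  ws <- vapply(fitted$modes, function(mo) mo$w, 0L)
  sum(3L * ws + 2L * fitted$window_width + 2L)
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = K ln(n) - 2 ln(P-hat)` where `P-hat` is the collapsed posterior
#' score at the MAP estimate and `n` the number of datapoints the likelihood
#' is computed over (the RC-augmented count).
#'
#' @param fitted an `exo_model`.
#' @param n datapoint count; defaults to the augmented count stored in the
#'   model.
#' @return the BIC value (smaller is better).
#' @export
bic <- function(fitted, n = fitted$n_data) {
  if (is.null(n) || n < 1) stop("n must be >= 1")
  count_free_parameters(fitted) * log(n) - 2 * fitted$logpost
}

#' Sweep over mode counts and select the minimum-BIC model
#'
#' Fits a model for every value in `m_values` (each with restarts) and
#' selects the mode count minimizing BIC, ties broken toward fewer modes.
#'
#' @inheritParams fit_modes
#' @param m_values integer vector of candidate mode counts.
#' @return list of class `exo_sweep`: `table` (one row per attempted m with
#'   `m, K, logpost, bic, seed, chosen`), `models` (all fitted models, named
#'   by m), `best` (the selected `exo_model`) and `m_best`.
#' @export
model_sweep <- function(dataset, m_values = 1:10, priors = mode_priors(),
                        config = sampler_config(), seed = 1L, bg = NULL) {
  stopifnot(length(m_values) >= 1)
  if (is.null(bg)) bg <- fit_backgrounds(dataset)
  rows <- list(); models <- list()
  for (m in m_values) {
    fit <- tryCatch(fit_modes(dataset, m, priors, config,
                              seed = as.integer(seed) + 1000L * as.integer(m),
                              bg = bg),
                    error = function(e) {
                      warning("m = ", m, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) {
      rows[[length(rows) + 1L]] <- data.frame(m = m, K = NA_integer_,
                                              logpost = NA_real_, bic = NA_real_,
                                              seed = NA_integer_, chosen = FALSE)
      next
    }
    fit$bic <- bic(fit)
    models[[as.character(m)]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(m = m, K = count_free_parameters(fit),
                                            logpost = fit$logpost, bic = fit$bic,
                                            seed = fit$seed, chosen = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$bic))
  if (!length(ok)) stop("every mode count failed to fit")
  best_row <- ok[order(tab$bic[ok], tab$m[ok])][1L]   # ties -> smaller m
  tab$chosen[best_row] <- TRUE
  structure(list(table = tab, models = models,
                 best = models[[as.character(tab$m[best_row])]],
                 m_best = tab$m[best_row]),
            class = "exo_sweep")
}

#' @export
print.exo_sweep <- function(x, ...) {
  cat("Mode-count sweep; chosen m =", x$m_best, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
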