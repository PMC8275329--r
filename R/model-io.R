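#' Serialize a fitted model to JSON
#'
#' Writes the complete point estimate (PWMs, window Bernoullis, offsets,
#' widths, mixture weights), the background models, the priors, the
#' binarization threshold and bookkeeping, sufficient to reload the model
#' for prediction with [read_model_json()].
#'
#' @param fitted an `exo_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(fitted, path) {
  stopifnot(inherits(fitted, "exo_model"))
  obj <- list(
    format = "exomodes_model", version = as.character(packageVersion("exomodes")),
    m = fitted$m, window_width = fitted$window_width,
    gamma = fitted$gamma,
    modes = lapply(fitted$modes, function(mo) list(
      w = mo$w, pwm = unname(mo$pwm), bern_pos = mo$bern_pos,
      bern_neg = mo$bern_neg, tau_pos = mo$tau_pos, tau_neg = mo$tau_neg,
      n_members = mo$n_members)),
    bg_seq = list(p0 = unname(fitted$bg_seq$p0), p1 = unname(fitted$bg_seq$p1),
                  p2 = unname(fitted$bg_seq$p2)),
    bg_read = list(p_pos = fitted$bg_read$p_pos, p_neg = fitted$bg_read$p_neg),
    priors = unclass(fitted$priors),
    logpost = fitted$logpost, bic = fitted$bic, n_data = fitted$n_data,
    binarize_threshold = fitted$binarize_threshold, seed = fitted$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a fitted model back from JSON
#'
#' @param path file written by [write_model_json()].
#' @return an `exo_model` (without per-region assignments).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "exomodes_model")) stop("not an exomodes model file: ", path)
  fix_mat <- function(m, nr) {
    m <- as.matrix(m)
    if (nrow(m) != nr) m <- t(m)
    m
  }
  modes <- lapply(seq_len(obj$m), function(k) {
    mo <- if (is.data.frame(obj$modes)) lapply(obj$modes, `[[`, k) else obj$modes[[k]]
    pwm <- fix_mat(if (is.list(mo$pwm) && !is.matrix(mo$pwm)) do.call(rbind, mo$pwm) else mo$pwm, 4L)
    rownames(pwm) <- BASES[1:4]
    list(w = as.integer(mo$w), pwm = pwm,
         bern_pos = as.numeric(mo$bern_pos), bern_neg = as.numeric(mo$bern_neg),
         tau_pos = as.integer(mo$tau_pos), tau_neg = as.integer(mo$tau_neg),
         n_members = as.integer(mo$n_members))
  })
  bg_seq <- structure(list(p0 = as.numeric(obj$bg_seq$p0),
                           p1 = fix_mat(obj$bg_seq$p1, 4L),
                           p2 = fix_mat(obj$bg_seq$p2, 16L)),
                      class = "exo_bg_seq")
  bg_read <- structure(list(p_pos = obj$bg_read$p_pos, p_neg = obj$bg_read$p_neg),
                       class = "exo_bg_read")
  structure(list(m = as.integer(obj$m), modes = modes, gamma = as.numeric(obj$gamma),
                 window_width = as.integer(obj$window_width),
                 bg_seq = bg_seq, bg_read = bg_read,
                 priors = do.call(mode_priors, obj$priors),
                 logpost = obj$logpost, bic = obj$bic,
                 n_data = obj$n_data, binarize_threshold = obj$binarize_threshold,
                 seed = obj$seed),
            class = "exo_model")
}

#' Write motifs in MEME minimal format
#'
#' One `MOTIF` block per binding mode, with `nsites` set to the mode's
#' membership count and the background line taken from the model's 0th-order
#' base composition.
#'
#' @param fitted an `exo_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_meme <- function(fitted, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p0 <- fitted$bg_seq$p0
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", p0[1], p0[2], p0[3], p0[4]),
               ""), con)
  for (k in seq_len(fitted$m)) {
    mo <- fitted$modes[[k]]
    writeLines(sprintf("MOTIF mode_%d", k), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       mo$w, max(1L, mo$n_members)), con)
    writeLines(apply(mo$pwm, 2, function(col) sprintf(" %.6f %.6f %.6f %.6f",
                                                      col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write all model outputs for a fitted dataset
#'
#' Writes, into `dir`: `assignments.tsv` (per-region mode call with genomic
#' motif coordinates and posterior), `motifs.meme` (per-mode PWMs, MEME
#' minimal format), `footprints.tsv` (window offsets and Bernoulli
#' probabilities per position and strand), `model.json` (full model for
#' reuse), `summary.json` (m, mixture weights, log posterior, BIC) and
#' `sites.bed` (BED6 motif sites).
#'
#' @param fitted an `exo_model`.
#' @param dataset the augmented [exo_dataset()] it was fitted to.
#' @param dir output directory; must be creatable/writable (checked before
#'   any computation).
#' @return invisibly, a named list of written paths.
#' @export
write_outputs <- function(fitted, dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("output directory is not writable: ", dir)
  calls <- resolve_orientation(dataset, fitted)
  paths <- list(
    assignments = file.path(dir, "assignments.tsv"),
    meme = file.path(dir, "motifs.meme"),
    footprints = file.path(dir, "footprints.tsv"),
    model = file.path(dir, "model.json"),
    summary = file.path(dir, "summary.json"),
    bed = file.path(dir, "sites.bed"))
  write.table(calls, paths$assignments, sep = "\t", quote = FALSE, row.names = FALSE)
  write_meme(fitted, paths$meme)
  fp <- do.call(rbind, lapply(seq_len(fitted$m), function(k) {
    mo <- fitted$modes[[k]]
    rbind(data.frame(mode = k, strand = "pos", tau = mo$tau_pos,
                     position = seq_along(mo$bern_pos), p = mo$bern_pos),
          data.frame(mode = k, strand = "neg", tau = mo$tau_neg,
                     position = seq_along(mo$bern_neg), p = mo$bern_neg))
  }))
  write.table(fp, paths$footprints, sep = "\t", quote = FALSE, row.names = FALSE)
  write_model_json(fitted, paths$model)
  jsonlite::write_json(list(m = fitted$m, gamma = fitted$gamma,
                            logpost = fitted$logpost,
                            bic = if (is.null(fitted$bic)) bic(fitted) else fitted$bic,
                            n_data = fitted$n_data,
                            binarize_threshold = fitted$binarize_threshold),
                       paths$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bed <- data.frame(calls$chrom, calls$start, calls$end,
                    paste0(calls$region, "_mode", calls$mode),
                    round(1000 * calls$posterior), calls$strand)
  write.table(bed, paths$bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
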