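#' Specification of one planted binding mode
#'
#' Describes the ground truth for one synthetic mode: a PWM (or a consensus
#' string expanded into one), strand footprint Bernoulli vectors, the signed
#' window offsets, and the mixture proportion. Proportions over all specs
#' may sum to less than 1; the remainder becomes pure-background regions.
#'
#' @param consensus consensus string (used when `pwm` is `NULL`).
#' @param strength probability of the consensus base at each column; the
#'   rest is spread evenly over the other three bases.
#' @param pwm optional explicit 4 x w matrix (rows A,C,G,T; columns sum to 1).
#' @param footprint_pos,footprint_neg per-position read probabilities inside
#'   the positive/negative strand windows (length = window width).
#' @param tau_pos,tau_neg signed window offsets from the motif start.
#' @param proportion mixture weight of this mode.
#' @param label mode label used in the truth table.
#' @return list of class `exo_mode_spec`.
#' @export
mode_spec <- function(consensus = NULL, strength = 0.9, pwm = NULL,
                      footprint_pos = rep(0.9, 5), footprint_neg = rep(0.9, 5),
                      tau_pos = -10L, tau_neg = 12L, proportion = 1,
                      label = NULL) {
  if (is.null(pwm)) {
    stopifnot(!is.null(consensus), strength > 0.25, strength < 1)
    b <- match(strsplit(toupper(consensus), "")[[1]], BASES[1:4])
    if (anyNA(b)) stop("consensus must be over A,C,G,T")
    pwm <- matrix((1 - strength) / 3, 4, length(b))
    pwm[cbind(b, seq_along(b))] <- strength
  }
  stopifnot(nrow(pwm) == 4, all(abs(colSums(pwm) - 1) < 1e-9),
            all(pwm > 0), all(footprint_pos > 0 & footprint_pos < 1),
            all(footprint_neg > 0 & footprint_neg < 1),
            length(footprint_pos) == length(footprint_neg),
            proportion >= 0, proportion <= 1)
  rownames(pwm) <- BASES[1:4]
  structure(list(pwm = pwm, w = ncol(pwm),
                 footprint_pos = footprint_pos, footprint_neg = footprint_neg,
                 tau_pos = as.integer(tau_pos), tau_neg = as.integer(tau_neg),
                 proportion = proportion,
                 label = if (is.null(label)) NA_character_ else label),
            class = "exo_mode_spec")
}

## 1st-order background chain parameterized by GC content, with mild
## same-base persistence; intentionally mismatched to the fitted 2nd-order
## background to exercise robustness
bg_chain <- function(gc, persistence = 0.1) {
  stat <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  trans <- matrix(rep(stat, each = 4), 4, 4) * (1 - persistence) +
    diag(4) * persistence
  list(stat = stat, trans = trans)
}

sim_bg_seq <- function(L, chain) {
  s <- integer(L)
  s[1] <- sample.int(4L, 1L, prob = chain$stat)
  for (j in seq_len(L - 1L)) s[j + 1L] <- sample.int(4L, 1L, prob = chain$trans[s[j], ])
  s
}

#' Generate a synthetic dataset with planted binding modes
#'
#' Emulates the generative model: each region draws a mode (or pure
#' background), a motif position uniform over feasible placements and an
#' orientation; the site is emitted from the mode's PWM, flanks from a
#' 1st-order background chain with the stated GC content, and binary reads
#' are Bernoulli draws from the footprint inside the windows and from the
#' background rate elsewhere.
#'
#' @param specs list of [mode_spec()]s (may be empty for pure background).
#' @param n number of regions.
#' @param L region length in bp.
#' @param bg_gc background GC content.
#' @param bg_read_p background per-position read probability (both strands).
#' @param window_width read-window width.
#' @param rc_prob probability a planted site sits on the minus strand.
#' @param count_mode `"binary"` writes the binary indicators directly as
#'   counts; `"geometric"` wraps ones in 2 + geometric counts and adds
#'   sparse unit noise, to exercise [binarize()].
#' @param seed RNG seed (generation is deterministic given the seed).
#' @return list with `dataset` (unaugmented [exo_dataset()]; for
#'   `count_mode = "geometric"` the binaries must be recreated with
#'   [binarize()]) and `truth` (data.frame: `region, mode, label, z,
#'   orientation`; `mode` 0 = background, `z` is the motif start in the
#'   motif-frame copy).
#' @export
generate_dataset <- function(specs, n, L = 240L, bg_gc = 0.41,
                             bg_read_p = 0.05, window_width = 5L,
                             rc_prob = 0.5, count_mode = c("binary", "geometric"),
                             seed = 1L) {
  count_mode <- match.arg(count_mode)
  if (inherits(specs, "exo_mode_spec")) specs <- list(specs)
  props <- vapply(specs, function(sp) sp$proportion, 0)
  if (sum(props) > 1 + 1e-9) stop("mode proportions sum to more than 1")
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    zv <- valid_placements(rep(1L, L), sp$w, sp$tau_pos, sp$tau_neg, window_width)
    if (!length(zv))
      stop("mode spec ", if (is.na(sp$label)) si else sp$label,
           " is infeasible within regions of length ", L)
  }
  set.seed(seed)
  chain <- bg_chain(bg_gc)
  seqs <- character(n)
  bp <- vector("list", n); bn <- vector("list", n)
  truth <- data.frame(region = paste0("region_", seq_len(n)),
                      mode = integer(n), label = NA_character_,
                      z = NA_integer_, orientation = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    u <- runif(1)
    k <- 0L; acc <- 0
    for (si in seq_along(props)) {
      acc <- acc + props[si]
      if (u <= acc) { k <- si; break }
    }
    s <- sim_bg_seq(L, chain)
    rp <- rbinom(L, 1L, bg_read_p)
    rn <- rbinom(L, 1L, bg_read_p)
    if (k > 0L) {
      sp <- specs[[k]]
      zv <- valid_placements(s, sp$w, sp$tau_pos, sp$tau_neg, window_width)
      z <- zv[sample.int(length(zv), 1L)]
      for (a in seq_len(sp$w)) s[z + a - 1L] <- sample.int(4L, 1L, prob = sp$pwm[, a])
      ww <- length(sp$footprint_pos)
      rp[z + sp$tau_pos + seq_len(ww) - 1L] <- rbinom(ww, 1L, sp$footprint_pos)
      rn[z + sp$tau_neg + seq_len(ww) - 1L] <- rbinom(ww, 1L, sp$footprint_neg)
      ori <- if (runif(1) < rc_prob) "-" else "+"
      if (ori == "-") {     # observed region is the RC of the motif frame
        s <- rev(5L - s)
        tmp <- rev(rn); rn <- rev(rp); rp <- tmp
      }
      truth$mode[i] <- k
      truth$label[i] <- sp$label
      truth$z[i] <- z
      truth$orientation[i] <- ori
    }
    seqs[i] <- paste(BASES[s], collapse = "")
    bp[[i]] <- rp; bn[[i]] <- rn
  }
  if (count_mode == "binary") {
    cp <- lapply(bp, identity); cn <- lapply(bn, identity)
    ds <- exo_dataset(seqs, bp, bn, counts_pos = cp, counts_neg = cn,
                      binarize_threshold = 0)
  } else {
    wrap <- function(b) as.integer(b * (2L + rgeom(length(b), 0.4)) +
                                     (1 - b) * rbinom(length(b), 1L, 0.02))
    cp <- lapply(bp, wrap); cn <- lapply(bn, wrap)
    ds <- exo_dataset(seqs, counts_pos = cp, counts_neg = cn)
  }
  list(dataset = ds, truth = truth,
       specs = specs, window_width = as.integer(window_width),
       bg_read_p = bg_read_p, bg_gc = bg_gc, seed = as.integer(seed))
}

#' Degenerate edge-case datasets
#'
#' Small fixtures for robustness tests: `no_reads` (all binary vectors
#' zero), `uniform_motif` (pure background sequence and reads, no planted
#' signal), `single_region` (n = 1), `all_N_flanks` (informative core
#' flanked by repeats masked to N).
#'
#' @param kind one of `"no_reads"`, `"uniform_motif"`, `"single_region"`,
#'   `"all_N_flanks"`.
#' @param seed RNG seed.
#' @return an unaugmented [exo_dataset()].
#' @export
generate_degenerate <- function(kind = c("no_reads", "uniform_motif",
                                         "single_region", "all_N_flanks"),
                                seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  chain <- bg_chain(0.5)
  switch(kind,
    no_reads = {
      seqs <- vapply(1:20, function(i) paste(BASES[sim_bg_seq(60L, chain)], collapse = ""), "")
      exo_dataset(seqs)
    },
    uniform_motif = {
      g <- generate_dataset(list(), n = 30L, L = 60L, bg_gc = 0.5, seed = seed)
      g$dataset
    },
    single_region = {
      g <- generate_dataset(mode_spec("ACGTACGT", tau_pos = -6L, tau_neg = 9L),
                            n = 1L, L = 60L, seed = seed)
      g$dataset
    },
    all_N_flanks = {
      core <- vapply(1:10, function(i) paste(BASES[sim_bg_seq(30L, chain)], collapse = ""), "")
      seqs <- paste0(strrep("N", 15), core, strrep("N", 15))
      exo_dataset(seqs)
    })
}

## ---- ground-truth matching & recovery evaluation --------------------------

#' Mirror a mode's parameters into the opposite orientation
#'
#' A mode learned on the reverse-complement frame of its members is
#' equivalent to the mirrored mode on the forward frame: the PWM is
#' reverse-complemented, the strand windows swap (reversed), and the offsets
#' map as `tau+ <- w - tau- - window_width` (and symmetrically).
#'
#' @param mode one mode list from an `exo_model` (or a [mode_spec()]).
#' @param window_width read window width.
#' @return the mirrored mode list.
#' @export
mirror_mode <- function(mode, window_width = length(mode$bern_pos)) {
  pwm <- mode$pwm
  w <- ncol(pwm)
  mpwm <- pwm[4:1, w:1, drop = FALSE]
  rownames(mpwm) <- BASES[1:4]
  fp <- if (!is.null(mode$bern_pos)) mode$bern_pos else mode$footprint_pos
  fn <- if (!is.null(mode$bern_neg)) mode$bern_neg else mode$footprint_neg
  out <- mode
  out$pwm <- mpwm
  if (!is.null(mode$bern_pos)) {
    out$bern_pos <- rev(fn); out$bern_neg <- rev(fp)
  } else {
    out$footprint_pos <- rev(fn); out$footprint_neg <- rev(fp)
  }
  out$tau_pos <- mode$w - mode$tau_neg - window_width
  out$tau_neg <- mode$w - mode$tau_pos - window_width
  out
}

## best sliding alignment of fitted pwm against a true pwm in one frame:
## maximizes the summed per-column similarity (1 - total variation), which
## prefers full overlaps over short strongly-matching cores; returns the
## offset d (fitted start = true start + d), the mean per-column total
## variation over the overlap, and the similarity score
align_pwms <- function(pwm_fit, pwm_true, min_overlap = 5L) {
  wf <- ncol(pwm_fit); wt <- ncol(pwm_true)
  best <- list(tv = Inf, d = 0L, overlap = 0L, score = -Inf)
  for (d in seq(-(wf - min_overlap), wt - min_overlap)) {
    tcols <- max(1L, 1L + d):min(wt, wf + d)
    fcols <- tcols - d
    if (length(tcols) < min_overlap) next
    tv_cols <- colSums(abs(pwm_fit[, fcols, drop = FALSE] -
                             pwm_true[, tcols, drop = FALSE])) / 2
    score <- sum(1 - tv_cols)
    if (score > best$score)
      best <- list(tv = mean(tv_cols), d = d, overlap = length(tcols),
                   score = score)
  }
  best
}

#' Match fitted modes to planted ground truth and measure recovery
#'
#' Finds the best bijection between fitted modes and the planted
#' [mode_spec()]s (each fitted mode may match in the forward or the mirrored
#' frame), then reports, per true mode, the mean per-column PWM total
#' variation over the aligned columns, the absolute window placement errors
#' on both strands, and the region label agreement after mapping.
#'
#' @param fitted an `exo_model`.
#' @param gen output of [generate_dataset()] (uses `specs` and `truth`).
#' @param dataset the augmented dataset the model was fitted to (for label
#'   agreement via [resolve_orientation()]); `NULL` skips agreement.
#' @return list: `mapping` (true mode -> fitted mode), `pwm_tv`, `tau_err`
#'   (matrix, strands x true modes), `agreement` (or `NA`).
#' @export
evaluate_recovery <- function(fitted, gen, dataset = NULL) {
  specs <- gen$specs
  ww <- fitted$window_width
  nt <- length(specs); nf <- fitted$m
  ## pairwise best-frame alignments
  tv <- matrix(Inf, nt, nf); dd <- matrix(0L, nt, nf); fr <- matrix(1L, nt, nf)
  for (t in seq_len(nt)) for (f in seq_len(nf)) {
    a1 <- align_pwms(fitted$modes[[f]]$pwm, specs[[t]]$pwm)
    a2 <- align_pwms(mirror_mode(fitted$modes[[f]], ww)$pwm, specs[[t]]$pwm)
    if (a1$score >= a2$score) { tv[t, f] <- a1$tv; dd[t, f] <- a1$d; fr[t, f] <- 1L }
    else { tv[t, f] <- a2$tv; dd[t, f] <- a2$d; fr[t, f] <- 2L }
  }
  ## best assignment over permutations (m is small)
  perms <- all_injections(nt, nf)
  costs <- vapply(perms, function(p) sum(tv[cbind(seq_len(nt), p)]), 0)
  map <- perms[[which.min(costs)]]
  pwm_tv <- tv[cbind(seq_len(nt), map)]
  tau_err <- matrix(NA_real_, 2, nt, dimnames = list(c("pos", "neg"), NULL))
  for (t in seq_len(nt)) {
    f <- map[t]
    mo <- fitted$modes[[f]]
    if (fr[t, f] == 2L) mo <- mirror_mode(mo, ww)
    d <- dd[t, f]
    tau_err["pos", t] <- abs(mo$tau_pos + d - specs[[t]]$tau_pos)
    tau_err["neg", t] <- abs(mo$tau_neg + d - specs[[t]]$tau_neg)
  }
  agreement <- NA_real_
  if (!is.null(dataset)) {
    calls <- resolve_orientation(dataset, fitted)
    inv <- rep(NA_integer_, nf); inv[map] <- seq_len(nt)
    pred_true <- inv[calls$mode]
    planted <- gen$truth$mode > 0L
    agreement <- mean(pred_true[planted] == gen$truth$mode[planted], na.rm = FALSE)
  }
  list(mapping = map, pwm_tv = pwm_tv, tau_err = tau_err, agreement = agreement)
}

## all injective maps from 1..nt into 1..nf
all_injections <- function(nt, nf) {
  stopifnot(nf >= nt)
  if (nt == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(chosen) {
    if (length(chosen) == nt) { out[[length(out) + 1L]] <<- chosen; return() }
    for (f in setdiff(seq_len(nf), chosen)) rec(c(chosen, f))
  }
  rec(integer(0))
  out
}

## ---- file writers (standard formats, full CLI round trip) -----------------

#' Write a synthetic dataset as standard genomic files
#'
#' Assembles a pseudo-genome (one chromosome, regions laid head-to-tail with
#' background gaps), and writes FASTA, a BED peak file of summit points,
#' per-strand bedGraph count tracks and the truth table, so the file-based
#' pipeline can be exercised end to end.
#'
#' @param gen output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param gap bp of background sequence between consecutive regions.
#' @return invisibly, a named list of the written file paths.
#' @export
write_dataset_files <- function(gen, dir, gap = 30L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen$dataset
  n <- ds$n_original
  lens <- nchar(ds$seqs[seq_len(n)])
  set.seed(gen$seed + 104729L)
  chain <- bg_chain(gen$bg_gc)
  gapseq <- function() paste(BASES[sim_bg_seq(gap, chain)], collapse = "")
  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- gapseq()
    pos <- pos + gap
    starts[i] <- pos
    pieces[2L * i] <- ds$seqs[i]
    pos <- pos + lens[i]
  }
  pieces[2L * n + 1L] <- gapseq()
  chrom <- "chrS"
  fa <- file.path(dir, "genome.fa")
  writeLines(c(paste0(">", chrom), paste(pieces, collapse = "")), fa)
  summit <- starts + lens %/% 2L
  bed <- file.path(dir, "peaks.bed")
  write.table(data.frame(chrom, summit, summit + 1L,
                         ds$regions$id[seq_len(n)]),
              bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  bedgraph <- function(counts, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      v <- counts[[i]]
      nz <- which(v > 0)
      if (length(nz))
        writeLines(sprintf("%s\t%d\t%d\t%d", chrom, starts[i] + nz - 1L,
                           starts[i] + nz, v[nz]), con)
    }
    path
  }
  cp <- if (!is.null(ds$counts_pos)) ds$counts_pos else ds$binary_pos
  cn <- if (!is.null(ds$counts_neg)) ds$counts_neg else ds$binary_neg
  bg_pos <- bedgraph(cp, file.path(dir, "reads_pos.bedGraph"))
  bg_neg <- bedgraph(cn, file.path(dir, "reads_neg.bedGraph"))
  truth <- file.path(dir, "truth.tsv")
  write.table(gen$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(genome = fa, peaks = bed, pos = bg_pos, neg = bg_neg,
                 truth = truth))
}
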