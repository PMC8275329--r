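---
title: "Resolving binding modes from exonuclease footprints: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving binding modes from exonuclease footprints: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomodes)
```

## The problem

ChIP-exo and ChIP-nexus use lambda exonuclease to digest DNA up to the
protein–DNA crosslink, so the 5′ ends of mapped reads pile up at sharp,
strand-specific borders flanking the bound site. The set of reported regions
is heterogeneous: the profiled factor binds different sequence variants,
partners with co-factors, or is tethered indirectly, and each of these
configurations stalls the exonuclease differently. `exomodes` partitions the
regions into *binding modes*, where a mode is jointly a DNA motif (a PWM)
and a strand-specific *read footprint*: one short window of per-position
read-presence probabilities on each strand, at a fixed offset from the
motif. Everything — motif locations, widths, window offsets, window
probabilities, mode memberships and the number of modes — is learned from
the data with no prior motif information.

## The model

A datapoint is a region `X` (length `L`) with binarized 5′-end indicator
vectors `R+` and `R-`. Conditional on its mode `k` and motif position `Z`,
the three parts are independent:

* **Sequence**: positions `Z..Z+w_k-1` are emitted by the mode's PWM
  `phi_k`; everything else by a 2nd-order Markov background fitted to the
  whole (reverse-complement-augmented) sequence set with add-one smoothing.
* **Reads**: within the strand window of width 5 (configurable) starting at
  `Z + tau_k^s`, position `a` carries a read with probability
  `phi_k,a^s`; outside the windows, a per-strand background Bernoulli rate.
* **Membership**: mode `k` is drawn with probability `gamma_k`.

All likelihoods are computed in log space as ratios against the background,
so a placement's weight depends only on its site string (with its left
context) and the two windows. Binarization of counts (strictly greater than
the pooled median of positive counts, by default) keeps the read model
honest on deeply and shallowly sequenced datasets alike.

Motifs can lie on either strand. Each region is therefore augmented with
its reverse complement (sequence complemented and reversed, strand vectors
swapped and reversed). During learning the two copies of a region are tied:
a region carries one latent orientation and one site, and the copy not in
use contributes pure background. Left untied, every planted mode would be
accompanied by an exact mirror-image mode built from the same regions'
opposite copies, and model selection would systematically double the mode
count — mirror duplicates that have no biological meaning. The reported
orientation is re-resolved at prediction time from the marginal likelihood
of the two copies, with ties going to the forward strand.

## Learning

PWM columns, window Bernoullis and mixture weights have conjugate priors
(symmetric Dirichlet(0.5) per column, Beta(0.5, 0.5) per window position,
Dirichlet(1) over modes) and are integrated out. A collapsed Gibbs sampler
iterates over:

* `(Z_i, O_i, I_i)` — position, orientation and mode of each region,
  sampled jointly from the exact collapsed predictive over every valid
  candidate (site and both windows inside the region, no `N` in the site);
* `tau_k^s` — each mode's window offsets over a bounded grid
  (`tau+` from `-max_offset - 5` to `w_k - 1`, `tau-` from `-4` to
  `w_k + max_offset`, default `max_offset` 25 bp), moving all members'
  windows together;
* `w_k` — ±1 bp edge moves (grow/shrink at either edge, or stay), chosen
  among the five candidates by their collapsed marginal likelihood, with
  member positions shifted for left-edge moves. Windows keep their absolute
  genomic positions across width moves: the footprint belongs to the bound
  complex, not to the motif parameterization.

The prior over `Z` is uniform over the valid placements and contributes no
term to the conditionals. Every update is scored with the exact closed-form
collapsed posterior (Dirichlet-multinomial and Beta-Bernoulli marginals plus
background terms); the chain stops when `5n` consecutive single-variable
updates fail to improve the best score seen (`n` = augmented datapoint
count), the best state is polished by coordinate-ascent hill climbing until
a full pass makes no change, and posterior-mean point estimates are
reported.

Mixtures of motifs have a well-known failure mode under Gibbs sampling:
one component absorbs everything early and the membership prior then makes
escape from the merged configuration exponentially unlikely, even though the
split configuration scores hundreds of nats higher. Two standard remedies
are combined here. First, several independent restarts are run per mode
count (default 3) and the best posterior wins. Second, during the first
`warm_sweeps` sweeps (default 10) the membership factor of the *sampling*
weights is flattened with a large pseudo-count, so an empty mode is not
penalized for being empty and can nucleate on datapoints the dominant mode
explains poorly; the tracked score, the stopping rule and the hill climb
always use the true prior, so the reported MAP estimate is unaffected by
the warm phase.

## Model selection

Models are fitted for a range of mode counts and compared by
`BIC = K ln(n) - 2 ln(P̂)`, with `K = sum_k (3 w_k + w_k+ + w_k- + 2)`
(three free parameters per PWM column, one per window position, two
offsets per mode) and `P̂` the collapsed posterior score at the MAP
estimate. `n` is the augmented datapoint count — the set the marginal
likelihood is computed over; ties break toward fewer modes.

## Prediction

For a new datapoint the per-mode score marginalizes the motif position
uniformly over *valid* placements (a proper positional prior; placements
whose windows leave the region are impossible, so dividing by raw `L` would
leak probability). Three scoring components are available: the full model,
sequence only, and reads only, with the corresponding factors dropped.
These yield mode posteriors, mode-by-mode confusion matrices (the mean
posterior over datapoints assigned to each mode), marginal likelihoods and
the two-model log-odds score `S(D)` used for classification; a rank-based
AUC utility is included for benchmarking `S(D)`.

## The synthetic generator

`generate_dataset()` emulates the generative model: each region draws a
mode (or pure background when the mode proportions sum to less than 1), a
uniform feasible motif position and an orientation; the site comes from the
mode's PWM, flanks from a 1st-order background chain parameterized by GC
content, and binary reads are Bernoulli draws from the footprint inside the
windows and the background rate outside. The deliberate order mismatch
(1st-order generator vs 2nd-order fitted background) exercises robustness
to background misspecification. What it does *not* emulate: exonuclease
chemistry, mappability, PCR duplicates, copy-number effects, or read-count
magnitudes beyond the optional geometric count wrapper — so passing
recovery tests demonstrate correctness of the inference machinery, not
that real libraries satisfy the model's assumptions.

Recovery experiments in the test suite use three planted modes with
distinct non-palindromic consensi at 0.9 per-column strength, footprints of
0.9 against a 0.05 background, offsets in the −12..+15 bp range, 600
regions of 240 bp (the default extraction window), and a BIC sweep over
1–6 modes; the null control uses 300 pure-background regions. These sizes
keep the full suite within a few minutes on one CPU while leaving the
per-mode sample sizes (~200) large enough that recovery is not borderline.
Self-reverse-complementary consensi are avoided in the fixtures: a
palindromic motif makes the orientation of each member genuinely ambiguous,
which smears the learned footprint across the two frames and makes
ground-truth matching ill-posed (a real phenomenon, but noise for a
correctness test).

## Numerical and design notes

* All mixture reductions use log-sum-exp; no likelihood is ever formed in
  linear space.
* The collapsed sufficient statistics are maintained incrementally in the
  C++ sampler; `audit_updates()` recounts them from scratch and the test
  suite requires exact agreement after thousands of random updates.
  `lgamma` values at integer-plus-prior arguments are precomputed once per
  chain.
* Background conditioning at a site uses the actual two preceding bases,
  falling back to lower orders at sequence starts and next to `N`s;
  repeat-masked (lowercase) genome bases become `N`, emit 1/4 under the
  background and are disallowed inside sites.
* Mirror symmetry: a configuration and its fully mirrored counterpart are
  scored identically under a strand-symmetric background, and every Gibbs
  conditional maps onto its mirror (verified exactly in the tests under a
  uniform background; the context-conditioned 2nd-order background breaks
  the identity only through its left-conditioning, by a vanishing amount on
  augmented training sets). Byte-identical mirrored *trajectories* are not
  guaranteed: categorical sampling by inverse CDF enumerates candidates in
  an order that mirroring permutes.
* Ties in hill climbing keep the current value; ties in BIC selection keep
  the smaller mode count; an exact orientation tie reports the forward
  strand.
* Degenerate inputs: all-zero read tracks binarize to all-zero with a
  warning and a threshold of 0; an empty mode is retained with
  prior-predictive parameters and a warning; regions with no valid
  placement at the initial width abort initialization with the offending
  region named.

## Known limitations

One mode per region; read windows have fixed, user-chosen width rather
than being learned; counts are reduced to presence/absence; the background
chain is global rather than region-specific. On real data, modes with weak
read signal may reflect experimental artefacts rather than distinct
complexes — inspection of the footprint probabilities written to
`footprints.tsv` is advisable before biological interpretation.
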