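---
title: "Measuring learning-induced change in semantic space with arrangement-based RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring learning-induced change in semantic space with arrangement-based RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swatrsa)
```

## The measurement problem

In a similarity-based word arrangement task (SWAT), a participant drags words
around a 2D canvas so that distance encodes perceived dissimilarity. When the
same participant also learns cue-target word pairs between two arrangement
sessions, the arrangement data become a behavioral window on how learning
reshapes semantic representations: do paired words converge, does the cue or
the target move more, and what happens to semantically related "lure" words
that were never studied?

The design this package supports uses 120 words forming 60 cue-target pairs
(30 semantically related with forward association strength below 0.5, 30
unrelated), counterbalanced into two matched sets, one assigned per
participant to retrieval practice (tested) and one to restudy. The critical
constraint is that the two members of a to-be-learned pair are **never shown
on the same arrangement trial**: the cue list and target list are each split
in half (C1, C2, T1, T2) and the four 60-word trials are the unions C1+C2,
C1+T2, C2+T1, T1+T2. Every word is arranged exactly twice, 5340 of the 7140
word pairs are measured directly (1740 of them twice), and the 1800 pairs
spanning C1-T1 or C2-T2 — including all 60 learned pairs — are structurally
unmeasured and must be imputed. `cooccurrence_counts()` verifies these counts
by brute-force enumeration for any assignment.

## From canvas pixels to a similarity matrix

`trial_distance_matrix()` converts a trial layout into Euclidean pixel
distances between word centers. Because each trial is an independent
arrangement at its own implicit scale, `combine_trials()` brings the four
partial matrices to a common scale before averaging: each trial is rescaled
by the least-squares factor matching the current estimate on its observed
cells, the estimate is recomputed as an evidence-weighted cell-wise mean, and
this alternation repeats until the largest cell change is below `1e-8` (cap
100 iterations; in practice a handful suffice because the only free
parameters are per-trial scalars). The evidence weight of a cell is the
squared on-screen distance: small separations are dominated by pixel-level
placement noise, while large separations reflect deliberate placement. Cells
observed only at zero distance carry no evidence and are treated as missing.

The combined dissimilarity matrix is scaled so that the completed upper
triangle has (approximately) unit Frobenius norm: observed cells are set to a
root-mean-square of `1/sqrt(n(n-1)/2)`, which *is* the unit Frobenius norm
when the matrix is fully observed. On this scale a 120-word matrix with
near-uniform entries has mean off-diagonal dissimilarity near
`1/sqrt(7140) = 0.0118`, so after the final `s = 1 - delta` conversion the
mean similarity sits near 0.989 — the magnitude this class of pipeline
reports in practice. The normalization makes the pipeline exactly invariant
to global rescaling of all coordinates (asserted to `1e-10` in the tests).

Structurally missing cells are filled by k-nearest-neighbor imputation
(`knn_impute()`, default `k = 40`): each word's row is a sample over n
features, row distances are nan-aware Euclidean (squared differences over
mutually observed features, rescaled by the observed fraction), and a missing
cell (i, j) receives the inverse-distance-weighted mean of column j over the
k nearest rows that observe it. Row-wise filling is not guaranteed symmetric,
so the filled matrix is symmetrized by transpose-averaging. The diagonal is
excluded as a feature. The implementation is validated cell-for-cell against
a brute-force oracle on all small instances and recovers structurally masked
cells of latent-geometry matrices at r >= 0.9.

## Recall scoring

Typed cued-recall responses are scored by `score_response()`: exact
case-insensitive match, else the dictionary word with minimal Levenshtein
distance (at most 2) must be the target. Two deliberate asymmetries: a
response equal to a *different* corpus word is never credited (no lure
credit), and ties among equally close candidates prefer corpus members, then
higher-frequency words. This deterministic rule replaces probabilistic
spell-checkers; the threshold is configurable. Day-1 responses for restudied
pairs only show the ability to re-type the visible target, so they are
excluded from Day-1 accuracy and flagged `restudied` in the three-level
Day-1-outcome split of tested pairs.

## Change statistics

All change statistics operate on the completed similarity matrices of the
two sessions:

* **Pairwise change** (`pair_change()`): `delta = s_post - s_pre` at the pair
  cell, classed by final-test recall, with random never-learned pairings as a
  baseline. No renormalization is applied at this stage — the value is the
  plain matrix difference.
* **Word-level change** (`word_change_table()`): each word's similarity
  vector to its top-20 normative nearest neighbors (cosine similarity of
  embedding vectors; self, learned partner and imputed cells excluded before
  truncation), correlated across sessions and Fisher z-transformed. Lower z
  means more representational change. Correlations are clipped at
  `|r| = 1 - 1e-12` before `atanh`.
* **Asymmetry** (`pair_asymmetry()`):
  `A = z(r(cue_pre, target_post)) - z(r(cue_post, target_pre))` over a shared
  column set. Negative A: the cue was drawn toward the target. The default
  column set is the union of the cue's and the target's top-20 normative
  neighbors minus the pair members and any imputed column; an `all-words`
  sensitivity mode uses every other word. The union was chosen because a
  cross-word correlation needs one shared dimension set and the union
  preserves both words' local neighborhoods; the statistic satisfies
  `A(pair) + A(role-swapped pair) = 0` exactly.
* **Lure table** (`lure_table()`): for each cue whose pair was recalled at
  the final test (excluding tested pairs missed at initial learning), all
  118 other words are binned by normative cosine: weak/non below 0.2,
  moderate `[0.2, 0.4)`, strong `[0.4, 0.6)`, very strong at 0.6 and above.
  Bin edges are half-open on the left, so 0.2 is moderate; "between 0.2 and
  0.4" is genuinely ambiguous and this is the documented resolution.
* **Normative alignment** (`normative_alignment_change()`): the change in
  Fisher-z correlation between a word's measured similarity vector and its
  normative cosine vector.

## Inference

`rm_anova()` fits fully within-subject ANOVAs through `aov()` error strata
and reports generalized eta-squared with the fully-within formula
`SS_effect / (SS_effect + SS_subjects + sum of error SS)` (all factors here
are measured within participants). `holm_adjust()` wraps
`p.adjust(method = "holm")`. `fit_lmm()` fits REML mixed models with a
subject random intercept and tests candidate random slopes sequentially by
boundary-aware likelihood-ratio tests: slopes enter as uncorrelated variance
components, so the null distribution is the 50:50 mixture of a point mass
and chi-square(1); fixed effects use Satterthwaite degrees of freedom (the
Kenward-Roger and Satterthwaite approximations agree closely at this
design's scale, and the method is recorded in the output).
`fit_mixed_logistic()` fits logit-link GLMMs with BOBYQA and a 200,000
iteration cap, refuses degenerate or separated outcomes explicitly, and
reports average marginal predicted probabilities over a focal-predictor
grid. `item_correlation()` provides the pair-level accuracy-similarity
correlation.

## The synthetic study generator

`generate_dataset()` produces complete synthetic studies so every stage has
ground truth. Design choices worth knowing:

* **Distortion happens in latent space**, before any measurement, so trial
  structure, placement noise, scale matching and imputation are exercised
  exactly as with real data. Words live on the unit sphere in an 8-dimensional
  latent space (8 dimensions give cosine spreads wide enough to populate all
  four lure bins); related targets are placed at cosine 0.75-0.92 from their
  cues, unrelated targets are re-drawn until they sit at least 0.2 below the
  related minimum.
* **Recall** follows
  `P = logistic(-0.95 + 1.5 related + 0.35 tested + 0 interaction)`, with a
  Day-2 logit penalty of -2 for tested pairs missed at Day 1 and a boost of
  +1.5 for tested pairs recalled at Day 1. These values were calibrated
  analytically to the recall marginals typical of this paradigm
  (unrelated-restudied near 0.28, related near 0.63, marginal testing effect
  near +0.08); the boost is what makes the marginal testing effect positive
  even though Day-1 failures are recalled worst.
* **Distortion**: for each correctly recalled pair the cue moves
  `alpha * gamma` of the separation toward the target and the target
  `alpha * (1 - gamma)` toward the cue; `gamma > 0.5` therefore produces
  negative asymmetry A. Moderate-bin lures of tested, recalled cues are
  pushed `rho` latent units away from the cue; very strong lures are pulled
  slightly in. Defaults (`alpha = 0.3`, `gamma = 0.5`, `rho = 0.1`) are
  moderate effect sizes; recovery tests use `alpha = 0.35`,
  `gamma_related = 0.8`, `rho = 0.15`.
* **Measurement**: each trial's 60 latent points are embedded in 2D by
  classical multidimensional scaling, refined by Sammon stress minimization
  when the latent space has more than two dimensions, scaled into the canvas
  and jittered with `sigma = 20` pixel Gaussian noise. With a 2D latent
  space and `sigma = 0` the pipeline recovers latent distances at
  r >= 0.999.
* Lure bins in synthetic mode are computed from the generated embedding
  cosines, which stand in for the single normative similarity source.

What the generator does **not** emulate: retrieval dynamics, word-specific
difficulty, arrangement strategies (clustering by scanning order, edge
effects), or session-level drift. Passing recovery tests therefore show that
the *pipeline* recovers effects that exist in the measured geometry; they do
not certify cognitive realism.

### A measurement artifact worth knowing about

With symmetric attraction (`gamma = 0.5`) the latent-space asymmetry is
exactly zero, and the full null pipeline (`alpha = rho = 0`) yields A within
Monte-Carlo error of zero. But symmetric attraction *plus* measurement
produces a small positive measured A for related pairs: compressing an
8-dimensional configuration into four list-structured 2D trials (cue-only
trials vs mixed trials) interacts with the pair-convergence distortion in a
label-dependent way. The asymmetry-share mechanism still works on top of
this offset — raising `gamma` from 0.2 to 0.8 swings mean A from positive to
negative at matched settings — and under the full study conditions
(asymmetric attraction on related pairs plus lure repulsion) mean A for
related pairs is robustly negative while unrelated pairs sit near zero. Real
studies comparing A across conditions should likewise lean on condition
contrasts rather than the raw sign of A alone. Note also that the stimulus
set itself is a random factor: mean A varies substantially from corpus to
corpus (simulated spread roughly 0.1 at these settings), so small-n runs on
a single unlucky corpus can flip its sign even when the generating
asymmetry is fixed.

## Problem sizes and numerical choices

Recovery simulations in the acceptance layer use 200 simulated participants
per condition (attraction-only, full study conditions, and null), 200
mixed-logistic refits for interaction sign recovery, and 10,000 null
datasets for t-test size; structural and oracle checks run on instances
small enough to enumerate. Convergence tolerances: `1e-8` (scale matching),
`|r|` clipping `1 - 1e-12` (Fisher z), symmetry tolerance `1e-8` on matrix
I/O. Degenerate inputs (constant vectors, zero-variance deltas, separated
outcomes, single-group models, disconnected trials) raise errors that name
the cause rather than returning silent fallbacks.

## Known limitations

* The evidence-weight function (squared distance) and the output scale of
  the multi-trial combination are documented conventions, not uniquely
  determined by the multi-arrangement literature; other monotone weightings
  change cell values slightly (never the structural zeros/missingness).
* The spell scorer is deterministic; probabilistic correctors can disagree
  on multi-error typos.
* Asymmetry column sets require a choice (union of neighborhoods vs all
  words); both are implemented, and conclusions should be checked under
  both.
* Imputed pair cells inherit neighborhood structure, so pair-cell effects
  are attenuated relative to their latent magnitude; between-condition
  contrasts remain unbiased under the null (checked by simulation).
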