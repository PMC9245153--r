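---
title: "Measuring form-meaning systematicity and its effect on age of acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring form-meaning systematicity and its effect on age of acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measures

`fsclex` quantifies, per word, how consistently a word's *form* predicts
its *meaning*, and provides the statistical machinery to ask whether that
consistency explains variance in age of acquisition (AoA) beyond standard
lexical predictors.

Form-to-Semantics Consistency (FSC) is a weighted mean cosine similarity
between the target word's semantic vector and the vectors of its
form-based nearest neighbours. Two retrieval/weighting schemes are
implemented:

* **Target-embedding (`te`)**: the neighbours are the `N` lexicon words
  that contain the target form as a contiguous substring (so all strictly
  longer than the target); cosines are weighted by neighbour corpus
  frequency and normalised by cumulative frequency. This variant is
  sensitive to morphological-family structure (*gold* → *golden*,
  *goldmine*). Words embedded in nothing receive a seeded random sample of
  20 reference-lexicon words as stand-in neighbours, and the score is
  flagged `fallback_used`.
* **Levenshtein-distance (`ld`)**: let `d*` be the unit-cost edit distance
  of the target's 5th-nearest lexicon word; the neighbour set is *all*
  words at distance `<= d*` (tie-inclusive, deterministic — no sampling
  among tied words), and cosines are weighted by `1/d_i`. This variant
  side-steps morphology and favours length-matched neighbours.

Computed over phonological transcriptions the measures are called PSC;
over orthography, OSC. The implementation is encoding-agnostic: the
`encoding` switch selects which form column neighbours are retrieved
from.

Controls: PND is Coltheart's *N* — the number of lexicon words obtainable
by substituting exactly one phoneme. SND is the mean cosine *distance*
(1 − similarity) of the word's 20 nearest semantic neighbours; larger SND
means a sparser semantic neighbourhood.

## Assumptions

* Semantic similarity is adequately captured by cosine similarity between
  distributional vectors; vectors are inputs, never trained here.
* One transcription character equals one phoneme (the CELEX/DISC
  convention); stress/syllable markers are stripped before anything is
  counted, with the marker set configurable because published resources
  disagree.
* Word identity is the exact lowercase orthographic form; joins across
  resources never lemmatise. Senses sharing a form are collapsed to the
  *earliest* AoA at assembly time.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `k` | 5 | the neighbour-count parameter of `ld` retrieval; the value used throughout the lexical-decision literature this measure comes from |
| SND `m` | 20 | semantic neighbourhood size (words); the convention of the AoA literature |
| `normalization` | `"literal"` | Eq. for `ld` divides by `N`; the printed formula is ambiguous between `N` and `Σ 1/d_i`, so both are implemented, the literal reading is the default, and every score records which was used. Note the literal mode is still bounded in [−1, 1] because each weight `1/d_i ≤ 1` |
| PND mode | `"substitution"` | the literal definition of Coltheart's N ("changing a single phoneme"); `"das"` (add/delete/substitute) is selectable because some published PhonND norms use it. `substitution ≤ das` always |
| fallback size | 20 | the `te` random stand-in sample; drawn uniformly without replacement, frequencies still weight the mean (the minimal reading of the protocol) |
| Box-Cox grid | `seq(-2, 2, 0.01)` | profile-ML grid; the 0.01 step bounds the lambda discretisation error well below any downstream effect |

## Numerical and design choices

* **Homophones**: a lexicon word at edit distance 0 from the target under
  a different identity would make the `1/d` weight undefined; such words
  are excluded during `ld` retrieval, and `psc_ld()` refuses distance-0
  members outright.
* **Self-exclusion**: the target never appears in its own neighbour set in
  any scheme (its cosine of 1 would inflate every score). Duplicate
  *vectors* under different words are legitimate neighbours.
* **Tie-breaking**: semantic nearest neighbours break distance ties by
  vocabulary order, deterministically; `ld` retrieval has no ties to break
  because it is tie-inclusive by construction.
* **Box-Cox shift**: FSC values can be negative, so each variable is
  shifted by `max(0, 1e-6 − min(x))` before the power transform; the shift
  is recorded in the returned spec so the identical transform can be
  re-applied to new data. The response (AoA) is never transformed — only
  independent variables are.
* **Interactions** are products of the z-scored main effects and are not
  re-standardised, keeping the simple-slopes algebra exact:
  `slope(q) = beta_fsc + beta_int * snd_q`.
* **AIC**: only differences are meaningful. `fit_linear()` offers the full
  Gaussian log-likelihood convention (`stats::AIC`) and an
  `n log(RSS/n) + 2p` convention; ΔAIC is invariant to the choice (tested)
  and positive ΔAIC always means the augmented model fits better.
* **Permutation baseline**: one uniform permutation of the word→vector
  assignment per iteration (fixed points allowed — the protocol says
  "randomly permuted", nothing stricter). Neighbour structures in both
  spaces are untouched; only the form-meaning pairing changes. Iteration
  `i` is seeded `seed + i`, so individual iterations are reproducible.
  The permuted FSC column is z-scored before entering the model, matching
  the treatment of the true column.
* **Random forest**: no RF package is assumed; a compact Rcpp
  implementation provides bootstrap bagging, `mtry = max(1, floor(p/3))`
  (a third of the predictors), minimum node size 5, OOB predictions, and
  *permutation* importance (mean OOB MSE increase when a predictor is
  shuffled within each tree's OOB rows) — the less biased default compared
  with impurity importance, whose exact values are implementation-specific
  anyway.
* **PCA disentanglement** eigendecomposes the 3×3 correlation matrix of
  PND, SND and PSC_ld; the sign convention makes each component's
  largest-magnitude loading positive; explained variances sum to the
  number of standardised inputs by trace conservation.
* **Multiple testing**: none applied; comparisons are reported
  individually, as in the protocol this pipeline mirrors.

## The synthetic world

The generator emulates the *joint structure* the analysis assumes, not
English:

* forms are uniform-length phoneme strings over a configurable inventory;
  sampling is prefix-stable in the seed, so enlarging `vocab_size` extends
  rather than reshuffles a lexicon;
* token frequencies follow a Zipf law, `f_r = max(1, round(V^a r^{-a}))`,
  giving positive integer counts whose log-log rank slope recovers `-a`;
* each word's semantic vector is
  `normalize(s·F(form) + (1−s)·g)`, with `F` a fixed, seed-derived Gaussian
  projection of boundary-marked character-bigram counts and `g` an
  independent unit Gaussian direction. The dial `s` ∈ [0, 1] is the
  *fraction of semantic signal derived from form*: at 0, form and meaning
  are unrelated; at 1, meaning is a deterministic function of form. The
  additive-mixture construction is this package's own modelling choice —
  the literature defines no generative model of systematicity — chosen
  because it makes form-similar words semantically similar, which is
  exactly the structure FSC is designed to detect, and because mean PSC is
  then monotone in `s` (property-tested);
* covariates are drawn independently of form (the simplest null
  structure); orthography equals the phoneme string, so the PSC/OSC
  distinction is exercised purely through the encoding switch;
* AoA is generated *after* the measures, as
  `intercept + Σ beta_k x_k + Normal(0, sd)` on a years-like scale
  (default intercept 9, residual sd 1, negative frequency and concreteness
  effects, positive length effect). Generating AoA from the *measured*
  PSC column lets tests inject a true systematicity effect of known size —
  a mild, deliberate circularity that makes exact parameter recovery
  checkable. In the permutation-calibration tests the zero-systematicity
  world correspondingly omits the PSC term (there is no true effect to
  find), while the high-systematicity world injects `beta = -0.5`.

What a green test does **not** establish: that real lexicons satisfy the
generator's independence assumptions (real covariates correlate with form
length and frequency; real phonotactics constrain neighbourhoods; real
semantic spaces are anisotropic). The synthetic world validates the
*machinery* — retrieval, weighting, transformation, model comparison,
baselines — not the empirical conclusion.

## Limitations

* Neighbour retrieval is exhaustive `O(V)` per target (correctness first);
  an index would be needed for lexicons far beyond 10^5 words.
* No phonological-feature-weighted distances, no syllable alignment, no
  GAMs or mixed models; non-linearity is only probed through the
  random-forest route.
* Multi-word and hyphenated resource entries pass through unmodified;
  out-of-lexicon pronunciation generation is out of scope.
* The reported `te`/`ld` correlation on synthetic data is logged by the
  test suite rather than asserted: the two measures tap different
  structure and their agreement depends on the systematicity dial.
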