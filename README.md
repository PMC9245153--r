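# fsclex

Word-level form-meaning systematicity and its effect on age of acquisition.

## The scientific problem

Natural languages are largely arbitrary — knowing how a word sounds rarely
tells you what it means — but not completely so. Sub-morphemic regularities
(phonaesthemes such as English *gl-* in *glow*, *glitter*; sound symbolism;
loose family resemblances between similar-sounding words) mean that words
with similar forms tend, statistically, to have similar meanings. If
learners exploit such regularities by analogy — guessing the meaning of a
new word from the meanings of similar-sounding known words — then words
whose form reliably cues their meaning should be learned earlier.

`fsclex` implements the word-level measures and the complete statistical
pipeline needed to test that hypothesis:

- **FSC (Form-to-Semantics Consistency)** — the weighted mean cosine
  similarity between a target word's semantic vector *t* and the vectors
  *n_i* of its form-based nearest neighbours, in two variants:
  - **target-embedding (`te`)**: neighbours are the *N* words that contain
    the target form as a substring, weighted by corpus frequency
    *f_i*:  `FSC_te(t) = Σ cos(t, n_i) f_i / Σ f_i`;
  - **Levenshtein-distance (`ld`)**: neighbours are all words within the
    edit distance of the 5th-nearest neighbour (tie-inclusive, no
    sampling), weighted by inverse distance:
    `FSC_ld(t) = Σ cos(t, n_i) (1/d_i) / N`.

  Computed over phonological transcriptions this is **PSC**, over spelling
  **OSC**. When no word embeds the target, 20 random reference-lexicon
  words stand in (flagged, seeded).
- **Neighbourhood controls** — Coltheart's *N* phonological neighbourhood
  density (PND) and semantic neighbourhood distance (SND, the mean cosine
  distance of the 20 nearest semantic neighbours).
- **Inference** — Box-Cox + z-standardisation of predictors, nested OLS
  models compared by ΔAIC (positive = the added term helps), random-forest
  regression with OOB permutation importance (collinearity check), PCA
  disentanglement of PND/SND/PSC, simple slopes for the SND × PSC
  interaction, and correlation reports with Fisher-z CIs.
- **Robustness baselines** — scrambling the form-meaning mapping
  (permuting the word→vector assignment while leaving both neighbourhood
  structures intact) and re-computing FSC under reference-lexicon
  subsampling.
- **A seeded synthetic-lexicon generator** whose *systematicity dial*
  controls the fraction of each word's semantic vector derived from its
  form, so every stage is testable without external resources.

It reads the standard formats the real resources come in: delimited norms
tables, one-phoneme-per-character phonological lexicons (CELEX/DISC style,
with configurable stress-marker stripping), and word vectors in the
embedding text format.

## Worked example

```r
library(fsclex)

cfg   <- synthetic_config(vocab_size = 800, systematicity = 0.7, seed = 42)
lex   <- generate_lexicon(cfg)
study <- synthetic_study_table(lex)
study <- compute_lexical_measures(study, lex$entries, lex$space, seed = 42)
head(study[, c("word", "frequency", "pnd", "snd", "psc_te", "psc_ld")], 4)
#>    word frequency pnd   snd psc_te psc_ld
#> 1    kp     2.903  16 0.566  0.334  0.268
#> 2    zd     2.602  13 0.601  0.330  0.234
#> 3   awm     2.427   1 0.594  0.046  0.076
#> 4 kloew     2.301   0 0.651 -0.024  0.057

zv <- c("frequency", "concreteness", "valence", "length_phonemes",
        "pnd", "snd", "psc_te", "psc_ld")
study     <- boxcox_z(study, zv)$table       # transform + z-score predictors
study$aoa <- generate_aoa(lex, study)$aoa    # inject beta_psc_ld = -0.5

suite <- run_nested_suite(study, iconicity = NULL)
suite$summary
#>     comparison       term    beta     se     t        p delta_aic
#> 1    pnd_x_snd    pnd:snd  0.1058 0.0408  2.59 9.64e-03      4.78
#> 2       psc_te     psc_te -0.1164 0.0475 -2.45 1.44e-02      4.06
#> 3       psc_ld     psc_ld -0.6333 0.0659 -9.62 8.88e-21     86.45
#> 4 snd_x_psc_ld snd:psc_ld  0.0809 0.0341  2.37 1.81e-02      3.66
```

Read: after controlling for frequency, concreteness, valence, length,
morphological complexity, PND and SND, adding `psc_ld` improves model fit
by ΔAIC = 86.5 with a negative coefficient (β = −0.63) — more systematic
words get earlier AoA values, recovering the injected effect (−0.5 plus
the share of covariate structure PSC absorbs). The forest agrees that the
signal is not a collinearity artefact:

```r
rf_regression(study, "aoa", c(zv, "morph_complex"), n_trees = 300, seed = 42)
#> <rf_fit> 300 trees, mtry = 3, OOB r2 = 0.5783
#>   importance: frequency=1.0543, psc_ld=0.6658, concreteness=0.5209, ...
```

Robustness baselines:

```r
permuted_fsc_baseline(study, lex$entries, lex$space,
                      baseline_predictors = c("frequency", "concreteness",
                        "valence", "length_phonemes", "morph_complex",
                        "pnd", "snd"),
                      n_iterations = 200, seed = 1)   # true mapping vs null
subsampled_fsc(study, lex$entries, lex$space, rate = 0.75,
               n_iterations = 50, seed = 1)           # lexicon stability
```

## Command line

```sh
Rscript -e 'fsclex::fsclex_cli()' generate --vocab-size 1000 --systematicity 0.6 --seed 1 --out data/
Rscript -e 'fsclex::fsclex_cli()' assemble --norms data/norms.csv \
    --phonemes data/lexicon.tsv --vectors data/vectors.txt --out study.csv
Rscript -e 'fsclex::fsclex_cli()' fsc --norms data/norms.csv \
    --phonemes data/lexicon.tsv --vectors data/vectors.txt \
    --method ld --seed 1 --out fsc.csv
```

(The same entry point is installed as `exec/fsclex` inside the package.)

## Further reading

`vignettes/form-meaning-systematicity.Rmd` documents the measures, the
modelling choices, the synthetic world's assumptions, and known
limitations.
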