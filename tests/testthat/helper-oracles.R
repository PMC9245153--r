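# Independent oracles and fixture builders. These deliberately re-derive
# quantities with naive textbook algorithms so the fast paths in the
# package are checked against something they share no code with.

# Textbook quadratic DP table for unit-cost edit distance.
lev_oracle <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- length(sa); m <- length(sb)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j] + (sa[i] != sb[j]),
                             d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L)
    }
  }
  d[n + 1, m + 1]
}

# Brute-force tie-inclusive kth-distance retrieval.
kth_oracle <- function(target, lexicon, k) {
  d <- vapply(lexicon, lev_oracle, integer(1), a = target)
  keep <- d >= 1L
  d <- d[keep]; lex <- lexicon[keep]
  ord <- order(d)
  dstar <- d[ord][k]
  sort(lex[d <= dstar])
}

# Naive substring-containment scan.
embedding_oracle <- function(target, lexicon) {
  sort(lexicon[vapply(lexicon, function(w)
    w != target && grepl(target, w, fixed = TRUE), logical(1))])
}

random_forms <- function(n, alphabet = letters[1:8], lens = 2:6) {
  forms <- character(0)
  while (length(forms) < n) {
    cand <- replicate(2 * n, paste(sample(alphabet, sample(lens, 1),
                                          replace = TRUE), collapse = ""))
    forms <- unique(c(forms, cand))
  }
  forms[seq_len(n)]
}

random_space <- function(words, dim = 8) {
  semantic_space(words, matrix(rnorm(length(words) * dim),
                               length(words), dim))
}

# Fully measured, z-scored synthetic study world used by several suites.
# Small vocabularies use a denser form space (6 symbols, lengths 2-4) so
# neighbourhood measures keep variance; larger ones use the config defaults.
build_synthetic_world <- function(vocab_size, systematicity, seed,
                                  vector_dim = 50, k = 5) {
  cfg <- if (vocab_size < 600) {
    synthetic_config(vocab_size = vocab_size,
                     systematicity = systematicity,
                     phoneme_inventory = c("a", "b", "c", "d", "e", "f"),
                     length_range = c(2, 4),
                     vector_dim = vector_dim, seed = seed)
  } else {
    synthetic_config(vocab_size = vocab_size,
                     systematicity = systematicity,
                     vector_dim = vector_dim, seed = seed)
  }
  lex <- generate_lexicon(cfg)
  study <- synthetic_study_table(lex)
  study <- compute_lexical_measures(study, lex$entries, lex$space, k = k,
                                    seed = seed)
  zvars <- c("frequency", "concreteness", "valence", "length_phonemes",
             "pnd", "snd", "psc_te", "psc_ld", "iconicity")
  zvars <- zvars[vapply(zvars, function(v) sd(study[[v]]) > 0, logical(1))]
  study_z <- boxcox_z(study, zvars)$table
  list(config = cfg, lexicon = lex, study = study, study_z = study_z)
}

baseline_vars <- c("frequency", "concreteness", "valence",
                   "length_phonemes", "morph_complex", "pnd", "snd")
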