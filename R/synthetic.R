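#' Configuration for the synthetic-lexicon generator
#'
#' Collects and validates every dial of the generator. Defaults describe a
#' small but realistic lexical world: a 21-symbol phoneme inventory, word
#' lengths of 2-7 phonemes, Zipfian token frequencies with exponent 1,
#' 50-dimensional unit-norm semantic vectors, rating-scale covariates, and
#' an AoA linear model on a years-like scale (intercept 9, residual sd 1).
#'
#' @param vocab_size number of words (>= 2).
#' @param phoneme_inventory unique single-character phoneme symbols.
#' @param length_range inclusive `(min, max)` word length in phonemes,
#'   `min >= 1`.
#' @param zipf_exponent positive Zipf rank-frequency exponent.
#' @param vector_dim semantic vector dimensionality.
#' @param systematicity fraction in `[0, 1]` of each word's semantic signal
#'   that derives from its form.
#' @param covariate_params list with `concreteness`, `valence`, `iconicity`
#'   (each `c(mean, sd)`) and `morph_prob` (Bernoulli probability of being
#'   polymorphemic).
#' @param aoa_coefficients named coefficients of the AoA linear model,
#'   including `intercept`; the other names must match predictor columns
#'   handed to [generate_aoa()].
#' @param aoa_noise_sd non-negative residual standard deviation.
#' @param seed integer RNG seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(vocab_size = 1000L,
                             phoneme_inventory = c("p", "b", "t", "d", "k",
                                                   "g", "m", "n", "s", "z",
                                                   "f", "v", "r", "l", "w",
                                                   "h", "a", "e", "i", "o",
                                                   "u"),
                             length_range = c(2L, 7L),
                             zipf_exponent = 1,
                             vector_dim = 50L,
                             systematicity = 0.5,
                             covariate_params = list(
                               concreteness = c(mean = 3, sd = 1),
                               valence = c(mean = 5, sd = 1.5),
                               iconicity = c(mean = 0, sd = 1),
                               morph_prob = 0.3),
                             aoa_coefficients = c(intercept = 9,
                                                  frequency = -0.8,
                                                  concreteness = -0.6,
                                                  length_phonemes = 0.4,
                                                  valence = -0.2,
                                                  morph_complex = 0.5,
                                                  psc_ld = -0.5),
                             aoa_noise_sd = 1,
                             seed = 1L) {
  stopifnot(vocab_size >= 2, length(length_range) == 2L,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            zipf_exponent > 0, vector_dim >= 1,
            systematicity >= 0, systematicity <= 1,
            aoa_noise_sd >= 0, "intercept" %in% names(aoa_coefficients))
  if (anyDuplicated(phoneme_inventory) ||
      any(nchar(phoneme_inventory) != 1L)) {
    stop("phoneme_inventory must be unique single-character symbols")
  }
  structure(list(vocab_size = as.integer(vocab_size),
                 phoneme_inventory = phoneme_inventory,
                 length_range = as.integer(length_range),
                 zipf_exponent = zipf_exponent,
                 vector_dim = as.integer(vector_dim),
                 systematicity = systematicity,
                 covariate_params = covariate_params,
                 aoa_coefficients = aoa_coefficients,
                 aoa_noise_sd = aoa_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Character-bigram count features with boundary markers: the fixed form
# feature map F. Rows index forms, columns index bigrams over the
# boundary-extended alphabet.
form_bigram_features <- function(forms, inventory) {
  alphabet <- c("#", inventory)
  a <- length(alphabet)
  out <- matrix(0, length(forms), a * a)
  for (i in seq_along(forms)) {
    s <- c("#", strsplit(forms[i], "", fixed = TRUE)[[1L]], "#")
    ix <- match(s, alphabet)
    code <- (ix[-length(ix)] - 1L) * a + ix[-1L]
    tab <- tabulate(code, a * a)
    out[i, ] <- tab
  }
  out
}

# Fixed Gaussian projection of bigram features into vector_dim dimensions,
# seeded from the config seed only (independent of word sampling), so the
# same form always projects to the same direction under the same config.
form_projection <- function(config) {
  a <- length(config$phoneme_inventory) + 1L
  with_seed(config$seed + 990001L,
            matrix(stats::rnorm(a * a * config$vector_dim),
                   a * a, config$vector_dim))
}

# Unit-normalised form-derived semantic directions for a set of forms.
form_semantic_signal <- function(forms, config) {
  feats <- form_bigram_features(forms, config$phoneme_inventory)
  raw <- feats %*% form_projection(config)
  raw / sqrt(rowSums(raw^2))
}

#' Generate a synthetic lexicon
#'
#' Draws `vocab_size` unique phoneme-string forms (lengths uniform over
#' `length_range`), assigns Zipfian integer frequencies
#' (`f_r = max(1, round(V^a r^-a))` over ranks r), and builds a unit-norm
#' semantic vector for each word as
#' `normalize(s * F(form) + (1 - s) * g)`, where `s` is the systematicity
#' dial, `F` is a fixed seeded Gaussian projection of the form's
#' boundary-marked character-bigram counts, and `g` an independent
#' unit-norm Gaussian draw. At `s = 1` the vector is a deterministic
#' function of the form; at `s = 0` form and meaning are unrelated.
#' Covariates (concreteness, valence, iconicity, morphological complexity)
#' are drawn independently of form. Everything is deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A `synthetic_lexicon`: `entries` (word, phonemes, frequency),
#'   `space` (a [semantic_space()]), `covariates`, `aoa` (`NULL` until
#'   [generate_aoa()]), and the config.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lens <- config$length_range[1]:config$length_range[2]
  capacity <- sum(length(config$phoneme_inventory)^lens)
  if (config$vocab_size > capacity) {
    stop("vocab_size (", config$vocab_size, ") exceeds the ", capacity,
         " distinct forms available at lengths ",
         config$length_range[1], "-", config$length_range[2],
         " over a ", length(config$phoneme_inventory), "-symbol inventory")
  }
  V <- config$vocab_size
  with_seed(config$seed, {
    # one candidate at a time (length, then symbols) so the sampled form
    # sequence is a prefix-stable function of the seed: the same seed with
    # a larger vocab_size extends, rather than reshuffles, the lexicon
    forms <- character(V)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    got <- 0L
    while (got < V) {
      l <- if (length(lens) == 1L) lens else sample(lens, 1L)
      cand <- paste(sample(config$phoneme_inventory, l, replace = TRUE),
                    collapse = "")
      if (!exists(cand, envir = seen, inherits = FALSE)) {
        assign(cand, TRUE, envir = seen)
        got <- got + 1L
        forms[got] <- cand
      }
    }

    ranks <- seq_len(V)
    freq <- pmax(1, round(V^config$zipf_exponent *
                            ranks^(-config$zipf_exponent)))

    s <- config$systematicity
    g <- matrix(stats::rnorm(V * config$vector_dim), V, config$vector_dim)
    g <- g / sqrt(rowSums(g^2))
    vf <- form_semantic_signal(forms, config)
    vec <- s * vf + (1 - s) * g
    nrm <- sqrt(rowSums(vec^2))
    degenerate <- nrm < 1e-10
    if (any(degenerate)) {  # astronomically unlikely exact cancellation
      vec[degenerate, ] <- g[degenerate, ]
      nrm[degenerate] <- 1
    }
    vec <- vec / sqrt(rowSums(vec^2))

    cp <- config$covariate_params
    covariates <- data.frame(
      word = forms,
      concreteness = stats::rnorm(V, cp$concreteness["mean"],
                                  cp$concreteness["sd"]),
      valence = stats::rnorm(V, cp$valence["mean"], cp$valence["sd"]),
      iconicity = stats::rnorm(V, cp$iconicity["mean"], cp$iconicity["sd"]),
      morph_complex = stats::rbinom(V, 1L, cp$morph_prob),
      length_phonemes = nchar(forms),
      stringsAsFactors = FALSE)

    structure(list(
      entries = data.frame(word = forms, phonemes = forms,
                           frequency = as.integer(freq),
                           stringsAsFactors = FALSE),
      space = semantic_space(forms, vec),
      covariates = covariates,
      aoa = NULL,
      config = config),
      class = "synthetic_lexicon")
  })
}

#' @export
print.synthetic_lexicon <- function(x, ...) {
  cat("<synthetic_lexicon> ", nrow(x$entries), " words, dim ",
      x$config$vector_dim, ", systematicity ", x$config$systematicity,
      if (!is.null(x$aoa)) ", AoA generated" else "", "\n", sep = "")
  invisible(x)
}

#' Generate AoA for a synthetic lexicon
#'
#' Second phase of the generator: `aoa_i = intercept + sum_k beta_k x_ik +
#' eps_i`, `eps_i ~ N(0, aoa_noise_sd)`, seeded from the config. Running
#' this after computing PSC/PND/SND on the lexicon lets a true
#' systematicity effect be injected into AoA for parameter-recovery tests.
#' Values may optionally be shifted to a positive range; an affine shift
#' leaves the correlation structure untouched.
#'
#' @param lexicon a `synthetic_lexicon`.
#' @param predictors per-word data.frame containing one column per
#'   coefficient name in `config$aoa_coefficients` (except `intercept`),
#'   rows aligned with `lexicon$entries`.
#' @param config a [synthetic_config()]; default the lexicon's own.
#' @param min_aoa if non-`NULL` and the minimum generated value falls below
#'   it, the whole vector is shifted up to this floor.
#' @return The lexicon with `aoa` filled.
#' @export
generate_aoa <- function(lexicon, predictors, config = lexicon$config,
                         min_aoa = NULL) {
  stopifnot(inherits(lexicon, "synthetic_lexicon"))
  beta <- config$aoa_coefficients
  terms <- setdiff(names(beta), "intercept")
  missing_cols <- setdiff(terms, names(predictors))
  if (length(missing_cols)) {
    stop("aoa_coefficients name predictor column(s) absent from the ",
         "predictor table: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(predictors) != nrow(lexicon$entries)) {
    stop("predictor table rows (", nrow(predictors),
         ") do not align with the lexicon (", nrow(lexicon$entries), ")")
  }
  X <- as.matrix(predictors[, terms, drop = FALSE])
  storage.mode(X) <- "double"
  mu <- beta[["intercept"]] + as.vector(X %*% beta[terms])
  eps <- with_seed(config$seed + 777001L,
                   stats::rnorm(nrow(X), 0, config$aoa_noise_sd))
  aoa <- mu + eps
  if (!is.null(min_aoa) && min(aoa) < min_aoa) {
    aoa <- aoa + (min_aoa - min(aoa))
  }
  lexicon$aoa <- aoa
  lexicon
}

#' Study table of a synthetic lexicon
#'
#' Flattens a `synthetic_lexicon` into the per-word study table consumed by
#' the measurement and inference layers: entries, covariates,
#' log10-frequency (`frequency` column, since raw Zipf counts span orders
#' of magnitude) and, when generated, AoA.
#'
#' @param lexicon a `synthetic_lexicon`.
#' @param log_frequency replace raw counts by `log10(count)` (default TRUE).
#' @return data.frame with one row per word.
#' @export
synthetic_study_table <- function(lexicon, log_frequency = TRUE) {
  stopifnot(inherits(lexicon, "synthetic_lexicon"))
  tab <- merge(lexicon$entries, lexicon$covariates, by = "word", sort = FALSE)
  tab <- tab[match(lexicon$entries$word, tab$word), , drop = FALSE]
  if (log_frequency) tab$frequency <- log10(tab$frequency)
  if (!is.null(lexicon$aoa)) tab$aoa <- lexicon$aoa
  rownames(tab) <- NULL
  tab
}

#' Write a synthetic lexicon through the standard writers
#'
#' Emits the three on-disk artefacts consumed by the readers: a norms CSV
#' (covariates plus AoA when present), a TAB phonological lexicon, and the
#' embedding text file.
#'
#' @param lexicon a `synthetic_lexicon`.
#' @param dir output directory (created if missing).
#' @return Named character vector of the three paths.
#' @export
write_synthetic_lexicon <- function(lexicon, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  norms <- merge(lexicon$covariates,
                 lexicon$entries[, c("word", "frequency")], by = "word")
  if (!is.null(lexicon$aoa)) {
    norms$aoa <- lexicon$aoa[match(norms$word, lexicon$entries$word)]
  }
  paths <- c(norms = file.path(dir, "norms.csv"),
             phonemes = file.path(dir, "lexicon.tsv"),
             vectors = file.path(dir, "vectors.txt"))
  write_norms_csv(norms, paths["norms"])
  write_phonological_lexicon(
    stats::setNames(lexicon$entries$phonemes, lexicon$entries$word),
    paths["phonemes"])
  write_semantic_vectors(lexicon$space, paths["vectors"])
  paths
}
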