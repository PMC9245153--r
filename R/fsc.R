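new_fsc_score <- function(word, value, method, encoding, n_neighbors,
                          fallback_used = FALSE, normalization = NA_character_) {
  structure(list(word = word, value = value, method = method,
                 encoding = encoding, n_neighbors = as.integer(n_neighbors),
                 fallback_used = isTRUE(fallback_used),
                 normalization = normalization),
            class = "fsc_score")
}

#' @export
print.fsc_score <- function(x, ...) {
  cat(sprintf("<fsc_score> %s %s/%s = %.4f (N = %d%s)\n", x$word, x$method,
              x$encoding, x$value, x$n_neighbors,
              if (x$fallback_used) ", fallback" else ""))
  invisible(x)
}

# cos(target, member) for member words resolved in `space`, with an
# informative error when a vector is missing.
member_cosines <- function(target, members, space) {
  ti <- match(target, space$vocabulary)
  if (is.na(ti)) stop("target has no semantic vector: ", target)
  ni <- match(members, space$vocabulary)
  if (anyNA(ni)) {
    stop("neighbour(s) missing a semantic vector: ",
         paste(members[is.na(ni)], collapse = ", "))
  }
  un <- space_unit_matrix(space)
  clamp1(as.vector(un[ni, , drop = FALSE] %*% un[ti, ]))
}

#' Target-embedding form-to-semantics consistency
#'
#' The frequency-weighted mean cosine similarity between a target word's
#' semantic vector and the vectors of the `N` words that embed its form:
#' `sum_i cos(t, n_i) f_i / sum_i f_i`, so more frequent neighbours
#' contribute more. When the embedding neighbour set is empty, 20 words are
#' drawn uniformly without replacement from the reference lexicon
#' (excluding the target) as stand-in neighbours, flagged `fallback_used`,
#' and the same weighted mean is applied with their frequencies.
#'
#' @param target target word (must have a semantic vector).
#' @param neighbors a `neighbor_set` from [embedding_neighbors()], members
#'   resolvable as words in `space`.
#' @param space a [semantic_space()].
#' @param frequencies named numeric vector word -> positive corpus count.
#' @param reference_words candidate pool for the random fallback.
#' @param n_fallback fallback sample size, default 20.
#' @param seed optional seed making the fallback draw reproducible.
#' @param encoding recorded in the score, default `"phonological"`.
#' @return An `fsc_score`.
#' @export
psc_te <- function(target, neighbors, space, frequencies,
                   reference_words = NULL, n_fallback = 20L, seed = NULL,
                   encoding = "phonological") {
  members <- neighbors$members
  fallback <- length(members) == 0L
  if (fallback) {
    if (is.null(reference_words)) {
      stop("empty embedding neighbour set for '", target,
           "' and no reference lexicon supplied for the random fallback")
    }
    pool <- setdiff(reference_words, target)
    members <- with_seed(seed, sample(pool, min(n_fallback, length(pool))))
  }
  f <- frequencies[members]
  if (anyNA(f)) {
    stop("neighbour(s) missing a frequency: ",
         paste(members[is.na(f)], collapse = ", "))
  }
  cs <- member_cosines(target, members, space)
  new_fsc_score(target, sum(cs * f) / sum(f), "te", encoding,
                length(members), fallback_used = fallback)
}

#' Levenshtein-distance form-to-semantics consistency
#'
#' Inverse-distance-weighted semantic similarity of the tie-inclusive
#' k-th-distance neighbours: `sum_i cos(t, n_i) (1/d_i) / N` in the
#' `"literal"` normalisation, or divided by `sum_i 1/d_i` in the
#' `"weight_sum"` normalisation. Distances of zero (homophones) are an
#' error; they must be filtered during retrieval.
#'
#' @param target target word.
#' @param neighbors a `neighbor_set` from [kth_distance_neighbors()] with
#'   member distances, members resolvable as words in `space`.
#' @param space a [semantic_space()].
#' @param normalization `"literal"` (default) or `"weight_sum"`.
#' @param encoding recorded in the score, default `"phonological"`.
#' @return An `fsc_score`.
#' @export
psc_ld <- function(target, neighbors, space,
                   normalization = c("literal", "weight_sum"),
                   encoding = "phonological") {
  normalization <- match.arg(normalization)
  d <- neighbors$distances
  if (is.null(d)) stop("neighbour set carries no distances (method=",
                       neighbors$method, ")")
  if (any(d == 0L)) stop("zero Levenshtein distance (homophone) in the ",
                         "neighbour set of '", target, "'")
  w <- 1 / d
  cs <- member_cosines(target, neighbors$members, space)
  denom <- if (normalization == "literal") length(d) else sum(w)
  new_fsc_score(target, sum(cs * w) / denom, "ld", encoding, length(d),
                normalization = normalization)
}

# --- batch machinery -------------------------------------------------------
# Neighbour retrieval is done once and summarised as flat (target, neighbour,
# weight) triples so FSC columns can be re-evaluated cheaply under permuted
# word->vector assignments (the permutation baseline) without touching the
# form-space structures.

fsc_prepare <- function(study, lexicon, space,
                        method = c("ld", "te"),
                        encoding = c("phonological", "orthographic"),
                        k = 5L, normalization = c("literal", "weight_sum"),
                        n_fallback = 20L, seed = NULL) {
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  normalization <- match.arg(normalization)
  lexicon <- as.data.frame(lexicon)
  stopifnot(all(c("word", "phonemes", "frequency") %in% names(lexicon)))
  t_forms <- if (encoding == "phonological") study$phonemes else study$word
  l_forms <- if (encoding == "phonological") lexicon$phonemes else lexicon$word
  if (is.null(t_forms)) stop("study table lacks the '", encoding, "' forms")

  t_space <- match(study$word, space$vocabulary)
  l_space <- match(lexicon$word, space$vocabulary)
  if (anyNA(t_space)) {
    stop("study word(s) missing a semantic vector: ",
         paste(head(study$word[is.na(t_space)], 5L), collapse = ", "))
  }
  if (anyNA(l_space)) {
    stop("reference-lexicon word(s) missing a semantic vector: ",
         paste(head(lexicon$word[is.na(l_space)], 5L), collapse = ", "))
  }

  n <- nrow(study)
  tid <- nid <- w <- vector("list", n)
  denom <- numeric(n)
  nneigh <- integer(n)
  fallback <- logical(n)

  if (method == "ld") {
    D <- lev_dist_matrix_cpp(t_forms, l_forms)
    for (i in seq_len(n)) {
      di <- D[i, ]
      keep <- di >= 1L & lexicon$word != study$word[i]
      dc <- di[keep]
      if (sum(keep) < k) {
        stop("'", study$word[i], "': k-th-distance retrieval needs k = ", k,
             " candidates, reference lexicon provides ", sum(keep))
      }
      dstar <- sort(dc, partial = k)[k]
      sel <- which(keep)[dc <= dstar]
      wi <- 1 / di[sel]
      tid[[i]] <- rep.int(i, length(sel))
      nid[[i]] <- l_space[sel]
      w[[i]] <- wi
      denom[i] <- if (normalization == "literal") length(sel) else sum(wi)
      nneigh[i] <- length(sel)
    }
  } else {
    for (i in seq_len(n)) {
      hit <- which(grepl(t_forms[i], l_forms, fixed = TRUE) &
                     l_forms != t_forms[i] & lexicon$word != study$word[i])
      if (length(hit) == 0L) {
        fallback[i] <- TRUE
        pool <- which(lexicon$word != study$word[i])
        hit <- with_seed(if (is.null(seed)) NULL else seed + i,
                         sample(pool, min(n_fallback, length(pool))))
      }
      wi <- lexicon$frequency[hit]
      tid[[i]] <- rep.int(i, length(hit))
      nid[[i]] <- l_space[hit]
      w[[i]] <- wi
      denom[i] <- sum(wi)
      nneigh[i] <- length(hit)
    }
  }

  list(method = method, encoding = encoding, k = if (method == "ld") k else NA,
       normalization = if (method == "ld") normalization else NA,
       n = n, t_space = t_space,
       pair_t = unlist(tid), pair_tspace = t_space[unlist(tid)],
       pair_n = unlist(nid), pair_w = unlist(w),
       denom = denom, n_neighbors = nneigh, fallback = fallback,
       seed = seed, n_fallback = n_fallback)
}

# Evaluate FSC scores from prepared triples. `perm` optionally permutes the
# word->vector assignment over the space vocabulary: word i reads the vector
# of word perm[i]; form-space neighbourhoods are untouched.
fsc_eval <- function(prep, unit_vectors, perm = NULL) {
  pt <- prep$pair_tspace
  pn <- prep$pair_n
  if (!is.null(perm)) {
    pt <- perm[pt]
    pn <- perm[pn]
  }
  cs <- clamp1(rowSums(unit_vectors[pt, , drop = FALSE] *
                         unit_vectors[pn, , drop = FALSE]))
  num <- rowsum(cs * prep$pair_w, prep$pair_t, reorder = TRUE)
  as.vector(num) / prep$denom
}

#' Batch FSC scores for a study table
#'
#' Computes one FSC score per study word with the configured retrieval
#' scheme and encoding, appending the column (named e.g. `psc_ld`,
#' `psc_te`, `osc_ld`, `osc_te`) to the table. A run manifest recording
#' method, encoding, k, normalisation and seed is attached as attribute
#' `"fsc_manifest"`.
#'
#' @param study study table with columns `word` and (for phonological
#'   encoding) `phonemes`.
#' @param lexicon reference lexicon data.frame (`word`, `phonemes`,
#'   `frequency`), every word present in `space`.
#' @param space a [semantic_space()].
#' @param method `"ld"` (tie-inclusive k-th-distance, inverse-distance
#'   weights) or `"te"` (target-embedding, frequency weights).
#' @param encoding `"phonological"` or `"orthographic"`.
#' @param k neighbour parameter for `"ld"`, default 5.
#' @param normalization `"literal"` or `"weight_sum"` (ld only).
#' @param n_fallback random-fallback sample size for `"te"`, default 20.
#' @param seed seed for the random fallback draws.
#' @param column name of the appended column; default derived from method
#'   and encoding.
#' @return `study` with the FSC column appended, plus attributes
#'   `fsc_manifest`, and columns `<column>_n` / `<column>_fallback` when
#'   `details = TRUE`.
#' @param details if `TRUE`, also append neighbour counts and fallback flags.
#' @export
fsc_batch <- function(study, lexicon, space, method = c("ld", "te"),
                      encoding = c("phonological", "orthographic"), k = 5L,
                      normalization = c("literal", "weight_sum"),
                      n_fallback = 20L, seed = NULL, column = NULL,
                      details = FALSE) {
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  normalization <- match.arg(normalization)
  prep <- fsc_prepare(study, lexicon, space, method, encoding, k,
                      normalization, n_fallback, seed)
  vals <- fsc_eval(prep, space_unit_matrix(space))
  if (is.null(column)) {
    column <- paste0(if (encoding == "phonological") "psc" else "osc",
                     "_", method)
  }
  study[[column]] <- vals
  if (details) {
    study[[paste0(column, "_n")]] <- prep$n_neighbors
    study[[paste0(column, "_fallback")]] <- prep$fallback
  }
  attr(study, "fsc_manifest") <-
    list(column = column, method = method, encoding = encoding,
         k = if (method == "ld") as.integer(k) else NA_integer_,
         normalization = if (method == "ld") normalization else NA_character_,
         n_fallback = if (method == "te") as.integer(n_fallback) else NA_integer_,
         seed = seed, n_words = nrow(study), n_lexicon = nrow(lexicon))
  study
}

#' Permutation baseline for FSC
#'
#' Scrambles the form-meaning correspondences: each iteration applies one
#' uniform random permutation to the word-to-vector assignment (leaving
#' neighbourhood structure in form space and in semantic space intact),
#' recomputes the FSC column, and records its Pearson correlation with the
#' response and the AIC difference of `baseline + FSC` over the baseline
#' model. The unpermuted (true-mapping) correlation and delta AIC are
#' reported alongside for calibration.
#'
#' @inheritParams fsc_batch
#' @param response response column name (default `"aoa"`).
#' @param baseline_predictors predictor columns of the baseline model.
#' @param n_iterations number of permutations, default 1000.
#' @param seed master seed; iteration `i` uses `seed + i`.
#' @return A `permutation_run`: per-iteration `cor` and `delta_aic`,
#'   `true_cor`, `true_delta_aic`, and a `summary` with mean, sd and
#'   percentiles.
#' @export
permuted_fsc_baseline <- function(study, lexicon, space,
                                  method = c("ld", "te"),
                                  encoding = c("phonological", "orthographic"),
                                  response = "aoa", baseline_predictors,
                                  n_iterations = 1000L, seed = 1L, k = 5L,
                                  normalization = c("literal", "weight_sum"),
                                  n_fallback = 20L) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  normalization <- match.arg(normalization)
  prep <- fsc_prepare(study, lexicon, space, method, encoding, k,
                      normalization, n_fallback, seed)
  un <- space_unit_matrix(space)
  y <- study[[response]]
  base_fit <- fit_linear(study, response, baseline_predictors)

  score_stats <- function(vals) {
    tab <- study
    tab$.fsc <- zscore(vals)
    aug <- fit_linear(tab, response, c(baseline_predictors, ".fsc"))
    c(cor = stats::cor(vals, y), delta_aic = base_fit$aic - aug$aic)
  }

  true_vals <- fsc_eval(prep, un)
  true_stats <- score_stats(true_vals)

  nv <- length(space$vocabulary)
  cors <- daic <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    perm <- with_seed(seed + i, sample.int(nv))
    st <- score_stats(fsc_eval(prep, un, perm))
    cors[i] <- st["cor"]
    daic[i] <- st["delta_aic"]
  }
  probs <- c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975)
  structure(list(
    n_iterations = n_iterations, seed = seed, cor = cors, delta_aic = daic,
    true_cor = unname(true_stats["cor"]),
    true_delta_aic = unname(true_stats["delta_aic"]),
    summary = list(
      cor = c(mean = mean(cors), sd = stats::sd(cors)),
      delta_aic = c(mean = mean(daic), sd = stats::sd(daic)),
      cor_percentiles = stats::quantile(cors, probs),
      delta_aic_percentiles = stats::quantile(daic, probs))),
    class = "permutation_run")
}

#' @export
print.permutation_run <- function(x, ...) {
  cat("<permutation_run> ", x$n_iterations, " iterations\n",
      sprintf("  true mapping: cor = %.3f, delta AIC = %.2f\n",
              x$true_cor, x$true_delta_aic),
      sprintf("  permuted delta AIC: mean = %.2f, 95th pct = %.2f\n",
              x$summary$delta_aic[["mean"]],
              x$summary$delta_aic_percentiles[["95%"]]), sep = "")
  invisible(x)
}

#' Lexicon-subsampling robustness check for FSC
#'
#' Each iteration draws `floor(rate * V)` reference-lexicon words without
#' replacement, retrieves form neighbours only within the subsample,
#' recomputes FSC, and records (a) the Pearson correlation with the
#' full-lexicon scores and (b) the delta AIC of `baseline + FSC` over the
#' baseline model when a model specification is supplied. Study words left
#' with fewer than `k` candidates in a draw are excluded from that
#' iteration and counted.
#'
#' @inheritParams permuted_fsc_baseline
#' @param rate subsampling rate in (0, 1], typically 0.5 or 0.75.
#' @param n_iterations number of subsampling iterations, default 500.
#' @return A `subsample_run` with per-iteration correlations, delta AICs,
#'   exclusion counts, the full-lexicon scores, and the score matrix.
#' @export
subsampled_fsc <- function(study, lexicon, space, method = c("ld", "te"),
                           encoding = c("phonological", "orthographic"),
                           rate, n_iterations = 500L, k = 5L, seed = 1L,
                           normalization = c("literal", "weight_sum"),
                           response = NULL, baseline_predictors = NULL,
                           n_fallback = 20L) {
  stopifnot(rate > 0, rate <= 1)
  method <- match.arg(method)
  encoding <- match.arg(encoding)
  normalization <- match.arg(normalization)
  lexicon <- as.data.frame(lexicon)
  t_forms <- if (encoding == "phonological") study$phonemes else study$word
  l_forms <- if (encoding == "phonological") lexicon$phonemes else lexicon$word
  l_space <- match(lexicon$word, space$vocabulary)
  t_space <- match(study$word, space$vocabulary)
  if (anyNA(l_space) || anyNA(t_space)) {
    stop("study or reference-lexicon word(s) missing a semantic vector")
  }
  n <- nrow(study); V <- nrow(lexicon)
  un <- space_unit_matrix(space)
  # cosine of every (study word, lexicon word) pair, computed once
  CS <- clamp1(un[t_space, , drop = FALSE] %*% t(un[l_space, , drop = FALSE]))

  full_prep <- fsc_prepare(study, lexicon, space, method, encoding, k,
                           normalization, n_fallback, seed)
  full_scores <- fsc_eval(full_prep, un)

  if (method == "ld") {
    D <- lev_dist_matrix_cpp(t_forms, l_forms)
  } else {
    EMB <- matrix(FALSE, n, V)
    for (i in seq_len(n)) {
      EMB[i, ] <- grepl(t_forms[i], l_forms, fixed = TRUE) &
        l_forms != t_forms[i]
    }
  }
  self_excl <- outer(study$word, lexicon$word, `==`)

  fit_base <- if (!is.null(response) && !is.null(baseline_predictors)) {
    fit_linear(study, response, baseline_predictors)
  } else NULL

  m_sub <- floor(rate * V)
  scores <- matrix(NA_real_, n, n_iterations)
  cors <- daic <- rep(NA_real_, n_iterations)
  n_excluded <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    idx <- with_seed(seed + it, sample.int(V, m_sub))
    for (i in seq_len(n)) {
      if (method == "ld") {
        di <- D[i, idx]
        keep <- di >= 1L & !self_excl[i, idx]
        if (sum(keep) < k) { n_excluded[it] <- n_excluded[it] + 1L; next }
        dc <- di[keep]
        dstar <- sort(dc, partial = k)[k]
        sel <- idx[keep][dc <= dstar]
        w <- 1 / D[i, sel]
        denom <- if (normalization == "literal") length(sel) else sum(w)
      } else {
        sel <- idx[EMB[i, idx] & !self_excl[i, idx]]
        if (length(sel) == 0L) {
          pool <- idx[!self_excl[i, idx]]
          sel <- with_seed(seed + it * 100003L + i,
                           sample(pool, min(n_fallback, length(pool))))
        }
        w <- lexicon$frequency[sel]
        denom <- sum(w)
      }
      scores[i, it] <- sum(CS[i, sel] * w) / denom
    }
    ok <- !is.na(scores[, it])
    cors[it] <- stats::cor(scores[ok, it], full_scores[ok])
    if (!is.null(fit_base)) {
      tab <- study[ok, , drop = FALSE]
      tab$.fsc <- zscore(scores[ok, it])
      base_it <- if (all(ok)) fit_base else
        fit_linear(tab, response, baseline_predictors)
      aug <- fit_linear(tab, response, c(baseline_predictors, ".fsc"))
      daic[it] <- base_it$aic - aug$aic
    }
  }
  structure(list(rate = rate, n_iterations = n_iterations, seed = seed,
                 scores = scores, full_scores = full_scores,
                 cor_with_full = cors, delta_aic = daic,
                 n_excluded = n_excluded,
                 summary = list(
                   mean_cor_with_full = mean(cors, na.rm = TRUE),
                   mean_delta_aic = mean(daic, na.rm = TRUE))),
            class = "subsample_run")
}

#' @export
print.subsample_run <- function(x, ...) {
  cat(sprintf(paste0("<subsample_run> rate = %.2f, %d iterations; mean cor ",
                     "with full scores = %.3f; mean delta AIC = %s\n"),
              x$rate, x$n_iterations, x$summary$mean_cor_with_full,
              if (all(is.na(x$delta_aic))) "NA" else
                sprintf("%.2f", x$summary$mean_delta_aic)))
  invisible(x)
}

#' Add the standard lexical measures to a study table
#'
#' Convenience pipeline step appending phonological neighbourhood density
#' (`pnd`, Coltheart's N), semantic neighbourhood distance (`snd`, mean
#' cosine distance of the 20 nearest semantic neighbours), and the two
#' phonological FSC measures (`psc_te`, `psc_ld`) to a study table.
#'
#' @inheritParams fsc_batch
#' @param snd_m semantic neighbourhood size, default 20.
#' @param pnd_mode `"substitution"` or `"das"`, see [coltheart_n()].
#' @return `study` with columns `pnd`, `snd`, `psc_te`, `psc_ld` appended.
#' @export
compute_lexical_measures <- function(study, lexicon, space, k = 5L,
                                     snd_m = 20L,
                                     pnd_mode = c("substitution", "das"),
                                     normalization = c("literal", "weight_sum"),
                                     seed = NULL) {
  pnd_mode <- match.arg(pnd_mode)
  normalization <- match.arg(normalization)
  study$pnd <- unname(coltheart_n_batch(study$phonemes, lexicon$phonemes,
                                        mode = pnd_mode))
  study$snd <- unname(snd_batch(space, study$word, m = snd_m))
  study <- fsc_batch(study, lexicon, space, method = "te",
                     encoding = "phonological", n_fallback = 20L, seed = seed)
  fsc_batch(study, lexicon, space, method = "ld",
            encoding = "phonological", k = k, normalization = normalization)
}
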