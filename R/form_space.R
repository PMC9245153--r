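#' Levenshtein edit distance between symbol sequences
#'
#' Unit-cost minimum number of single-symbol insertions, deletions and
#' substitutions. Inputs may be single strings (one character = one symbol,
#' the usual one-phoneme-per-character encoding) or character vectors of
#' symbols (for multi-character phoneme labels).
#'
#' @param a,b strings or character vectors of symbols.
#' @return Non-negative integer distance.
#' @examples
#' levenshtein_distance("water", "eater")  # 1
#' @export
levenshtein_distance <- function(a, b) {
  lev_seq_cpp(as_symbols(a), as_symbols(b))
}

as_symbols <- function(x) {
  if (length(x) == 1L) strsplit(as.character(x), "", fixed = TRUE)[[1L]]
  else as.character(x)
}

#' Pairwise Levenshtein distances between two string sets
#'
#' One character = one symbol. Returns the full integer distance matrix
#' (targets in rows); this is the building block for batch neighbour
#' retrieval and for the lexicon-subsampling robustness check, where the
#' matrix is computed once and re-thresholded per subsample.
#'
#' @param targets,lexicon character vectors of forms.
#' @return Integer matrix of dim `length(targets)` x `length(lexicon)`.
#' @export
form_distance_matrix <- function(targets, lexicon) {
  m <- lev_dist_matrix_cpp(as.character(targets), as.character(lexicon))
  dimnames(m) <- list(targets, lexicon)
  m
}

new_neighbor_set <- function(target, method, members, distances = NULL,
                             k = NA_integer_, fallback_needed = FALSE) {
  structure(list(target = target, method = method,
                 members = as.character(members),
                 distances = if (is.null(distances)) NULL else as.integer(distances),
                 k = as.integer(k), fallback_needed = isTRUE(fallback_needed)),
            class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("<neighbor_set> target=", x$target, " method=", x$method,
      " n=", length(x$members),
      if (x$fallback_needed) " (fallback needed)" else "", "\n", sep = "")
  invisible(x)
}

#' Target-embedding neighbours
#'
#' All lexicon words (other than the target) that contain the target form as
#' a contiguous substring — hence all strictly longer than the target. When
#' no word embeds the target, the returned set is empty and flagged
#' `fallback_needed`; the FSC layer then falls back to a random neighbour
#' sample.
#'
#' @param target a word form.
#' @param lexicon character vector of word forms in the same encoding.
#' @return A `neighbor_set` with `method = "embedding"`.
#' @examples
#' embedding_neighbors("red", c("reduce", "credit", "dog"))
#' @export
embedding_neighbors <- function(target, lexicon) {
  lexicon <- as.character(lexicon)
  hit <- grepl(target, lexicon, fixed = TRUE) & lexicon != target
  members <- lexicon[hit]
  new_neighbor_set(target, "embedding", members,
                   fallback_needed = length(members) == 0L)
}

#' Tie-inclusive k-th-distance neighbours
#'
#' Levenshtein-based retrieval: let `d*` be the k-th smallest edit distance
#' from the target to the lexicon (target itself and distance-0 homophones
#' excluded); the neighbour set is *all* words at distance `<= d*`. This is
#' deterministic — no sampling among tied words — and can return more than
#' `k` members.
#'
#' @param target a word form.
#' @param lexicon character vector of word forms (one symbol per character).
#' @param k neighbour parameter, default 5.
#' @param lexicon_words optional word identities matching `lexicon`, used to
#'   exclude the target word itself (rather than every homograph form).
#' @return A `neighbor_set` with `method = "kth_distance"` carrying member
#'   distances.
#' @examples
#' kth_distance_neighbors("water",
#'   c("eater", "later", "waiter", "gate", "whiter", "laser", "elephant"))
#' @export
kth_distance_neighbors <- function(target, lexicon, k = 5L,
                                   lexicon_words = NULL) {
  lexicon <- as.character(lexicon)
  d <- as.integer(lev_dist_matrix_cpp(target, lexicon))
  if (is.null(lexicon_words)) {
    keep <- d >= 1L  # drops the target and any homophone (1/d undefined at 0)
  } else {
    keep <- d >= 1L & lexicon_words != target
  }
  cand <- lexicon[keep]
  dc <- d[keep]
  if (length(cand) < k) {
    stop("k-th-distance retrieval needs at least k = ", k,
         " candidate words; lexicon provides ", length(cand))
  }
  dstar <- sort(dc, partial = k)[k]
  sel <- dc <= dstar
  new_neighbor_set(target, "kth_distance", cand[sel], distances = dc[sel], k = k)
}

#' Coltheart's N (phonological neighbourhood density)
#'
#' Number of lexicon words obtainable from the target by changing exactly
#' one phoneme (same length, Hamming distance 1). The alternative `"das"`
#' mode counts all words at Levenshtein distance 1 (additions, deletions
#' and substitutions), the convention used by some published PhonND norms.
#' The target itself never counts.
#'
#' @param target phoneme string (or symbol vector, single-character symbols).
#' @param lexicon character vector of phoneme strings.
#' @param mode `"substitution"` (default, the literal Coltheart N) or `"das"`.
#' @return Non-negative integer count.
#' @export
coltheart_n <- function(target, lexicon, mode = c("substitution", "das")) {
  mode <- match.arg(mode)
  if (length(target) > 1L) target <- paste(target, collapse = "")
  coltheart_counts_cpp(as.character(target), as.character(lexicon),
                       mode == "das")[1L]
}

#' @rdname coltheart_n
#' @param targets character vector of phoneme strings to score in one pass.
#' @export
coltheart_n_batch <- function(targets, lexicon,
                              mode = c("substitution", "das")) {
  mode <- match.arg(mode)
  stats::setNames(
    coltheart_counts_cpp(as.character(targets), as.character(lexicon),
                         mode == "das"),
    targets)
}
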