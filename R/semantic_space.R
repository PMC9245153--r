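#' Construct a semantic space
#'
#' A semantic space pairs an ordered vocabulary with a dense real matrix of
#' word vectors (one row per word) and caches the per-row Euclidean norms so
#' cosine queries are cheap. Proximity between words is always measured as
#' the cosine of the angle between their vectors.
#'
#' @param words character vector of unique, non-empty word forms.
#' @param vectors numeric matrix with `length(words)` rows; no `NA`/`Inf`
#'   entries and no zero-norm rows are allowed.
#' @return An object of class `semantic_space` with fields `vocabulary`,
#'   `vectors` and `norms`.
#' @examples
#' sp <- semantic_space(c("a", "b"), rbind(c(1, 0), c(0, 1)))
#' cosine_similarity(sp$vectors[1, ], sp$vectors[2, ])
#' @export
semantic_space <- function(words, vectors) {
  words <- as.character(words)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (anyDuplicated(words)) {
    stop("duplicate words in semantic space: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  }
  if (length(words) != nrow(vectors)) {
    stop("vocabulary length (", length(words), ") does not match matrix rows (",
         nrow(vectors), ")")
  }
  if (any(!is.finite(vectors))) stop("semantic vectors contain NaN/Inf entries")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) {
    stop("zero-norm vector(s) for: ",
         paste(head(words[nrm == 0], 5L), collapse = ", "))
  }
  rownames(vectors) <- words
  structure(list(vocabulary = words, vectors = vectors, norms = nrm),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space> ", length(x$vocabulary), " words, dim ",
      ncol(x$vectors), "\n", sep = "")
  invisible(x)
}

#' @export
dim.semantic_space <- function(x) dim(x$vectors)

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against floating-point
#' rounding. Zero vectors are an error, never silently 0.
#'
#' @param u,v numeric vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in dimension")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# Unit-normalised copy of the vector matrix.
space_unit_matrix <- function(space) space$vectors / space$norms

# Cosine similarity of `word` to every word in the space (named vector).
space_cosines_to <- function(space, word) {
  i <- match(word, space$vocabulary)
  if (is.na(i)) stop("word not in semantic space: ", word)
  v <- space$vectors[i, ]
  cs <- as.vector(space$vectors %*% v) / (space$norms * space$norms[i])
  stats::setNames(clamp1(cs), space$vocabulary)
}

#' Nearest semantic neighbours of a word
#'
#' Returns the `m` words with smallest cosine distance (1 - cosine
#' similarity) to the target, target excluded, sorted ascending. Ties are
#' broken by vocabulary order, deterministically.
#'
#' @param word target word (must be in the vocabulary).
#' @param space a [semantic_space()].
#' @param m number of neighbours, `m < length(space$vocabulary)`.
#' @return data.frame with columns `word` and `distance`.
#' @export
nearest_semantic_neighbors <- function(word, space, m) {
  i <- match(word, space$vocabulary)
  if (is.na(i)) stop("word not in semantic space: ", word)
  if (m >= length(space$vocabulary)) {
    stop("m (", m, ") must be smaller than the vocabulary size (",
         length(space$vocabulary), ")")
  }
  d <- 1 - space_cosines_to(space, word)
  d <- d[-i]
  ord <- order(d)[seq_len(m)]  # order() is stable: ties fall back to position
  data.frame(word = names(d)[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}

#' Semantic neighbourhood distance (SND)
#'
#' Mean cosine distance from a word to its `m` (default 20) nearest
#' neighbours in semantic space. Higher SND means the word sits in a sparser
#' semantic neighbourhood.
#'
#' @inheritParams nearest_semantic_neighbors
#' @param m neighbourhood size, default 20.
#' @return Non-negative scalar in `[0, 2]`.
#' @export
snd <- function(word, space, m = 20) {
  mean(nearest_semantic_neighbors(word, space, m)$distance)
}

#' SND for every word in a space
#'
#' Vectorised version of [snd()] over the whole vocabulary (or a subset),
#' using a blocked similarity-matrix computation.
#'
#' @param space a [semantic_space()].
#' @param words words to score; default the full vocabulary.
#' @param m neighbourhood size, default 20.
#' @param block rows per similarity block (memory/speed trade-off).
#' @return Named numeric vector of SND values.
#' @export
snd_batch <- function(space, words = space$vocabulary, m = 20, block = 512L) {
  idx <- match(words, space$vocabulary)
  if (anyNA(idx)) {
    stop("words not in semantic space: ",
         paste(head(words[is.na(idx)], 5L), collapse = ", "))
  }
  if (m >= length(space$vocabulary)) {
    stop("m (", m, ") must be smaller than the vocabulary size")
  }
  un <- space_unit_matrix(space)
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = block)) {
    rows <- idx[start:min(start + block - 1L, length(idx))]
    cs <- un[rows, , drop = FALSE] %*% t(un)  # |rows| x V
    for (r in seq_along(rows)) {
      d <- 1 - clamp1(cs[r, ])
      d <- d[-rows[r]]
      out[start + r - 1L] <- mean(sort(d, partial = m)[seq_len(m)])
    }
  }
  stats::setNames(out, words)
}
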