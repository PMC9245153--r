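#' Read a delimited norms table
#'
#' Reads a CSV/TSV norms resource (header required) and maps its columns to
#' the canonical record fields (`word`, `aoa`, `frequency`, `concreteness`,
#' `valence`, `iconicity`, `morph_complex`, `length_phonemes`). Unmapped
#' extra columns are ignored; empty cells stay missing (`NA`), never zero.
#' Duplicate rows for the same word (different senses) pass through; they
#' are reduced to the earliest AoA at assembly time.
#'
#' @param path delimited text file with a header row.
#' @param column_map named character vector `canonical = file_column`; the
#'   `word` entry is mandatory.
#' @param sep field separator; default `"auto"` infers from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return data.frame with the mapped canonical columns; `word` lowercased
#'   and trimmed.
#' @export
read_tabular_norms <- function(path, column_map = c(word = "word", aoa = "aoa"),
                               sep = "auto") {
  if (sep == "auto") {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), data.table = FALSE,
                          colClasses = list(character = unname(column_map["word"])))
  missing_cols <- setdiff(unname(column_map), names(dt))
  if (length(missing_cols)) {
    stop("mapped column(s) absent from ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- dt[, unname(column_map), drop = FALSE]
  names(out) <- names(column_map)
  out$word <- trimws(tolower(as.character(out$word)))
  if ("aoa" %in% names(out) && any(!is.na(out$aoa) & out$aoa <= 0)) {
    stop("non-positive AoA values in ", path)
  }
  out
}

#' Write a norms table as CSV
#'
#' Inverse of [read_tabular_norms()] with identity column map; missing
#' values are written as empty cells.
#'
#' @param x data.frame of norms records.
#' @param path output file.
#' @export
write_norms_csv <- function(x, path) {
  data.table::fwrite(x, path, sep = ",", na = "", quote = FALSE)
  invisible(path)
}

#' Read a phonological lexicon
#'
#' Each line is `word<TAB>transcription` with one character per phoneme
#' (CELEX/DISC style). Stress/syllable markers listed in `strip_markers`
#' are removed before the transcription is interpreted, so the phoneme
#' count equals the character count of the stripped transcription.
#'
#' @param path two-column TAB-separated text file, no header.
#' @param strip_markers character vector of single-character markers to
#'   remove (e.g. `c("'", "-", ":")`); default none.
#' @param duplicates `"strict"` (default) fails on a repeated word with a
#'   conflicting transcription; `"lenient"` keeps the first and warns.
#' @return Named character vector: word -> phoneme string.
#' @export
read_phonological_lexicon <- function(path, strip_markers = character(),
                                      duplicates = c("strict", "lenient")) {
  duplicates <- match.arg(duplicates)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed line(s) in ", path, " (need word<TAB>transcription): ",
         paste(head(which(bad), 3L), collapse = ", "))
  }
  words <- trimws(tolower(vapply(parts, `[[`, "", 1L)))
  trans <- vapply(parts, `[[`, "", 2L)
  if (length(strip_markers)) {
    for (mk in strip_markers) trans <- gsub(mk, "", trans, fixed = TRUE)
  }
  dup <- duplicated(words)
  if (any(dup)) {
    first <- match(words[dup], words)
    conflict <- trans[dup] != trans[first]
    if (any(conflict)) {
      msg <- paste0("duplicate word(s) with conflicting transcription: ",
                    paste(unique(words[dup][conflict]), collapse = ", "))
      if (duplicates == "strict") stop(msg) else warning(msg, "; keeping first")
    }
    words <- words[!dup]
    trans <- trans[!dup]
  }
  stats::setNames(trans, words)
}

#' Write a phonological lexicon
#'
#' @param phonemes named character vector word -> phoneme string.
#' @param path output file.
#' @export
write_phonological_lexicon <- function(phonemes, path) {
  writeLines(paste(names(phonemes), phonemes, sep = "\t"), path)
  invisible(path)
}

#' Read word vectors in the embedding text format
#'
#' First line `<vocab> <dim>`, then one word plus `dim` reals per line
#' (the word2vec/GloVe-with-header convention). The declared vocabulary
#' count must match the number of data lines; duplicate words and zero-norm
#' vectors are rejected.
#'
#' @param path embedding text file.
#' @return A [semantic_space()].
#' @export
read_semantic_vectors <- function(path) {
  header <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  if (length(header) != 2L) stop("malformed embedding header in ", path)
  vocab <- header[1L]; d <- header[2L]
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = " ",
                          data.table = FALSE)
  if (nrow(dt) != vocab) {
    stop("embedding header declares ", vocab, " words but file has ",
         nrow(dt), " data lines")
  }
  if (ncol(dt) != d + 1L) {
    stop("embedding header declares dim ", d, " but rows have ",
         ncol(dt) - 1L, " values")
  }
  words <- as.character(dt[[1L]])
  if (anyDuplicated(words)) {
    stop("duplicate word(s) in embedding file: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  }
  semantic_space(words, as.matrix(dt[, -1L, drop = FALSE]))
}

#' Write a semantic space in the embedding text format
#'
#' Values are serialised with 6 decimal digits, so a write/read round trip
#' agrees to 1e-6 elementwise.
#'
#' @param space a [semantic_space()].
#' @param path output file.
#' @export
write_semantic_vectors <- function(space, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(space$vocabulary), ncol(space$vectors)), con)
  rows <- apply(space$vectors, 1L, function(v)
    paste(sprintf("%.6f", v), collapse = " "))
  writeLines(paste(space$vocabulary, rows), con)
  invisible(path)
}

#' Assemble the study table and reference lexicon
#'
#' Joins multi-source norms records with the frequency lexicon and the
#' semantic space under the study's inclusion rules:
#' senses sharing a word form are reduced to the *earliest* (minimum) AoA;
#' study rows are the word forms present in every norms source, in the
#' frequency lexicon and in the semantic space, with no missing analysis
#' value (iconicity exempt unless `require_iconicity`); the reference
#' lexicon is every frequency-lexicon word that appears in at least one
#' norms source and has a semantic vector.
#'
#' @param norms_list named list of norms data.frames (as returned by
#'   [read_tabular_norms()]); each must have a `word` column.
#' @param lexicon data.frame with columns `word`, `phonemes`, `frequency`
#'   (the frequency/reference lexicon).
#' @param space a [semantic_space()].
#' @param require_iconicity if `TRUE`, study rows must also have a
#'   non-missing `iconicity`.
#' @return list with elements `study` (data.frame, one row per word) and
#'   `reference` (the filtered reference lexicon data.frame).
#' @export
assemble_study_lexicon <- function(norms_list, lexicon, space,
                                   require_iconicity = FALSE) {
  stopifnot(is.list(norms_list), length(norms_list) >= 1L)
  lexicon <- as.data.frame(lexicon)
  lexicon$word <- trimws(tolower(as.character(lexicon$word)))

  merged <- NULL
  for (nm in names(norms_list)) {
    tab <- as.data.frame(norms_list[[nm]])
    tab$word <- trimws(tolower(as.character(tab$word)))
    if ("aoa" %in% names(tab)) {
      # earliest AoA per word form across senses
      agg <- stats::aggregate(aoa ~ word, data = tab[!is.na(tab$aoa), ],
                              FUN = min)
      rest <- tab[!duplicated(tab$word), setdiff(names(tab), "aoa"),
                  drop = FALSE]
      tab <- merge(rest, agg, by = "word", all.x = TRUE)
    } else {
      tab <- tab[!duplicated(tab$word), , drop = FALSE]
    }
    merged <- if (is.null(merged)) tab else
      merge(merged, tab, by = "word", all = FALSE,
            suffixes = c("", paste0(".", nm)))
  }
  if (!nrow(merged)) {
    stop("no word appears in every norms source; check the column_map and ",
         "strip-marker settings of the readers")
  }

  in_any_norms <- Reduce(union, lapply(norms_list, function(t)
    trimws(tolower(as.character(t$word)))))
  reference <- lexicon[lexicon$word %in% in_any_norms &
                         lexicon$word %in% space$vocabulary, , drop = FALSE]
  reference <- reference[!duplicated(reference$word), , drop = FALSE]

  # the frequency lexicon is authoritative for its own columns
  clash <- setdiff(intersect(names(merged), names(lexicon)), "word")
  merged <- merged[, setdiff(names(merged), clash), drop = FALSE]
  study <- merge(merged, lexicon[!duplicated(lexicon$word), ], by = "word")
  study <- study[study$word %in% space$vocabulary, , drop = FALSE]
  core <- intersect(c("aoa", "frequency"), names(study))
  keep <- stats::complete.cases(study[, core, drop = FALSE])
  if (require_iconicity) {
    if (!"iconicity" %in% names(study)) {
      stop("iconicity analysis requested but no iconicity column is present")
    }
    keep <- keep & !is.na(study$iconicity)
  }
  study <- study[keep, , drop = FALSE]
  if (!nrow(study)) {
    stop("empty study table after intersection; check the column_map and ",
         "strip-marker settings of the readers")
  }
  study <- study[order(study$word), , drop = FALSE]
  rownames(study) <- NULL
  rownames(reference) <- NULL
  list(study = study, reference = reference)
}

#' Write a study table as CSV
#'
#' Fixed, documented column order: `word` first, then the remaining columns
#' in their current order.
#'
#' @param study study table data.frame.
#' @param path output file.
#' @export
write_study_table <- function(study, path) {
  cols <- c("word", setdiff(names(study), "word"))
  data.table::fwrite(study[, cols, drop = FALSE], path, na = "")
  invisible(path)
}
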