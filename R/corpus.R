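#' Default clause delimiter set
#'
#' Chinese and ASCII sentence/clause punctuation used to split review text
#' into clauses. The set is configurable via [tokenizer_config()] because
#' punctuation conventions differ across platforms and languages.
#'
#' @format A character vector of single-character delimiters.
#' @export
DEFAULT_DELIMITERS <- c(
  "，", "。", "！", "？", "；", "、",
  ",", ".", "!", "?", ";", ":", "…"
)

#' Tokenizer configuration
#'
#' Bundles the clause delimiter set, the stopword list, and the word
#' segmentation mode used by [segment_clauses()] and [tokenize()].
#'
#' @param delimiters Character vector of single-character clause delimiters.
#'   Must be non-empty.
#' @param stopwords Character vector of tokens removed during tokenization.
#' @param mode Either `"whitespace"` (split tokens on runs of whitespace;
#'   sufficient for pre-segmented or synthetic text) or a function
#'   `function(text) character()` supplying an external word segmenter for
#'   unsegmented text.
#' @return An object of class `tokenizer_config`.
#' @export
tokenizer_config <- function(delimiters = DEFAULT_DELIMITERS,
                             stopwords = character(),
                             mode = "whitespace") {
  if (length(delimiters) == 0L) {
    stop("`delimiters` must contain at least one character", call. = FALSE)
  }
  if (any(nchar(delimiters) != 1L)) {
    stop("every delimiter must be a single character", call. = FALSE)
  }
  if (!is.function(mode) && !identical(mode, "whitespace")) {
    stop('`mode` must be "whitespace" or a segmentation function', call. = FALSE)
  }
  structure(
    list(
      delimiters = unique(delimiters),
      stopwords = unique(as.character(stopwords)),
      mode = mode
    ),
    class = "tokenizer_config"
  )
}

#' Split review text into clauses at punctuation delimiters
#'
#' A clause is a maximal run of non-delimiter characters containing at least
#' one non-whitespace character. Runs that are empty or whitespace-only are
#' dropped; clause text is not trimmed, so surrounding spaces survive.
#'
#' @param text A single character string (may be empty).
#' @param cfg A [tokenizer_config()].
#' @return Character vector of clause texts, in order of appearance;
#'   `character(0)` for empty or all-delimiter input.
#' @examples
#' segment_clauses("good attitude, clear plan.", tokenizer_config())
#' @export
segment_clauses <- function(text, cfg = tokenizer_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  pattern <- paste0("[", paste0("\\Q", cfg$delimiters, "\\E", collapse = ""), "]")
  runs <- strsplit(text, pattern, perl = TRUE)[[1]]
  runs[grepl("\\S", runs)]
}

#' Segment every review of a corpus into clauses
#'
#' @param reviews A tibble with columns `review_id`, `doctor_id`, `week`,
#'   `text` (as returned by [read_corpus()]).
#' @param cfg A [tokenizer_config()].
#' @return A tibble with columns `review_id`, `doctor_id`, `week`, `ordinal`
#'   (0-based clause position within its review) and `text`.
#' @export
segment_corpus <- function(reviews, cfg = tokenizer_config()) {
  stopifnot(all(c("review_id", "doctor_id", "week", "text") %in% names(reviews)))
  pieces <- lapply(seq_len(nrow(reviews)), function(i) {
    cl <- segment_clauses(reviews$text[i], cfg)
    if (length(cl) == 0L) return(NULL)
    tibble::tibble(
      review_id = reviews$review_id[i],
      doctor_id = reviews$doctor_id[i],
      week = reviews$week[i],
      ordinal = seq_along(cl) - 1L,
      text = cl
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      review_id = character(), doctor_id = character(),
      week = integer(), ordinal = integer(), text = character()
    )
  }
  out
}

#' Tokenize clause text and remove stopwords
#'
#' @param text Character vector of clause texts.
#' @param cfg A [tokenizer_config()]. In `"whitespace"` mode tokens are
#'   maximal runs of non-whitespace characters; a function mode delegates
#'   splitting to the supplied segmenter. Stopwords are removed after
#'   splitting; token order is preserved.
#' @return A list of character vectors, one per input string (possibly empty
#'   when every token was a stopword).
#' @export
tokenize <- function(text, cfg = tokenizer_config()) {
  stopifnot(is.character(text))
  toks <- if (is.function(cfg$mode)) {
    lapply(text, cfg$mode)
  } else {
    strsplit(trimws(text), "\\s+", perl = TRUE)
  }
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk[!(tk %in% cfg$stopwords)]
  })
}

#' Read a review corpus from a JSON-lines file
#'
#' One JSON object per line with fields `review_id`, `doctor_id`, `week`
#' (non-negative integer) and `text`.
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @return A tibble with one row per review.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      review_id = character(), doctor_id = character(),
      week = integer(), text = character()
    ))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || !all(c("review_id", "doctor_id", "week", "text") %in% names(rec))) {
      stop(sprintf("malformed corpus record at line %d of %s", i, path), call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(rec$week))) || as.integer(rec$week) < 0L) {
      stop(sprintf("invalid week at line %d of %s", i, path), call. = FALSE)
    }
    recs[[i]] <- tibble::tibble(
      review_id = as.character(rec$review_id),
      doctor_id = as.character(rec$doctor_id),
      week = as.integer(rec$week),
      text = as.character(rec$text)
    )
  }
  out <- dplyr::bind_rows(recs)
  dup <- out$review_id[duplicated(out$review_id)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate review_id in corpus: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Write a review corpus as JSON-lines
#'
#' @param reviews Tibble with `review_id`, `doctor_id`, `week`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(reviews, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(reviews))) {
    writeLines(jsonlite::toJSON(list(
      review_id = reviews$review_id[i],
      doctor_id = reviews$doctor_id[i],
      week = reviews$week[i],
      text = reviews$text[i]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Write / read a clause table as CSV
#'
#' Tokens are stored space-joined in a `tokens` column and split again on
#' read, so the round trip is the identity for whitespace-tokenized text.
#'
#' @param clauses Tibble with `review_id`, `ordinal`, `text` and a
#'   list-column `tokens` (plus any other columns, which are preserved).
#' @param path CSV path.
#' @return `path` invisibly for the writer; the clause tibble for the reader.
#' @export
write_clauses <- function(clauses, path) {
  out <- clauses
  if (is.list(out$tokens)) {
    out$tokens <- vapply(out$tokens, paste, character(1), collapse = " ")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_clauses
#' @export
read_clauses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("tokens" %in% names(out)) {
    out$tokens <- strsplit(ifelse(is.na(out$tokens), "", out$tokens), " ", fixed = TRUE)
    out$tokens <- lapply(out$tokens, function(tk) tk[nzchar(tk)])
  }
  for (col in intersect(c("ordinal", "week"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  tibble::as_tibble(out)
}
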