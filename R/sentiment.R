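#' Bundle sentiment, degree, and negation word tables
#'
#' @param polarity Named numeric vector: sentiment word -> signed polarity
#'   (positives > 0, negatives < 0).
#' @param degree Named numeric vector: degree adverb -> positive intensity
#'   multiplier.
#' @param negation Character vector of negation words.
#' @return An object of class `sentiment_lexicons`. The three word sets must
#'   be pairwise disjoint.
#' @export
sentiment_lexicons <- function(polarity, degree = stats::setNames(numeric(0), character(0)),
                               negation = character()) {
  stopifnot(is.numeric(polarity), !is.null(names(polarity)))
  if (length(degree) > 0L) {
    stopifnot(is.numeric(degree), !is.null(names(degree)))
    if (any(degree <= 0)) stop("degree weights must be positive", call. = FALSE)
  }
  sets <- list(polarity = names(polarity), degree = names(degree), negation = negation)
  for (i in 1:2) for (j in (i + 1):3) {
    clash <- intersect(sets[[i]], sets[[j]])
    if (length(clash) > 0L) {
      stop(sprintf("word(s) in both %s and %s lexicons: %s",
                   names(sets)[i], names(sets)[j], paste(clash, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(polarity = polarity, degree = degree,
                 negation = unique(negation)),
            class = "sentiment_lexicons")
}

#' Score one clause with the rule-based lexicon algorithm
#'
#' For each sentiment word at position k, its scope is the token span from
#' just after the previous sentiment word (or the clause start) up to k - 1.
#' The word's contribution is its polarity, multiplied by the product of the
#' degree weights found in the scope, with the sign flipped when the scope
#' contains an odd number of negation words. The raw score is the sum of
#' contributions; the normalized score divides by the clause token count.
#' A clause without sentiment words scores 0.
#'
#' @param tokens Non-empty character vector of clause tokens.
#' @param lexicons A [sentiment_lexicons()].
#' @return List with `raw`, `normalized` and `n_tokens`.
#' @export
score_clause <- function(tokens, lexicons) {
  stopifnot(length(tokens) >= 1)
  is_sent <- tokens %in% names(lexicons$polarity)
  sent_pos <- which(is_sent)
  raw <- 0
  prev <- 0L
  for (k in sent_pos) {
    scope <- if (k - 1L >= prev + 1L) tokens[(prev + 1L):(k - 1L)] else character(0)
    deg <- lexicons$degree[scope[scope %in% names(lexicons$degree)]]
    n_neg <- sum(scope %in% lexicons$negation)
    raw <- raw + lexicons$polarity[[tokens[k]]] * prod(deg) * (-1)^n_neg
    prev <- k
  }
  list(raw = raw, normalized = raw / length(tokens), n_tokens = length(tokens))
}

#' Score a table of clauses
#'
#' @param clauses Tibble with a `tokens` list-column; all other columns are
#'   carried through.
#' @param lexicons A [sentiment_lexicons()].
#' @return The input tibble with `raw`, `normalized` and `n_tokens` columns
#'   appended.
#' @export
score_clauses <- function(clauses, lexicons) {
  scores <- lapply(clauses$tokens, score_clause, lexicons = lexicons)
  clauses$raw <- vapply(scores, `[[`, numeric(1), "raw")
  clauses$normalized <- vapply(scores, `[[`, numeric(1), "normalized")
  clauses$n_tokens <- vapply(scores, `[[`, integer(1), "n_tokens")
  clauses
}

#' Aggregate clause scores into doctor-week dimension scores
#'
#' Per (doctor, week, dimension) group, the score is the sum of the raw
#' clause scores divided by the total token count of the contributing
#' clauses — averaging by corpus length rather than clause count, so verbose
#' neutral text dilutes the signal. Clauses labeled `"other"` never
#' contribute; groups with no clauses emit no row.
#'
#' @param scored Tibble with `doctor_id`, `week`, `label` (aspect), `raw`,
#'   `n_tokens` (as produced by [score_clauses()] after aspect labels are
#'   attached).
#' @return Tibble with `doctor_id`, `week`, `dimension`, `score`,
#'   `n_clauses`, `n_tokens`.
#' @export
aggregate_dimension_scores <- function(scored) {
  stopifnot(all(c("doctor_id", "week", "label", "raw", "n_tokens") %in% names(scored)))
  scored |>
    dplyr::filter(.data$label != "other") |>
    dplyr::group_by(.data$doctor_id, .data$week, dimension = .data$label) |>
    dplyr::summarise(
      score = sum(.data$raw) / sum(.data$n_tokens),
      n_clauses = dplyr::n(),
      n_tokens = sum(.data$n_tokens),
      .groups = "drop"
    )
}

#' Read sentiment lexicons from three TSV files
#'
#' `polarity_path` and `degree_path` are two-column TSVs (word, numeric
#' value) without headers; `negation_path` is a one-column word list.
#' Duplicate words within a file are resolved last-wins with a warning; a
#' word appearing in two different lexicons is an error.
#'
#' @param polarity_path,degree_path,negation_path File paths. `degree_path`
#'   and `negation_path` may be `NULL` (empty tables; degree lookups then
#'   implicitly weight 1).
#' @return A [sentiment_lexicons()].
#' @export
read_lexicons <- function(polarity_path, degree_path = NULL, negation_path = NULL) {
  read_pairs <- function(path, what) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    words <- character(length(lines)); vals <- numeric(length(lines))
    for (i in seq_along(lines)) {
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L) {
        stop(sprintf("line %d of %s: expected 'word<TAB>value'", i, path), call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(parts[2L]))
      if (is.na(v)) {
        stop(sprintf("line %d of %s: non-numeric %s value '%s'", i, path, what, parts[2L]),
             call. = FALSE)
      }
      words[i] <- parts[1L]; vals[i] <- v
    }
    if (anyDuplicated(words)) {
      warning(sprintf("duplicate %s words in %s; keeping the last occurrence", what, path),
              call. = FALSE)
    }
    # last wins
    keep <- !duplicated(words, fromLast = TRUE)
    stats::setNames(vals[keep], words[keep])
  }
  polarity <- read_pairs(polarity_path, "polarity")
  degree <- if (is.null(degree_path)) stats::setNames(numeric(0), character(0)) else
    read_pairs(degree_path, "degree")
  negation <- if (is.null(negation_path)) character() else {
    neg <- trimws(readLines(negation_path, encoding = "UTF-8", warn = FALSE))
    unique(neg[nzchar(neg)])
  }
  sentiment_lexicons(polarity, degree, negation)
}

#' Write sentiment lexicons to three TSV files
#'
#' @param lexicons A [sentiment_lexicons()].
#' @param polarity_path,degree_path,negation_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_lexicons <- function(lexicons, polarity_path, degree_path, negation_path) {
  writeLines(sprintf("%s\t%.10g", names(lexicons$polarity), lexicons$polarity),
             polarity_path, useBytes = TRUE)
  writeLines(sprintf("%s\t%.10g", names(lexicons$degree), lexicons$degree),
             degree_path, useBytes = TRUE)
  writeLines(lexicons$negation, negation_path, useBytes = TRUE)
  invisible(c(polarity_path, degree_path, negation_path))
}
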