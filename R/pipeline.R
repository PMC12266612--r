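#' Percentage with half-up rounding to two decimals
#'
#' Matches the printed style of share statistics: `100 * numerator /
#' denominator`, rounded half-up (not banker's rounding) to two decimal
#' places.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @return A number in \[0, 100\] with at most two decimals.
#' @examples
#' percentage(3715, 4925)   # 75.43
#' percentage(608538, 672195)  # 90.53
#' @export
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive", call. = FALSE)
  stopifnot(all(numerator >= 0), all(numerator <= denominator))
  x <- 100 * numerator / denominator
  floor(signif(x * 100, 14) + 0.5) / 100
}

#' Cue coverage statistics for an aspect-labeled clause table
#'
#' Computes, at review level and at doctor level, the share of units with at
#' least one clause of each quality dimension, and the distribution of the
#' number of distinct dimensions per unit (`"other"` never counts as a cue).
#' Every percentage is stored beside the counts it was computed from.
#'
#' @param clauses Tibble with `review_id`, `doctor_id`, `label`.
#' @return List of tibbles: `review_dimension` and `doctor_dimension`
#'   (per-dimension shares), `review_k` and `doctor_k` (counts and shares of
#'   units with exactly k and at least k distinct dimensions, k = 0..5),
#'   plus `n_reviews` and `n_doctors`.
#' @export
cue_coverage <- function(clauses) {
  stopifnot(all(c("review_id", "doctor_id", "label") %in% names(clauses)))
  units <- list(
    review = dplyr::distinct(clauses, unit = .data$review_id, .data$label),
    doctor = dplyr::distinct(clauses, unit = .data$doctor_id, .data$label)
  )
  n_units <- c(review = dplyr::n_distinct(clauses$review_id),
               doctor = dplyr::n_distinct(clauses$doctor_id))
  out <- list()
  for (lv in names(units)) {
    u <- units[[lv]]
    n <- n_units[[lv]]
    dim_counts <- unname(vapply(DIMENSIONS, function(d) {
      length(unique(u$unit[u$label == d]))
    }, integer(1)))
    out[[paste0(lv, "_dimension")]] <- tibble::tibble(
      dimension = DIMENSIONS,
      n_with_cue = dim_counts,
      n_units = n,
      share_pct = percentage(dim_counts, n)
    )
    k_of <- table(factor(
      tapply(u$label, u$unit, function(l) length(setdiff(unique(l), "other"))),
      levels = 0:5
    ))
    k_counts <- as.integer(k_of)
    at_least <- rev(cumsum(rev(k_counts)))
    out[[paste0(lv, "_k")]] <- tibble::tibble(
      k = 0:5,
      n_exactly = k_counts,
      n_at_least = at_least,
      share_exactly_pct = percentage(k_counts, n),
      share_at_least_pct = percentage(at_least, n)
    )
  }
  out$n_reviews <- n_units[["review"]]
  out$n_doctors <- n_units[["doctor"]]
  out
}

#' Run the full assessment pipeline on a scenario bundle
#'
#' Orchestrates the stages end to end: clause segmentation and tokenization,
#' aspect classification (either the trained shallow classifier or the
#' oracle truth labels), lexicon sentiment scoring, doctor-week dimension
#' aggregation, cue-coverage statistics, panel construction, the
#' fixed-effects demand regression, and the stepwise variance-explained
#' table. Rerunning with the same bundle and seed reproduces every number.
#'
#' @param bundle A [scenario()] bundle (or any list with the same elements).
#' @param classifier `"trained"` (default) or `"oracle"` (use the generator's
#'   true labels, bypassing the classifier).
#' @param stages Character vector of optional stages to run; subset of
#'   `c("coverage", "regression", "infoload")`.
#' @param lr,epochs,dim Classifier hyperparameters (defaults 0.8, 25, 20).
#' @param fe_mode Estimation mode for the regression stage.
#' @param seed Seed for the classifier split and training.
#' @return List of stage outputs: `clauses` (scored, labeled), `aspect_eval`
#'   (`NULL` in oracle mode), `dimension_scores`, `coverage`, `panel`,
#'   `fit`, `infoload`, and a `log` tibble of per-stage row counts and
#'   seeds.
#' @export
run_pipeline <- function(bundle, classifier = c("trained", "oracle"),
                         stages = c("coverage", "regression", "infoload"),
                         lr = 0.8, epochs = 25, dim = 20,
                         fe_mode = "twoway_fe", seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(all(stages %in% c("coverage", "regression", "infoload")))
  log <- tibble::tibble(stage = character(), rows = integer(), note = character())
  note <- function(stage, rows, msg = "") {
    log <<- dplyr::bind_rows(log, tibble::tibble(stage = stage, rows = as.integer(rows),
                                                 note = msg))
  }

  cfg <- tokenizer_config()
  clauses <- segment_corpus(bundle$corpus$reviews, cfg)
  clauses$tokens <- tokenize(clauses$text, cfg)
  note("segment", nrow(clauses))

  aspect_eval <- NULL
  if (classifier == "oracle") {
    truth <- bundle$corpus$clauses
    key_truth <- paste(truth$review_id, truth$ordinal)
    clauses$label <- truth$label[match(paste(clauses$review_id, clauses$ordinal), key_truth)]
    if (anyNA(clauses$label)) stop("segmentation did not recover the generated clauses",
                                   call. = FALSE)
    note("classify", nrow(clauses), "oracle labels")
  } else {
    labeled <- bundle$corpus$clauses
    sp <- split_labeled(labeled, train_fraction = 0.8, seed = seed)
    model <- train_aspect(sp$train, lr = lr, epochs = epochs, dim = dim, seed = seed)
    aspect_eval <- evaluate_aspect(model, sp$test)
    clauses$label <- suppressMessages(predict_aspect(model, clauses$tokens))$label
    note("classify", nrow(clauses),
         sprintf("trained, test accuracy %.4f, seed %d", aspect_eval$accuracy, seed))
  }

  scored <- score_clauses(clauses, bundle$lexicons)
  dimension_scores <- aggregate_dimension_scores(scored)
  note("score", nrow(dimension_scores))

  coverage <- NULL
  if ("coverage" %in% stages) {
    coverage <- cue_coverage(clauses)
    note("coverage", coverage$n_reviews)
  }

  panel <- fit <- infoload <- NULL
  if (any(c("regression", "infoload") %in% stages)) {
    panel <- build_panel(dimension_scores, bundle$panel$demand)
    note("panel", nrow(panel))
  }
  if ("regression" %in% stages) {
    fit <- suppressMessages(fit_fe(panel, mode = fe_mode))
    note("regression", fit$n, sprintf("R2 %.4f", fit$r_squared))
  }
  if ("infoload" %in% stages) {
    infoload <- stepwise_r2(panel, mode = fe_mode)
    note("infoload", nrow(infoload))
  }

  list(clauses = scored, aspect_eval = aspect_eval,
       dimension_scores = dimension_scores, coverage = coverage,
       panel = panel, fit = fit, infoload = infoload, log = log)
}
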