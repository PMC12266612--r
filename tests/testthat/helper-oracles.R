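# Independent oracle implementations, deliberately coded differently from
# the package internals they cross-check.

# Count non-empty (non-whitespace) delimiter-separated runs by a plain
# character scan.
oracle_count_runs <- function(text, delims) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- 0L
  buf <- character(0)
  flush <- function(buf) if (any(grepl("\\S", buf))) 1L else 0L
  for (ch in chars) {
    if (ch %in% delims) {
      n <- n + flush(buf)
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
  }
  n + flush(buf)
}

# Sentiment scan oracle: walk the tokens once, accumulating degree product
# and negation count, resetting the accumulator after each sentiment word.
oracle_sentiment_raw <- function(tokens, lex) {
  total <- 0
  mult <- 1
  n_neg <- 0L
  for (tk in tokens) {
    if (tk %in% names(lex$polarity)) {
      total <- total + lex$polarity[[tk]] * mult * (-1)^n_neg
      mult <- 1
      n_neg <- 0L
    } else if (tk %in% names(lex$degree)) {
      mult <- mult * lex$degree[[tk]]
    } else if (tk %in% lex$negation) {
      n_neg <- n_neg + 1L
    }
  }
  total
}

# Cohen's kappa from an explicit contingency table.
oracle_kappa <- function(a, b) {
  levs <- union(a, b)
  tab <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Small fixed lexicon used across sentiment tests.
make_lex <- function() {
  sentiment_lexicons(
    polarity = c(good = 1, great = 2, bad = -1, awful = -2),
    degree = c(very = 2, slightly = 0.5, extremely = 3),
    negation = c("not", "never")
  )
}

# Random clause over a lexicon's token universe.
random_clause <- function(lex, fillers = c("the", "doctor", "visit", "x1", "x2"),
                          len = sample(1:8, 1)) {
  universe <- c(names(lex$polarity), names(lex$degree), lex$negation, fillers)
  sample(universe, len, replace = TRUE)
}

# Separable labeled clause set: each aspect draws tokens from its own
# disjoint vocabulary.
make_separable_clauses <- function(n_per_class = 30, seed = 1) {
  set.seed(seed)
  rows <- lapply(ASPECT_LEVELS, function(lab) {
    vocab <- sprintf("%s_w%d", lab, 1:10)
    tibble::tibble(
      label = lab,
      tokens = lapply(seq_len(n_per_class), function(i) {
        sample(vocab, sample(2:5, 1), replace = TRUE)
      })
    )
  })
  dplyr::bind_rows(rows)
}

# Dummy-variable OLS + CR1 sandwich oracle for the two-way FE estimator.
oracle_twfe <- function(panel, dims) {
  df <- as.data.frame(panel)
  fml <- stats::as.formula(paste(
    "y ~", paste(dims, collapse = " + "), "+ factor(doctor_id) + factor(week)"
  ))
  fit <- stats::lm(fml, data = df)
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  G <- length(unique(df$doctor_id))
  N <- nrow(df); K <- ncol(X)
  bread <- solve(crossprod(X))
  S <- rowsum(X * e, group = df$doctor_id)
  V <- (G / (G - 1)) * ((N - 1) / (N - K)) * bread %*% crossprod(S) %*% bread
  list(coef = stats::coef(fit)[dims], se = sqrt(diag(V))[dims],
       r2 = summary(fit)$r.squared)
}
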