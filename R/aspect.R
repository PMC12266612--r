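#' The six clause aspect labels
#'
#' Five service-quality dimensions plus the residual class `other`, in the
#' fixed order used for probability vectors and argmax tie-breaking.
#'
#' @format Character vector of length 6.
#' @export
ASPECT_LEVELS <- c("expertise", "process", "attitude", "empathy", "outcome", "other")

#' The five quality dimensions (aspects excluding `other`)
#' @format Character vector of length 5.
#' @export
DIMENSIONS <- ASPECT_LEVELS[1:5]

#' Stratified train/test split of labeled clauses
#'
#' Splits within each label so class proportions are preserved to within one
#' clause per class; the split is exhaustive, disjoint, and reproducible
#' given `seed`.
#'
#' @param labeled Tibble with at least a `label` column.
#' @param train_fraction Fraction assigned to the training set (default 0.8).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_labeled <- function(labeled, train_fraction = 0.8, seed = 1L) {
  stopifnot(nrow(labeled) >= 5, train_fraction > 0, train_fraction < 1)
  counts <- table(labeled$label)
  if (any(counts < 2L)) {
    stop(sprintf("every class needs >= 2 examples; deficient: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  }
  set.seed(seed)
  in_train <- logical(nrow(labeled))
  for (lab in names(counts)) {
    idx <- which(labeled$label == lab)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
    in_train[sample(idx, n_tr)] <- TRUE
  }
  list(train = labeled[in_train, , drop = FALSE],
       test = labeled[!in_train, , drop = FALSE])
}

aspect_features <- function(tokens, use_bigrams) {
  if (length(tokens) == 0L) return(character(0))
  if (use_bigrams && length(tokens) >= 2L) {
    c(tokens, paste(tokens[-length(tokens)], tokens[-1L], sep = "__"))
  } else {
    tokens
  }
}

#' Train a shallow averaged n-gram embedding clause classifier
#'
#' A fastText-style linear model: each clause is represented by the mean of
#' its feature embeddings (words, optionally word bigrams), mapped through a
#' 6-way softmax. Trained by stochastic gradient descent on the negative
#' log-likelihood, one example at a time, with the learning rate decaying
#' linearly from `lr` to 0 over `epochs * n` updates. Plain softmax is used
#' rather than a hierarchical one: with six classes the hierarchy buys
#' nothing.
#'
#' @param train Tibble with a `tokens` list-column and a `label` column
#'   drawn from [ASPECT_LEVELS].
#' @param lr Initial learning rate (default 0.8).
#' @param epochs Training epochs (default 25).
#' @param dim Embedding dimension (default 20).
#' @param bigrams Add word-bigram features (default `FALSE`).
#' @param seed Integer RNG seed (embedding init and epoch shuffles).
#' @return An object of class `aspect_model`.
#' @export
train_aspect <- function(train, lr = 0.8, epochs = 25, dim = 20,
                         bigrams = FALSE, seed = 1L) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(dim >= 1, epochs >= 1, lr > 0)
  if (any(lengths(train$tokens) == 0L)) {
    stop("every training clause needs at least one token", call. = FALSE)
  }
  if (!all(train$label %in% ASPECT_LEVELS)) {
    stop("labels must be drawn from ASPECT_LEVELS", call. = FALSE)
  }

  feats <- lapply(train$tokens, aspect_features, use_bigrams = bigrams)
  vocab <- unique(unlist(feats, use.names = FALSE))
  feat_ids <- lapply(feats, match, table = vocab)
  y <- match(train$label, ASPECT_LEVELS)

  set.seed(seed)
  E <- matrix(stats::runif(length(vocab) * dim, -1 / dim, 1 / dim),
              nrow = length(vocab))
  W <- matrix(0, nrow = 6L, ncol = dim)

  n <- nrow(train)
  total_updates <- epochs * n
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      ids <- feat_ids[[i]]
      h <- colMeans(E[ids, , drop = FALSE])
      s <- as.vector(W %*% h)
      p <- exp(s - max(s)); p <- p / sum(p)
      target <- numeric(6L); target[y[i]] <- 1
      g <- target - p
      cur_lr <- lr * (1 - step / total_updates)
      grad_h <- as.vector(crossprod(W, g))
      W <- W + cur_lr * tcrossprod(g, h)
      E[ids, ] <- E[ids, , drop = FALSE] +
        matrix(cur_lr * grad_h / length(ids), nrow = length(ids),
               ncol = dim, byrow = TRUE)
      step <- step + 1L
    }
  }

  structure(
    list(vocab = vocab, E = E, W = W,
         config = list(lr = lr, epochs = epochs, dim = dim,
                       bigrams = bigrams, seed = as.integer(seed))),
    class = "aspect_model"
  )
}

#' Predict the aspect of one or more clauses
#'
#' The label is the argmax of the softmax probabilities, ties broken by the
#' fixed class order of [ASPECT_LEVELS]. A clause whose features are all out
#' of vocabulary falls back to `"other"` with a uniform probability vector,
#' so downstream sentiment never scores unclassifiable text under a quality
#' dimension.
#'
#' @param model An `aspect_model`.
#' @param tokens A character vector (single clause) or a list of them.
#' @return Tibble with `label` and six probability columns (one per aspect),
#'   each row summing to one.
#' @export
predict_aspect <- function(model, tokens) {
  if (!is.list(tokens)) tokens <- list(tokens)
  probs <- matrix(NA_real_, nrow = length(tokens), ncol = 6L,
                  dimnames = list(NULL, ASPECT_LEVELS))
  oov <- logical(length(tokens))
  for (i in seq_along(tokens)) {
    ids <- match(aspect_features(tokens[[i]], model$config$bigrams), model$vocab)
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) {
      probs[i, ] <- rep(1 / 6, 6L)
      oov[i] <- TRUE
      next
    }
    h <- colMeans(model$E[ids, , drop = FALSE])
    s <- as.vector(model$W %*% h)
    p <- exp(s - max(s))
    probs[i, ] <- p / sum(p)
  }
  lab <- ifelse(oov, "other",
                ASPECT_LEVELS[apply(probs, 1L, which.max)])
  n_oov <- sum(oov)
  if (n_oov > 0L) {
    rlang::inform(sprintf("%d clause(s) had no in-vocabulary features; assigned 'other'", n_oov),
                  class = "hsq5d_oov")
  }
  out <- tibble::as_tibble(as.data.frame(probs))
  out <- dplyr::bind_cols(tibble::tibble(label = lab), out)
  out
}

#' Evaluate a classifier on a labeled test set
#'
#' @param model An `aspect_model`.
#' @param test Tibble with `tokens` list-column and `label`.
#' @return List with `accuracy`, `by_class` (precision/recall/F1 per class)
#'   and the 6 x 6 `confusion` table (rows = truth, columns = prediction).
#' @export
evaluate_aspect <- function(model, test) {
  stopifnot(nrow(test) >= 1)
  pred <- suppressMessages(predict_aspect(model, test$tokens))$label
  truth <- factor(test$label, levels = ASPECT_LEVELS)
  pred <- factor(pred, levels = ASPECT_LEVELS)
  confusion <- table(truth = truth, prediction = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  by_class <- tibble::tibble(
    class = ASPECT_LEVELS,
    precision = vapply(ASPECT_LEVELS, function(cl) {
      denom <- sum(confusion[, cl])
      if (denom == 0) NA_real_ else confusion[cl, cl] / denom
    }, numeric(1)),
    recall = vapply(ASPECT_LEVELS, function(cl) {
      denom <- sum(confusion[cl, ])
      if (denom == 0) NA_real_ else confusion[cl, cl] / denom
    }, numeric(1))
  )
  by_class$f1 <- with(by_class, ifelse(
    is.na(precision) | is.na(recall) | (precision + recall) == 0,
    NA_real_, 2 * precision * recall / (precision + recall)
  ))
  list(accuracy = acc, by_class = by_class, confusion = confusion)
}

#' Cohen's kappa for two parallel annotations
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement \eqn{p_e}
#' from the marginal label frequencies. When both annotators are constant
#' and identical (\eqn{p_e = 1}) the value is 1 by convention.
#'
#' @param a,b Equal-length label vectors.
#' @return A number in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("annotation lengths differ", call. = FALSE)
  stopifnot(length(a) >= 1)
  levs <- union(unique(a), unique(b))
  ta <- factor(a, levels = levs)
  tb <- factor(b, levels = levs)
  n <- length(a)
  p_o <- mean(ta == tb)
  p_e <- sum((table(ta) / n) * (table(tb) / n))
  if (p_e >= 1) {
    rlang::inform("both annotators constant and identical; kappa = 1 by convention",
                  class = "hsq5d_kappa_degenerate")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
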