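#' @useDynLib hsq5d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Internal: convert a list of token vectors into the integer token stream
## the Gibbs sampler consumes. Vocabulary order = first appearance.
lda_index_docs <- function(docs, vocab = NULL) {
  stopifnot(is.list(docs))
  if (is.null(vocab)) vocab <- unique(unlist(docs, use.names = FALSE))
  lens <- lengths(docs)
  doc_of <- rep.int(seq_along(docs), lens)
  ids <- match(unlist(docs, use.names = FALSE), vocab)
  keep <- !is.na(ids)
  list(
    vocab = vocab,
    doc_of = doc_of[keep] - 1L,
    word_of = ids[keep] - 1L,
    n_docs = length(docs)
  )
}

lda_count_tables <- function(doc_of, word_of, z, D, K, V) {
  n_dk <- matrix(0L, D, K)
  n_kw <- matrix(0L, K, V)
  for (t in seq_along(z)) {
    n_dk[doc_of[t] + 1L, z[t] + 1L] <- n_dk[doc_of[t] + 1L, z[t] + 1L] + 1L
    n_kw[z[t] + 1L, word_of[t] + 1L] <- n_kw[z[t] + 1L, word_of[t] + 1L] + 1L
  }
  list(n_dk = n_dk, n_kw = n_kw, n_k = as.integer(rowSums(n_kw)))
}

#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Each token's topic is resampled from the collapsed conditional
#' \eqn{p(z = k) \propto (n_{dk} + \alpha)\,(n_{kw} + \beta)/(n_k + V\beta)}
#' with the current token excluded from all counts. Symmetric priors;
#' defaults follow common LDA practice (\eqn{\alpha = 50/K}, \eqn{\beta = 0.01}).
#'
#' @param docs List of character vectors, one tokenized document each. For
#'   review corpora, documents are whole reviews (tokenized and
#'   stopword-filtered), since topics describe complete after-service
#'   comments rather than single clauses.
#' @param K Number of topics (>= 2).
#' @param alpha,beta Symmetric Dirichlet hyperparameters.
#' @param n_iter Number of full Gibbs sweeps.
#' @param seed Integer RNG seed; identical seed and input reproduce the
#'   identical assignment vector.
#' @return An object of class `lda_state`: vocabulary, token stream, topic
#'   assignments `z`, count tables `n_dk` (documents x topics), `n_kw`
#'   (topics x vocabulary), `n_k`, and the hyperparameters.
#' @export
fit_lda <- function(docs, K, alpha = 50 / K, beta = 0.01,
                    n_iter = 200, seed = 1L) {
  stopifnot(K >= 2, n_iter >= 1)
  if (length(docs) == 0L) stop("empty corpus", call. = FALSE)
  if (any(lengths(docs) == 0L)) stop("every document must be non-empty", call. = FALSE)
  idx <- lda_index_docs(docs)
  N <- length(idx$word_of)
  if (K > N) stop("K exceeds the total token count", call. = FALSE)
  V <- length(idx$vocab)

  set.seed(seed)
  z0 <- sample.int(K, N, replace = TRUE) - 1L
  ct <- lda_count_tables(idx$doc_of, idx$word_of, z0, idx$n_docs, K, V)
  res <- lda_gibbs_cpp(idx$doc_of, idx$word_of, z0, ct$n_dk, ct$n_kw, ct$n_k,
                       alpha, beta, as.integer(n_iter))
  structure(
    list(
      K = as.integer(K), V = V, alpha = alpha, beta = beta,
      vocab = idx$vocab, doc_of = idx$doc_of, word_of = idx$word_of,
      z = res$z, n_dk = res$n_dk, n_kw = res$n_kw, n_k = res$n_k,
      n_iter = as.integer(n_iter), seed = as.integer(seed)
    ),
    class = "lda_state"
  )
}

#' Smoothed topic-word and document-topic probability estimates
#'
#' \eqn{\hat\phi_{kw} = (n_{kw} + \beta)/(n_k + V\beta)};
#' \eqn{\hat\theta_{dk} = (n_{dk} + \alpha)/(n_d + K\alpha)}. Rows of both
#' matrices sum to one.
#'
#' @param state An `lda_state`.
#' @return `lda_phi`: K x V matrix; `lda_theta`: D x K matrix.
#' @export
lda_phi <- function(state) {
  (state$n_kw + state$beta) / (state$n_k + state$V * state$beta)
}

#' @rdname lda_phi
#' @export
lda_theta <- function(state) {
  nd <- rowSums(state$n_dk)
  (state$n_dk + state$alpha) / (nd + state$K * state$alpha)
}

#' Held-out perplexity and log-likelihood under a fitted topic model
#'
#' Topic-word probabilities are frozen at their training estimate; held-out
#' document-topic proportions are estimated by fold-in Gibbs sampling (point
#' estimate after `foldin_iters` sweeps). Tokens outside the training
#' vocabulary are dropped. Perplexity is
#' \eqn{\exp(-\sum_d\sum_w \log p(w\mid d) / N)} with
#' \eqn{p(w\mid d) = \sum_k \hat\theta_{dk}\hat\phi_{kw}}.
#'
#' @param state A fitted `lda_state`.
#' @param docs Held-out documents (list of token vectors).
#' @param foldin_iters Fold-in Gibbs sweeps (default 20).
#' @param seed RNG seed for the fold-in chain.
#' @return List with `perplexity` (>= 1), `log_likelihood` (total held-out
#'   log probability), `n_tokens` scored, and the fold-in `theta` estimate
#'   with the scored token stream (`doc_of`, `word_of`, 0-based).
#' @export
heldout_perplexity <- function(state, docs, foldin_iters = 20, seed = 1L) {
  if (length(docs) == 0L) stop("empty held-out set", call. = FALSE)
  idx <- lda_index_docs(docs, vocab = state$vocab)
  N <- length(idx$word_of)
  if (N == 0L) stop("no held-out tokens in the training vocabulary", call. = FALSE)
  phi <- lda_phi(state)

  set.seed(seed)
  z0 <- sample.int(state$K, N, replace = TRUE) - 1L
  n_dk <- matrix(0L, idx$n_docs, state$K)
  for (t in seq_len(N)) {
    n_dk[idx$doc_of[t] + 1L, z0[t] + 1L] <- n_dk[idx$doc_of[t] + 1L, z0[t] + 1L] + 1L
  }
  res <- lda_foldin_cpp(idx$doc_of, idx$word_of, z0, n_dk, phi,
                        state$alpha, as.integer(foldin_iters))
  nd <- rowSums(res$n_dk)
  theta <- (res$n_dk + state$alpha) / (nd + state$K * state$alpha)

  ll <- 0
  for (t in seq_len(N)) {
    pw <- sum(theta[idx$doc_of[t] + 1L, ] * phi[, idx$word_of[t] + 1L])
    ll <- ll + log(pw)
  }
  list(perplexity = exp(-ll / N), log_likelihood = ll, n_tokens = N,
       theta = theta, doc_of = idx$doc_of, word_of = idx$word_of)
}

#' Choose the number of topics by k-fold cross-validated perplexity
#'
#' Documents are partitioned into `folds` folds; for every candidate K the
#' model is trained on all but one fold and scored on the remainder, and the
#' per-K metrics are averaged. The selected K minimizes mean perplexity;
#' ties go to the larger mean log-likelihood, then to the smaller K.
#'
#' @param docs List of tokenized documents (length >= `folds`).
#' @param K_grid Candidate topic counts.
#' @param folds Number of cross-validation folds (default 3).
#' @param seed RNG seed controlling the fold assignment and all fits.
#' @param n_iter,foldin_iters Gibbs sweeps for training and fold-in scoring.
#' @param alpha,beta Optional hyperparameter overrides (defaults 50/K, 0.01).
#' @return List with `K` (the selection) and `metrics`, a tibble of per-K
#'   mean perplexity and mean log-likelihood.
#' @export
select_topic_count <- function(docs, K_grid, folds = 3, seed = 1L,
                               n_iter = 100, foldin_iters = 20,
                               alpha = NULL, beta = 0.01) {
  stopifnot(length(K_grid) >= 1, length(docs) >= folds)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(docs)))
  rows <- list()
  for (K in K_grid) {
    a <- if (is.null(alpha)) 50 / K else alpha
    perp <- ll <- numeric(folds)
    for (f in seq_len(folds)) {
      train <- docs[fold_of != f]
      test <- docs[fold_of == f]
      st <- fit_lda(train, K = K, alpha = a, beta = beta,
                    n_iter = n_iter, seed = seed + 97L * f + K)
      sc <- heldout_perplexity(st, test, foldin_iters = foldin_iters,
                               seed = seed + 31L * f + K)
      perp[f] <- sc$perplexity
      ll[f] <- sc$log_likelihood
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      K = K, mean_perplexity = mean(perp), mean_log_likelihood = mean(ll)
    )
  }
  metrics <- dplyr::bind_rows(rows)
  ord <- order(metrics$mean_perplexity, -metrics$mean_log_likelihood, metrics$K)
  list(K = metrics$K[ord[1L]], metrics = metrics)
}

#' Cosine similarity between two topics' word distributions
#'
#' Computed on the smoothed topic-word probability rows, so the value lies
#' in (0, 1] and equals 1 for proportional count rows.
#'
#' @param state An `lda_state`.
#' @param i,j Distinct topic indices (1-based).
#' @return A number in \[0, 1\].
#' @export
topic_cosine <- function(state, i, j) {
  stopifnot(i != j, i >= 1, j >= 1, i <= state$K, j <= state$K)
  phi <- lda_phi(state)
  cosine_vec(phi[i, ], phi[j, ])
}

cosine_vec <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' Greedily merge topics with near-identical word distributions
#'
#' Repeatedly finds the most similar pair of topics (cosine on smoothed
#' word distributions); while the best pair exceeds `threshold`, their count
#' rows are summed, topics are renumbered contiguously, and the search
#' repeats. Token assignments are remapped, so count conservation holds.
#'
#' @param state An `lda_state`.
#' @param threshold Cosine threshold in (0, 1\] above which a pair merges
#'   (default 0.75).
#' @return List with `state` (the merged `lda_state`) and `log`, a tibble of
#'   the merges performed (`kept`, `absorbed`, `cosine`, indices referring to
#'   the numbering at the time of each merge).
#' @export
merge_similar_topics <- function(state, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  log <- tibble::tibble(kept = integer(), absorbed = integer(), cosine = numeric())
  repeat {
    if (state$K < 2L) break
    phi <- lda_phi(state)
    best <- c(NA_integer_, NA_integer_); best_cos <- -Inf
    for (i in seq_len(state$K - 1L)) {
      for (j in seq(i + 1L, state$K)) {
        cs <- cosine_vec(phi[i, ], phi[j, ])
        if (cs > best_cos) { best_cos <- cs; best <- c(i, j) }
      }
    }
    if (best_cos <= threshold) break
    i <- best[1L]; j <- best[2L]
    map <- seq_len(state$K)
    map[j] <- i
    map[map > j] <- map[map > j] - 1L
    state$n_kw <- rowsum(state$n_kw, group = map)
    storage.mode(state$n_kw) <- "integer"
    state$n_dk <- t(rowsum(t(state$n_dk), group = map))
    storage.mode(state$n_dk) <- "integer"
    state$n_k <- as.integer(rowSums(state$n_kw))
    state$z <- map[state$z + 1L] - 1L
    state$K <- state$K - 1L
    log <- dplyr::bind_rows(log, tibble::tibble(kept = i, absorbed = j, cosine = best_cos))
  }
  list(state = state, log = log)
}

#' Top words per topic
#'
#' @param state An `lda_state`.
#' @param n Number of words per topic.
#' @return Tibble with `topic`, `word`, `probability`, probabilities sorted
#'   descending within each topic.
#' @export
top_words <- function(state, n = 20) {
  phi <- lda_phi(state)
  rows <- lapply(seq_len(state$K), function(k) {
    ord <- order(phi[k, ], decreasing = TRUE)[seq_len(min(n, state$V))]
    tibble::tibble(topic = k, word = state$vocab[ord], probability = phi[k, ord])
  })
  dplyr::bind_rows(rows)
}

#' Agreement between two annotators' topic labels
#'
#' For each topic, the two label strings are turned into bag-of-words count
#' vectors over their union vocabulary and compared by cosine similarity;
#' the mean over topics is returned. 1 iff the per-topic bags are identical,
#' 0 when every pair is word-disjoint.
#'
#' @param labels_a,labels_b Character vectors of equal length, one label
#'   string per topic.
#' @return A number in \[0, 1\].
#' @export
label_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sets must cover the same number of topics", call. = FALSE)
  }
  stopifnot(length(labels_a) >= 1)
  sims <- vapply(seq_along(labels_a), function(k) {
    ta <- strsplit(tolower(labels_a[k]), "\\s+")[[1]]
    tb <- strsplit(tolower(labels_b[k]), "\\s+")[[1]]
    ta <- ta[nzchar(ta)]; tb <- tb[nzchar(tb)]
    voc <- union(ta, tb)
    if (length(voc) == 0L) return(1)
    cosine_vec(tabulate(match(ta, voc), length(voc)),
               tabulate(match(tb, voc), length(voc)))
  }, numeric(1))
  mean(sims)
}
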