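# A three-topic corpus whose topics use pairwise disjoint vocabularies, so
# the generating word distributions are recoverable.
disjoint_corpus <- function(n_docs_per_topic = 20, doc_len = 12, n_words = 6,
                            seed = 1) {
  set.seed(seed)
  vocabs <- lapply(1:3, function(k) sprintf("t%d_w%d", k, seq_len(n_words)))
  docs <- list()
  for (k in 1:3) {
    for (d in seq_len(n_docs_per_topic)) {
      docs[[length(docs) + 1L]] <- sample(vocabs[[k]], doc_len, replace = TRUE)
    }
  }
  list(docs = docs, vocabs = vocabs)
}

test_that("Gibbs sampling conserves counts and is seed-deterministic", {
  st <- fit_lda(list(c("a", "a", "a")), K = 2, n_iter = 10, seed = 3)
  expect_identical(sum(st$n_dk), 3L)
  expect_identical(sum(st$n_k), 3L)
  expect_identical(as.integer(rowSums(st$n_kw)), st$n_k)

  dc <- disjoint_corpus(n_docs_per_topic = 5, seed = 2)
  s1 <- fit_lda(dc$docs, K = 3, n_iter = 30, seed = 11)
  s2 <- fit_lda(dc$docs, K = 3, n_iter = 30, seed = 11)
  expect_identical(s1$z, s2$z)
  # count-table invariants after sweeps
  expect_identical(as.integer(rowSums(s1$n_kw)), s1$n_k)
  expect_identical(as.integer(rowSums(s1$n_dk)), lengths(dc$docs))
  # degenerate inputs
  expect_error(fit_lda(list(), K = 2), "empty")
  expect_error(fit_lda(list(c("a", "b")), K = 5), "K exceeds")
})

test_that("phi and theta rows are probability distributions", {
  dc <- disjoint_corpus(n_docs_per_topic = 5, seed = 4)
  st <- fit_lda(dc$docs, K = 3, n_iter = 20, seed = 1)
  expect_true(all(abs(rowSums(lda_phi(st)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(lda_theta(st)) - 1) < 1e-9))
})

test_that("fitted topics recover disjoint-vocabulary generating topics", {
  dc <- disjoint_corpus(seed = 5)
  st <- fit_lda(dc$docs, K = 3, alpha = 0.1, n_iter = 120, seed = 9)
  phi <- lda_phi(st)
  # greedy matching of fitted topics to true uniform-over-vocab topics
  truth <- t(sapply(dc$vocabs, function(v) {
    p <- numeric(st$V)
    p[match(v, st$vocab)] <- 1 / length(v)
    p
  }))
  remaining <- 1:3
  for (k in 1:3) {
    cosims <- apply(truth[remaining, , drop = FALSE], 1,
                    function(tv) sum(tv * phi[k, ]) /
                      sqrt(sum(tv^2) * sum(phi[k, ]^2)))
    best <- which.max(cosims)
    expect_gte(max(cosims), 0.9)
    remaining <- remaining[-best]
  }
})

test_that("held-out perplexity matches closed forms and the mixture oracle", {
  # single-word vocabulary: the model is certain, perplexity 1
  docs1 <- replicate(4, rep("only", 5), simplify = FALSE)
  st1 <- fit_lda(docs1, K = 2, beta = 1e-9, n_iter = 5, seed = 1)
  expect_equal(heldout_perplexity(st1, docs1[1:2])$perplexity, 1, tolerance = 1e-9)

  # uniform topic-word and uniform counts: perplexity equals V exactly
  V <- 5
  st_unif <- structure(list(
    K = 2L, V = V, alpha = 0.5, beta = 0.01,
    vocab = paste0("w", 1:V),
    n_kw = matrix(3L, 2, V), n_k = rep(3L * V, 2),
    n_dk = matrix(2L, 3, 2)
  ), class = "lda_state")
  heldout <- list(c("w1", "w2"), c("w3", "w4", "w5"))
  expect_equal(heldout_perplexity(st_unif, heldout)$perplexity, V, tolerance = 1e-9)

  # general case: exp(-sum log sum_k theta phi / N) recomputed by enumeration;
  # train/held-out split is interleaved so every topic's vocabulary is seen
  dc <- disjoint_corpus(n_docs_per_topic = 6, seed = 6)
  heldout_idx <- c(5:6, 11:12, 17:18)
  st <- fit_lda(dc$docs[-heldout_idx], K = 3, n_iter = 40, seed = 2)
  res <- heldout_perplexity(st, dc$docs[heldout_idx], seed = 8)
  phi <- lda_phi(st)
  ll <- 0
  for (t in seq_along(res$word_of)) {
    p <- 0
    for (k in 1:st$K) {
      p <- p + res$theta[res$doc_of[t] + 1, k] * phi[k, res$word_of[t] + 1]
    }
    ll <- ll + log(p)
  }
  expect_equal(res$perplexity, exp(-ll / res$n_tokens), tolerance = 1e-12)
  expect_gte(res$perplexity, 1)
  expect_error(heldout_perplexity(st, list()), "empty")
})

test_that("training fit improves with more sweeps on average", {
  # trend over 10 seeds: training-set perplexity after many sweeps is no
  # worse than after very few
  dc <- disjoint_corpus(n_docs_per_topic = 8, seed = 10)
  diffs <- sapply(1:10, function(s) {
    early <- fit_lda(dc$docs, K = 3, n_iter = 2, seed = s)
    late <- fit_lda(dc$docs, K = 3, n_iter = 60, seed = s)
    heldout_perplexity(early, dc$docs, seed = s)$perplexity -
      heldout_perplexity(late, dc$docs, seed = s)$perplexity
  })
  expect_gt(mean(diffs), 0)
})

test_that("cross-validated topic-count selection picks the generating K", {
  dc4 <- local({
    set.seed(20)
    vocabs <- lapply(1:4, function(k) sprintf("q%d_w%d", k, 1:6))
    docs <- list()
    for (k in 1:4) for (d in 1:12) {
      docs[[length(docs) + 1L]] <- sample(vocabs[[k]], 10, replace = TRUE)
    }
    docs
  })
  # singleton grid
  expect_identical(select_topic_count(dc4, K_grid = 3, seed = 1, n_iter = 5)$K, 3)
  # duplicated entries tie on every metric; the smaller (first) K wins
  sel_dup <- select_topic_count(dc4, K_grid = c(4, 4), seed = 1, n_iter = 10)
  expect_identical(sel_dup$K, 4)
  expect_equal(sel_dup$metrics$mean_perplexity[1], sel_dup$metrics$mean_perplexity[2])

  # sparse document-topic prior and a smoothing beta that penalises
  # needlessly split topics on these short six-word-vocabulary documents
  hits <- sapply(1:20, function(s) {
    select_topic_count(dc4, K_grid = c(2, 4, 8), folds = 3, seed = s,
                       n_iter = 80, foldin_iters = 20,
                       alpha = 0.1, beta = 0.5)$K == 4
  })
  expect_gte(mean(hits), 0.8)
})

test_that("topic cosine and greedy merging behave like the agglomeration oracle", {
  mk_state <- function(n_kw, alpha = 0.5, beta = 0.01) {
    K <- nrow(n_kw); V <- ncol(n_kw)
    structure(list(K = K, V = V, alpha = alpha, beta = beta,
                   vocab = paste0("w", 1:V),
                   n_kw = n_kw, n_k = as.integer(rowSums(n_kw)),
                   n_dk = matrix(as.integer(rowSums(n_kw)), nrow = 1),
                   z = integer(0)),
              class = "lda_state")
  }
  # identical rows: cosine 1, pair merges
  st <- mk_state(rbind(c(5L, 0L, 2L), c(5L, 0L, 2L)))
  st$n_dk <- matrix(c(7L, 7L), 1)
  expect_equal(topic_cosine(st, 1, 2), 1)
  merged <- merge_similar_topics(st, threshold = 0.75)
  expect_identical(merged$state$K, 1L)
  expect_identical(sum(merged$state$n_kw), 14L)

  # disjoint support with tiny smoothing: cosine ~ 0, no merge
  st2 <- mk_state(rbind(c(9L, 0L, 0L), c(0L, 0L, 9L)), beta = 1e-12)
  st2$n_dk <- matrix(c(9L, 9L), 1)
  expect_lt(topic_cosine(st2, 1, 2), 1e-6)
  expect_identical(merge_similar_topics(st2, 0.75)$state$K, 2L)

  # 5-topic toy state vs a brute-force agglomeration oracle
  set.seed(31)
  base <- matrix(as.integer(rpois(5 * 8, 3)), 5, 8)
  base[4, ] <- base[1, ] + 1L  # near-duplicate pair
  base[5, ] <- base[2, ]       # exact duplicate pair
  st5 <- mk_state(base)
  st5$n_dk <- matrix(as.integer(rowSums(base)), 1)
  res <- merge_similar_topics(st5, threshold = 0.95)

  smooth <- function(m, beta = 0.01) (m + beta) / (rowSums(m) + ncol(m) * beta)
  oracle_rows <- lapply(seq_len(nrow(base)), function(i) base[i, ])
  repeat {
    K <- length(oracle_rows)
    if (K < 2) break
    pm <- smooth(do.call(rbind, oracle_rows))
    best <- c(0, 0); bc <- -Inf
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      cs <- sum(pm[i, ] * pm[j, ]) / sqrt(sum(pm[i, ]^2) * sum(pm[j, ]^2))
      if (cs > bc) { bc <- cs; best <- c(i, j) }
    }
    if (bc <= 0.95) break
    oracle_rows[[best[1]]] <- oracle_rows[[best[1]]] + oracle_rows[[best[2]]]
    oracle_rows[[best[2]]] <- NULL
  }
  expect_identical(res$state$K, length(oracle_rows))
  expect_identical(sum(res$state$n_kw), sum(base))
})

test_that("annotator label agreement is the mean bag-of-words cosine", {
  expect_equal(label_agreement(c("care approach", "expertise"),
                               c("care approach", "expertise")), 1)
  expect_equal(label_agreement("alpha beta", "gamma delta"), 0)
  # hand-computed: {great doctor} vs {good doctor} -> 1/2; second pair 1
  expect_equal(label_agreement(c("great doctor", "same"), c("good doctor", "same")),
               mean(c(0.5, 1)))
  expect_error(label_agreement(c("a", "b"), "a"), "same number")
})
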