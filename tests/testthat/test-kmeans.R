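test_that("word vectors hold per-document TF-IDF weights", {
  docs <- list(c("a", "a", "b"), c("b", "c"))
  wv <- build_word_vectors(docs, c("a", "b"), normalize = FALSE)
  idf <- inverse_document_frequency(docs)
  # token only in doc 1 -> vector (w, 0)
  expect_equal(unname(wv$vectors["a", ]),
               c((2 / 3) * idf[["a"]], 0))
  expect_equal(unname(wv$vectors["b", ]),
               c((1 / 3) * idf[["b"]], 0.5 * idf[["b"]]))
  expect_error(build_word_vectors(docs, c("a", "zzz")), "zzz")
})

test_that("normalized word vectors have unit norm", {
  corp <- generate_corpus(corpus_config("wv", n_docs = 60, seed = 8))
  tab <- top_keywords(tfidf_scores(corp), 30)
  wv <- build_word_vectors(corp, tab)
  expect_equal(unname(rowSums(wv$vectors^2)), rep(1, 30),
               tolerance = 1e-12)
})

test_that("toy one-dimensional instances are solved exactly", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  res <- kmeans_lloyd(x, k = 2, seed = 1)
  expect_equal(res$J, 1.0)
  expect_setequal(round(as.numeric(res$centroids), 6), c(0.5, 10.5))
  expect_identical(res$assignments[["p1"]], res$assignments[["p2"]])
  expect_identical(res$assignments[["p3"]], res$assignments[["p4"]])
  expect_false(res$assignments[["p1"]] == res$assignments[["p3"]])

  res1 <- kmeans_lloyd(x, k = 1, seed = 1)
  expect_equal(as.numeric(res1$centroids), 5.5)
  expect_equal(res1$J, 101.0)

  resN <- kmeans_lloyd(x, k = 4, seed = 1)
  expect_equal(resN$J, 0)

  expect_error(kmeans_lloyd(x, k = 5), "exceeds")
  expect_error(kmeans_lloyd(x, k = 0), "positive integer")
})

test_that("the loss never increases across Lloyd iterations", {
  set.seed(10)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    res <- kmeans_lloyd(x, k = sample(2:5, 1), seed = rep, nstart = 3)
    expect_true(all(diff(res$J_history) <= 1e-9))
    # final assignments are 1-nearest-centroid consistent
    d2 <- opinionflow:::sq_dist_to_centers(x, res$centroids)
    expect_true(all(d2[cbind(seq_len(40), res$assignments)] <=
                      apply(d2, 1, min) + 1e-9))
    # J equals the sum of squared distances to assigned centroids
    expect_equal(res$J,
                 sum(d2[cbind(seq_len(40), res$assignments)]),
                 tolerance = 1e-9)
  }
})

test_that("restarted Lloyd reaches the exhaustive-partition optimum on small instances", {
  set.seed(77)
  for (rep in 1:4) {
    n <- sample(6:8, 1); k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    res <- kmeans_lloyd(x, k = k, seed = rep, nstart = 20)
    expect_equal(res$J, exhaustive_kmeans_J(x, k), tolerance = 1e-8)
  }
})

test_that("clustering is deterministic for a fixed seed and matches stats::kmeans quality", {
  set.seed(5)
  x <- matrix(rnorm(60 * 4), 60, 4)
  r1 <- kmeans_lloyd(x, 3, seed = 11)
  r2 <- kmeans_lloyd(x, 3, seed = 11)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$J, r2$J)
  # independent cross-check: comparable loss to the reference implementation
  # (Hartigan-Wong can edge out Lloyd on unstructured data, hence the slack)
  ref <- stats::kmeans(x, 3, nstart = 10, iter.max = 100)
  expect_lte(r1$J, ref$tot.withinss * 1.05)
})

test_that("clusters are labelled by their dominant seed indicator", {
  lex <- dimension_lexicon(list(
    original_event = list(infections = c("cases", "positive")),
    derived_event = list(event_name = c("fire", "transfer"))))
  res <- structure(
    list(k = 3L,
         assignments = c(cases = 1L, positive = 1L, od_x = 1L,
                         fire = 2L, other = 3L),
         centroids = matrix(0, 3, 2), J = 0, J_history = 0,
         iterations = 1L, seed = 1L, tol = 1e-8),
    class = "clustering_result")
  map <- assign_clusters_to_indicators(res, lex)
  expect_identical(map$dimension, c("original_event", "derived_event",
                                    "unassigned"))
  expect_identical(map$indicator[1], "infections")
  expect_identical(map$n_seed_matches, c(2L, 1L, 0L))
  td <- token_dimension_map(res, map)
  expect_identical(td[["cases"]], "original_event")
  expect_identical(td[["other"]], "unassigned")
})

test_that("lexicon ties are broken by lexicon order", {
  lex <- dimension_lexicon(list(
    original_event = list(first = "w1", second = "w2")))
  res <- structure(
    list(k = 1L, assignments = c(w1 = 1L, w2 = 1L),
         centroids = matrix(0, 1, 2), J = 0, J_history = 0,
         iterations = 1L, seed = 1L, tol = 1e-8),
    class = "clustering_result")
  map <- assign_clusters_to_indicators(res, lex)
  expect_identical(map$indicator, "first")
})
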