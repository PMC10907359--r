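test_that("tokenize filters stop words and preserves order", {
  expect_identical(tokenize(c("a", "the", "b"), stopwords = "the"),
                   c("a", "b"))
  expect_identical(tokenize(c("a", "b")), c("a", "b"))
  expect_identical(tokenize(c("a", "a", "DATE1", "b"), stopwords = "DATE1"),
                   c("a", "a", "b"))
  # whitespace segmentation of raw text, and a pluggable segmenter
  expect_identical(tokenize("x  y z", stopwords = "y"), c("x", "z"))
  expect_identical(tokenize("a-b", segmenter = function(s)
    strsplit(s, "-")[[1]]), c("a", "b"))
  expect_identical(tokenize(character(0)), character(0))
})

test_that("term frequencies are counts normalised by document length", {
  expect_equal(term_frequency(c("a", "a", "b", "c")),
               c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(term_frequency("a"), c(a = 1))
  expect_equal(term_frequency(c("a", "a", "a", "b", "b",
                                "c", "c", "c", "c", "c")),
               c(a = 0.3, b = 0.2, c = 0.5))
  expect_error(term_frequency(character(0)), "empty")
  # normalisation property on random documents
  set.seed(1)
  for (i in 1:20) {
    doc <- sample(letters[1:6], sample(1:30, 1), replace = TRUE)
    expect_equal(sum(term_frequency(doc)), 1, tolerance = 1e-12)
  }
})

test_that("standard IDF follows the smoothed formula and is anti-monotone in df", {
  docs <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("a", "b"))
  idf <- inverse_document_frequency(docs)
  expect_equal(unname(idf["a"]), log(4 / 5))   # df = 4 (negative, kept)
  expect_equal(unname(idf["b"]), log(4 / 3))
  # D = 4, token in 3 docs -> ln(4/4) = 0
  docs3 <- list(c("x", "y"), c("x", "z"), c("x", "w"), c("q"))
  expect_equal(unname(inverse_document_frequency(docs3)["x"]), 0)
  # D = 10, token in 4 docs -> ln(2)
  docs10 <- c(lapply(1:4, function(i) c("t", "u")),
              lapply(5:10, function(i) "u"))
  expect_equal(unname(inverse_document_frequency(docs10)["t"]), log(2),
               tolerance = 1e-12)
  # anti-monotone: rarer token has the larger IDF
  mixed <- c(lapply(1:2, function(i) c("rare", "fill")),
             lapply(1:5, function(i) c("common", "fill")))
  idf2 <- inverse_document_frequency(mixed)
  expect_gt(idf2[["rare"]], idf2[["common"]])
  expect_error(inverse_document_frequency(list()), "empty")
})

test_that("the literal IDF variant evaluates the unsmoothed printed form", {
  docs <- list(c("a", "b"), c("a", "c"))
  idf <- inverse_document_frequency(docs, mode = "literal")
  df <- c(a = 2, b = 1, c = 1)
  expect_equal(unname(idf["a"]), log(2 / (sum(df) + 1)))
  expect_equal(unname(idf["b"]), log(1 / (sum(df) + 1)))
})

test_that("per-document TF-IDF is the product of IF and IDF", {
  # "a" occurs only in doc 1 with IF 0.5; df = 1, D = 10 so IDF = ln(5)
  docs <- c(list(c("a", "a", "b", "b")),
            lapply(1:9, function(i) c("b", "c")))
  stats <- tfidf_scores(docs)
  expect_equal(stats$score[stats$token == "a"], 0.5 * log(10 / 2),
               tolerance = 1e-12)
  # a token absent from every document simply has no row (zero mass)
  expect_false("q" %in% stats$token)
})

test_that("corpus scores equal the naive double-loop oracle", {
  set.seed(42)
  for (rep in 1:8) {
    n_docs <- sample(2:10, 1)
    docs <- lapply(seq_len(n_docs), function(i)
      sample(letters[1:8], sample(3:12, 1), replace = TRUE))
    got <- tfidf_scores(docs)
    ref <- naive_tfidf(docs)
    expect_equal(stats::setNames(got$score, got$token)[names(ref$score)],
                 ref$score, tolerance = 1e-12)
    expect_equal(stats::setNames(got$idf, got$token)[names(ref$idf)],
                 ref$idf, tolerance = 1e-12)
    expect_identical(stats::setNames(got$df, got$token)[names(ref$df)],
                     stats::setNames(as.integer(ref$df), names(ref$df)))
  }
})

test_that("score increases with occurrences at fixed document frequency", {
  # df(w) = 1 in both corpora (D = 3, so IDF = ln(3/2) > 0); only the
  # within-document count of w changes
  base <- list(c("w", "x", "x", "x"), c("y", "z"), c("y", "z"))
  more <- list(c("w", "w", "x", "x"), c("y", "z"), c("y", "z"))
  s1 <- tfidf_scores(base); s2 <- tfidf_scores(more)
  expect_gt(s2$score[s2$token == "w"], s1$score[s1$token == "w"])
})

test_that("top_keywords ranks, tie-breaks and normalises", {
  stats <- data.frame(token = c("c", "b", "a"), score = c(1, 3, 3))
  top2 <- top_keywords(stats, 2)
  expect_identical(top2$token, c("a", "b"))  # lexicographic tie-break
  expect_equal(sum(top2$normalized_share), 1, tolerance = 1e-12)
  expect_identical(top2$rank, 1:2)

  # top-20 out of a top-100 table
  set.seed(3)
  big <- data.frame(token = sprintf("t%03d", 1:150),
                    score = round(runif(150, 1, 10), 3))
  top100 <- top_keywords(big, 100)
  top20 <- top_keywords(top100, 20, previous = top100)
  expect_identical(top20$token,
                   top100$token[order(-top100$score,
                                      top100$token)][1:20])
  expect_true(all(diff(top20$score) <= 0))
  expect_equal(sum(top20$normalized_share), 1, tolerance = 1e-9)

  # short table is returned whole and flagged
  expect_warning(short <- top_keywords(stats, 5), "short")
  expect_identical(nrow(short), 3L)
  expect_true(attr(short, "short"))
})
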