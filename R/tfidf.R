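# TF-IDF keyword extraction.
#
# Term frequency is normalised within each document (counts divided by
# document length); inverse document frequency uses the smoothed form
# ln(D / (1 + df)). The formula variant that places the word's own document
# frequency in the numerator, ln(df / (sum(df) + 1)), is kept behind
# mode = "literal" for audit only: it is anti-monotone in the wrong direction
# and its prose description ("the more common the word, the closer IDF is to
# 0") uniquely identifies the smoothed form as the intended one.

#' Tokenize a document
#'
#' Splits text into tokens with a pluggable segmenter and removes stop words,
#' preserving token order. Synthetic corpora are pre-tokenized, so a
#' character vector of length greater than one (or a document from an
#' `opinion_corpus`) is passed through segmentation untouched and only
#' filtered. The default segmenter splits on whitespace; any function mapping
#' a string to a character vector (e.g. a Chinese word segmenter) can be
#' supplied instead.
#'
#' @param x A single string, a character vector of tokens, or a document
#'   (list with a `tokens` field).
#' @param stopwords Character vector of tokens to remove (may be empty).
#' @param segmenter Function `character(1) -> character()`; defaults to
#'   whitespace splitting.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("the fire in the city", stopwords = c("the", "in"))
#' @export
tokenize <- function(x, stopwords = character(), segmenter = NULL) {
  tokens <-
    if (is.list(x) && !is.null(x$tokens)) as.character(x$tokens)
    else if (is.character(x) && length(x) == 1) {
      seg <- segmenter %||% function(s) strsplit(trimws(s), "\\s+")[[1]]
      as.character(seg(x))
    } else as.character(x)
  tokens <- tokens[nzchar(tokens)]
  tokens[!(tokens %in% stopwords)]
}

#' Normalised within-document term frequency
#'
#' Each count is divided by the document length, so the returned frequencies
#' sum to 1 and documents of different lengths are comparable.
#'
#' @param tokens Non-empty character vector of tokens (one document).
#' @return Named numeric vector of frequencies summing to 1.
#' @examples
#' term_frequency(c("a", "a", "b", "c"))
#' @export
term_frequency <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0)
    stop("cannot compute term frequencies of an empty document")
  tab <- table(tokens)
  stats::setNames(as.numeric(tab) / length(tokens), names(tab))
}

# documents of a corpus as a plain list of token vectors
corpus_tokens <- function(corpus) {
  if (inherits(corpus, "opinion_corpus"))
    lapply(corpus$documents, `[[`, "tokens")
  else if (is.list(corpus)) lapply(corpus, as.character)
  else stop("`corpus` must be an opinion_corpus or a list of token vectors")
}

document_frequency <- function(corpus) {
  docs <- corpus_tokens(corpus)
  tab <- table(unlist(lapply(docs, unique)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Inverse document frequency
#'
#' Default (`mode = "standard"`): `IDF = ln(D / (1 + df))` where `D` is the
#' number of documents and `df` the number of documents containing the token;
#' the `+ 1` smooths against tokens contained in every document and the value
#' decreases as a token becomes more common. `mode = "literal"` evaluates the
#' unsmoothed variant `ln(df / (sum(df) + 1))` and is intended for audit
#' only. Negative values (possible when `df + 1 > D`) are kept, not clipped.
#'
#' @param corpus An `opinion_corpus` or list of token vectors; non-empty.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return Named numeric vector over the corpus vocabulary.
#' @examples
#' idf <- inverse_document_frequency(list(c("a", "b"), c("a", "c")))
#' @export
inverse_document_frequency <- function(corpus,
                                       mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  docs <- corpus_tokens(corpus)
  if (length(docs) == 0) stop("cannot compute IDF of an empty corpus")
  df <- document_frequency(docs)
  if (mode == "standard") log(length(docs) / (1 + df))
  else log(df / (sum(df) + 1))
}

#' Corpus-level TF-IDF statistics
#'
#' For each document the per-document score of a token is its normalised term
#' frequency times the corpus IDF; corpus-level scores aggregate over
#' documents by sum (default, a frequency-weighted salience) or mean.
#'
#' @inheritParams inverse_document_frequency
#' @param aggregate `"sum"` (default) or `"mean"` over documents.
#' @return A `term_stats` data frame with columns `token`, `count` (total
#'   occurrences), `df`, `idf` and `score`, sorted by decreasing score (ties
#'   broken lexicographically). The attribute `negative_idf` flags whether
#'   any token had a negative IDF.
#' @examples
#' stats <- tfidf_scores(list(c("a", "a", "b"), c("b", "c")))
#' @export
tfidf_scores <- function(corpus, mode = c("standard", "literal"),
                         aggregate = c("sum", "mean")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  docs <- corpus_tokens(corpus)
  if (length(docs) == 0) stop("cannot compute TF-IDF of an empty corpus")
  if (any(lengths(docs) == 0))
    stop("corpus contains an empty document")
  idf <- inverse_document_frequency(docs, mode)
  counts <- table(unlist(docs))
  score <- stats::setNames(numeric(length(counts)), names(counts))
  for (d in docs) {
    tf <- term_frequency(d)
    score[names(tf)] <- score[names(tf)] + tf * idf[names(tf)]
  }
  if (aggregate == "mean") score <- score / length(docs)
  df <- document_frequency(docs)
  out <- data.frame(token = names(score),
                    count = as.integer(counts[names(score)]),
                    df = as.integer(df[names(score)]),
                    idf = as.numeric(idf[names(score)]),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$token), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("term_stats", "data.frame"),
            mode = mode, aggregate = aggregate, n_docs = length(docs),
            negative_idf = any(out$idf < 0))
}

#' Top-K keyword table
#'
#' Selects the K highest-scoring tokens (ties broken lexicographically) and
#' normalises their scores into shares of the table mass. When `previous` is
#' given the selection is restricted to its tokens, e.g. the top 20 out of a
#' previously extracted top 100.
#'
#' @param stats A `term_stats` data frame from [tfidf_scores()], or any data
#'   frame with `token` and `score` columns.
#' @param k Table size (e.g. 100 or 20).
#' @param previous Optional `keyword_table` restricting the candidate tokens.
#' @return A `keyword_table` data frame with columns `rank`, `token`,
#'   `score`, `normalized_share` (summing to 1 over the table). If fewer than
#'   `k` tokens are available all are returned and the attribute `short` is
#'   set.
#' @examples
#' stats <- tfidf_scores(list(c("a", "a", "b"), c("b", "c")))
#' top_keywords(stats, k = 2)
#' @export
top_keywords <- function(stats, k = 100L, previous = NULL) {
  if (!is.data.frame(stats) || !all(c("token", "score") %in% names(stats)))
    stop("`stats` must have `token` and `score` columns")
  if (!is_count(k)) stop("`k` must be a positive integer")
  cand <- as.data.frame(stats)[, c("token", "score")]
  if (!is.null(previous)) cand <- cand[cand$token %in% previous$token, ]
  cand <- cand[order(-cand$score, cand$token), , drop = FALSE]
  short <- nrow(cand) < k
  if (short)
    warning("only ", nrow(cand), " distinct tokens available for k = ", k,
            "; returning a short table")
  top <- utils::head(cand, k)
  total <- sum(top$score)
  if (total <= 0)
    stop("total score of the selected table is not positive; ",
         "cannot normalise shares")
  out <- data.frame(rank = seq_len(nrow(top)),
                    token = top$token,
                    score = top$score,
                    normalized_share = top$score / total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("keyword_table", "data.frame"),
            k = as.integer(k), short = short)
}

#' Write a keyword table as CSV
#'
#' @param table A `keyword_table`.
#' @param path Output CSV path (columns rank, token, score,
#'   normalized_share).
#' @return `path`, invisibly.
#' @export
write_keywords <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
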