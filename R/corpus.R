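# Synthetic microblog corpus generator.
#
# Downstream statistics only see token identities, so tokens are synthetic
# ASCII strings tagged by the dimension vocabulary they come from
# ("od_0001", "bg_0042", ...). Each document mixes its event's four concern
# dimensions (per-document Dirichlet mixture) with a shared background
# vocabulary; within a vocabulary token ranks follow a Zipf law so that a few
# head words dominate, as in real top-keyword profiles.

DIMENSIONS <- c("original_event", "derived_event",
                "public_prediction", "public_expectation")
DIM_PREFIX <- c(original_event = "od", derived_event = "de",
                public_prediction = "pp", public_expectation = "pe")

#' The four concern dimensions
#'
#' Public concern is decomposed into four dimensions: the original event
#' (the anchoring emergency), derived events (incidents occurring during its
#' life cycle), public prediction (what the public expects policy will do)
#' and public expectation (what the public wants policy to do).
#'
#' @return Character vector of the four dimension labels, in canonical order.
#' @export
opinion_dimensions <- function() DIMENSIONS

#' Per-event corpus sizes of the motivating case study
#'
#' Post counts for the seven social-media search queries of the late-2022
#' Chinese COVID-19 policy-adaptation case study (two queries for the Guizhou
#' transfer-truck accident, one for the "20 new rules", three for the
#' Xinjiang fire, one for the Zhejiang people-first policy).
#'
#' @return Named integer vector of corpus sizes.
#' @export
default_event_sizes <- function() {
  c(guizhou_accident = 716L, guizhou_27_killed = 381L,
    new_20_rules = 1844L, xinjiang_fire = 1013L,
    xinjiang_fire_deaths = 1126L, xinjiang_lifting_lockdown = 1841L,
    zhejiang_policy = 622L)
}

#' Configuration for the synthetic corpus generator
#'
#' @param event Event label attached to every generated document.
#' @param n_docs Number of documents (posts) to generate.
#' @param dimension_weights Probability vector over the four dimensions
#'   (order of [opinion_dimensions()]); must sum to 1 within 1e-12.
#' @param separation Probability in `[0, 1]` that a token is drawn from the
#'   document's dimension vocabulary rather than the shared background
#'   vocabulary. Higher values give cleaner dimension structure.
#' @param vocab_sizes Named integer vector with entries for each dimension
#'   plus `background`; all at least 1.
#' @param doc_length_mean Mean tokens per post (Poisson, truncated at 3).
#' @param concentration Dirichlet concentration for the per-document mixture
#'   over dimensions; small values give near-single-topic posts.
#' @param zipf_exponent Exponent of the within-vocabulary Zipf law.
#' @param platforms Platforms sampled uniformly per document.
#' @param start_date First posting date; documents are spread uniformly over
#'   `n_days` days from it.
#' @param n_days Length of the posting window in days.
#' @param seed Integer seed; identical configurations generate identical
#'   corpora.
#' @return An object of class `corpus_config`.
#' @examples
#' cfg <- corpus_config("guizhou_accident", n_docs = 50, seed = 1)
#' @export
corpus_config <- function(event = "event",
                          n_docs = 1000L,
                          dimension_weights = c(0.4, 0.3, 0.15, 0.15),
                          separation = 0.9,
                          vocab_sizes = c(original_event = 400L,
                                          derived_event = 400L,
                                          public_prediction = 400L,
                                          public_expectation = 400L,
                                          background = 600L),
                          doc_length_mean = 10,
                          concentration = 0.8,
                          zipf_exponent = 1.1,
                          platforms = c("weibo", "baidu", "wechat"),
                          start_date = as.Date("2022-11-01"),
                          n_days = 14L,
                          seed = 1L) {
  if (!is.character(event) || length(event) != 1 || !nzchar(event))
    stop("`event` must be a non-empty string")
  if (!is_count(n_docs))
    stop("`n_docs` must be a positive integer")
  if (!is.numeric(dimension_weights) || length(dimension_weights) != 4 ||
      any(is.na(dimension_weights)) || any(dimension_weights < 0))
    stop("`dimension_weights` must be four non-negative numbers")
  if (abs(sum(dimension_weights) - 1) > 1e-12)
    stop("`dimension_weights` must sum to 1 (within 1e-12), got ",
         format(sum(dimension_weights), digits = 15))
  if (is.null(names(dimension_weights)))
    names(dimension_weights) <- DIMENSIONS
  if (!identical(sort(names(dimension_weights)), sort(DIMENSIONS)))
    stop("`dimension_weights` names must be the four dimensions")
  dimension_weights <- dimension_weights[DIMENSIONS]
  if (!is_prob(separation))
    stop("`separation` must be a single probability in [0, 1]")
  need <- c(DIMENSIONS, "background")
  if (is.null(names(vocab_sizes)) ||
      !all(need %in% names(vocab_sizes)))
    stop("`vocab_sizes` must be named with the four dimensions and 'background'")
  vocab_sizes <- vocab_sizes[need]
  if (!all(vapply(vocab_sizes, is_count, logical(1))))
    stop("all `vocab_sizes` must be integers >= 1")
  if (!is.numeric(doc_length_mean) || doc_length_mean <= 0)
    stop("`doc_length_mean` must be positive")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("`concentration` must be positive")
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0)
    stop("`zipf_exponent` must be positive")
  if (!is_count(n_days)) stop("`n_days` must be a positive integer")
  structure(
    list(event = event, n_docs = as.integer(n_docs),
         dimension_weights = dimension_weights,
         separation = separation,
         vocab_sizes = vapply(vocab_sizes, as.integer, integer(1)),
         doc_length_mean = doc_length_mean,
         concentration = concentration,
         zipf_exponent = zipf_exponent,
         platforms = platforms,
         start_date = as.Date(start_date),
         n_days = as.integer(n_days),
         seed = as.integer(seed)),
    class = "corpus_config")
}

#' @export
print.corpus_config <- function(x, ...) {
  cat("<corpus_config>", x$event, "\n")
  cat("  n_docs:", x$n_docs, " separation:", x$separation,
      " doc_length_mean:", x$doc_length_mean, "\n")
  cat("  dimension_weights:",
      paste(sprintf("%s=%.3g", names(x$dimension_weights),
                    x$dimension_weights), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic labelled corpus
#'
#' Draws `n_docs` short documents. For each document a dimension mixture is
#' sampled from a Dirichlet centred on `dimension_weights`; each token then
#' comes from the sampled dimension's Zipf-weighted vocabulary with
#' probability `separation`, otherwise from the shared background vocabulary.
#' The generator's ground truth (token to dimension) is kept in the corpus so
#' downstream recovery can be scored.
#'
#' @param config A [corpus_config()].
#' @return An object of class `opinion_corpus`: a list with `documents`
#'   (each a list with `doc_id`, `event`, `platform`, `timestamp`, `tokens`),
#'   `vocabulary` (sorted distinct observed tokens), `truth` (named character
#'   vector, token to dimension, for every dimension-vocabulary token) and
#'   the generating `config`.
#' @examples
#' corp <- generate_corpus(corpus_config("demo", n_docs = 20, seed = 7))
#' corp
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "corpus_config"))
    stop("`config` must be a corpus_config object")
  vocabs <- lapply(DIMENSIONS, function(d) {
    sprintf("%s_%04d", DIM_PREFIX[[d]], seq_len(config$vocab_sizes[[d]]))
  })
  names(vocabs) <- DIMENSIONS
  bg <- sprintf("bg_%04d", seq_len(config$vocab_sizes[["background"]]))
  pz <- lapply(DIMENSIONS, function(d)
    zipf_probs(config$vocab_sizes[[d]], config$zipf_exponent))
  names(pz) <- DIMENSIONS
  pbg <- zipf_probs(config$vocab_sizes[["background"]], config$zipf_exponent)

  docs <- with_seed(config$seed, {
    lapply(seq_len(config$n_docs), function(i) {
      g <- stats::rgamma(4, shape = config$concentration *
                              config$dimension_weights)
      mix <- if (sum(g) > 0) g / sum(g) else config$dimension_weights
      len <- max(3L, stats::rpois(1, config$doc_length_mean))
      from_dim <- stats::runif(len) < config$separation
      dim_idx <- sample.int(4L, len, replace = TRUE, prob = mix)
      tokens <- character(len)
      nd <- sum(from_dim)
      if (nd > 0) {
        pos <- which(from_dim)
        di <- dim_idx[from_dim]
        for (d in unique(di)) {
          sel <- di == d
          ranks <- sample.int(length(pz[[d]]), sum(sel), replace = TRUE,
                              prob = pz[[d]])
          tokens[pos[sel]] <- vocabs[[d]][ranks]
        }
      }
      if (len - nd > 0) {
        tokens[!from_dim] <- bg[sample.int(length(pbg), len - nd,
                                           replace = TRUE, prob = pbg)]
      }
      list(doc_id = sprintf("%s_%05d", config$event, i),
           event = config$event,
           platform = sample(config$platforms, 1),
           timestamp = format(config$start_date +
                                sample.int(config$n_days, 1) - 1L),
           tokens = tokens)
    })
  })

  truth <- unlist(lapply(DIMENSIONS, function(d) {
    stats::setNames(rep(d, length(vocabs[[d]])), vocabs[[d]])
  }))
  structure(
    list(documents = docs,
         vocabulary = sort(unique(unlist(lapply(docs, `[[`, "tokens")))),
         truth = truth,
         config = config),
    class = "opinion_corpus")
}

#' @export
print.opinion_corpus <- function(x, ...) {
  ev <- unique(vapply(x$documents, `[[`, character(1), "event"))
  cat("<opinion_corpus> ", length(x$documents), " documents (",
      paste(ev, collapse = ", "), "), ",
      length(x$vocabulary), " distinct tokens\n", sep = "")
  invisible(x)
}

# Construct an opinion_corpus from bare token vectors; used by tests and by
# read_corpus. `truth` may be NULL.
as_corpus <- function(token_lists, event = "event", truth = NULL,
                      doc_ids = NULL, platforms = NULL, timestamps = NULL) {
  n <- length(token_lists)
  docs <- lapply(seq_len(n), function(i) {
    list(doc_id = if (is.null(doc_ids)) sprintf("%s_%05d", event, i)
         else doc_ids[[i]],
         event = event,
         platform = if (is.null(platforms)) "weibo" else platforms[[i]],
         timestamp = if (is.null(timestamps)) "2022-11-01"
         else timestamps[[i]],
         tokens = as.character(token_lists[[i]]))
  })
  structure(
    list(documents = docs,
         vocabulary = sort(unique(unlist(token_lists))),
         truth = truth,
         config = NULL),
    class = "opinion_corpus")
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per line with fields `doc_id`, `event`, `platform`,
#' `timestamp` and `tokens`; the generator ground-truth map is stored in a
#' sidecar JSON file so that the round trip is lossless.
#'
#' @param corpus An `opinion_corpus`.
#' @param path Path of the JSONL file.
#' @param truth_path Path of the sidecar truth JSON; defaults to
#'   `<path>.truth.json`. Set `NULL` to skip the sidecar.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns an
#'   `opinion_corpus`.
#' @examples
#' corp <- generate_corpus(corpus_config("demo", n_docs = 5, seed = 1))
#' f <- tempfile(fileext = ".jsonl")
#' write_corpus(corp, f)
#' corp2 <- read_corpus(f)
#' @export
write_corpus <- function(corpus, path,
                         truth_path = paste0(path, ".truth.json")) {
  if (!inherits(corpus, "opinion_corpus"))
    stop("`corpus` must be an opinion_corpus")
  lines <- vapply(corpus$documents, function(d) {
    as.character(jsonlite::toJSON(
      list(doc_id = d$doc_id, event = d$event, platform = d$platform,
           timestamp = d$timestamp, tokens = d$tokens),
      auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(truth_path) && !is.null(corpus$truth)) {
    jsonlite::write_json(as.list(corpus$truth), truth_path,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, truth_path = paste0(path, ".truth.json")) {
  lines <- readLines(path, warn = FALSE)
  docs <- lapply(seq_along(lines), function(i) {
    d <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                  error = function(e)
                    stop("parse error at line ", i, " of '", path, "': ",
                         conditionMessage(e), call. = FALSE))
    if (!all(c("doc_id", "event", "platform", "timestamp", "tokens") %in%
               names(d)))
      stop("parse error at line ", i, " of '", path,
           "': missing document fields", call. = FALSE)
    d$tokens <- as.character(d$tokens)
    d[c("doc_id", "event", "platform", "timestamp", "tokens")]
  })
  truth <- NULL
  if (!is.null(truth_path) && file.exists(truth_path)) {
    tl <- jsonlite::fromJSON(truth_path, simplifyVector = TRUE)
    truth <- stats::setNames(as.character(unlist(tl)), names(tl))
  }
  structure(
    list(documents = docs,
         vocabulary = sort(unique(unlist(lapply(docs, `[[`, "tokens")))),
         truth = truth,
         config = NULL),
    class = "opinion_corpus")
}
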