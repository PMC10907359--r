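# Dimension -> indicator -> seed-word lexicon used to label keyword clusters.

#' Build a dimension/indicator seed lexicon
#'
#' A lexicon is a two-level hierarchy: each of the four concern dimensions
#' holds named indicators, each with a list of seed words. Seed words must be
#' unique across all indicators so that cluster labelling is unambiguous.
#'
#' @param x Nested named list `dimension -> indicator -> character vector of
#'   seed words`. Dimension names must come from [opinion_dimensions()].
#' @return An object of class `dimension_lexicon`.
#' @examples
#' lex <- dimension_lexicon(list(
#'   original_event = list(infections = c("cases", "positive")),
#'   derived_event = list(event_name = c("fire"))))
#' @export
dimension_lexicon <- function(x) {
  if (!is.list(x) || is.null(names(x)) || length(x) == 0)
    stop("lexicon must be a non-empty named list of dimensions")
  bad <- setdiff(names(x), DIMENSIONS)
  if (length(bad))
    stop("unknown dimensions in lexicon: ", paste(bad, collapse = ", "))
  for (d in names(x)) {
    if (!is.list(x[[d]]) || is.null(names(x[[d]])) || length(x[[d]]) == 0)
      stop("dimension '", d, "' must be a named list of indicators")
    x[[d]] <- lapply(x[[d]], as.character)
    if (any(lengths(x[[d]]) == 0))
      stop("dimension '", d, "' has an indicator with no seed words")
  }
  seeds <- unlist(x, use.names = FALSE)
  if (anyDuplicated(seeds))
    stop("seed words must be unique across indicators; duplicated: ",
         paste(unique(seeds[duplicated(seeds)]), collapse = ", "))
  structure(x, class = "dimension_lexicon")
}

#' @export
print.dimension_lexicon <- function(x, ...) {
  cat("<dimension_lexicon>", sum(lengths(x)), "indicators,",
      length(unlist(x)), "seed words\n")
  for (d in names(x))
    cat("  ", d, ": ", paste(names(x[[d]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# long-format view: one row per seed word
lexicon_seeds <- function(lexicon) {
  rows <- list()
  for (d in names(lexicon)) {
    for (ind in names(lexicon[[d]])) {
      rows[[length(rows) + 1L]] <-
        data.frame(dimension = d, indicator = ind,
                   token = lexicon[[d]][[ind]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# one row per indicator, in lexicon order (used for tie-breaking)
lexicon_indicators <- function(lexicon) {
  rows <- list()
  for (d in names(lexicon))
    for (ind in names(lexicon[[d]]))
      rows[[length(rows) + 1L]] <-
        data.frame(dimension = d, indicator = ind, stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' The case-study indicator system
#'
#' The dimension/indicator hierarchy of the motivating COVID-19 case study:
#' original-event and derived-event indicators follow the 5M risk-management
#' decomposition (man, machine, management, environment, mission), while
#' prediction and expectation indicators come from domain expertise.
#' Multi-word seed terms are normalised to underscore-joined lowercase
#' tokens. The duplicate seed "death" (listed historically under both an
#' original-event and a derived-event indicator) is kept only under the
#' original event so that seeds stay unique.
#'
#' @return A `dimension_lexicon` with 4 dimensions and 23 indicators.
#' @export
default_lexicon <- function() {
  dimension_lexicon(list(
    original_event = list(
      epidemic_name = c("covid-19", "epidemic", "pneumonia"),
      infections = c("cases", "positive"),
      virus = "asymptomatic",
      status = c("death", "virus_parameters"),
      policies = c("close_loop", "initial_screening")),
    derived_event = list(
      event_name = c("fire", "transfer"),
      people = c("experts", "out_of_province"),
      materials = "wire_board",
      environment = c("xinjiang", "time"),
      response = c("detection", "prevention"),
      consequence = "injured"),
    public_prediction = list(
      residence = c("mass", "public"),
      vulnerable_groups = "the_elderly",
      measures = c("government", "current"),
      projections = c("according_to", "other_provinces"),
      environment = c("community", "neighborhood"),
      service = c("designated_hospitals", "medical_observation"),
      livelihood = c("high_risk", "local"),
      management = c("recovery", "homestay")),
    public_expectation = list(
      object = c("state", "country"),
      condition = c("public_health", "economy"),
      requirement = c("optimization", "development"),
      desires = c("release", "scientific"))))
}

#' Seed lexicon from generator ground truth
#'
#' Builds a one-indicator-per-dimension lexicon for a synthetic corpus by
#' taking the most frequent observed tokens of each dimension as seed words.
#' This is how synthetic pipeline runs label their clusters.
#'
#' @param corpus An `opinion_corpus` with a ground-truth map.
#' @param seeds_per_dimension Number of seed words per dimension.
#' @return A `dimension_lexicon`.
#' @export
lexicon_from_truth <- function(corpus, seeds_per_dimension = 8L) {
  if (!inherits(corpus, "opinion_corpus") || is.null(corpus$truth))
    stop("`corpus` must be an opinion_corpus with a truth map")
  counts <- table(unlist(corpus_tokens(corpus)))
  lex <- list()
  for (d in DIMENSIONS) {
    toks <- names(corpus$truth)[corpus$truth == d]
    toks <- toks[toks %in% names(counts)]
    if (length(toks) == 0) next
    toks <- toks[order(-as.numeric(counts[toks]), toks)]
    lex[[d]] <- list(core_terms = utils::head(toks, seeds_per_dimension))
  }
  dimension_lexicon(lex)
}

#' Read / write a lexicon as JSON
#'
#' JSON layout: `{dimension: {indicator: [seed words]}}`.
#'
#' @param lexicon A `dimension_lexicon`.
#' @param path File path.
#' @return `read_lexicon` returns a `dimension_lexicon`; `write_lexicon`
#'   returns `path` invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  jsonlite::write_json(unclass(lexicon), path)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  dimension_lexicon(jsonlite::fromJSON(path, simplifyVector = TRUE))
}
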