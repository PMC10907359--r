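# Dimension-level concern shares, the satisfaction statistic and discrete
# opinion states.
#
# The satisfaction statistic is defined as the original-event share of the
# assigned top-K keyword mass: attention still flowing to the original event
# (rather than to derived incidents or to demands for new policy) is read as
# approval of the current policy. The statistic is pluggable via dimension
# weights so alternative readings can be tested.

#' Dimension-level concern profile of a keyword table
#'
#' Sums the normalised keyword shares of a top-K table by the dimension each
#' token's cluster was mapped to. Tokens missing from the map count as
#' `"unassigned"`; shares over assigned dimensions plus `"unassigned"` sum
#' to 1.
#'
#' @param keywords A `keyword_table` (columns `token`, `normalized_share`).
#' @param dimension_of Named character vector token -> dimension, e.g. from
#'   [token_dimension_map()].
#' @param event Event label stored with the profile.
#' @return An object of class `concern_profile`: list with `event`, `shares`
#'   (named numeric over the four dimensions plus `"unassigned"`), and the
#'   keyword `table` augmented with a `dimension` column.
#' @examples
#' tab <- structure(data.frame(rank = 1:2, token = c("cases", "fire"),
#'                             score = c(3, 1),
#'                             normalized_share = c(0.75, 0.25)),
#'                  class = c("keyword_table", "data.frame"))
#' concern_profile(tab, c(cases = "original_event", fire = "derived_event"))
#' @export
concern_profile <- function(keywords, dimension_of, event = "") {
  if (!is.data.frame(keywords) || nrow(keywords) == 0)
    stop("empty keyword table")
  if (!all(c("token", "normalized_share") %in% names(keywords)))
    stop("`keywords` must have token and normalized_share columns")
  if (any(keywords$normalized_share < 0))
    stop("negative keyword shares; concern shares are undefined")
  dims <- if (length(dimension_of) == 0) rep(NA_character_, nrow(keywords))
          else as.character(dimension_of[keywords$token])
  dims[is.na(dims)] <- "unassigned"
  levels <- c(DIMENSIONS, "unassigned")
  dims[!(dims %in% levels)] <- "unassigned"
  shares <- vapply(levels, function(d)
    sum(keywords$normalized_share[dims == d]), numeric(1))
  # residual mass of a table whose shares do not sum to 1 is unassigned
  shares[["unassigned"]] <- shares[["unassigned"]] +
    max(0, 1 - sum(keywords$normalized_share))
  tab <- as.data.frame(keywords)
  tab$dimension <- dims
  structure(list(event = event, shares = shares, table = tab),
            class = "concern_profile")
}

#' @export
print.concern_profile <- function(x, ...) {
  cat("<concern_profile>", if (nzchar(x$event)) x$event, "\n")
  for (d in names(x$shares))
    cat(sprintf("  %-20s %.3f\n", d, x$shares[[d]]))
  invisible(x)
}

#' Satisfaction statistic of a concern profile
#'
#' Default: the concern share of the original-event dimension within the
#' assigned (non-`unassigned`) top-K mass. Alternative weightings are
#' selected by giving per-dimension weights; satisfaction is then the
#' weighted mean of the renormalised assigned shares.
#'
#' @param profile A `concern_profile`.
#' @param weights Optional named numeric vector over dimensions in `[0, 1]`;
#'   the default `c(original_event = 1)` (all other dimensions 0) yields the
#'   original-event share.
#' @return Satisfaction fraction in `[0, 1]`.
#' @examples
#' # a profile fully concentrated on the original event has satisfaction 1
#' @export
satisfaction <- function(profile, weights = NULL) {
  if (!inherits(profile, "concern_profile"))
    stop("`profile` must be a concern_profile")
  assigned <- profile$shares[DIMENSIONS]
  total <- sum(assigned)
  if (total <= 0)
    stop("profile has zero assigned mass; satisfaction is undefined")
  if (is.null(weights)) weights <- c(original_event = 1)
  w <- stats::setNames(numeric(length(DIMENSIONS)), DIMENSIONS)
  bad <- setdiff(names(weights), DIMENSIONS)
  if (length(bad)) stop("unknown dimensions in weights: ",
                        paste(bad, collapse = ", "))
  w[names(weights)] <- weights
  if (any(w < 0) || any(w > 1)) stop("weights must be in [0, 1]")
  sum(w * assigned / total)
}

#' Discretise satisfaction into an opinion state
#'
#' Satisfaction at or above the high threshold maps to support (1), at or
#' below the low threshold to opposition (0), and to neutrality (0.5) in
#' between. These are the observation symbols of the opinion-policy HMM.
#'
#' @param satisfaction Satisfaction fraction(s) in `[0, 1]`.
#' @param thresholds Numeric `c(low, high)` with `0 <= low < high <= 1`;
#'   defaults `c(0.4, 0.6)`, symmetric around neutrality.
#' @return Numeric state code(s) in `{1, 0.5, 0}` named with the state
#'   label(s) (`support`, `neutral`, `oppose`).
#' @examples
#' opinion_state(c(0.73, 0.35, 0.5))
#' @export
opinion_state <- function(satisfaction, thresholds = c(low = 0.4,
                                                       high = 0.6)) {
  if (!is.numeric(thresholds) || length(thresholds) != 2 ||
      any(is.na(thresholds)))
    stop("`thresholds` must be two numbers c(low, high)")
  low <- thresholds[[1]]; high <- thresholds[[2]]
  if (!(low >= 0 && low < high && high <= 1))
    stop("thresholds must satisfy 0 <= low < high <= 1")
  if (!is.numeric(satisfaction) || any(is.na(satisfaction)) ||
      any(satisfaction < 0 | satisfaction > 1))
    stop("`satisfaction` must be in [0, 1]")
  state <- ifelse(satisfaction >= high, 1,
                  ifelse(satisfaction <= low, 0, 0.5))
  labels <- c(`1` = "support", `0.5` = "neutral", `0` = "oppose")
  stats::setNames(state, labels[as.character(state)])
}

#' Chronological opinion observation sequence
#'
#' Converts an ordered series of event checkpoints (concern profiles or bare
#' satisfaction values) into the observation sequence consumed by the
#' opinion-policy HMM.
#'
#' @param x A list of `concern_profile` objects in chronological order, or a
#'   numeric vector of satisfaction values (optionally named by event).
#' @param thresholds Passed to [opinion_state()].
#' @param weights Passed to [satisfaction()] when `x` holds profiles.
#' @return An `opinion_sequence` data frame with columns `checkpoint`,
#'   `event`, `satisfaction`, `state`, `label`.
#' @examples
#' opinion_sequence(c(0.73, 0.37, 0.35, 0.29))
#' @export
opinion_sequence <- function(x, thresholds = c(low = 0.4, high = 0.6),
                             weights = NULL) {
  if (length(x) == 0) stop("empty checkpoint sequence")
  if (is.list(x) && all(vapply(x, inherits, logical(1), "concern_profile"))) {
    sats <- vapply(x, satisfaction, numeric(1), weights = weights)
    events <- vapply(x, `[[`, character(1), "event")
  } else if (is.numeric(x)) {
    sats <- as.numeric(x)
    events <- names(x) %||% sprintf("checkpoint_%d", seq_along(x))
  } else {
    stop("`x` must be a list of concern profiles or numeric satisfactions")
  }
  states <- opinion_state(sats, thresholds)
  out <- data.frame(checkpoint = seq_along(sats), event = events,
                    satisfaction = sats, state = as.numeric(states),
                    label = names(states), stringsAsFactors = FALSE)
  structure(out, class = c("opinion_sequence", "data.frame"),
            thresholds = thresholds)
}
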