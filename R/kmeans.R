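# Word vectors over documents and Lloyd K-means with k-means++-style seeding.
#
# Each keyword's vector lives in document space: entry d is the token's
# per-document TF-IDF weight in document d (optionally L2-normalised), so
# tokens that co-occur across the same posts sit close together. The
# clustering loss is J(c, p) = sum_i ||x_i - p_{c_i}||^2, minimised by
# alternating nearest-centroid assignment and centroid update.

#' Build TF-IDF word vectors for a keyword set
#'
#' @param corpus An `opinion_corpus` or list of token vectors.
#' @param keywords A `keyword_table` (from [top_keywords()]) or character
#'   vector of tokens; every token must occur in at least one document.
#' @param mode IDF mode passed to [inverse_document_frequency()].
#' @param normalize L2-normalise each token's vector (default `TRUE`), so
#'   distances compare co-occurrence profiles rather than raw salience.
#' @return An object of class `word_vectors`: list with `tokens`, `vectors`
#'   (tokens-by-documents matrix) and `normalized`.
#' @examples
#' wv <- build_word_vectors(list(c("a", "b"), c("a", "c")), c("a", "b"))
#' @export
build_word_vectors <- function(corpus, keywords,
                               mode = c("standard", "literal"),
                               normalize = TRUE) {
  mode <- match.arg(mode)
  docs <- corpus_tokens(corpus)
  tokens <- if (is.data.frame(keywords)) keywords$token
            else as.character(keywords)
  if (anyDuplicated(tokens)) stop("duplicate keywords")
  idf <- inverse_document_frequency(docs, mode)
  missing <- setdiff(tokens, names(idf))
  if (length(missing))
    stop("keyword(s) absent from corpus: ",
         paste(utils::head(missing, 5), collapse = ", "))
  M <- matrix(0, nrow = length(tokens), ncol = length(docs),
              dimnames = list(tokens, NULL))
  for (j in seq_along(docs)) {
    tf <- term_frequency(docs[[j]])
    keep <- intersect(names(tf), tokens)
    if (length(keep))
      M[keep, j] <- as.numeric(tf[keep]) * as.numeric(idf[keep])
  }
  if (normalize) {
    nrm <- sqrt(rowSums(M^2))
    if (any(nrm == 0))
      stop("all-zero vector for token(s): ",
           paste(utils::head(tokens[nrm == 0], 5), collapse = ", "))
    M <- M / nrm
  }
  structure(list(tokens = tokens, vectors = M, normalized = normalize),
            class = "word_vectors")
}

#' @export
print.word_vectors <- function(x, ...) {
  cat("<word_vectors> ", length(x$tokens), " tokens x ",
      ncol(x$vectors), " documents",
      if (x$normalized) " (L2-normalized)", "\n", sep = "")
  invisible(x)
}

# squared Euclidean distances of rows of x to rows of centers: n x k matrix
sq_dist_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

kmeans_loss <- function(x, centers, assign) {
  sum((x - centers[assign, , drop = FALSE])^2)
}

# Greedy k-means++-style seeded initialisation: first centre uniform; each
# subsequent centre is chosen among several candidates sampled with
# probability proportional to the squared distance from the nearest chosen
# centre, keeping the candidate that most reduces the total potential.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  n_cand <- min(n, 2L + as.integer(ceiling(log(max(k, 2)))) * 2L)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- sq_dist_to_centers(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      cand <- if (sum(d2) <= 0) sample.int(n, n_cand)
              else sample.int(n, n_cand, prob = pmax(d2, 0) + 1e-300)
      pots <- vapply(cand, function(i) {
        sum(pmin(d2, sq_dist_to_centers(x, x[i, , drop = FALSE])[, 1]))
      }, numeric(1))
      idx <- cand[which.min(pots)]
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, sq_dist_to_centers(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(x, k, tol, max_iter, init = c("pp", "uniform")) {
  init <- match.arg(init)
  n <- nrow(x)
  centers <- if (init == "pp") kmeanspp_init(x, k)
             else x[sample.int(n, k), , drop = FALSE]
  d2 <- sq_dist_to_centers(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  J_prev <- Inf
  J_history <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # update step
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # empty cluster: re-seed at the globally farthest point
        d2c <- sq_dist_to_centers(x, centers)
        nearest <- d2c[cbind(seq_len(n), assign)]
        far <- which.max(nearest)
        centers[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    # assignment step
    d2 <- sq_dist_to_centers(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    J <- sum(d2[cbind(seq_len(n), new_assign)])
    J_history <- c(J_history, J)
    stable <- identical(new_assign, assign)
    assign <- new_assign
    if (stable || (is.finite(J_prev) && J_prev - J < tol) ||
        iter >= max_iter) break
    J_prev <- J
  }
  # final update so centroids are the means of the final assignment
  for (j in seq_len(k)) {
    members <- assign == j
    if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
  }
  J <- kmeans_loss(x, centers, assign)
  J_history <- c(J_history, J)
  list(assignments = assign, centroids = centers, J = J,
       J_history = J_history, iterations = iter)
}

#' K-means clustering of word vectors (Lloyd's algorithm)
#'
#' Minimises the within-cluster sum of squared Euclidean distances
#' `J(c, p) = sum_i ||x_i - p_{c_i}||^2` by Lloyd iterations from a
#' k-means++-style seeded initialisation, restarted `nstart` times keeping
#' the lowest-loss solution. Iterations stop when assignments are stable,
#' the loss improvement falls below `tol`, or `max_iter` is reached; an
#' empty cluster is re-seeded at the point farthest from its centroid. The
#' run is deterministic for a fixed `seed`. The recorded loss history is
#' checked to be non-increasing on every run.
#'
#' @param x A `word_vectors` object or numeric matrix (rows are points).
#' @param k Number of clusters, `1 <= k <=` number of points.
#' @param seed Integer seed controlling initialisation.
#' @param tol Convergence tolerance on the loss decrease.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param nstart Number of seeded restarts.
#' @return An object of class `clustering_result`: list with `k`,
#'   `assignments` (integer vector, named by token when available),
#'   `centroids`, `J`, `J_history` (loss after each iteration of the winning
#'   restart), `iterations`, `seed`.
#' @examples
#' res <- kmeans_lloyd(matrix(c(0, 1, 10, 11), ncol = 1), k = 2, seed = 1)
#' res$J # 1.0
#' @export
kmeans_lloyd <- function(x, k, seed = 1L, tol = 1e-8, max_iter = 300L,
                         nstart = 10L) {
  mat <- if (inherits(x, "word_vectors")) x$vectors else as.matrix(x)
  if (!is.numeric(mat)) stop("`x` must be numeric")
  n <- nrow(mat)
  if (!is_count(k)) stop("`k` must be a positive integer")
  if (k > n) stop("k = ", k, " exceeds the number of points (", n, ")")
  if (!is_count(nstart)) stop("`nstart` must be a positive integer")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(nstart)) {
      # alternate seeding strategies across restarts: distance-weighted
      # (k-means++-style) and uniform sampling of data points
      run <- lloyd_once(mat, k, tol, max_iter,
                        init = if (r %% 2 == 1) "pp" else "uniform")
      if (any(diff(run$J_history) > 1e-9 * max(1, run$J_history[1])))
        stop("internal error: loss increased across Lloyd iterations")
      if (is.null(best) || run$J < best$J) best <- run
    }
  })
  names(best$assignments) <- rownames(mat)
  structure(
    list(k = as.integer(k), assignments = best$assignments,
         centroids = best$centroids, J = best$J,
         J_history = best$J_history, iterations = best$iterations,
         seed = as.integer(seed), tol = tol),
    class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result> k =", x$k, " J =", format(x$J, digits = 6),
      " (", x$iterations, "iterations )\n")
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Label clusters with dimensions and indicators
#'
#' Each cluster is labelled by the indicator whose seed words overlap its
#' tokens the most; ties are broken by lexicon order and clusters with no
#' seed-word overlap are labelled `"unassigned"`.
#'
#' @param result A `clustering_result` with token-named assignments.
#' @param lexicon A `dimension_lexicon`.
#' @return Data frame with one row per cluster: `cluster`, `dimension`,
#'   `indicator`, `n_seed_matches`.
#' @export
assign_clusters_to_indicators <- function(result, lexicon) {
  if (!inherits(result, "clustering_result"))
    stop("`result` must be a clustering_result")
  if (!inherits(lexicon, "dimension_lexicon"))
    stop("`lexicon` must be a dimension_lexicon")
  if (is.null(names(result$assignments)))
    stop("cluster assignments carry no token names")
  seeds <- lexicon_seeds(lexicon)
  inds <- lexicon_indicators(lexicon)
  rows <- lapply(seq_len(result$k), function(cl) {
    toks <- names(result$assignments)[result$assignments == cl]
    overlap <- vapply(seq_len(nrow(inds)), function(i) {
      sw <- lexicon[[inds$dimension[i]]][[inds$indicator[i]]]
      sum(sw %in% toks)
    }, integer(1))
    if (all(overlap == 0)) {
      data.frame(cluster = cl, dimension = "unassigned",
                 indicator = "unassigned", n_seed_matches = 0L,
                 stringsAsFactors = FALSE)
    } else {
      i <- which.max(overlap) # first maximum = lexicon order tie-break
      data.frame(cluster = cl, dimension = inds$dimension[i],
                 indicator = inds$indicator[i],
                 n_seed_matches = overlap[i], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Token-to-dimension map implied by a labelled clustering
#'
#' @param result A `clustering_result` with token-named assignments.
#' @param mapping Output of [assign_clusters_to_indicators()].
#' @return Named character vector token -> dimension (possibly
#'   `"unassigned"`).
#' @export
token_dimension_map <- function(result, mapping) {
  dims <- stats::setNames(mapping$dimension, mapping$cluster)
  stats::setNames(as.character(dims[as.character(result$assignments)]),
                  names(result$assignments))
}
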