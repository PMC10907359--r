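# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation.

# Reference TF-IDF by double loop over documents and vocabulary.
# Returns list(score, df, idf) named by token; standard smoothed IDF.
naive_tfidf <- function(docs) {
  vocab <- sort(unique(unlist(docs)))
  D <- length(docs)
  df <- sapply(vocab, function(w) sum(sapply(docs, function(d) w %in% d)))
  idf <- log(D / (1 + df))
  score <- sapply(vocab, function(w) {
    s <- 0
    for (d in docs) {
      f <- sum(d == w)
      if (f > 0) s <- s + (f / length(d)) * idf[[w]]
    }
    s
  })
  list(score = score, df = df, idf = idf)
}

# Minimum k-means loss over every assignment of n points to k clusters.
exhaustive_kmeans_J <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k^n <= 2e5)
  grids <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    a <- as.integer(grids[r, ])
    J <- 0
    for (cl in unique(a)) {
      pts <- x[a == cl, , drop = FALSE]
      ctr <- colMeans(pts)
      J <- J + sum(sweep(pts, 2, ctr)^2)
    }
    if (J < best) best <- J
  }
  best
}

# Filtered posteriors and likelihood by explicit enumeration of all hidden
# paths (feasible for T <= 8 with two states).
brute_filter <- function(spec, obs_idx) {
  n <- spec$n
  T_len <- length(obs_idx)
  post <- matrix(0, T_len, n)
  for (t in seq_len(T_len)) {
    paths <- do.call(expand.grid, rep(list(seq_len(n)), t))
    joint <- numeric(n)
    for (r in seq_len(nrow(paths))) {
      p <- as.integer(paths[r, ])
      pr <- spec$pi[p[1]] * spec$B[p[1], obs_idx[1]]
      if (t > 1) {
        for (u in 2:t)
          pr <- pr * spec$A[p[u - 1], p[u]] * spec$B[p[u], obs_idx[u]]
      }
      joint[p[t]] <- joint[p[t]] + pr
    }
    post[t, ] <- joint / sum(joint)
    if (t == T_len) lik <- sum(joint)
  }
  list(posterior = post, log_likelihood = log(lik))
}

# tiny corpus constructor from bare token vectors
tiny_corpus <- function(...) {
  opinionflow:::as_corpus(list(...))
}

random_hmm_spec <- function(seed, n = 2, m = 3) {
  set.seed(seed)
  rows <- function(r, c) t(apply(matrix(runif(r * c, 0.05, 1), r), 1,
                                 function(z) z / sum(z)))
  hmm_spec(pi = as.numeric(rows(1, n)), A = rows(n, n), B = rows(n, m),
           states = setNames(seq(n, 1), paste0("S", seq_len(n))),
           symbols = setNames(seq_len(m) / m, paste0("V", seq_len(m))))
}
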