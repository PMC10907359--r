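# Discrete opinion-policy hidden Markov model.
#
# Hidden states are the emergency-management agency's policy intent
# (Continue = 1, Change = 0); observations are the discretised public
# opinion states (Support = 1, Neutral = 0.5, Opposed = 0). The model
# phi = (A, B, pi) is a dual stochastic process: a Markov chain over policy
# intent plus state-conditional random emission of opinion symbols.

#' Construct a discrete hidden Markov model specification
#'
#' @param pi Initial state probability vector (length `n`).
#' @param A `n x n` state transition matrix, `A[i, j] = P(state j at t+1 |
#'   state i at t)`; rows must sum to 1 within 1e-12.
#' @param B `n x m` observation matrix, `B[j, k] = P(symbol k | state j)`;
#'   rows must sum to 1 within 1e-12.
#' @param states Named numeric vector of hidden-state codes, e.g.
#'   `c(Continue = 1, Change = 0)`.
#' @param symbols Named numeric vector of observation values, e.g.
#'   `c(Support = 1, Neutral = 0.5, Opposed = 0)`.
#' @return An object of class `hmm_spec`.
#' @examples
#' spec <- opinion_policy_hmm()
#' spec$A
#' @export
hmm_spec <- function(pi, A, B,
                     states = c(Continue = 1, Change = 0),
                     symbols = c(Support = 1, Neutral = 0.5, Opposed = 0)) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- length(states); m <- length(symbols)
  if (is.null(names(states)) || is.null(names(symbols)))
    stop("`states` and `symbols` must be named numeric vectors")
  if (length(pi) != n || nrow(A) != n || ncol(A) != n ||
      nrow(B) != n || ncol(B) != m)
    stop("dimension mismatch between pi (", length(pi), "), A (",
         nrow(A), "x", ncol(A), "), B (", nrow(B), "x", ncol(B),
         ") and the ", n, " states / ", m, " symbols")
  if (any(pi < 0) || any(A < 0) || any(B < 0))
    stop("probabilities must be non-negative")
  if (abs(sum(pi) - 1) > 1e-12)
    stop("pi must sum to 1 within 1e-12")
  if (any(abs(rowSums(A) - 1) > 1e-12))
    stop("each row of A must sum to 1 within 1e-12")
  if (any(abs(rowSums(B) - 1) > 1e-12))
    stop("each row of B must sum to 1 within 1e-12")
  dimnames(A) <- list(names(states), names(states))
  dimnames(B) <- list(names(states), names(symbols))
  structure(list(states = states, symbols = symbols, n = n, m = m,
                 pi = stats::setNames(as.numeric(pi), names(states)),
                 A = A, B = B),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, digits = 3, ...) {
  cat("<hmm_spec> ", x$n, " hidden states (",
      paste(sprintf("%s=%g", names(x$states), x$states), collapse = ", "),
      "), ", x$m, " symbols (",
      paste(sprintf("%s=%g", names(x$symbols), x$symbols), collapse = ", "),
      ")\n", sep = "")
  cat("pi:\n"); print(round(x$pi, digits))
  cat("A (transitions):\n"); print(round(x$A, digits))
  cat("B (emissions):\n"); print(round(x$B, digits))
  invisible(x)
}

#' The case-study opinion-policy HMM parameters
#'
#' The two-state opinion-policy model of the motivating case study: the
#' agency starts certain to continue its policy, `pi = (1, 0)`; policy
#' intent persists with probability 0.7 and switches with probability 0.3 in
#' both directions; a continuing (satisfied) state emits
#' support/neutral/opposed with probabilities (0.6, 0.3, 0.1) and a changing
#' (dissatisfied) state with (0.1, 0.3, 0.6).
#'
#' @return An `hmm_spec`.
#' @examples
#' opinion_policy_hmm()
#' @export
opinion_policy_hmm <- function() {
  hmm_spec(pi = c(1, 0),
           A = matrix(c(0.7, 0.3,
                        0.3, 0.7), 2, 2, byrow = TRUE),
           B = matrix(c(0.6, 0.3, 0.1,
                        0.1, 0.3, 0.6), 2, 3, byrow = TRUE))
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `A` for eigenvalue 1, normalised to sum to 1.
#'
#' @param A Row-stochastic matrix (or an `hmm_spec`, whose `A` is used).
#' @return Numeric stationary probability vector.
#' @examples
#' stationary_distribution(opinion_policy_hmm()) # (0.5, 0.5)
#' @export
stationary_distribution <- function(A) {
  if (inherits(A, "hmm_spec")) A <- A$A
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), rownames(A))
}

# map observations given as numeric values or labels to symbol indices
symbol_index <- function(spec, observations) {
  if (is.character(observations)) {
    idx <- match(observations, names(spec$symbols))
  } else if (is.numeric(observations)) {
    idx <- match(as.numeric(observations), as.numeric(spec$symbols))
  } else stop("observations must be numeric values or symbol labels")
  if (any(is.na(idx)))
    stop("observation(s) outside the symbol set: ",
         paste(utils::head(unique(observations[is.na(idx)]), 5),
               collapse = ", "))
  idx
}

#' Sample a state/observation trajectory
#'
#' `i_1 ~ pi`; `i_{t+1} ~ A[i_t, ]`; `o_t ~ B[i_t, ]`. Deterministic for a
#' fixed seed.
#'
#' @param spec An `hmm_spec`.
#' @param n_steps Trajectory length `T >= 1`.
#' @param seed Integer seed.
#' @return An `hmm_trajectory` data frame with columns `t`, `state` (label),
#'   `state_code`, `observation` (label), `observation_value`.
#' @examples
#' traj <- sample_trajectory(opinion_policy_hmm(), 5, seed = 1)
#' @export
sample_trajectory <- function(spec, n_steps, seed = 1L) {
  if (!inherits(spec, "hmm_spec")) stop("`spec` must be an hmm_spec")
  if (!is_count(n_steps)) stop("`n_steps` must be a positive integer")
  n_steps <- as.integer(n_steps)
  with_seed(seed, {
    states <- integer(n_steps)
    states[1] <- sample.int(spec$n, 1, prob = spec$pi)
    if (n_steps > 1) {
      for (t in 2:n_steps)
        states[t] <- sample.int(spec$n, 1, prob = spec$A[states[t - 1], ])
    }
    obs <- vapply(states, function(s)
      sample.int(spec$m, 1, prob = spec$B[s, ]), integer(1))
    out <- data.frame(
      t = seq_len(n_steps),
      state = names(spec$states)[states],
      state_code = as.numeric(spec$states[states]),
      observation = names(spec$symbols)[obs],
      observation_value = as.numeric(spec$symbols[obs]),
      stringsAsFactors = FALSE)
    structure(out, class = c("hmm_trajectory", "data.frame"),
              seed = as.integer(seed))
  })
}

#' Ensemble simulation with per-step averages
#'
#' Samples `n_runs` independent trajectories (run seeds derived
#' deterministically from the master seed) and averages the numeric
#' observation values and state codes per time step; the case study uses
#' `n_runs = 10`.
#'
#' @inheritParams sample_trajectory
#' @param n_runs Number of independent runs (default 10).
#' @return An `hmm_ensemble` data frame with columns `t`, `mean_state`,
#'   `mean_observation`; attributes `n_runs`, `seed` and `grand_means`
#'   (overall time-and-run averages).
#' @examples
#' ens <- simulate_ensemble(opinion_policy_hmm(), n_steps = 4, n_runs = 10,
#'                          seed = 1)
#' @export
simulate_ensemble <- function(spec, n_steps, n_runs = 10L, seed = 1L) {
  if (!is_count(n_runs)) stop("`n_runs` must be a positive integer")
  obs <- matrix(0, n_runs, n_steps)
  st <- matrix(0, n_runs, n_steps)
  for (r in seq_len(n_runs)) {
    traj <- sample_trajectory(spec, n_steps,
                              seed = derive_seed(seed, paste0("run", r)))
    obs[r, ] <- traj$observation_value
    st[r, ] <- traj$state_code
  }
  out <- data.frame(t = seq_len(n_steps),
                    mean_state = colMeans(st),
                    mean_observation = colMeans(obs))
  structure(out, class = c("hmm_ensemble", "data.frame"),
            n_runs = as.integer(n_runs), seed = as.integer(seed),
            grand_means = c(state = mean(st), observation = mean(obs)))
}

#' Forward filtering of the hidden policy state
#'
#' Scaled forward recursion: at each step the filtered posterior
#' `P(state_t | o_1..o_t)` is computed and normalised; the scaling constants
#' accumulate into the log-likelihood of the observation sequence.
#'
#' @param spec An `hmm_spec`.
#' @param observations Numeric observation values (members of the symbol
#'   value set) or symbol labels.
#' @return An object of class `hmm_filter`: list with `posterior` (T-by-n
#'   matrix, rows summing to 1), `log_likelihood`, and the symbol indices
#'   `observations`.
#' @examples
#' forward_filter(opinion_policy_hmm(), c(1, 1))
#' @export
forward_filter <- function(spec, observations) {
  if (!inherits(spec, "hmm_spec")) stop("`spec` must be an hmm_spec")
  if (inherits(observations, "opinion_sequence"))
    observations <- observations$state
  idx <- symbol_index(spec, observations)
  T_len <- length(idx)
  if (T_len == 0) stop("empty observation sequence")
  post <- matrix(0, T_len, spec$n,
                 dimnames = list(NULL, names(spec$states)))
  loglik <- 0
  alpha <- spec$pi * spec$B[, idx[1]]
  for (t in seq_len(T_len)) {
    if (t > 1) alpha <- as.numeric(alpha %*% spec$A) * spec$B[, idx[t]]
    c_t <- sum(alpha)
    if (c_t <= 0)
      stop("observation at step ", t, " has zero probability under the model")
    alpha <- alpha / c_t
    loglik <- loglik + log(c_t)
    post[t, ] <- alpha
  }
  structure(list(posterior = post, log_likelihood = loglik,
                 observations = idx),
            class = "hmm_filter")
}

#' @export
print.hmm_filter <- function(x, digits = 4, ...) {
  cat("<hmm_filter> T =", nrow(x$posterior),
      " log-likelihood =", format(x$log_likelihood, digits = 6), "\n")
  print(round(x$posterior, digits))
  invisible(x)
}

#' Read / write an HMM specification as JSON
#'
#' @param spec An `hmm_spec`.
#' @param path File path.
#' @return `read_hmm_spec` returns an `hmm_spec`; `write_hmm_spec` returns
#'   `path` invisibly.
#' @export
write_hmm_spec <- function(spec, path) {
  jsonlite::write_json(
    list(states = as.list(spec$states), symbols = as.list(spec$symbols),
         pi = spec$pi, A = spec$A, B = spec$B),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_spec
#' @export
read_hmm_spec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hmm_spec(pi = as.numeric(x$pi), A = x$A, B = x$B,
           states = unlist(x$states), symbols = unlist(x$symbols))
}
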