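# Baum-Welch (EM) estimation of the opinion-policy HMM, with the classic
# fitted-model interface: fit_hmm() returns an "opinion_hmm" object with
# print, summary, coef, logLik and simulate methods.

# one scaled forward-backward pass; obs_idx is a vector of symbol indices
forward_backward <- function(pi, A, B, obs_idx) {
  T_len <- length(obs_idx)
  n <- length(pi)
  alpha <- matrix(0, T_len, n)
  beta <- matrix(0, T_len, n)
  scale <- numeric(T_len)
  a <- pi * B[, obs_idx[1]]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  if (T_len > 1) {
    for (t in 2:T_len) {
      a <- as.numeric(alpha[t - 1, ] %*% A) * B[, obs_idx[t]]
      scale[t] <- sum(a)
      if (scale[t] <= 0) stop("zero-probability observation during EM")
      alpha[t, ] <- a / scale[t]
    }
  }
  beta[T_len, ] <- 1
  if (T_len > 1) {
    for (t in (T_len - 1):1) {
      b <- as.numeric(A %*% (B[, obs_idx[t + 1]] * beta[t + 1, ]))
      beta[t, ] <- b / scale[t + 1]
    }
  }
  list(alpha = alpha, beta = beta, scale = scale,
       loglik = sum(log(scale)))
}

baum_welch_once <- function(spec, seq_idx, tol, max_iter) {
  pi <- as.numeric(spec$pi); A <- unname(spec$A); B <- unname(spec$B)
  n <- spec$n; m <- spec$m
  observed <- sort(unique(unlist(seq_idx)))
  zero_col <- observed[colSums(B[, observed, drop = FALSE]) == 0]
  if (length(zero_col))
    stop("initial emission matrix gives zero probability in every state ",
         "to observed symbol(s): ",
         paste(names(spec$symbols)[zero_col], collapse = ", "))
  history <- numeric(0)
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    pi_acc <- numeric(n)
    A_num <- matrix(0, n, n)
    gamma_sum <- numeric(n)       # sum of gamma over t = 1..T-1 (for A)
    B_num <- matrix(0, n, m)
    gamma_all <- numeric(n)       # sum of gamma over all t (for B)
    loglik <- 0
    for (s in seq_idx) {
      fb <- forward_backward(pi, A, B, s)
      loglik <- loglik + fb$loglik
      T_len <- length(s)
      gamma <- fb$alpha * fb$beta
      gamma <- gamma / rowSums(gamma)
      pi_acc <- pi_acc + gamma[1, ]
      for (k in seq_len(m)) {
        sel <- s == k
        if (any(sel))
          B_num[, k] <- B_num[, k] + colSums(gamma[sel, , drop = FALSE])
      }
      gamma_all <- gamma_all + colSums(gamma)
      if (T_len > 1) {
        for (t in seq_len(T_len - 1)) {
          xi <- (fb$alpha[t, ] %o% (B[, s[t + 1]] * fb$beta[t + 1, ])) * A
          xi <- xi / sum(xi)
          A_num <- A_num + xi
          gamma_sum <- gamma_sum + gamma[t, ]
        }
      }
    }
    history <- c(history, loglik)
    if (is.finite(prev) && loglik < prev - 1e-9)
      stop("internal error: EM log-likelihood decreased (",
           prev, " -> ", loglik, ")")
    converged <- is.finite(prev) && (loglik - prev) < tol
    # M-step
    pi <- pi_acc / sum(pi_acc)
    A_new <- A_num / ifelse(gamma_sum > 0, gamma_sum, 1)
    A_new[gamma_sum == 0, ] <- A[gamma_sum == 0, ]
    A <- A_new / rowSums(A_new)
    B_new <- B_num / ifelse(gamma_all > 0, gamma_all, 1)
    B_new[gamma_all == 0, ] <- B[gamma_all == 0, ]
    B <- B_new / rowSums(B_new)
    if (converged) break
    prev <- loglik
  }
  list(pi = pi, A = A, B = B, loglik = history[length(history)],
       history = history, iterations = length(history),
       converged = converged)
}

# order states canonically: the state with the larger emission probability of
# the highest-value symbol (Support) comes first, matching Continue. Resolves
# the label switching inherent to EM on HMMs.
canonical_order <- function(B, symbols) {
  top <- which.max(symbols)
  order(-B[, top])
}

#' Fit an opinion-policy HMM by Baum-Welch (EM)
#'
#' Estimates `(pi, A, B)` from one or more observation sequences. Starting
#' from `init` (or from `n_restarts` randomly perturbed starts when no init
#' is given), scaled forward-backward E-steps alternate with row-stochastic
#' M-steps; the per-iteration log-likelihood is checked to be non-decreasing
#' and iteration stops when its gain falls below `tol` or at `max_iter`.
#' After fitting, states are relabelled canonically: the state with the
#' higher Support emission becomes Continue.
#'
#' @param sequences A list of observation sequences (numeric symbol values or
#'   labels), or a single sequence.
#' @param init Optional `hmm_spec` used as the single starting point. When
#'   omitted, random row-stochastic starts around a uniform model are drawn.
#' @param states,symbols State/symbol definitions used when `init` is
#'   omitted.
#' @param tol Stop when the log-likelihood gain drops below this.
#' @param max_iter Maximum EM iterations per start.
#' @param n_restarts Number of random starts when `init` is omitted.
#' @param seed Integer seed for the random starts.
#' @return An object of class `opinion_hmm`: list with `spec` (the fitted
#'   `hmm_spec`, canonically relabelled), `log_likelihood`, `history`
#'   (per-iteration log-likelihoods of the winning start), `iterations`,
#'   `converged`, `n_sequences`, `n_obs`.
#' @examples
#' seqs <- lapply(1:5, function(i)
#'   sample_trajectory(opinion_policy_hmm(), 30, seed = i)$observation_value)
#' fit <- fit_hmm(seqs, init = opinion_policy_hmm(), max_iter = 20)
#' @export
fit_hmm <- function(sequences, init = NULL,
                    states = c(Continue = 1, Change = 0),
                    symbols = c(Support = 1, Neutral = 0.5, Opposed = 0),
                    tol = 1e-6, max_iter = 200L, n_restarts = 10L,
                    seed = 1L) {
  if (!is.list(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0) stop("need at least one observation sequence")
  if (any(lengths(sequences) == 0)) stop("empty observation sequence")
  ref <- init %||% hmm_spec(
    pi = rep(1 / length(states), length(states)),
    A = matrix(1 / length(states), length(states), length(states)),
    B = matrix(1 / length(symbols), length(states), length(symbols)),
    states = states, symbols = symbols)
  seq_idx <- lapply(sequences, function(s) symbol_index(ref, s))
  runs <- if (!is.null(init)) {
    list(baum_welch_once(ref, seq_idx, tol, max_iter))
  } else {
    with_seed(seed, {
      lapply(seq_len(n_restarts), function(r) {
        start <- hmm_spec(
          pi = prop.table(stats::runif(ref$n, 0.3, 1)),
          A = t(apply(matrix(stats::runif(ref$n^2, 0.3, 1), ref$n), 1,
                      prop.table)),
          B = t(apply(matrix(stats::runif(ref$n * ref$m, 0.3, 1), ref$n), 1,
                      prop.table)),
          states = ref$states, symbols = ref$symbols)
        baum_welch_once(start, seq_idx, tol, max_iter)
      })
    })
  }
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  ord <- canonical_order(best$B, as.numeric(ref$symbols))
  spec <- hmm_spec(pi = best$pi[ord],
                   A = best$A[ord, ord, drop = FALSE],
                   B = best$B[ord, , drop = FALSE],
                   states = ref$states, symbols = ref$symbols)
  structure(
    list(spec = spec, log_likelihood = best$loglik,
         history = best$history, iterations = best$iterations,
         converged = best$converged,
         n_sequences = length(seq_idx), n_obs = sum(lengths(seq_idx)),
         seed = as.integer(seed)),
    class = "opinion_hmm")
}

#' @export
print.opinion_hmm <- function(x, ...) {
  cat("Opinion-policy HMM fitted by Baum-Welch EM\n")
  cat("  ", x$n_sequences, " sequence(s), ", x$n_obs, " observations; ",
      x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 8), "\n")
  print(x$spec)
  invisible(x)
}

#' @export
summary.opinion_hmm <- function(object, ...) {
  cat("Opinion-policy HMM (Baum-Welch)\n\n")
  print(object$spec)
  cat("\nlog-likelihood: ", format(object$log_likelihood, digits = 8),
      " on ", object$n_obs, " observations (df = ",
      attr(logLik(object), "df"), ")\n", sep = "")
  cat("EM iterations: ", object$iterations,
      if (object$converged) " (converged)" else " (not converged)", "\n",
      sep = "")
  invisible(object)
}

#' @export
logLik.opinion_hmm <- function(object, ...) {
  n <- object$spec$n; m <- object$spec$m
  structure(object$log_likelihood,
            df = (n - 1) + n * (n - 1) + n * (m - 1),
            nobs = object$n_obs, class = "logLik")
}

#' @export
coef.opinion_hmm <- function(object, ...) {
  list(pi = object$spec$pi, A = object$spec$A, B = object$spec$B)
}

#' @export
simulate.opinion_hmm <- function(object, nsim = 1, seed = NULL,
                                 n_steps = 4L, ...) {
  seed <- seed %||% 1L
  lapply(seq_len(nsim), function(r)
    sample_trajectory(object$spec, n_steps,
                      seed = derive_seed(seed, paste0("sim", r))))
}
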