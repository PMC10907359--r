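test_that("the case-study parameterisation is exactly as published", {
  spec <- opinion_policy_hmm()
  expect_equal(unname(spec$pi), c(1, 0))
  expect_equal(unname(spec$A),
               matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE))
  expect_equal(unname(spec$B["Change", ]), c(0.1, 0.3, 0.6))
  expect_equal(unname(spec$B["Continue", ]), c(0.6, 0.3, 0.1))
  expect_equal(rowSums(spec$A), c(Continue = 1, Change = 1))
  expect_equal(rowSums(spec$B), c(Continue = 1, Change = 1))
  expect_equal(unname(spec$symbols), c(1, 0.5, 0))
})

test_that("invalid specifications are rejected", {
  expect_error(hmm_spec(c(0.5, 0.6), diag(2), matrix(0.5, 2, 2),
                        symbols = c(A = 1, B = 0)), "sum to 1")
  expect_error(hmm_spec(c(1, 0), matrix(c(0.9, 0.2, 0.2, 0.8), 2),
                        matrix(1 / 3, 2, 3)), "row of A")
  expect_error(hmm_spec(c(1, 0), diag(2),
                        matrix(c(-0.1, 1.1, 1.1, -0.1), 2),
                        symbols = c(A = 1, B = 0)), "non-negative")
  expect_error(hmm_spec(c(1, 0, 0), diag(2), matrix(1 / 3, 2, 3)),
               "dimension mismatch")
})

test_that("an absorbing chain never leaves its initial state", {
  spec <- hmm_spec(pi = c(1, 0), A = diag(2),
                   B = matrix(c(1, 0, 0, 0, 0, 1), 2, 3, byrow = TRUE))
  traj <- sample_trajectory(spec, 50, seed = 3)
  expect_true(all(traj$state == "Continue"))
  # deterministic emission row -> all observations Support in that state
  expect_true(all(traj$observation == "Support"))
})

test_that("trajectories are deterministic given the seed", {
  spec <- opinion_policy_hmm()
  t1 <- sample_trajectory(spec, 100, seed = 9)
  t2 <- sample_trajectory(spec, 100, seed = 9)
  expect_identical(t1, t2)
  t3 <- sample_trajectory(spec, 100, seed = 10)
  expect_false(identical(t1$observation_value, t3$observation_value))
})

test_that("long-run transition frequencies match the transition matrix", {
  spec <- opinion_policy_hmm()
  traj <- sample_trajectory(spec, 1e5, seed = 123)
  s <- traj$state
  from_cont <- which(s[-length(s)] == "Continue")
  p_cc <- mean(s[from_cont + 1] == "Continue")
  expect_lt(abs(p_cc - 0.7), 0.01)
  # emission frequencies while in Continue
  in_cont <- traj$state == "Continue"
  p_support <- mean(traj$observation[in_cont] == "Support")
  expect_lt(abs(p_support - 0.6), 0.01)
})

test_that("the stationary distribution of the symmetric chain is uniform", {
  expect_equal(unname(stationary_distribution(opinion_policy_hmm())),
               c(0.5, 0.5), tolerance = 1e-12)
  A <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  pi_inf <- stationary_distribution(A)
  expect_equal(as.numeric(pi_inf %*% A), as.numeric(pi_inf),
               tolerance = 1e-12)
})

test_that("ensemble averaging is consistent with single trajectories", {
  spec <- opinion_policy_hmm()
  ens1 <- simulate_ensemble(spec, 20, n_runs = 1, seed = 6)
  traj <- sample_trajectory(spec, 20, seed = derive_seed(6, "run1"))
  expect_equal(ens1$mean_observation, traj$observation_value)
  expect_equal(ens1$mean_state, traj$state_code)
  expect_error(simulate_ensemble(spec, 10, n_runs = 0), "positive integer")
})

test_that("the first-step mean observation matches its expectation 0.75", {
  spec <- opinion_policy_hmm()
  # pi = (1,0): E[o_1] = 0.6*1 + 0.3*0.5 + 0.1*0 = 0.75
  n <- 4000
  ens <- simulate_ensemble(spec, 1, n_runs = n, seed = 21)
  se <- sqrt(0.1125 / n) # var of one draw from the Continue emission row
  expect_lt(abs(ens$mean_observation[1] - 0.75), 3 * se)
})

test_that("forward filtering reproduces hand-derived posteriors", {
  spec <- opinion_policy_hmm()
  f1 <- forward_filter(spec, 1) # one Support observation
  expect_equal(unname(f1$posterior[1, ]), c(1, 0))
  f2 <- forward_filter(spec, c(1, 1))
  expect_equal(unname(f2$posterior[2, ]), c(0.42, 0.03) / 0.45,
               tolerance = 1e-12)
  expect_equal(unname(f2$posterior[2, ]), c(0.9333, 0.0667),
               tolerance = 1e-4)
  # labels are accepted too
  f2b <- forward_filter(spec, c("Support", "Support"))
  expect_equal(f2$posterior, f2b$posterior)
  expect_error(forward_filter(spec, c(1, 0.7)), "outside the symbol set")
})

test_that("filtering matches brute-force path enumeration", {
  set.seed(14)
  for (rep in 1:5) {
    spec <- random_hmm_spec(seed = rep)
    T_len <- sample(2:8, 1)
    obs <- sample.int(spec$m, T_len, replace = TRUE)
    got <- forward_filter(spec, names(spec$symbols)[obs])
    ref <- brute_filter(spec, obs)
    expect_equal(unname(got$posterior), ref$posterior, tolerance = 1e-10)
    expect_equal(got$log_likelihood, ref$log_likelihood,
                 tolerance = 1e-10)
  }
})

test_that("uninformative emissions reduce filtering to the Markov prediction", {
  spec <- hmm_spec(pi = c(0.8, 0.2),
                   A = matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE),
                   B = matrix(1 / 3, 2, 3))
  obs <- c(1, 0.5, 0, 1)
  got <- forward_filter(spec, obs)
  pred <- spec$pi
  for (t in seq_along(obs)) {
    if (t > 1) pred <- as.numeric(pred %*% spec$A)
    expect_equal(unname(got$posterior[t, ]), unname(pred),
                 tolerance = 1e-12)
  }
})

test_that("HMM specifications survive a JSON round trip", {
  spec <- opinion_policy_hmm()
  f <- tempfile(fileext = ".json")
  write_hmm_spec(spec, f)
  back <- read_hmm_spec(f)
  expect_equal(back$pi, spec$pi)
  expect_equal(back$A, spec$A)
  expect_equal(back$B, spec$B)
  expect_equal(back$symbols, spec$symbols)
})

test_that("EM from the truth stays at the truth with monotone log-likelihood", {
  spec <- opinion_policy_hmm()
  seqs <- lapply(1:30, function(i)
    sample_trajectory(spec, 60, seed = 100 + i)$observation_value)
  fit <- fit_hmm(seqs, init = spec, tol = 1e-3, max_iter = 200)
  expect_true(all(diff(fit$history) >= -1e-9))
  expect_true(fit$converged)
  # the truth is (close to) a fixed point: parameters barely move
  expect_lt(max(abs(coef(fit)$A - spec$A)), 0.1)
  expect_lt(max(abs(coef(fit)$B - spec$B)), 0.1)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 1 + 2 + 4)
  expect_equal(attr(ll, "nobs"), 30L * 60L)
})

test_that("EM log-likelihood is monotone from arbitrary starts", {
  spec <- opinion_policy_hmm()
  seqs <- lapply(1:10, function(i)
    sample_trajectory(spec, 40, seed = 200 + i)$observation_value)
  fit <- fit_hmm(seqs, n_restarts = 4, max_iter = 60, seed = 2)
  expect_true(all(diff(fit$history) >= -1e-9))
  # canonical relabelling: Continue has the larger Support emission
  expect_gte(fit$spec$B["Continue", "Support"],
             fit$spec$B["Change", "Support"])
})

test_that("EM rejects inits that zero out an observed symbol", {
  bad <- hmm_spec(pi = c(1, 0),
                  A = matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE),
                  B = matrix(c(0.7, 0.3, 0, 0.4, 0.6, 0), 2, byrow = TRUE))
  expect_error(fit_hmm(list(c(1, 0.5, 0)), init = bad),
               "zero probability")
})
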