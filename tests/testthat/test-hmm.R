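test_that("initial state split follows the methylation cutoff", {
  st <- initialize_states(c(0.05, 0.95, 0.50), cutoff = 0.6)[[1]]
  expect_identical(st, c(1L, 2L, 1L))
  # boundary value belongs to LOW by the <= convention
  expect_identical(initialize_states(0.6)[[1]], 1L)
  expect_identical(initialize_states(rep(0.9, 5))[[1]], rep(2L, 5))
  # the inverted orientation reproduces the literal published grouping
  expect_identical(initialize_states(c(0.05, 0.95), orientation = "low_above")[[1]],
                   c(2L, 1L))
  expect_error(initialize_states(list(numeric(0))), "empty")
  expect_error(initialize_states(c(0.1, 0.2), cutoff = 1.2), "cutoff")
})

test_that("transition estimates are pooled pseudocounted pair frequencies", {
  # single chain L,L,H,H,H: pairs L->L 1, L->H 1, H->H 2
  tr <- estimate_transitions(list(c(1L, 1L, 2L, 2L, 2L)), pseudocount = 0)
  expect_equal(tr$A, matrix(c(0.5, 0.5, 0, 1), 2L, byrow = TRUE))
  # alternating chain
  tr2 <- estimate_transitions(list(c(1L, 2L, 1L, 2L)), pseudocount = 0)
  expect_equal(tr2$A, matrix(c(0, 1, 1, 0), 2L, byrow = TRUE))
  # unobserved state falls back to uniform under a pseudocount
  tr3 <- estimate_transitions(list(rep(1L, 10)), pseudocount = 0.5)
  expect_equal(tr3$A[2L, ], c(0.5, 0.5))
  expect_equal(rowSums(tr3$A), c(1, 1), tolerance = 1e-12)
  # pooling across chains
  tr4 <- estimate_transitions(list(c(1L, 1L), c(1L, 2L)), pseudocount = 0)
  expect_equal(tr4$A[1L, ], c(0.5, 0.5))
})

test_that("emission estimates are group moments with a sigma floor", {
  em <- estimate_emissions(c(0.1, 0.2, 0.3), c(0.8, 0.9, 1.0))
  expect_equal(em$mu, c(0.2, 0.9))
  expect_equal(em$sigma[1L]^2, 0.01) # sample variance, n-1 denominator
  em2 <- estimate_emissions(c(0.5), c(0.9), sigma_floor = 0.01)
  expect_equal(em2$mu, c(0.5, 0.9))
  expect_equal(em2$sigma, c(0.01, 0.01))
  em3 <- estimate_emissions(rep(0.4, 5), c(0.8, 0.8, 0.8), sigma_floor = 1e-3)
  expect_equal(em3$sigma, c(1e-3, 1e-3))
  expect_error(estimate_emissions(numeric(0), c(0.9)), "cutoff")
})

test_that("joint log-probability matches an independent per-term computation", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      p <- random_hmm_params()
      k <- sample(1:9, 1L)
      obs <- runif(k)
      st <- sample(1:2, k, replace = TRUE)
      expect_equal(log_joint(obs, st, p),
                   ref_log_joint(obs, st, p$pi, p$A, p$mu, p$sigma),
                   tolerance = 1e-10)
    }
  })
  # zero-probability transition on the path
  p <- hmm_params(c(1, 0), matrix(c(1, 0, 0.5, 0.5), 2L, byrow = TRUE),
                  c(0.2, 0.8), c(0.1, 0.1))
  expect_identical(log_joint(c(0.2, 0.8), c(1L, 2L), p), -Inf)
  expect_error(log_joint(c(0.1, 0.2), c(1L), p), "mismatch")
})

test_that("forward-backward posteriors sum to one at every position", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      p <- random_hmm_params()
      chains <- list(runif(40), runif(7))
      fb <- forward_backward(chains, p)
      for (g in fb$gamma) {
        expect_lt(max(abs(rowSums(g) - 1)), 1e-9)
      }
      expect_true(is.finite(fb$loglik))
    }
  })
})

test_that("viterbi equals exhaustive joint maximization on short chains", {
  withr::with_seed(41, {
    for (rep in 1:60) {
      p <- random_hmm_params()
      k <- sample(2:10, 1L)
      obs <- runif(k)
      expect_identical(viterbi(obs, p)[[1]], brute_force_viterbi(obs, p),
                       label = sprintf("case %d", rep))
    }
  })
})

test_that("viterbi handles degenerate cases deterministically", {
  p <- hmm_params(c(0.7, 0.3), diag(2), c(0.5, 0.5), c(0.1, 0.1))
  # identical emissions + identity transitions: path pinned to argmax pi
  expect_identical(viterbi(runif(6), p)[[1]], rep(1L, 6))
  # length-1 chain: argmax of pi * emission
  p2 <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.1, 0.9), c(0.05, 0.05))
  expect_identical(viterbi(0.95, p2)[[1]], 2L)
  expect_error(viterbi(list(numeric(0)), p2), "empty")
})

test_that("Baum-Welch improves monotonically and honours max_iter", {
  true <- hmm_params(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2L),
                     c(0.1, 0.9), c(0.05, 0.05))
  d <- simulate_hmm_chain(600, true, seed = 8)
  init <- initialize_hmm(d$obs, 0.6)
  fit <- baum_welch(d$obs, init, tol = 1e-6, max_iter = 50L)
  expect_gte(min(diff(fit$log_likelihood_trace)), -1e-8)
  # zero iterations: initial parameters untouched, empty trace
  fit0 <- baum_welch(d$obs, init, max_iter = 0L)
  expect_identical(fit0$params, init)
  expect_length(fit0$log_likelihood_trace, 0L)
  expect_false(fit0$converged)
})

test_that("Baum-Welch keeps rows of A and pi normalized", {
  true <- hmm_params(c(0.3, 0.7), matrix(c(0.8, 0.2, 0.2, 0.8), 2L),
                     c(0.15, 0.85), c(0.07, 0.07))
  d <- simulate_hmm_chain(400, true, seed = 13)
  fit <- baum_welch(d$obs, initialize_hmm(d$obs, 0.6), max_iter = 30L)
  expect_lt(max(abs(rowSums(fit$params$A) - 1)), 1e-9)
  expect_lt(abs(sum(fit$params$pi) - 1), 1e-9)
  expect_true(all(fit$params$sigma >= 1e-3))
})

test_that("parameters are recovered from simulated chains", {
  true <- hmm_params(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2L),
                     c(0.1, 0.9), c(0.05, 0.05))
  d <- simulate_hmm_chain(2000, true, seed = 42)
  fit <- baum_welch(d$obs, initialize_hmm(d$obs, 0.6))
  expect_lt(max(abs(fit$params$mu - true$mu)), 0.02)
  expect_lt(max(abs(diag(fit$params$A) - 0.9)), 0.05)
  dec <- viterbi(d$obs, fit$params)[[1]]
  expect_gte(mean(dec == d$states), 0.95)
})

test_that("simulated chains are reproducible from the seed", {
  p <- hmm_params(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2L),
                  c(0.1, 0.9), c(0.05, 0.05))
  expect_identical(simulate_hmm_chain(100, p, seed = 3),
                   simulate_hmm_chain(100, p, seed = 3))
})
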