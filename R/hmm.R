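## Two-state hidden Markov model with truncated-normal emissions.
##
## Observations are beta-values (or region mean beta-values) chained in
## genomic order, one chain per chromosome; chains share one parameter set.
## States are coded 1 = LOW (low-methyl) and 2 = HIGH (high-methyl).

STATE_LOW <- 1L
STATE_HIGH <- 2L
STATE_LABELS <- c("LOW", "HIGH")

#' Construct a two-state HMM parameter set
#'
#' @param pi Length-2 initial state distribution (LOW, HIGH).
#' @param A 2x2 row-stochastic transition matrix, rows/columns ordered
#'   (LOW, HIGH).
#' @param mu Length-2 emission means (underlying normal, before truncation
#'   to \[0, 1\]).
#' @param sigma Length-2 emission standard deviations.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, mu, sigma) {
  pi <- as.numeric(pi)
  A <- matrix(as.numeric(A), 2L, 2L)
  stopifnot(length(pi) == 2L, length(mu) == 2L, length(sigma) == 2L,
            all(sigma > 0), all(pi >= 0), all(A >= 0))
  if (abs(sum(pi) - 1) > 1e-9) stop("'pi' must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop("rows of 'A' must sum to 1")
  structure(
    list(pi = pi, A = A, mu = as.numeric(mu), sigma = as.numeric(sigma)),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Two-state HMM parameters (truncated-normal emissions on [0,1])\n")
  cat(sprintf("  pi:    LOW %.4f  HIGH %.4f\n", x$pi[1], x$pi[2]))
  cat(sprintf("  A:     LOW->LOW %.4f  LOW->HIGH %.4f\n", x$A[1, 1], x$A[1, 2]))
  cat(sprintf("         HIGH->LOW %.4f  HIGH->HIGH %.4f\n", x$A[2, 1], x$A[2, 2]))
  cat(sprintf("  emit:  LOW  mu %.4f sigma %.4f\n", x$mu[1], x$sigma[1]))
  cat(sprintf("         HIGH mu %.4f sigma %.4f\n", x$mu[2], x$sigma[2]))
  invisible(x)
}

check_chains <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  if (!is.list(chains) || length(chains) == 0L) {
    stop("'chains' must be a non-empty list of numeric observation vectors")
  }
  for (ch in chains) {
    if (length(ch) == 0L) stop("empty observation chain")
    if (!is.numeric(ch) || anyNA(ch) || any(ch < 0 | ch > 1)) {
      stop("observations must be finite values in [0, 1]")
    }
  }
  chains
}

#' Initial state assignment by methylation-level cutoff
#'
#' Splits each observation chain into LOW/HIGH groups at a fixed
#' methylation cutoff (default 0.6).  This hard assignment seeds the
#' transition and emission estimates before Baum-Welch refinement.
#'
#' @param chains Numeric vector or list of numeric vectors (one chain per
#'   chromosome), values in \[0, 1\].
#' @param cutoff Cutoff in (0, 1); observations `<= cutoff` are LOW.
#' @param orientation `"low_below"` (the default) assigns LOW to values at
#'   or below the cutoff.  `"low_above"` inverts the rule; it exists only
#'   to reproduce the literal published grouping rule, whose printed
#'   orientation is inconsistent with the low/high emission model.
#' @return List of integer vectors (1 = LOW, 2 = HIGH), one per chain.
#' @export
initialize_states <- function(chains, cutoff = 0.6,
                              orientation = c("low_below", "low_above")) {
  orientation <- match.arg(orientation)
  chains <- check_chains(chains)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1) {
    stop("'cutoff' must be a single value in (0, 1)")
  }
  lapply(chains, function(ch) {
    low <- ch <= cutoff
    if (orientation == "low_above") low <- !low
    ifelse(low, STATE_LOW, STATE_HIGH)
  })
}

#' Estimate transition matrix and initial distribution from state chains
#'
#' Transition probabilities are the pseudocounted frequencies of state
#' changes between adjacent sites, pooled across chains; the initial
#' distribution comes from the states at chain starts.
#'
#' @param states List of integer state vectors (1 = LOW, 2 = HIGH).
#' @param pseudocount Added to every transition/start count (default 0.5)
#'   so unobserved states fall back towards uniform rows.
#' @return List with `A` (2x2 row-stochastic) and `pi` (length 2).
#' @export
estimate_transitions <- function(states, pseudocount = 0.5) {
  if (is.numeric(states)) states <- list(states)
  stopifnot(is.list(states), length(states) > 0L, pseudocount >= 0)
  counts <- matrix(0, 2L, 2L)
  starts <- numeric(2L)
  for (st in states) {
    st <- as.integer(st)
    if (any(!st %in% c(1L, 2L))) stop("states must be coded 1 (LOW) / 2 (HIGH)")
    starts[st[1L]] <- starts[st[1L]] + 1
    if (length(st) >= 2L) {
      from <- st[-length(st)]
      to <- st[-1L]
      for (s in 1:2) for (t in 1:2) {
        counts[s, t] <- counts[s, t] + sum(from == s & to == t)
      }
    }
  }
  A <- (counts + pseudocount) / (rowSums(counts) + 2 * pseudocount)
  pi <- (starts + pseudocount) / (sum(starts) + 2 * pseudocount)
  if (pseudocount == 0) {
    ## rows with no observed transitions fall back to uniform
    bad <- rowSums(counts) == 0
    A[bad, ] <- 0.5
    if (sum(starts) == 0) pi[] <- 0.5
  }
  list(A = A, pi = pi)
}

#' Estimate emission parameters from grouped observations
#'
#' Plain mean / sample standard deviation per state group, with a floor on
#' the standard deviation so that degenerate groups cannot collapse the
#' emission density.
#'
#' @param obs_low,obs_high Observations currently assigned to each state.
#' @param sigma_floor Minimum standard deviation (default 1e-3).
#' @return List with `mu` and `sigma`, each length 2 (LOW, HIGH).
#' @export
estimate_emissions <- function(obs_low, obs_high, sigma_floor = 1e-3) {
  stopifnot(sigma_floor > 0)
  if (length(obs_low) == 0L || length(obs_high) == 0L) {
    stop(paste(
      "a state has zero assigned observations;",
      "choose a different initialization cutoff"
    ))
  }
  one <- function(v) {
    s <- if (length(v) >= 2L) stats::sd(v) else 0
    if (!is.finite(s)) s <- 0
    c(mean(v), max(s, sigma_floor))
  }
  lo <- one(obs_low)
  hi <- one(obs_high)
  list(mu = c(lo[1L], hi[1L]), sigma = c(lo[2L], hi[2L]))
}

#' Initialize HMM parameters from observation chains
#'
#' Convenience composition of [initialize_states()],
#' [estimate_transitions()] and [estimate_emissions()].
#'
#' @inheritParams initialize_states
#' @param pseudocount Transition pseudocount, see [estimate_transitions()].
#' @param sigma_floor Emission floor, see [estimate_emissions()].
#' @return An `hmm_params` object.
#' @export
initialize_hmm <- function(chains, cutoff = 0.6, pseudocount = 0.5,
                           sigma_floor = 1e-3,
                           orientation = c("low_below", "low_above")) {
  chains <- check_chains(chains)
  states <- initialize_states(chains, cutoff, orientation = match.arg(orientation))
  tr <- estimate_transitions(states, pseudocount)
  obs <- unlist(chains, use.names = FALSE)
  grp <- unlist(states, use.names = FALSE)
  em <- estimate_emissions(obs[grp == STATE_LOW], obs[grp == STATE_HIGH],
                           sigma_floor)
  hmm_params(tr$pi, tr$A, em$mu, em$sigma)
}

## log emission matrix: k x 2
log_emission_matrix <- function(obs, params) {
  cbind(
    tnorm_pdf(obs, params$mu[1L], params$sigma[1L], log = TRUE),
    tnorm_pdf(obs, params$mu[2L], params$sigma[2L], log = TRUE)
  )
}

## Emission M-step for one state: maximize the responsibility-weighted
## truncated-normal log-likelihood.  The weighted moment estimate (mean /
## sd of the responsibilities' observations) is the natural candidate and
## is optimal up to truncation bias; when truncation makes it fail to
## improve on the current parameters, refine numerically.  Only updates
## that do not decrease the weighted likelihood are accepted, which makes
## the whole procedure a generalized EM with a non-decreasing
## log-likelihood trace.
update_emission <- function(obs, w, mu_cur, sigma_cur, sigma_floor) {
  sw <- sum(w)
  if (sw <= 0) return(c(mu_cur, sigma_cur))
  q_of <- function(mu, sigma) sum(w * tnorm_pdf(obs, mu, sigma, log = TRUE))
  q_cur <- q_of(mu_cur, sigma_cur)
  m <- sum(w * obs) / sw
  v <- sum(w * (obs - m)^2) / sw
  s <- max(sqrt(v), sigma_floor)
  q_cand <- q_of(m, s)
  if (q_cand >= q_cur) return(c(m, s))
  opt <- stats::optim(
    c(m, log(s)),
    function(p) -q_of(p[1L], max(exp(p[2L]), sigma_floor)),
    method = "Nelder-Mead", control = list(maxit = 200L)
  )
  mu_opt <- opt$par[1L]
  sigma_opt <- max(exp(opt$par[2L]), sigma_floor)
  if (-opt$value >= q_cur) c(mu_opt, sigma_opt) else c(mu_cur, sigma_cur)
}

## pairwise log-sum-exp, vectorized
lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Joint log-probability of one observation/state path
#'
#' Log of the HMM joint probability
#' `P(O, H) = P(h1) P(o1|h1) prod_i P(h_i|h_{i-1}) P(o_i|h_i)`
#' with truncated-normal emissions.
#'
#' @param obs Numeric observation chain in \[0, 1\].
#' @param states Integer state chain (1 = LOW, 2 = HIGH), same length.
#' @param params An `hmm_params` object.
#' @return A single log-probability (may be `-Inf`).
#' @export
log_joint <- function(obs, states, params) {
  states <- as.integer(states)
  if (length(obs) != length(states)) stop("'obs' and 'states' length mismatch")
  if (length(obs) == 0L) stop("empty chain")
  le <- log_emission_matrix(obs, params)
  k <- length(obs)
  ll <- log(params$pi[states[1L]]) + le[1L, states[1L]]
  if (k >= 2L) {
    ll <- ll + sum(log(params$A[cbind(states[-k], states[-1L])])) +
      sum(le[cbind(2:k, states[-1L])])
  }
  ll
}

## Scaled-free log-space forward-backward for one chain.
## Returns log-likelihood, posteriors gamma (k x 2) and summed transition
## responsibilities xi_sum (2 x 2).
forward_backward_chain <- function(obs, params) {
  k <- length(obs)
  le <- log_emission_matrix(obs, params)
  lA <- log(params$A)
  la <- matrix(-Inf, k, 2L)
  lb <- matrix(0, k, 2L)
  la[1L, ] <- log(params$pi) + le[1L, ]
  if (k >= 2L) {
    for (t in 2:k) {
      la[t, 1L] <- lse2(la[t - 1L, 1L] + lA[1L, 1L], la[t - 1L, 2L] + lA[2L, 1L]) + le[t, 1L]
      la[t, 2L] <- lse2(la[t - 1L, 1L] + lA[1L, 2L], la[t - 1L, 2L] + lA[2L, 2L]) + le[t, 2L]
    }
    for (t in (k - 1L):1L) {
      lb[t, 1L] <- lse2(lA[1L, 1L] + le[t + 1L, 1L] + lb[t + 1L, 1L],
                        lA[1L, 2L] + le[t + 1L, 2L] + lb[t + 1L, 2L])
      lb[t, 2L] <- lse2(lA[2L, 1L] + le[t + 1L, 1L] + lb[t + 1L, 1L],
                        lA[2L, 2L] + le[t + 1L, 2L] + lb[t + 1L, 2L])
    }
  }
  ll <- lse2(la[k, 1L], la[k, 2L])
  if (!is.finite(ll)) stop("non-finite likelihood in forward pass")
  lg <- la + lb - ll
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, 2L, 2L)
  if (k >= 2L) {
    for (s in 1:2) for (t2 in 1:2) {
      v <- la[1:(k - 1L), s] + lA[s, t2] + le[2:k, t2] + lb[2:k, t2] - ll
      xi_sum[s, t2] <- sum(exp(v))
    }
  }
  list(loglik = ll, gamma = gamma, xi_sum = xi_sum)
}

#' Forward-backward posterior decoding
#'
#' @param chains Numeric vector or list of observation chains.
#' @param params An `hmm_params` object.
#' @return List with per-chain `gamma` posterior matrices (rows sum to 1)
#'   and the total `loglik` across chains.
#' @export
forward_backward <- function(chains, params) {
  chains <- check_chains(chains)
  fb <- lapply(chains, forward_backward_chain, params = params)
  list(
    gamma = lapply(fb, `[[`, "gamma"),
    loglik = sum(vapply(fb, `[[`, numeric(1L), "loglik"))
  )
}

#' Baum-Welch training of the two-state HMM
#'
#' Expectation-maximization over multiple chains sharing one parameter
#' set.  The E-step is the log-space forward-backward recursion; the
#' M-step updates `pi` and `A` in closed form and the truncated-normal
#' emissions by responsibility-weighted moments, falling back to a
#' numerical maximization of the weighted truncated-normal likelihood
#' whenever truncation bias would make the moment update lose
#' likelihood (a generalized-EM scheme, so the log-likelihood trace is
#' non-decreasing by construction; details in the methods vignette).
#'
#' @param chains Numeric vector or list of observation chains in \[0, 1\].
#' @param init An `hmm_params` object (e.g. from [initialize_hmm()]).
#' @param tol Convergence tolerance on the change in total log-likelihood
#'   (default 1e-4).
#' @param max_iter Maximum EM iterations (default 100); `0` returns the
#'   initial parameters untouched with an empty trace.
#' @param sigma_floor Lower bound on emission standard deviations.
#' @return An object of class `hmm_fit`: list with `params`,
#'   `log_likelihood_trace`, `n_iter`, `converged`.
#' @export
baum_welch <- function(chains, init, tol = 1e-4, max_iter = 100L,
                       sigma_floor = 1e-3) {
  chains <- check_chains(chains)
  stopifnot(inherits(init, "hmm_params"), tol > 0, max_iter >= 0)
  params <- init
  trace <- numeric(0L)
  converged <- FALSE
  iter <- 0L
  obs_all <- unlist(chains, use.names = FALSE)
  while (iter < max_iter) {
    fb <- lapply(chains, forward_backward_chain, params = params)
    ll <- sum(vapply(fb, `[[`, numeric(1L), "loglik"))
    if (length(trace) > 0L && ll - trace[length(trace)] < tol) {
      trace <- c(trace, ll)
      converged <- TRUE
      iter <- iter + 1L
      break
    }
    trace <- c(trace, ll)
    ## M-step
    g1 <- Reduce(`+`, lapply(fb, function(f) f$gamma[1L, ]))
    pi_new <- g1 / sum(g1)
    xi <- Reduce(`+`, lapply(fb, `[[`, "xi_sum"))
    A_new <- params$A
    for (s in 1:2) {
      rs <- sum(xi[s, ])
      if (rs > 0) A_new[s, ] <- xi[s, ] / rs
    }
    gamma_all <- do.call(rbind, lapply(fb, `[[`, "gamma"))
    mu_new <- params$mu
    sigma_new <- params$sigma
    for (s in 1:2) {
      w <- gamma_all[, s]
      upd <- update_emission(obs_all, w, params$mu[s], params$sigma[s],
                             sigma_floor)
      mu_new[s] <- upd[1L]
      sigma_new[s] <- upd[2L]
    }
    params <- hmm_params(pi_new, A_new, mu_new, sigma_new)
    iter <- iter + 1L
  }
  structure(
    list(params = params, log_likelihood_trace = trace, n_iter = iter,
         converged = converged),
    class = "hmm_fit"
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "Baum-Welch fit: %d iteration(s), %sconverged, final logL %.4f\n",
    x$n_iter, if (x$converged) "" else "NOT ",
    if (length(x$log_likelihood_trace)) tail(x$log_likelihood_trace, 1L) else NA_real_
  ))
  print(x$params)
  invisible(x)
}

#' Viterbi decoding
#'
#' Per chain, the state path maximizing the joint probability, computed in
#' log space.  Ties are broken towards LOW, so decoding is deterministic.
#'
#' @param chains Numeric vector or list of observation chains.
#' @param params An `hmm_params` object.
#' @return List of integer state vectors (1 = LOW, 2 = HIGH).
#' @export
viterbi <- function(chains, params) {
  chains <- check_chains(chains)
  lA <- log(params$A)
  lpi <- log(params$pi)
  lapply(chains, function(obs) {
    k <- length(obs)
    le <- log_emission_matrix(obs, params)
    delta <- matrix(-Inf, k, 2L)
    back <- matrix(1L, k, 2L)
    delta[1L, ] <- lpi + le[1L, ]
    if (k >= 2L) {
      for (t in 2:k) {
        for (s in 1:2) {
          cand <- delta[t - 1L, ] + lA[, s]
          b <- which.max(cand) # first max -> prefers LOW on ties
          back[t, s] <- b
          delta[t, s] <- cand[b] + le[t, s]
        }
      }
    }
    path <- integer(k)
    path[k] <- which.max(delta[k, ])
    if (k >= 2L) {
      for (t in (k - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
    }
    path
  })
}

#' Simulate observation/state chains from a two-state HMM
#'
#' Draws a hidden state path from `params$pi` / `params$A` and emissions
#' from the per-state truncated normal on \[0, 1\] (inverse-cdf
#' sampling).  Used for parameter recovery checks and as a light-weight
#' fixture generator.
#'
#' @param n Chain length.
#' @param params An `hmm_params` object.
#' @param seed Integer seed (applied locally; the global RNG stream is
#'   left untouched).
#' @return List with numeric `obs` and integer `states`.
#' @export
simulate_hmm_chain <- function(n, params, seed = 1L) {
  stopifnot(n >= 1L, inherits(params, "hmm_params"))
  withr::with_seed(seed, {
    states <- integer(n)
    states[1L] <- sample(1:2, 1L, prob = params$pi)
    if (n >= 2L) {
      for (t in 2:n) {
        states[t] <- sample(1:2, 1L, prob = params$A[states[t - 1L], ])
      }
    }
    obs <- rtnorm01(n, params$mu[states], params$sigma[states])
    list(obs = obs, states = states)
  })
}
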