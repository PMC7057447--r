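# Shared fixtures, built in code.

# quick profile from vectors
make_profile <- function(pos, beta, chrom = "chr1", platform = "GENERIC",
                         island = NA, detection_p = NA_real_,
                         probe_id = NULL) {
  n <- length(pos)
  if (is.null(probe_id)) probe_id <- sprintf("cg%05d", seq_len(n))
  p <- methylation_profile(
    data.frame(probe_id = probe_id, chrom = rep_len(chrom, n), pos = pos,
               beta = beta, detection_p = rep_len(detection_p, n),
               stringsAsFactors = FALSE),
    platform = platform
  )
  p$records$island_member <- rep_len(island, n)
  p
}

# aligned site-call frame with given final labels
make_calls <- function(profile, final, layer1 = NULL) {
  rec <- profile$records
  if (is.null(layer1)) {
    layer1 <- ifelse(final == "FMS", "HIGH", "LOW")
  }
  calls <- data.frame(
    probe_id = rec$probe_id, chrom = rec$chrom, pos = rec$pos,
    beta = rec$beta, layer1 = rep_len(layer1, nrow(rec)),
    final = rep_len(final, nrow(rec)), stringsAsFactors = FALSE
  )
  class(calls) <- c("site_calls", "data.frame")
  calls
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent joint probability of one path: own truncated-normal and
# product arithmetic, no package HMM code
ref_log_joint <- function(obs, states, pi, A, mu, sigma) {
  tn <- function(x, m, s) {
    stats::dnorm(x, m, s) / (stats::pnorm(1, m, s) - stats::pnorm(0, m, s))
  }
  ll <- log(pi[states[1L]]) + log(tn(obs[1L], mu[states[1L]], sigma[states[1L]]))
  for (t in seq_along(obs)[-1L]) {
    ll <- ll + log(A[states[t - 1L], states[t]]) +
      log(tn(obs[t], mu[states[t]], sigma[states[t]]))
  }
  ll
}

# exhaustive maximization of the joint over all 2^k state paths,
# vectorized over paths; truncated-normal arithmetic written out directly
brute_force_viterbi <- function(obs, params) {
  k <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(1:2), k)))
  tn <- function(x, m, s) {
    stats::dnorm(x, m, s) / (stats::pnorm(1, m, s) - stats::pnorm(0, m, s))
  }
  le <- rbind(log(tn(obs, params$mu[1L], params$sigma[1L])),
              log(tn(obs, params$mu[2L], params$sigma[2L]))) # 2 x k
  lA <- log(params$A)
  ll <- log(params$pi[paths[, 1L]]) + le[cbind(paths[, 1L], 1L)]
  if (k >= 2L) {
    for (t in 2:k) {
      ll <- ll + lA[cbind(paths[, t - 1L], paths[, t])] +
        le[cbind(paths[, t], t)]
    }
  }
  as.integer(paths[which.max(ll), ])
}

random_hmm_params <- function() {
  pi <- stats::runif(2, 0.1, 0.9)
  pi <- pi / sum(pi)
  A <- matrix(stats::runif(4, 0.05, 0.95), 2L)
  A <- A / rowSums(A)
  hmm_params(pi, A,
             mu = sort(stats::runif(2, 0.05, 0.95)),
             sigma = stats::runif(2, 0.03, 0.3))
}
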