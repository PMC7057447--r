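## Hartigan's dip statistic, computed exactly.
##
## The dip of an empirical cdf F_n is the smallest sup-norm distance from
## F_n to the class of unimodal distribution functions (convex below the
## mode, concave above it, with an atom allowed at the mode).  We compute
## it by a convex-hull sweep: for every candidate mode position u, the
## minimal sup-error of the convex side over the points left of u equals
## half the largest amount by which a lower cdf bound pokes above the
## greatest convex minorant of the upper cdf bounds (and mirrored for the
## concave side right of u); the dip is the minimum over u of the larger
## of the two half-errors.  Both one-sided error curves are monotone in u
## and are maintained incrementally with Andrew's monotone-chain hull,
## which keeps the whole computation O(n log n).

## One-sided sweep.  xs: unique positions in increasing order; hull_y:
## cdf value entering the convex minorant at each position; viol_y: cdf
## value that must stay above/below the minorant.  Returns, per position
## u, the largest (viol - hull) gap over positions strictly before u,
## measured against the hull anchored at u.
dip_sweep <- function(xs, hull_y, viol_y) {
  U <- length(xs)
  D <- numeric(U)
  hx <- numeric(U) # hull vertex x
  hy <- numeric(U) # hull vertex y
  hi <- integer(U) # hull vertex index into xs
  top <- 0L
  run <- 0
  for (u in seq_len(U)) {
    xu <- xs[u]
    yu <- hull_y[u]
    while (top >= 2L &&
           (hy[top] - hy[top - 1L]) * (xu - hx[top - 1L]) >=
           (yu - hy[top - 1L]) * (hx[top] - hx[top - 1L])) {
      top <- top - 1L
    }
    if (top >= 1L && hi[top] < u - 1L) {
      ## the closing edge replaced part of the hull; re-measure the gap
      ## for every position under the new edge
      js <- (hi[top] + 1L):(u - 1L)
      slope <- (yu - hy[top]) / (xu - hx[top])
      edge <- hy[top] + slope * (xs[js] - hx[top])
      run <- max(run, max(viol_y[js] - edge))
    }
    D[u] <- run
    run <- max(run, viol_y[u] - yu)
    top <- top + 1L
    hx[top] <- xu
    hy[top] <- yu
    hi[top] <- u
  }
  D
}

## Coupled feasibility at error level t: some mode u must admit both a
## convex branch threading its band on the left and a concave branch on
## the right whose values at the mode can be ordered (left-limit <=
## value), since the fitted cdf is one nondecreasing function.  The
## minimal convex-branch end value A(u) and maximal concave-branch start
## value B(u) follow from supporting-line bounds: an upper bound hi_i
## before a lower bound lo_j forces slope at least
## (lo_j - hi_i)/(x_j - x_i) from x_j onwards (convexity), and mirrored
## on the concave side.
dip_coupled_feasible <- function(t, ux, first, last, n, Dc, Dv) {
  eps <- 1e-12
  U <- length(ux)
  band <- pmax(Dc, Dv) <= 2 * t + eps
  if (!any(band)) return(FALSE)
  lo <- pmax(last / n - t, 0)
  hi <- pmin((first - 1) / n + t, 1)
  modes <- which(band)
  umax <- max(modes)
  umin <- min(modes)
  ## minimal onward slope forced at each lower bound (left-to-right)
  m_fwd <- numeric(U)
  if (umax >= 2L) {
    for (j in 2:umax) {
      ii <- seq_len(j - 1L)
      m_fwd[j] <- max(0, max((lo[j] - hi[ii]) / (ux[j] - ux[ii])))
    }
  }
  ## minimal backward slope forced at each upper bound (right-to-left)
  m_bwd <- numeric(U)
  if (umin <= U - 1L) {
    for (l in (U - 1L):umin) {
      kk <- (l + 1L):U
      m_bwd[l] <- max(0, max((lo[kk] - hi[l]) / (ux[kk] - ux[l])))
    }
  }
  for (u in modes) {
    A <- if (u == 1L) 0 else {
      jj <- seq_len(u - 1L)
      max(lo[jj] + m_fwd[jj] * (ux[u] - ux[jj]))
    }
    B <- if (u == U) 1 else {
      ll <- (u + 1L):U
      min(hi[ll] - m_bwd[ll] * (ux[ll] - ux[u]))
    }
    hi_start <- min(last[u] / n + t, 1)
    if (A <= hi[u] + eps && max(lo[u], A) <= min(B, hi_start) + eps) {
      return(TRUE)
    }
  }
  FALSE
}

#' Hartigan's dip statistic
#'
#' Exact sup-norm distance between the empirical cdf of `x` and the
#' nearest unimodal distribution function (convex below its mode,
#' concave above it, an atom allowed at the mode).  Values range from
#' `1/(2n)` (perfectly unimodal-looking samples) to `1/4` (half the mass
#' at each of two points).
#'
#' The per-mode one-sided band errors are computed by an incremental
#' convex-hull sweep; their minimum is a lower bound that is already
#' exact whenever the two branches' values at the mode can be ordered,
#' and is otherwise tightened by bisection on the coupled feasibility
#' condition.
#'
#' @param x Numeric sample (NAs and non-finite values are dropped).
#' @return The dip statistic, a single number.
#' @examples
#' dip_statistic(c(rep(0, 50), rep(1, 50))) # 0.25, maximally bimodal
#' dip_statistic(seq(0, 1, length.out = 50)) # 1/100, flat sample
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n <= 1L) {
    return(0)
  }
  ux <- unique(x)
  U <- length(ux)
  if (U == 1L) {
    return(0) # a single point mass is itself unimodal
  }
  first <- match(ux, x)
  last <- (n + 1L) - match(ux, rev(x))
  ## one-sided band errors per mode: convex (left-of-mode) side from the
  ## hull of upper bounds (first-1)/n against lower bounds last/n, and
  ## the concave side mirrored through (x, y) -> (-x, -y)
  Dc <- dip_sweep(ux, (first - 1) / n, last / n)
  Dv <- rev(dip_sweep(-rev(ux), -rev(last / n), -rev((first - 1) / n)))
  t0 <- 0.5 * min(pmax(Dc, Dv))
  if (dip_coupled_feasible(t0, ux, first, last, n, Dc, Dv)) {
    return(t0)
  }
  ## branch coupling binds: expand a window above the band bound, then
  ## bisect to the exact value
  w <- 0.5 / n
  while (t0 + w < 0.25 &&
         !dip_coupled_feasible(t0 + w, ux, first, last, n, Dc, Dv)) {
    w <- 2 * w
  }
  lo_t <- t0
  hi_t <- min(t0 + w, 0.25)
  while (hi_t - lo_t > 1e-8) {
    mid <- (lo_t + hi_t) / 2
    if (dip_coupled_feasible(mid, ux, first, last, n, Dc, Dv)) {
      hi_t <- mid
    } else {
      lo_t <- mid
    }
  }
  hi_t
}

#' Dip-test p-value from the precomputed null table
#'
#' Interpolates the package's table of dip quantiles under uniform
#' samples (the classical least-favourable unimodal null; 999 Monte-
#' Carlo replicates per tabulated sample size, regenerable with
#' `tools/make-dip-table.R`).  Quantiles are interpolated between
#' tabulated sample sizes on the `sqrt(n) * dip` scale, the scale on
#' which the null distribution is asymptotically stable; beyond the
#' largest tabulated size the scaled quantiles are held constant.
#'
#' @param statistic Observed dip statistic.
#' @param n Sample size it was computed from.
#' @return Interpolated p-value (clamped to the tabulated range,
#'   0.005-1).
#' @export
dip_null_pvalue <- function(statistic, n) {
  stopifnot(is.finite(statistic), n >= 2)
  sq <- sqrt(DIP_NULL_N)
  scaled <- DIP_NULL_QUANTILES * sq # rows: n, cols: probs
  s_obs <- sqrt(n) * statistic
  ## scaled quantile curve at this n, linear in sqrt(n) within the table
  at_n <- vapply(seq_along(DIP_NULL_PROBS), function(j) {
    stats::approx(sq, scaled[, j], xout = sqrt(n), rule = 2)$y
  }, numeric(1L))
  ## anchor at the minimal possible dip (prob 0) for smooth upper p-values
  probs <- c(0, DIP_NULL_PROBS)
  at_n <- c(0.5 / sqrt(n), at_n) # sqrt(n) * 1/(2n), the minimal dip, scaled
  cdf <- stats::approx(at_n, probs, xout = s_obs, rule = 2, ties = "ordered")$y
  max(1 - cdf, 1 - DIP_NULL_PROBS[length(DIP_NULL_PROBS)])
}

#' Dip test of unimodality with Monte-Carlo calibration
#'
#' Compares the observed dip statistic with its null distribution under
#' samples of the same size from the uniform distribution (the classical
#' least-favourable unimodal null for the dip test).  The Monte-Carlo
#' draws use a locally seeded RNG stream, so the test is deterministic
#' and leaves the global RNG untouched.
#'
#' @param x Numeric sample.
#' @param n_boot Number of null replicates (default 200).
#' @param seed Integer seed for the null replicates.
#' @return List with `statistic` (the dip) and `p_value`.
#' @export
dip_test <- function(x, n_boot = 200L, seed = 1L) {
  stopifnot(n_boot >= 1L)
  d <- dip_statistic(x)
  n <- sum(is.finite(x))
  null_dips <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) dip_statistic(stats::runif(n)),
           numeric(1L))
  })
  p <- (1 + sum(null_dips >= d)) / (n_boot + 1)
  list(statistic = d, p_value = p)
}
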