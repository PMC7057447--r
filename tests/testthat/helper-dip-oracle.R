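# Slow, first-principles oracle for the dip statistic: direct minimization
# over unimodal cdfs G (convex below a mode point, concave above it, atom
# allowed at the mode) of sup|F_n - G|, by bisection on the error t.  For
# a candidate t, feasibility is checked mode by mode: the convex branch
# must thread the band [F_lower - t, F_upper + t] left of the mode, the
# concave branch right of it, and the two end values must be orderable.
# Band-threading is decided from the defining geometry (a convex function
# fits under upper bounds iff their lower convex hull clears the lower
# bounds), with the branch end value pinned by inner bisection.  O(n^2
# log^2) - only for small test fixtures.

dip_oracle <- function(x, tol = 1e-6) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n <= 1L) return(0)
  ux <- unique(x)
  U <- length(ux)
  if (U == 1L) return(0)
  first <- match(ux, x)
  last <- (n + 1L) - match(ux, rev(x))
  lo_all <- function(t) pmax(last / n - t, 0)
  hi_all <- function(t) pmin((first - 1) / n + t, 1)

  lower_hull_vals <- function(xs, ys) {
    # piecewise-linear lower convex hull through the point set, evaluated
    # at the xs themselves
    k <- length(xs)
    if (k <= 2L) return(ys)
    hull <- 1L
    for (i in 2:k) {
      while (length(hull) >= 2L) {
        a <- hull[length(hull) - 1L]
        b <- hull[length(hull)]
        if ((ys[b] - ys[a]) * (xs[i] - xs[a]) >=
            (ys[i] - ys[a]) * (xs[b] - xs[a])) hull <- hull[-length(hull)]
        else break
      }
      hull <- c(hull, i)
    }
    stats::approx(xs[hull], ys[hull], xout = xs)$y
  }

  conv_feasible <- function(u, t, v) {
    # convex nondecreasing branch through boxes at uniques 1..u-1 ending
    # at (ux[u], v)
    if (u == 1L) return(TRUE)
    js <- seq_len(u - 1L)
    lo <- lo_all(t)[js]
    hi <- pmin(hi_all(t)[js], v) # monotone: branch never exceeds its end
    if (any(lo > hi + 1e-12)) return(FALSE)
    xs <- c(ux[js], ux[u])
    ys <- c(hi, v)
    h <- lower_hull_vals(xs, ys)
    all(h[js] >= lo - 1e-12)
  }

  conc_feasible <- function(u, t, v) {
    # concave nondecreasing branch from (ux[u], v) through boxes u+1..U,
    # mirrored into the convex problem
    if (u == U) return(TRUE)
    js <- (u + 1L):U
    lo <- pmax(lo_all(t)[js], v)
    hi <- hi_all(t)[js]
    if (any(lo > hi + 1e-12)) return(FALSE)
    xs <- c(-rev(ux[js]), -ux[u])
    ys <- c(-rev(lo), -v)
    h <- lower_hull_vals(xs, ys)
    all(h[seq_along(js)] >= -rev(hi) - 1e-12)
  }

  mode_feasible <- function(u, t) {
    hi_end <- min((first[u] - 1) / n + t, 1)
    lo_start <- max(last[u] / n - t, 0)
    hi_start <- min(last[u] / n + t, 1)
    if (lo_start > hi_start + 1e-12) return(FALSE)
    # minimal feasible convex end value A (feasibility is up-closed in v)
    if (!conv_feasible(u, t, hi_end)) return(FALSE)
    lo_v <- 0; hi_v <- hi_end
    for (k in 1:40) {
      mid <- (lo_v + hi_v) / 2
      if (conv_feasible(u, t, mid)) hi_v <- mid else lo_v <- mid
    }
    A <- hi_v
    # maximal feasible concave start value B (down-closed in v)
    if (!conc_feasible(u, t, lo_start)) return(FALSE)
    lo_v <- lo_start; hi_v <- hi_start
    for (k in 1:40) {
      mid <- (lo_v + hi_v) / 2
      if (conc_feasible(u, t, mid)) lo_v <- mid else hi_v <- mid
    }
    B <- lo_v
    A <= B + 1e-9
  }

  feasible <- function(t) any(vapply(seq_len(U), mode_feasible, logical(1L),
                                     t = t))
  lo_t <- 0; hi_t <- 0.26
  for (k in seq_len(ceiling(log2(0.26 / tol)))) {
    mid <- (lo_t + hi_t) / 2
    if (feasible(mid)) hi_t <- mid else lo_t <- mid
  }
  hi_t
}
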