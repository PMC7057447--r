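#' Settings for the bimodality gate
#'
#' @param method `"DIP"` (Hartigan's dip test, the default) or
#'   `"KDE_PEAKS"` (count local maxima of a Gaussian kernel density).
#' @param alpha Dip-test significance level (default 0.05).
#' @param min_n Below this sample size the verdict is always unimodal,
#'   with a warning (default 50).
#' @param kde_n Grid size of the kernel density estimate (default 512).
#' @param minor_peak_frac A density local maximum only counts as a second
#'   peak when its height is at least this fraction of the major peak
#'   (default 0.10).
#' @return List of class `bimodality_config`.
#' @export
bimodality_config <- function(method = c("DIP", "KDE_PEAKS"), alpha = 0.05,
                              min_n = 50L, kde_n = 512L,
                              minor_peak_frac = 0.10) {
  structure(
    list(method = match.arg(method), alpha = alpha, min_n = min_n,
         kde_n = kde_n, minor_peak_frac = minor_peak_frac),
    class = "bimodality_config"
  )
}

kde_peak_count <- function(values, config) {
  d <- stats::density(values, bw = "nrd0", n = config$kde_n,
                      kernel = "gaussian", from = 0, to = 1)
  y <- d$y
  k <- length(y)
  is_max <- y > c(-Inf, y[-k]) & y >= c(y[-1L], -Inf)
  peaks <- y[is_max]
  major <- max(peaks)
  sum(peaks >= config$minor_peak_frac * major)
}

#' Decide whether a set of beta-values is bimodal
#'
#' The gate between the first and second HMM layer: a class of sites is
#' split again only when its methylation-level distribution is bimodal.
#' The default test is Hartigan's dip, calibrated against the package's
#' precomputed table of null quantiles (see [dip_null_pvalue()]); the
#' alternative counts kernel-density peaks (minor peaks below 10% of the
#' major peak's height are ignored).
#'
#' @param values Numeric vector of beta-values in \[0, 1\].
#' @param config A [bimodality_config()].
#' @return List of class `bimodality_verdict` with `is_bimodal`,
#'   `statistic` (dip value or peak count), `threshold` and `method`.
#' @export
assess_bimodality <- function(values, config = bimodality_config()) {
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop("'values' must lie in [0, 1]")
  }
  n <- length(values)
  if (n < config$min_n) {
    warning(sprintf(
      "only %d value(s) (< min_n = %d): treating distribution as unimodal",
      n, config$min_n
    ))
    return(structure(
      list(is_bimodal = FALSE, statistic = NA_real_, threshold = NA_real_,
           method = config$method, p_value = NA_real_, n = n),
      class = "bimodality_verdict"
    ))
  }
  if (config$method == "DIP") {
    d <- dip_statistic(values)
    p <- dip_null_pvalue(d, n)
    structure(
      list(is_bimodal = p < config$alpha, statistic = d,
           threshold = config$alpha, method = "DIP", p_value = p,
           n = n),
      class = "bimodality_verdict"
    )
  } else {
    np <- kde_peak_count(values, config)
    structure(
      list(is_bimodal = np >= 2L, statistic = as.numeric(np), threshold = 2,
           method = "KDE_PEAKS", p_value = NA_real_, n = n),
      class = "bimodality_verdict"
    )
  }
}

#' @export
print.bimodality_verdict <- function(x, ...) {
  cat(sprintf("bimodality [%s, n=%d]: %s (statistic %.4g%s)\n",
              x$method, x$n, if (x$is_bimodal) "bimodal" else "unimodal",
              x$statistic,
              if (!is.na(x$p_value)) sprintf(", p=%.3g", x$p_value) else ""))
  invisible(x)
}
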