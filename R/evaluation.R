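## Validation machinery: base-pair overlap between two labeled region
## sets, common-site Pearson correlation between two platforms' profiles,
## and per-state region-width summaries.

labeled_granges <- function(regions, zero_based = FALSE) {
  if (nrow(regions) == 0L) {
    return(stats::setNames(list(), character(0)))
  }
  if (anyNA(regions$state)) stop("regions must all carry a state label")
  start1 <- if (zero_based) regions$start + 1L else regions$start
  bad <- which(start1 > regions$end)
  if (length(bad)) stop("malformed interval at row ", bad[1L])
  grl <- lapply(split(seq_len(nrow(regions)), regions$state), function(ii) {
    GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = regions$chrom[ii],
      ranges = IRanges::IRanges(start = start1[ii], end = regions$end[ii])
    ))
  })
  grl
}

#' Base-pair overlap matrix between two labeled region sets
#'
#' For every label pair, the number of base pairs shared between the two
#' sets (after a per-label validation merge), and the fraction of each
#' row label's total span that the overlap covers.  Row fractions sum to
#' at most 1; the remainder is span overlapping no column region.
#'
#' @param set_a,set_b Region data.frames with `chrom`, `start`, `end`,
#'   `state`.  Coordinates are 1-based inclusive spans as produced by
#'   [segment_profile()] / [read_region_bed()]; pass `zero_based = TRUE`
#'   for raw BED-convention frames.
#' @param zero_based_a,zero_based_b Interpret the respective set's
#'   `start` as 0-based half-open.
#' @param weight `"bp"` (default) weights coincidence by base pairs;
#'   `"count"` reports, per row label, the fraction of its regions that
#'   overlap each column label by at least 1 bp.
#' @return List of class `overlap_matrix` with `basepair_overlap`,
#'   `row_fractions`, `row_total_bp` and the label vectors.
#' @export
overlap_matrix <- function(set_a, set_b, zero_based_a = FALSE,
                           zero_based_b = FALSE, weight = c("bp", "count")) {
  weight <- match.arg(weight)
  ga <- labeled_granges(set_a, zero_based_a)
  gb <- labeled_granges(set_b, zero_based_b)
  la <- names(ga)
  lb <- names(gb)
  bp <- matrix(0, length(la), length(lb), dimnames = list(la, lb))
  frac <- bp
  total_a <- vapply(ga, function(g) sum(as.numeric(GenomicRanges::width(g))),
                    numeric(1L))
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      ov <- GenomicRanges::intersect(ga[[i]], gb[[j]])
      bp[i, j] <- sum(as.numeric(GenomicRanges::width(ov)))
      if (weight == "bp") {
        frac[i, j] <- if (total_a[i] > 0) bp[i, j] / total_a[i] else 0
      } else {
        n_i <- length(ga[[i]])
        hit <- GenomicRanges::countOverlaps(ga[[i]], gb[[j]]) > 0L
        frac[i, j] <- if (n_i > 0) sum(hit) / n_i else 0
      }
    }
  }
  structure(
    list(row_labels = la, col_labels = lb, basepair_overlap = bp,
         row_fractions = frac, row_total_bp = total_a, weight = weight),
    class = "overlap_matrix"
  )
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("overlap matrix (%s-weighted row fractions):\n", x$weight))
  print(round(x$row_fractions, 4))
  invisible(x)
}

#' Pearson correlation on common CpG sites
#'
#' Correlates the beta-values of two profiles at the intersection of
#' their (chrom, pos) coordinates — the standard cross-platform
#' concordance check.
#'
#' @param profile_a,profile_b `methylation_profile` objects.
#' @return List with `r` (Pearson correlation) and `n_common`.
#' @export
common_site_correlation <- function(profile_a, profile_b) {
  a <- profile_a$records
  b <- profile_b$records
  key_a <- paste(a$chrom, a$pos)
  key_b <- paste(b$chrom, b$pos)
  common <- intersect(key_a, key_b)
  if (length(common) < 3L) {
    stop("fewer than 3 common (chrom, pos) sites between the profiles")
  }
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  list(r = stats::cor(a$beta[ia], b$beta[ib]), n_common = length(common))
}

#' Five-number width summary per region state
#'
#' Width is the 1-based inclusive span `end - start + 1`; quartiles use
#' linear interpolation (type-7 quantiles).
#'
#' @param regions Region data.frame with `chrom`, `start`, `end`,
#'   `state`.
#' @return data.frame with one row per state present: n, min, q1,
#'   median, q3, max (bp).  States absent from the input are omitted.
#' @export
width_summary <- function(regions) {
  if (nrow(regions) == 0L) {
    return(data.frame(state = character(0), n = integer(0), min = numeric(0),
                      q1 = numeric(0), median = numeric(0), q3 = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE))
  }
  widths <- regions$end - regions$start + 1
  out <- lapply(split(widths, regions$state), function(w) {
    q <- stats::quantile(w, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    data.frame(n = length(w), min = q[1L], q1 = q[2L], median = q[3L],
               q3 = q[4L], max = q[5L])
  })
  res <- do.call(rbind, out)
  res <- cbind(state = rownames(res), res)
  rownames(res) <- NULL
  res$state <- as.character(res$state)
  res
}
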