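## Region segmentation: merge CpGs into candidate regions by inter-probe
## gap and site state, drop regions with too few CpGs, re-merge across the
## dropped fragments, then classify region mean beta-values with the same
## two-layer HMM used at site level.

PLATFORM_OPENSEA_GAP <- c(HM450K = 11300L, EPIC = 4800L)

#' Segmentation configuration
#'
#' All thresholds of the region pipeline.  The island gap (300 bp)
#' applies between island-associated probe pairs; the open-sea gap is
#' platform-specific (11,300 bp on HM450K, 4,800 bp on EPIC, reflecting
#' the platforms' inter-probe gap distributions) and must be given
#' explicitly for GENERIC data.
#'
#' @param platform `"HM450K"`, `"EPIC"` or `"GENERIC"`.
#' @param island_gap Gap threshold (bp) between island-associated pairs.
#' @param opensea_gap Gap threshold (bp) otherwise; defaults from the
#'   platform, required for GENERIC.
#' @param min_cpgs Minimum CpGs per region (default 3).
#' @param init_cutoff Layer-1 HMM initialization cutoff (default 0.6).
#' @param min_regions Below this many regions the HMM classifier falls
#'   back to fixed thresholds (default 10).
#' @param fallback_low,fallback_high Fallback mean-beta thresholds for
#'   UMR (<) and FMR (>) when too few regions exist for an HMM fit.
#' @param remerge_same_state_only If `TRUE`, the re-merge step only joins
#'   regions whose (uniform) member site-state matches; the default
#'   `FALSE` also joins differing-state regions when a dropped fragment
#'   lies between them, which is what lets the step heal fragmentation
#'   caused by one- or two-CpG state flickers (see [remerge_regions()]).
#' @param bimodality A [bimodality_config()].  The default lowers the
#'   gate's minimum sample size to 10: region mean beta-values are far
#'   fewer than CpG sites (each one already averages a whole region), so
#'   the site-level guard of 50 would silently disable the second layer
#'   on real-sized region sets.
#' @param hmm_tol,hmm_max_iter,pseudocount,sigma_floor HMM settings shared
#'   with [call_site_states()].
#' @return List of class `segmentation_config`.
#' @export
segmentation_config <- function(platform = c("HM450K", "EPIC", "GENERIC"),
                                island_gap = 300L, opensea_gap = NULL,
                                min_cpgs = 3L, init_cutoff = 0.6,
                                min_regions = 10L, fallback_low = 0.25,
                                fallback_high = 0.75,
                                remerge_same_state_only = FALSE,
                                bimodality = bimodality_config(min_n = 10L),
                                hmm_tol = 1e-4, hmm_max_iter = 100L,
                                pseudocount = 0.5, sigma_floor = 1e-3) {
  platform <- match.arg(platform)
  if (is.null(opensea_gap)) {
    if (platform == "GENERIC") {
      stop("platform GENERIC requires an explicit 'opensea_gap'")
    }
    opensea_gap <- PLATFORM_OPENSEA_GAP[[platform]]
  }
  stopifnot(island_gap > 0, opensea_gap > 0, min_cpgs >= 1L)
  structure(
    list(platform = platform, island_gap = as.integer(island_gap),
         opensea_gap = as.integer(opensea_gap),
         min_cpgs = as.integer(min_cpgs), init_cutoff = init_cutoff,
         min_regions = as.integer(min_regions),
         fallback_low = fallback_low, fallback_high = fallback_high,
         remerge_same_state_only = remerge_same_state_only,
         bimodality = bimodality, hmm_tol = hmm_tol,
         hmm_max_iter = as.integer(hmm_max_iter),
         pseudocount = pseudocount, sigma_floor = sigma_floor),
    class = "segmentation_config"
  )
}

#' Gap threshold applicable between two adjacent probes
#'
#' The island gap applies only when both probes are island-associated; a
#' mixed or open-sea pair uses the (larger) open-sea gap, so island
#' shores are not split by the strict threshold.
#'
#' @param island_a,island_b Logical island-membership flags of the two
#'   probes (same chromosome; callers split chains beforehand).
#' @param config A [segmentation_config()].
#' @return Gap threshold in bp.
#' @export
gap_threshold <- function(island_a, island_b, config) {
  if (is.na(island_a) || is.na(island_b)) {
    stop("island membership not annotated; run annotate_islands() first")
  }
  if (island_a && island_b) config$island_gap else config$opensea_gap
}

region_row <- function(rec, idx, site_state = NA_character_) {
  data.frame(
    chrom = rec$chrom[idx[1L]], start = rec$pos[idx[1L]],
    end = rec$pos[idx[length(idx)]], n_cpg = length(idx),
    mean_beta = mean(rec$beta[idx]), state = NA_character_,
    site_state = site_state, stringsAsFactors = FALSE
  )
}

empty_regions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n_cpg = integer(0), mean_beta = numeric(0),
             state = character(0), site_state = character(0),
             stringsAsFactors = FALSE)
}

## attach/refresh the member-index list column
set_members <- function(regions, members) {
  attr(regions, "cpg_indices") <- members
  regions
}

#' Member CpG indices of each region
#'
#' @param regions A region data.frame produced by the segmentation steps.
#' @return List of integer vectors indexing the profile's records.
#' @export
region_members <- function(regions) {
  attr(regions, "cpg_indices")
}

#' Build primary regions from adjacent same-state CpGs
#'
#' Scanning each chromosome in genomic order, two adjacent CpGs join the
#' same region iff their positional gap is at most the applicable gap
#' threshold AND they carry the same final site-state; violating either
#' starts a new region.
#'
#' @param profile An island-annotated `methylation_profile`.
#' @param site_calls `site_calls` aligned to the profile (same order).
#' @param config A [segmentation_config()].
#' @return Region data.frame (columns chrom, start, end, n_cpg,
#'   mean_beta, state = NA, site_state) with member indices attached;
#'   spans are first-to-last member CpG position, 1-based inclusive.
#' @export
build_primary_regions <- function(profile, site_calls, config) {
  rec <- profile$records
  if (nrow(rec) == 0L) return(set_members(empty_regions(), list()))
  if (nrow(site_calls) != nrow(rec) ||
      any(site_calls$pos != rec$pos) || any(site_calls$chrom != rec$chrom)) {
    stop("site_calls are not aligned to the profile")
  }
  state <- site_calls$final
  out <- list()
  members <- list()
  for (chrom in unique(rec$chrom)) {
    idx <- which(rec$chrom == chrom)
    cur <- idx[1L]
    for (k in seq_along(idx)[-1L]) {
      i <- idx[k - 1L]
      j <- idx[k]
      thr <- gap_threshold(rec$island_member[i], rec$island_member[j], config)
      if ((rec$pos[j] - rec$pos[i]) <= thr && state[j] == state[i]) {
        cur <- c(cur, j)
      } else {
        out[[length(out) + 1L]] <- region_row(rec, cur, state[cur[1L]])
        members[[length(members) + 1L]] <- cur
        cur <- j
      }
    }
    out[[length(out) + 1L]] <- region_row(rec, cur, state[cur[1L]])
    members[[length(members) + 1L]] <- cur
  }
  set_members(do.call(rbind, out), members)
}

#' Drop regions with fewer than `min_cpgs` CpGs
#'
#' @param regions Regions from [build_primary_regions()].
#' @param config A [segmentation_config()].
#' @return Filtered regions; the member indices of dropped regions are
#'   attached as attribute `"unassigned"` for the re-merge step.
#' @export
filter_small_regions <- function(regions, config) {
  members <- region_members(regions)
  keep <- regions$n_cpg >= config$min_cpgs
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- set_members(out, members[keep])
  attr(out, "unassigned") <- sort(unlist(members[!keep], use.names = FALSE))
  out
}

#' Re-merge surviving regions across small dropped fragments
#'
#' The minimum-CpG filter can fragment a methylation domain when a one-
#' or two-CpG state flicker inside it was dropped: the two surviving
#' halves end up as separate regions.  This step heals that: adjacent
#' surviving regions on one chromosome merge when the gap between the
#' last CpG of the first and the first CpG of the second is at most the
#' gap threshold for that probe pair AND the boundary is of the healing
#' kind — either dropped CpGs lie between the two regions (a filtered
#' flicker, merged regardless of the flanking states) or the two regions
#' carry the same member site-state.  A plain state-change boundary
#' between two surviving regions is left alone; re-merging it would undo
#' the state-aware split that defines the method.  Dropped CpGs inside a
#' merged span are re-absorbed.  Iterates to a fixpoint.  Set
#' `remerge_same_state_only` in the config to forbid merges across
#' differing flank states entirely.
#'
#' @param regions Output of [filter_small_regions()].
#' @param profile The annotated `methylation_profile`.
#' @param config A [segmentation_config()].
#' @return Re-merged regions (mean beta and spans recomputed).
#' @export
remerge_regions <- function(regions, profile, config) {
  rec <- profile$records
  members <- region_members(regions)
  if (length(members) <= 1L) return(regions)
  site_state <- regions$site_state
  chroms <- regions$chrom
  assigned <- rep(FALSE, nrow(rec))
  assigned[unlist(members, use.names = FALSE)] <- TRUE
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < length(members)) {
      j <- i + 1L
      same_chrom <- chroms[i] == chroms[j]
      if (same_chrom) {
        a <- members[[i]][length(members[[i]])]
        b <- members[[j]][1L]
        same_state <- !is.na(site_state[i]) && !is.na(site_state[j]) &&
          site_state[i] == site_state[j]
        dropped_between <- any(!assigned & rec$chrom == chroms[i] &
                                 rec$pos > rec$pos[a] & rec$pos < rec$pos[b])
        ok_state <- if (config$remerge_same_state_only) same_state else
          (same_state || dropped_between)
        thr <- gap_threshold(rec$island_member[a], rec$island_member[b],
                             config)
        if (ok_state && (rec$pos[b] - rec$pos[a]) <= thr) {
          ## absorb every profile CpG inside the merged span (the only
          ## non-members there are previously dropped fragments)
          span <- which(rec$chrom == chroms[i] &
                          rec$pos >= rec$pos[members[[i]][1L]] &
                          rec$pos <= rec$pos[members[[j]][length(members[[j]])]])
          members[[i]] <- span
          members[[j]] <- NULL
          assigned[span] <- TRUE
          new_state <- if (same_state) site_state[i] else NA_character_
          site_state <- c(site_state[seq_len(i - 1L)], new_state,
                          site_state[-seq_len(j)])
          chroms <- chroms[-j]
          merged_any <- TRUE
          next
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(seq_along(members), function(k) {
    region_row(rec, members[[k]], site_state[k])
  }))
  set_members(out, members)
}

#' Classify regions into UMR/MMR/FMR
#'
#' Re-runs the full two-layer two-state HMM with the region mean
#' beta-values as observations, chained per chromosome in genomic order.
#' With fewer than `min_regions` regions an HMM fit is not meaningful and
#' fixed mean-beta thresholds are used instead, with a warning.
#'
#' @param regions Regions from [remerge_regions()].
#' @param config A [segmentation_config()].
#' @return Regions with the `state` column set.
#' @export
classify_regions <- function(regions, config) {
  if (nrow(regions) == 0L) return(regions)
  if (nrow(regions) < config$min_regions) {
    warning(sprintf(
      "only %d region(s): classifying by fixed thresholds (UMR < %.2f, FMR > %.2f) instead of the HMM",
      nrow(regions), config$fallback_low, config$fallback_high
    ))
    regions$state <- ifelse(
      regions$mean_beta < config$fallback_low, "UMR",
      ifelse(regions$mean_beta > config$fallback_high, "FMR", "MMR")
    )
    return(regions)
  }
  chains <- split(regions$mean_beta,
                  factor(regions$chrom, levels = unique(regions$chrom)))
  res <- two_layer_call(chains, config$init_cutoff, config$bimodality,
                        config$hmm_tol, config$hmm_max_iter,
                        config$pseudocount, config$sigma_floor)
  regions$state <- c("UMR", "MMR", "FMR")[res$final]
  attr(regions, "classification") <- res$diagnostics
  regions
}

#' Segment a methylation profile into UMR/MMR/FMR regions
#'
#' Composition of the four steps: build primary regions by gap and site
#' state, drop regions with fewer than `min_cpgs` CpGs, re-merge across
#' the dropped fragments, classify region mean beta-values with the
#' two-layer HMM.
#'
#' @param profile An island-annotated `methylation_profile`.
#' @param site_calls Optional `site_calls`; computed with
#'   [call_site_states()] when missing.
#' @param config A [segmentation_config()]; defaults to the profile's
#'   platform presets.
#' @return Sorted, disjoint region data.frame with columns chrom,
#'   start/end (1-based inclusive CpG span), n_cpg, mean_beta, state.
#' @export
segment_profile <- function(profile, site_calls = NULL,
                            config = NULL) {
  stopifnot(inherits(profile, "methylation_profile"))
  if (is.null(config)) config <- segmentation_config(profile$platform)
  if (nrow(profile$records) == 0L) return(empty_regions())
  if (is.null(site_calls)) {
    site_calls <- call_site_states(
      profile, init_cutoff = config$init_cutoff,
      bimodality = config$bimodality, hmm_tol = config$hmm_tol,
      hmm_max_iter = config$hmm_max_iter, pseudocount = config$pseudocount,
      sigma_floor = config$sigma_floor
    )
  }
  regions <- build_primary_regions(profile, site_calls, config)
  regions <- filter_small_regions(regions, config)
  regions <- remerge_regions(regions, profile, config)
  classify_regions(regions, config)
}
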