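## Two-layer two-state calling.
##
## Layer 1 splits observations into low-/high-methyl classes with one
## two-state HMM.  Each class is then inspected: if its methylation-level
## distribution is bimodal, a second two-state HMM splits it again,
## turning two classes into three final labels (low class -> {un, middle},
## high class -> {middle, full}); a unimodal class maps straight to the
## outer label.  The same machinery labels CpG sites (UMS/MMS/FMS) and,
## applied to region mean beta-values, regions (UMR/MMR/FMR).

## Generic two-layer run over observation chains.
## Returns final labels 1 (low), 2 (middle), 3 (high) per observation in
## chain order, plus layer-1 states and diagnostics.
two_layer_call <- function(chains, init_cutoff = 0.6,
                           bimodality = bimodality_config(),
                           hmm_tol = 1e-4, hmm_max_iter = 100L,
                           pseudocount = 0.5, sigma_floor = 1e-3) {
  chains <- check_chains(chains)
  lens <- lengths(chains)
  obs_all <- unlist(chains, use.names = FALSE)
  n <- length(obs_all)
  diagnostics <- list(layer1_fit = NULL, layer2_fits = list(),
                      verdicts = list())

  ## ---- layer 1 ----
  init_grp <- unlist(initialize_states(chains, init_cutoff),
                     use.names = FALSE)
  if (length(unique(init_grp)) < 2L) {
    ## one-class input: no two-state model can be initialized
    layer1 <- init_grp
  } else {
    fit1 <- baum_welch(chains, initialize_hmm(chains, init_cutoff,
                                              pseudocount, sigma_floor),
                       tol = hmm_tol, max_iter = hmm_max_iter,
                       sigma_floor = sigma_floor)
    diagnostics$layer1_fit <- fit1
    layer1 <- unlist(viterbi(chains, fit1$params), use.names = FALSE)
  }

  ## ---- layer 2, per class ----
  final <- integer(n)
  for (cls in c(STATE_LOW, STATE_HIGH)) {
    idx <- which(layer1 == cls)
    if (length(idx) == 0L) next
    outer_label <- if (cls == STATE_LOW) 1L else 3L
    vals <- obs_all[idx]
    verdict <- withCallingHandlers(
      assess_bimodality(vals, bimodality),
      warning = function(w) invokeRestart("muffleWarning")
    )
    diagnostics$verdicts[[STATE_LABELS[cls]]] <- verdict
    split_done <- FALSE
    if (verdict$is_bimodal) {
      sub <- split_class(chains, lens, layer1 == cls, stats::median(vals),
                         hmm_tol, hmm_max_iter, pseudocount, sigma_floor)
      if (!is.null(sub)) {
        diagnostics$layer2_fits[[STATE_LABELS[cls]]] <- sub$fit
        ## sub-state with the smaller emission mean takes the lower label
        lower_first <- sub$fit$params$mu[1L] <= sub$fit$params$mu[2L]
        if (cls == STATE_LOW) {
          labels <- if (lower_first) c(1L, 2L) else c(2L, 1L)
        } else {
          labels <- if (lower_first) c(2L, 3L) else c(3L, 2L)
        }
        final[idx] <- labels[sub$states]
        split_done <- TRUE
      }
    }
    if (!split_done) final[idx] <- outer_label
  }
  list(final = final, layer1 = layer1, diagnostics = diagnostics)
}

## Fit a second-layer HMM on the members of one class, re-chained in
## genomic order per chromosome (sites of the other class are skipped
## over).  Returns NULL when a two-state initialization is impossible.
split_class <- function(chains, lens, mask, cutoff, hmm_tol, hmm_max_iter,
                        pseudocount, sigma_floor) {
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  sub_chains <- list()
  for (i in seq_along(chains)) {
    m <- mask[offsets[i] + seq_len(lens[i])]
    if (any(m)) sub_chains[[length(sub_chains) + 1L]] <- chains[[i]][m]
  }
  vals <- unlist(sub_chains, use.names = FALSE)
  if (cutoff <= 0 || cutoff >= 1) return(NULL)
  grp <- vals <= cutoff
  if (!any(grp) || all(grp)) return(NULL)
  init <- tryCatch(
    initialize_hmm(sub_chains, cutoff, pseudocount, sigma_floor),
    error = function(e) NULL
  )
  if (is.null(init)) return(NULL)
  fit <- baum_welch(sub_chains, init, tol = hmm_tol,
                    max_iter = hmm_max_iter, sigma_floor = sigma_floor)
  states <- unlist(viterbi(sub_chains, fit$params), use.names = FALSE)
  list(fit = fit, states = states)
}

profile_chains <- function(profile) {
  rec <- profile$records
  split(rec$beta, factor(rec$chrom, levels = unique(rec$chrom)))
}

#' Call per-CpG methylation states (UMS/MMS/FMS)
#'
#' Runs the two-layer two-state HMM over a methylation profile: layer 1
#' (initialization at `init_cutoff`, Baum-Welch, Viterbi; one chain per
#' chromosome) separates low- from high-methyl sites; each class is
#' re-split by a second HMM when its beta distribution is bimodal,
#' otherwise the low class becomes UMS and the high class FMS wholesale.
#' Middle-methylated calls from both classes share the single MMS label.
#'
#' @param profile A `methylation_profile`.
#' @param init_cutoff Layer-1 initialization cutoff (default 0.6).  The
#'   second layer initializes at the class median.
#' @param bimodality A [bimodality_config()].
#' @param hmm_tol,hmm_max_iter Baum-Welch convergence settings.
#' @param pseudocount,sigma_floor Initialization guards, see
#'   [estimate_transitions()] / [estimate_emissions()].
#' @return A data.frame of class `site_calls` with columns `probe_id`,
#'   `chrom`, `pos`, `beta`, `layer1` ("LOW"/"HIGH") and `final`
#'   ("UMS"/"MMS"/"FMS"), one row per retained CpG, plus a
#'   `"diagnostics"` attribute holding the layer fits and bimodality
#'   verdicts.
#' @export
call_site_states <- function(profile, init_cutoff = 0.6,
                             bimodality = bimodality_config(),
                             hmm_tol = 1e-4, hmm_max_iter = 100L,
                             pseudocount = 0.5, sigma_floor = 1e-3) {
  stopifnot(inherits(profile, "methylation_profile"))
  if (nrow(profile$records) == 0L) stop("empty profile")
  chains <- profile_chains(profile)
  res <- two_layer_call(chains, init_cutoff, bimodality, hmm_tol,
                        hmm_max_iter, pseudocount, sigma_floor)
  rec <- profile$records
  calls <- data.frame(
    probe_id = rec$probe_id, chrom = rec$chrom, pos = rec$pos,
    beta = rec$beta, layer1 = STATE_LABELS[res$layer1],
    final = c("UMS", "MMS", "FMS")[res$final],
    stringsAsFactors = FALSE
  )
  class(calls) <- c("site_calls", "data.frame")
  attr(calls, "diagnostics") <- res$diagnostics
  calls
}

#' Summarize site calls as label counts and mean beta per label
#'
#' @param calls A `site_calls` data.frame.
#' @return data.frame with one row per final label.
#' @export
summarize_site_calls <- function(calls) {
  labs <- c("UMS", "MMS", "FMS")
  data.frame(
    final = labs,
    n = vapply(labs, function(l) sum(calls$final == l), integer(1L)),
    mean_beta = vapply(labs, function(l) {
      if (any(calls$final == l)) mean(calls$beta[calls$final == l]) else NA_real_
    }, numeric(1L)),
    row.names = NULL
  )
}
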