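## Synthetic methylome generator.
##
## Emulates the structure the model assumes in array data: CpG positions
## clustered densely inside CpG islands and sparsely in the open sea, a
## hidden three-state Markov chain (un-/middle-/full-methylated) running
## along each chromosome, and per-state truncated-normal beta noise.
## Ground truth (site states, state-run regions, island intervals) is
## returned alongside the profile so every pipeline stage can be scored.

#' Configuration of the synthetic methylome
#'
#' Defaults aim at HM450K-like geometry: dense islands (20-100 bp probe
#' spacing) embedded in sparse open sea (500-4,000 bp spacing), and
#' well-separated strata at mean beta 0.05 / 0.5 / 0.95 with sd 0.05.
#' The planted chain is sticky (diagonal 0.98) so state runs span tens
#' of CpGs, as methylation domains do.
#'
#' @param n_cpgs Total number of CpGs to generate (default 3000).
#' @param n_chrom Number of synthetic chromosomes (default 2).
#' @param island_every One island is laid down after this many open-sea
#'   CpGs on average (default 12).
#' @param island_len Island length range in bp.
#' @param island_cpg_spacing Probe spacing range inside islands (bp).
#' @param opensea_cpg_spacing Probe spacing range in the open sea (bp).
#' @param state_means Planted mean beta of the three strata (ascending).
#' @param state_sds Planted sd of the three strata.
#' @param state_transition 3x3 row-stochastic transition matrix of the
#'   planted chain.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param platform Platform tag given to the generated profile.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cpgs = 3000L, n_chrom = 2L,
                              island_every = 12L,
                              island_len = c(500L, 2000L),
                              island_cpg_spacing = c(20L, 100L),
                              opensea_cpg_spacing = c(500L, 4000L),
                              state_means = c(0.05, 0.5, 0.95),
                              state_sds = c(0.05, 0.05, 0.05),
                              state_transition = NULL,
                              seed = 1L,
                              platform = c("HM450K", "EPIC", "GENERIC")) {
  if (is.null(state_transition)) {
    state_transition <- matrix(0.01, 3L, 3L)
    diag(state_transition) <- 0.98
  }
  stopifnot(
    n_cpgs >= 1L, n_chrom >= 1L,
    length(state_means) == 3L, length(state_sds) == 3L,
    all(diff(state_means) > 0), all(state_sds >= 0),
    all(island_cpg_spacing > 0), all(opensea_cpg_spacing > 0),
    all(dim(state_transition) == c(3L, 3L)),
    all(abs(rowSums(state_transition) - 1) < 1e-9)
  )
  if (island_len[1L] < island_cpg_spacing[1L]) {
    stop("island_len must be at least the minimum island CpG spacing")
  }
  structure(
    list(n_cpgs = as.integer(n_cpgs), n_chrom = as.integer(n_chrom),
         island_every = as.integer(island_every),
         island_len = as.integer(island_len),
         island_cpg_spacing = as.integer(island_cpg_spacing),
         opensea_cpg_spacing = as.integer(opensea_cpg_spacing),
         state_means = state_means, state_sds = state_sds,
         state_transition = state_transition, seed = as.integer(seed),
         platform = match.arg(platform)),
    class = "simulation_config"
  )
}

#' Stationary distribution of a Markov transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1,
#' normalized to sum to 1.
#'
#' @param P Row-stochastic square matrix.
#' @return Numeric stationary probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Generate a synthetic methylome with known truth
#'
#' Lays out alternating open-sea and island blocks on each chromosome,
#' walks the planted three-state Markov chain over the CpGs (initialized
#' from its stationary distribution), and emits beta-values from the
#' per-state truncated normal on \[0, 1\] (inverse-cdf sampling, so the
#' boundaries carry no artificial atoms).
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_truth` with:
#'   * `profile`: an island-annotated `methylation_profile`;
#'   * `true_site_state`: planted per-CpG label ("UMS"/"MMS"/"FMS");
#'   * `true_regions`: planted state runs as a region data.frame
#'     (1-based inclusive spans, states "UMR"/"MMR"/"FMR");
#'   * `islands`: the island annotation (0-based half-open BED frame).
#' @export
simulate_methylome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_methylome_impl(config))
}

simulate_methylome_impl <- function(config) {
  per_chrom <- diff(round(seq(0L, config$n_cpgs,
                              length.out = config$n_chrom + 1L)))
  runif_int <- function(n, range) {
    if (range[1L] == range[2L]) rep(range[1L], n)
    else sample(seq(range[1L], range[2L]), n, replace = TRUE)
  }
  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  recs <- list()
  isl <- list()
  for (ci in seq_len(config$n_chrom)) {
    n_target <- per_chrom[ci]
    pos <- integer(0)
    in_island <- logical(0)
    cursor <- 1000L
    while (length(pos) < n_target) {
      ## open-sea stretch
      n_os <- max(1L, stats::rpois(1L, config$island_every))
      sp <- runif_int(n_os, config$opensea_cpg_spacing)
      p <- cursor + cumsum(sp)
      pos <- c(pos, p)
      in_island <- c(in_island, rep(FALSE, n_os))
      cursor <- p[n_os]
      if (length(pos) >= n_target) break
      ## island block
      len <- runif_int(1L, config$island_len)
      start <- cursor + runif_int(1L, config$opensea_cpg_spacing)
      p <- start
      repeat {
        nxt <- p[length(p)] + runif_int(1L, config$island_cpg_spacing)
        if (nxt > start + len) break
        p <- c(p, nxt)
      }
      isl[[length(isl) + 1L]] <- data.frame(
        chrom = chrom_names[ci], start = start - 1L,
        end = start + len, stringsAsFactors = FALSE
      )
      pos <- c(pos, p)
      in_island <- c(in_island, rep(TRUE, length(p)))
      cursor <- max(p)
    }
    keep <- seq_len(n_target)
    recs[[ci]] <- data.frame(
      chrom = chrom_names[ci], pos = pos[keep],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, recs)
  n <- nrow(rec)
  rec$probe_id <- sprintf("cg%08d", seq_len(n))
  ## planted Markov chain, restarted per chromosome
  pi0 <- stationary_distribution(config$state_transition)
  state <- integer(n)
  for (ci in seq_len(config$n_chrom)) {
    ii <- which(rec$chrom == chrom_names[ci])
    state[ii[1L]] <- sample(1:3, 1L, prob = pi0)
    for (k in seq_along(ii)[-1L]) {
      state[ii[k]] <- sample(1:3, 1L,
                             prob = config$state_transition[state[ii[k - 1L]], ])
    }
  }
  rec$beta <- rtnorm01(n, config$state_means[state],
                       config$state_sds[state])
  rec$detection_p <- 0.001
  islands_df <- if (length(isl)) do.call(rbind, isl) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  islands <- structure(islands_df[order(islands_df$chrom, islands_df$start), ,
                                  drop = FALSE],
                       class = c("island_annotation", "data.frame"))
  rownames(islands) <- NULL
  profile <- methylation_profile(rec, config$platform)
  profile <- annotate_islands(profile, islands)
  ## planted regions = maximal runs of one state per chromosome
  prec <- profile$records
  pstate <- state[order(rec$chrom, rec$pos)]
  runs <- list()
  for (ci in unique(prec$chrom)) {
    ii <- which(prec$chrom == ci)
    r <- rle(pstate[ii])
    ends <- cumsum(r$lengths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    runs[[ci]] <- data.frame(
      chrom = ci,
      start = prec$pos[ii[starts]], end = prec$pos[ii[ends]],
      n_cpg = r$lengths,
      state = c("UMR", "MMR", "FMR")[r$values],
      stringsAsFactors = FALSE
    )
  }
  true_regions <- do.call(rbind, runs)
  rownames(true_regions) <- NULL
  structure(
    list(profile = profile,
         true_site_state = c("UMS", "MMS", "FMS")[pstate],
         true_regions = true_regions,
         islands = islands,
         config = config),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "synthetic methylome: %d CpGs, %d chromosome(s), %d islands, %d planted regions\n",
    nrow(x$profile$records), length(unique(x$profile$records$chrom)),
    nrow(x$islands), nrow(x$true_regions)
  ))
  invisible(x)
}
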