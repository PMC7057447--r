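cfg450 <- segmentation_config("HM450K")
cfg_epic <- segmentation_config("EPIC")

test_that("gap thresholds follow island membership and platform", {
  expect_identical(gap_threshold(TRUE, TRUE, cfg450), 300L)
  expect_identical(gap_threshold(FALSE, FALSE, cfg450), 11300L)
  expect_identical(gap_threshold(FALSE, FALSE, cfg_epic), 4800L)
  # mixed pair uses the permissive open-sea gap
  expect_identical(gap_threshold(TRUE, FALSE, cfg450), 11300L)
  expect_error(gap_threshold(NA, TRUE, cfg450), "annotate")
  expect_error(segmentation_config("GENERIC"), "opensea_gap")
  expect_identical(segmentation_config("GENERIC", opensea_gap = 5000L)$opensea_gap,
                   5000L)
})

test_that("primary regions split on gap or state change", {
  # island sites at 1000/1100/1900, all UMS: 1900 is 800 bp away (> 300)
  prof <- make_profile(pos = c(1000L, 1100L, 1900L), beta = c(0.05, 0.06, 0.04),
                       island = TRUE, platform = "HM450K")
  regions <- build_primary_regions(prof, make_calls(prof, "UMS"), cfg450)
  expect_equal(nrow(regions), 2L)
  expect_equal(regions$n_cpg, c(2L, 1L))
  expect_equal(regions$start, c(1000L, 1900L))
  expect_equal(regions$end, c(1100L, 1900L))

  # small gap but different states: still two regions
  prof2 <- make_profile(pos = c(1000L, 1100L), beta = c(0.05, 0.95),
                        island = TRUE, platform = "HM450K")
  calls2 <- make_calls(prof2, c("UMS", "FMS"))
  expect_equal(nrow(build_primary_regions(prof2, calls2, cfg450)), 2L)

  # single site: one 1-CpG region
  prof3 <- make_profile(pos = 500L, beta = 0.5, island = FALSE)
  r3 <- build_primary_regions(prof3, make_calls(prof3, "MMS"),
                              segmentation_config("GENERIC", opensea_gap = 1000L))
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$n_cpg, 1L)
})

test_that("regions below the CpG minimum are dropped and remembered", {
  prof <- make_profile(pos = c(1000L, 1100L, 5000L, 5100L, 5200L),
                       beta = c(0.1, 0.1, 0.9, 0.9, 0.9), island = TRUE,
                       platform = "HM450K")
  calls <- make_calls(prof, c("UMS", "UMS", "FMS", "FMS", "FMS"))
  prim <- build_primary_regions(prof, calls, cfg450)
  expect_equal(nrow(prim), 2L)
  filt <- filter_small_regions(prim, cfg450)
  expect_equal(nrow(filt), 1L) # the 2-CpG region is gone
  expect_equal(filt$n_cpg, 3L) # exactly 3 CpGs is kept (boundary)
  expect_identical(attr(filt, "unassigned"), c(1L, 2L))
  empty <- filter_small_regions(prim[0, ], cfg450)
  expect_equal(nrow(empty), 0L)
})

test_that("re-merge heals fragmentation across a dropped flicker", {
  # UMS x3 .. [MMS x2 flicker] .. UMS x3, all island-associated, gaps 100
  pos <- c(1000L, 1100L, 1200L, 1300L, 1400L, 1500L, 1600L, 1700L)
  beta <- c(0.05, 0.05, 0.05, 0.5, 0.5, 0.05, 0.05, 0.05)
  st <- c("UMS", "UMS", "UMS", "MMS", "MMS", "UMS", "UMS", "UMS")
  prof <- make_profile(pos = pos, beta = beta, island = TRUE,
                       platform = "HM450K")
  calls <- make_calls(prof, st)
  prim <- build_primary_regions(prof, calls, cfg450)
  expect_equal(nrow(prim), 3L)
  filt <- filter_small_regions(prim, cfg450)
  expect_equal(nrow(filt), 2L)
  merged <- remerge_regions(filt, prof, cfg450)
  expect_equal(nrow(merged), 1L)
  # the dropped flicker pair is re-absorbed
  expect_equal(merged$n_cpg, 8L)
  expect_equal(merged$start, 1000L)
  expect_equal(merged$end, 1700L)
  expect_equal(merged$mean_beta, mean(beta))
  # fixpoint: re-running changes nothing
  again <- remerge_regions(merged, prof, cfg450)
  expect_equal(as.data.frame(again), as.data.frame(merged))
})

test_that("re-merge joins differing-state flanks only across dropped CpGs", {
  # UMS block, dropped 1-CpG flicker, FMS block: heals (flicker between)
  prof <- make_profile(pos = c(1:3 * 100L, 350L, 401L, 501L, 601L),
                       beta = c(0.05, 0.05, 0.05, 0.5, 0.95, 0.95, 0.95),
                       island = TRUE, platform = "HM450K")
  calls <- make_calls(prof, c(rep("UMS", 3), "MMS", rep("FMS", 3)))
  filt <- filter_small_regions(build_primary_regions(prof, calls, cfg450),
                               cfg450)
  expect_equal(nrow(filt), 2L)
  merged <- remerge_regions(filt, prof, cfg450)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_cpg, 7L)
  expect_true(is.na(merged$site_state))

  # same geometry but nothing dropped between: the state boundary stays
  prof2 <- make_profile(pos = c(1:3 * 100L, 401L, 501L, 601L),
                        beta = c(0.05, 0.05, 0.05, 0.95, 0.95, 0.95),
                        island = TRUE, platform = "HM450K")
  calls2 <- make_calls(prof2, c(rep("UMS", 3), rep("FMS", 3)))
  filt2 <- filter_small_regions(build_primary_regions(prof2, calls2, cfg450),
                                cfg450)
  merged2 <- remerge_regions(filt2, prof2, cfg450)
  expect_equal(nrow(merged2), 2L)

  # strict same-state-only configuration refuses the healing merge too
  strict <- segmentation_config("HM450K", remerge_same_state_only = TRUE)
  expect_equal(nrow(remerge_regions(filt, prof, strict)), 2L)
})

test_that("re-merge leaves far-apart regions alone", {
  prof <- make_profile(pos = c(1:3 * 100L, 50000L + 1:3 * 100L),
                       beta = rep(c(0.05, 0.95), each = 3), island = FALSE,
                       platform = "HM450K")
  calls <- make_calls(prof, rep(c("UMS", "FMS"), each = 3))
  filt <- filter_small_regions(build_primary_regions(prof, calls, cfg450),
                               cfg450)
  merged <- remerge_regions(filt, prof, cfg450)
  expect_equal(nrow(merged), 2L) # 50 kb > 11,300
})

test_that("region classification recovers planted strata and their order", {
  # alternating low/middle/high blocks of 4 CpGs, 36 regions after build
  withr::with_seed(77, {
    means <- rep(c(0.05, 0.5, 0.95), times = 12L)
    pos <- integer(0)
    beta <- numeric(0)
    st <- character(0)
    p <- 0L
    for (b in seq_along(means)) {
      pos <- c(pos, p + 1:4 * 100L)
      p <- max(pos) + 20000L # force a region break between blocks
      beta <- c(beta, pmin(pmax(rnorm(4, means[b], 0.03), 0), 1))
      st <- c(st, rep(c("UMS", "MMS", "FMS")[(b - 1L) %% 3L + 1L], 4))
    }
    prof <- make_profile(pos = pos, beta = beta, island = FALSE,
                         platform = "HM450K")
    calls <- make_calls(prof, st)
    regions <- segment_profile(prof, calls, cfg450)
    expect_equal(nrow(regions), 36L)
    planted <- rep(c("UMR", "MMR", "FMR"), times = 12L)
    expect_gte(mean(regions$state == planted), 0.9)
    mb <- tapply(regions$mean_beta, regions$state, mean)
    expect_lt(mb[["UMR"]], mb[["MMR"]])
    expect_lt(mb[["MMR"]], mb[["FMR"]])
  })
})

test_that("few regions trigger the threshold fallback with a warning", {
  prof <- make_profile(pos = c(1:3 * 100L, 50000L + 1:3 * 100L),
                       beta = c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5), island = FALSE,
                       platform = "HM450K")
  calls <- make_calls(prof, rep(c("UMS", "MMS"), each = 3))
  filt <- filter_small_regions(build_primary_regions(prof, calls, cfg450),
                               cfg450)
  expect_warning(out <- classify_regions(filt, cfg450), "fixed thresholds")
  expect_identical(out$state, c("UMR", "MMR"))
})

test_that("an all-low profile yields only unmethylated regions", {
  prof <- make_profile(pos = 1:30 * 100L,
                       beta = withr::with_seed(6, runif(30, 0, 0.15)),
                       island = FALSE, platform = "HM450K")
  calls <- make_calls(prof, "UMS")
  regions <- suppressWarnings(segment_profile(prof, calls, cfg450))
  expect_true(all(regions$state == "UMR"))
})

test_that("the composed pipeline keeps regions sorted, disjoint and large enough", {
  sim <- simulate_methylome(simulation_config(n_cpgs = 1200L, seed = 3L))
  calls <- call_site_states(sim$profile)
  regions <- segment_profile(sim$profile, calls)
  expect_true(all(regions$n_cpg >= 3L))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    expect_true(all(diff(r$start) > 0))
    expect_true(all(r$start[-1L] > r$end[-nrow(r)])) # disjoint
    expect_true(all(r$start <= r$end))
  }
  # deterministic
  expect_identical(as.data.frame(segment_profile(sim$profile, calls)),
                   as.data.frame(regions))
  # empty profile
  empty <- make_profile(pos = integer(0), beta = numeric(0))
  expect_equal(nrow(segment_profile(empty, config = cfg450)), 0L)
})

test_that("planted state-change boundaries are recovered within one probe gap", {
  sim <- simulate_methylome(simulation_config(n_cpgs = 2000L, seed = 9L))
  calls <- call_site_states(sim$profile)
  regions <- segment_profile(sim$profile, calls)
  hit <- 0L
  tot <- 0L
  for (ch in unique(sim$true_regions$chrom)) {
    tr <- sim$true_regions[sim$true_regions$chrom == ch, ]
    cr <- regions[regions$chrom == ch, ]
    pos <- sim$profile$records$pos[sim$profile$records$chrom == ch]
    if (nrow(tr) < 2L || nrow(cr) == 0L) next
    called_bounds <- sort(unique(c(cr$start, cr$end)))
    for (b in tr$end[-nrow(tr)]) { # planted state-change boundaries
      tot <- tot + 1L
      # allowed slack: one inter-CpG gap around the boundary probe
      i <- findInterval(b, pos)
      lo <- if (i >= 2L) pos[i - 1L] else pos[1L]
      hi <- if (i < length(pos)) pos[i + 1L] else pos[length(pos)]
      if (any(called_bounds >= lo & called_bounds <= hi)) hit <- hit + 1L
    }
  }
  expect_gte(hit / tot, 0.8)
})
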