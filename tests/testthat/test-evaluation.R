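test_that("overlap matrix handles identity, disjoint and partial overlap", {
  a <- data.frame(chrom = "chr1", start = c(1L, 201L), end = c(100L, 300L),
                  state = c("UMR", "FMR"), stringsAsFactors = FALSE)
  # identity
  om <- overlap_matrix(a, a)
  expect_equal(om$row_fractions, diag(2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # disjoint
  b <- data.frame(chrom = "chr1", start = 1001L, end = 1100L, state = "UMR")
  expect_true(all(overlap_matrix(a, b)$row_fractions == 0))
  # half overlap: [0,100) FMR vs [50,150) FMR in BED coordinates
  a2 <- data.frame(chrom = "chr1", start = 0L, end = 100L, state = "FMR")
  b2 <- data.frame(chrom = "chr1", start = 50L, end = 150L, state = "FMR")
  om2 <- overlap_matrix(a2, b2, zero_based_a = TRUE, zero_based_b = TRUE)
  expect_equal(om2$basepair_overlap[1L, 1L], 50)
  expect_equal(om2$row_fractions[1L, 1L], 0.5)
})

test_that("overlap base-pair counts are symmetric and bounded by row totals", {
  withr::with_seed(19, {
    mk <- function() {
      n <- 15L
      start <- sort(sample.int(5000L, n)) * 10L
      width <- sample(50:500, n, replace = TRUE)
      # enforce disjointness by construction on one chromosome
      start <- cumsum(width + sample(10:200, n, replace = TRUE))
      data.frame(chrom = "chr1", start = start, end = start + width,
                 state = sample(c("UMR", "MMR", "FMR"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    a <- mk()
    b <- mk()
    ab <- overlap_matrix(a, b)
    ba <- overlap_matrix(b, a)
    common_r <- intersect(ab$row_labels, ba$col_labels)
    common_c <- intersect(ab$col_labels, ba$row_labels)
    expect_equal(ab$basepair_overlap[common_r, common_c],
                 t(ba$basepair_overlap)[common_r, common_c])
    expect_true(all(rowSums(ab$basepair_overlap) <= ab$row_total_bp + 1e-9))
    expect_true(all(rowSums(ab$row_fractions) <= 1 + 1e-12))
  })
})

test_that("count-weighted fractions count regions, not base pairs", {
  a <- data.frame(chrom = "chr1", start = c(1L, 1001L), end = c(10L, 2000L),
                  state = "FMR", stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", start = 1L, end = 10L, state = "FMR",
                  stringsAsFactors = FALSE)
  om_bp <- overlap_matrix(a, b, weight = "bp")
  om_ct <- overlap_matrix(a, b, weight = "count")
  expect_equal(om_bp$row_fractions[1L, 1L], 10 / 1010)
  expect_equal(om_ct$row_fractions[1L, 1L], 0.5) # 1 of 2 regions touches b
})

test_that("common-site correlation matches hand computations", {
  pa <- make_profile(pos = c(10L, 20L, 30L), beta = c(0.1, 0.2, 0.4))
  pb <- make_profile(pos = c(10L, 20L, 30L), beta = c(0.2, 0.3, 0.8))
  res <- common_site_correlation(pa, pb)
  expect_equal(res$n_common, 3L)
  expect_equal(res$r, stats::cor(c(0.1, 0.2, 0.4), c(0.2, 0.3, 0.8)))
  # closed form for the same numbers: 87 / sqrt(42 * 186)
  expect_equal(res$r, 87 / sqrt(42 * 186), tolerance = 1e-12)
  expect_equal(common_site_correlation(pa, pa)$r, 1)
  pc <- make_profile(pos = c(10L, 20L, 30L), beta = 1 - c(0.1, 0.2, 0.4))
  expect_equal(common_site_correlation(pa, pc)$r, -1)
  # mismatched coordinates
  pd <- make_profile(pos = c(11L, 21L, 31L), beta = c(0.1, 0.2, 0.4))
  expect_error(common_site_correlation(pa, pd), "common")
})

test_that("width summaries use inclusive spans and linear quartiles", {
  r1 <- data.frame(chrom = "chr1", start = 1L, end = 100L, state = "UMR")
  w1 <- width_summary(r1)
  expect_true(all(w1[, c("min", "q1", "median", "q3", "max")] == 100))
  r2 <- data.frame(chrom = "chr1", start = c(1L, 1L, 1L),
                   end = c(10L, 20L, 30L), state = "FMR")
  expect_equal(width_summary(r2)$median, 20)
  # absent state classes are simply omitted
  expect_identical(width_summary(r2)$state, "FMR")
  expect_equal(nrow(width_summary(r2[0, ])), 0L)
})
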