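#!/usr/bin/env Rscript
# Regenerates R/dip-null-table.R: quantiles of the dip statistic under
# samples of the uniform distribution (the least-favourable unimodal
# null), 999 replicates per sample size, RNG seed 20200305.
# Run from the package root:  Rscript tools/make-dip-table.R

pkgload::load_all(".", quiet = TRUE)

ns <- c(10L, 20L, 30L, 50L, 100L, 200L, 500L, 1000L, 2000L)
probs <- c(0.5, 0.7, 0.8, 0.9, 0.95, 0.975, 0.99, 0.995)
n_rep <- 999L

set.seed(20200305)
tab <- t(vapply(ns, function(n) {
  dips <- vapply(seq_len(n_rep), function(i) dip_statistic(runif(n)),
                 numeric(1L))
  stats::quantile(dips, probs = probs, type = 7, names = FALSE)
}, numeric(length(probs))))
dimnames(tab) <- list(as.character(ns), format(probs))

out <- file.path("R", "dip-null-table.R")
con <- file(out, "w")
writeLines(c(
  "## Null quantiles of the dip statistic under uniform samples.",
  "## Generated by tools/make-dip-table.R (999 replicates per n, seed",
  "## 20200305); do not edit by hand.",
  "",
  sprintf("DIP_NULL_PROBS <- c(%s)", paste(format(probs), collapse = ", ")),
  sprintf("DIP_NULL_N <- c(%s)", paste(ns, collapse = "L, ")),
  "",
  "DIP_NULL_QUANTILES <- matrix(c("
), con)
vals <- apply(tab, 1L, function(r) paste(sprintf("%.6f", r), collapse = ", "))
writeLines(paste0("  ", vals, c(rep(",", length(vals) - 1L), "")), con)
writeLines(c(
  sprintf("), nrow = %dL, byrow = TRUE,", length(ns)),
  "  dimnames = list(as.character(DIP_NULL_N), format(DIP_NULL_PROBS)))"
), con)
close(con)
cat("wrote", out, "\n")
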