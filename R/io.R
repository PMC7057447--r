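## Reading/writing the external formats: delimited beta tables (minfi-style
## exports), CpG-island BED, site-call TSV and region BED.  Input probe
## coordinates are 1-based (Illumina manifest convention); BED files are
## 0-based half-open at the boundary, as usual.

#' Column dialect for delimited beta tables
#'
#' Declares the delimiter and the column names that map onto probe id,
#' chromosome, position, beta-value and (optionally) detection p-value.
#'
#' @param sep Field delimiter (default tab).
#' @param probe_id,chrom,pos,beta Column names in the file.
#' @param detection_p Column name of the detection p-value, or `NULL` if
#'   the file has none.
#' @return A list of class `beta_dialect`.
#' @export
beta_dialect <- function(sep = "\t", probe_id = "probe_id", chrom = "chrom",
                         pos = "pos", beta = "beta", detection_p = NULL) {
  structure(
    list(sep = sep, probe_id = probe_id, chrom = chrom, pos = pos,
         beta = beta, detection_p = detection_p),
    class = "beta_dialect"
  )
}

#' Construct a methylation profile
#'
#' A methylation profile is the ordered per-CpG record set for one sample:
#' probe id, chromosome, 1-based position, beta-value in \[0, 1\] and an
#' optional detection p-value, strictly sorted by (chrom, pos).
#'
#' @param records data.frame with columns `probe_id`, `chrom`, `pos`,
#'   `beta` and optionally `detection_p`, `island_member`.
#' @param platform One of `"HM450K"`, `"EPIC"`, `"GENERIC"`.
#' @return An object of class `methylation_profile`.
#' @export
methylation_profile <- function(records, platform = c("HM450K", "EPIC", "GENERIC")) {
  platform <- match.arg(platform)
  req <- c("probe_id", "chrom", "pos", "beta")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  records$probe_id <- as.character(records$probe_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$beta <- as.numeric(records$beta)
  if (is.null(records$detection_p)) {
    records$detection_p <- rep(NA_real_, nrow(records))
  }
  if (is.null(records$island_member)) {
    records$island_member <- rep(NA, nrow(records))
  }
  bad <- which(!is.finite(records$beta) | records$beta < 0 | records$beta > 1)
  if (length(bad)) {
    stop(sprintf("beta-value out of [0, 1] at row %d (value %s)",
                 bad[1L], format(records$beta[bad[1L]])))
  }
  if (any(records$pos < 1L)) stop("positions must be >= 1 (1-based)")
  ord <- order(records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  dup <- duplicated(records[, c("chrom", "pos")])
  if (any(dup)) {
    warning(sprintf("dropping %d record(s) at duplicated (chrom, pos)", sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(list(platform = platform, records = records),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("methylation_profile: %d CpG sites on %d chromosome(s) [%s]\n",
              nrow(x$records), length(unique(x$records$chrom)), x$platform))
  if (!all(is.na(x$records$island_member))) {
    cat(sprintf("  island-associated sites: %d\n", sum(x$records$island_member)))
  }
  invisible(x)
}

#' Read a delimited per-probe beta table
#'
#' @param path File path.
#' @param dialect A [beta_dialect()] describing delimiter/column names.
#' @param platform Array platform of the sample.
#' @return A `methylation_profile`, sorted by (chrom, pos).  Rows with a
#'   missing beta-value are dropped with a message.
#' @export
read_beta_table <- function(path, dialect = beta_dialect(),
                            platform = c("HM450K", "EPIC", "GENERIC")) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = dialect$sep,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#", quote = ""),
    error = function(e) stop("cannot parse beta table '", path, "': ",
                             conditionMessage(e))
  )
  need <- c(dialect$probe_id, dialect$chrom, dialect$pos, dialect$beta)
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("beta table lacks column(s): ", paste(miss, collapse = ", "))
  }
  rec <- data.frame(
    probe_id = as.character(tab[[dialect$probe_id]]),
    chrom = as.character(tab[[dialect$chrom]]),
    pos = tab[[dialect$pos]],
    beta = suppressWarnings(as.numeric(tab[[dialect$beta]])),
    stringsAsFactors = FALSE
  )
  if (!is.null(dialect$detection_p) && dialect$detection_p %in% names(tab)) {
    rec$detection_p <- suppressWarnings(as.numeric(tab[[dialect$detection_p]]))
  }
  na_beta <- is.na(rec$beta)
  if (any(na_beta)) {
    message(sprintf("dropping %d row(s) with missing beta-value", sum(na_beta)))
    rec <- rec[!na_beta, , drop = FALSE]
  }
  bad <- which(rec$beta < 0 | rec$beta > 1)
  if (length(bad)) {
    stop(sprintf("beta-value out of [0, 1] at data row %d of '%s'",
                 which(!na_beta)[bad[1L]], path))
  }
  methylation_profile(rec, match.arg(platform))
}

is_sex_chrom <- function(chrom) {
  tolower(sub("^chr", "", chrom)) %in% c("x", "y")
}

#' Apply probe-level filters
#'
#' Removes probes with detection p-value above `p_cutoff`, probes on the
#' sex chromosomes (tolerant of "X"/"chrX" spellings) and probes on a
#' user-supplied blacklist (e.g. SNP-overlapping probes).  Idempotent.
#'
#' @param profile A `methylation_profile`.
#' @param p_cutoff Detection p-value cutoff in (0, 1); default 0.05.
#'   Probes with missing detection p-value are kept.
#' @param drop_sex Drop chrX/chrY probes (default TRUE).
#' @param blacklist Character vector of probe ids to remove.
#' @return A filtered `methylation_profile`; removal counts per reason are
#'   attached as attribute `"filter_log"` and reported via `message()`.
#' @export
filter_probes <- function(profile, p_cutoff = 0.05, drop_sex = TRUE,
                          blacklist = character(0)) {
  stopifnot(inherits(profile, "methylation_profile"),
            p_cutoff > 0, p_cutoff < 1)
  rec <- profile$records
  by_p <- !is.na(rec$detection_p) & rec$detection_p > p_cutoff
  by_sex <- if (drop_sex) is_sex_chrom(rec$chrom) else rep(FALSE, nrow(rec))
  by_black <- rec$probe_id %in% blacklist
  keep <- !(by_p | by_sex | by_black)
  log <- c(detection_p = sum(by_p), sex_chrom = sum(by_sex),
           blacklist = sum(by_black), kept = sum(keep))
  message(sprintf(
    "filter_probes: removed %d (detection p), %d (sex chrom), %d (blacklist); %d kept",
    log[["detection_p"]], log[["sex_chrom"]], log[["blacklist"]], log[["kept"]]
  ))
  if (!any(keep)) warning("all probes removed by filters")
  out <- profile
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Read a CpG-island annotation from BED
#'
#' BED3+ with 0-based half-open intervals; overlapping or bookended
#' intervals on a chromosome are merged on load.
#'
#' @param path BED file path.
#' @return A data.frame of class `island_annotation` with columns `chrom`,
#'   `start`, `end` (0-based half-open), sorted and disjoint per
#'   chromosome.  An empty file yields an empty annotation.
#' @export
read_island_bed <- function(path) {
  bed <- read_bed3(path)
  if (nrow(bed) == 0L) {
    return(structure(bed, class = c("island_annotation", "data.frame")))
  }
  gr <- GenomicRanges::reduce(bed_to_granges(bed))
  out <- granges_to_bed(gr)
  structure(out, class = c("island_annotation", "data.frame"))
}

## shared BED3 parser with per-line validation
read_bed3 <- function(path, extra_cols = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("line %d of '%s': fewer than 3 BED fields",
                 line_no[which(nf < 3L)[1L]], path))
  }
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1L), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("line %d of '%s': non-numeric BED coordinates",
                 line_no[bad[1L]], path))
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop(sprintf("line %d of '%s': invalid interval (start >= end or start < 0)",
                 line_no[bad[1L]], path))
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  for (k in seq_len(extra_cols)) {
    if (!all(nf >= 3L + k)) break
    out[[paste0("V", 3L + k)]] <- vapply(fields, `[[`, character(1L), 3L + k)
  }
  out
}

bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1L, end = bed$end)
  )
}

granges_to_bed <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Flag island-associated CpG sites
#'
#' A site is island-associated when it lies inside a CpG island or within
#' `flank` bp of an island boundary.  The flag selects the gap threshold
#' used during region building.
#'
#' @param profile A `methylation_profile`.
#' @param islands An `island_annotation` from [read_island_bed()].
#' @param flank Flank in bp (default 300).
#' @return The profile with the `island_member` flag set on every record.
#' @export
annotate_islands <- function(profile, islands, flank = 300L) {
  stopifnot(inherits(profile, "methylation_profile"), flank >= 0)
  rec <- profile$records
  member <- rep(FALSE, nrow(rec))
  if (nrow(islands) > 0L && nrow(rec) > 0L) {
    sites <- GenomicRanges::GRanges(
      seqnames = rec$chrom,
      ranges = IRanges::IRanges(start = rec$pos, width = 1L)
    )
    isl <- bed_to_granges(islands)
    ## maxgap counts positions strictly between the ranges, so being
    ## "within flank bp" of a boundary means a gap of at most flank - 1
    hits <- GenomicRanges::countOverlaps(sites, isl, maxgap = flank - 1L)
    member <- hits > 0L
  }
  profile$records$island_member <- member
  profile
}

#' Write per-CpG state calls as TSV
#'
#' Tab-delimited with header: probe_id, chrom, pos, beta, layer1_state,
#' final_state.
#'
#' @param calls A site-call data.frame from [call_site_states()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_calls <- function(calls, path) {
  out <- data.frame(
    probe_id = calls$probe_id, chrom = calls$chrom, pos = calls$pos,
    beta = calls$beta, layer1_state = calls$layer1, final_state = calls$final,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read site calls written by [write_site_calls()]
#'
#' @param path TSV path.
#' @return data.frame with the same columns (`layer1`, `final` restored).
#' @export
read_site_calls <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(
    probe_id = as.character(tab$probe_id), chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos), beta = as.numeric(tab$beta),
    layer1 = as.character(tab$layer1_state),
    final = as.character(tab$final_state), stringsAsFactors = FALSE
  )
}

#' Write labeled regions as BED6+
#'
#' Columns: chrom, start (0-based), end (half-open), name (UMR/MMR/FMR),
#' score = round(1000 * mean beta), strand ".", then n_cpg and mean_beta.
#' Regions are emitted sorted by (chrom, start).
#'
#' @param regions A region data.frame from [segment_profile()] (1-based
#'   inclusive `start`/`end` spans).
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#` comment lines (e.g. the configuration used).
#' @return Invisibly, `path`.
#' @export
write_region_bed <- function(regions, path, header_comment = NULL) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  if (nrow(regions) > 0L) {
    ord <- order(regions$chrom, regions$start)
    regions <- regions[ord, , drop = FALSE]
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%d\t%.6g",
      regions$chrom, regions$start - 1L, regions$end, regions$state,
      as.integer(round(1000 * regions$mean_beta)), regions$n_cpg,
      regions$mean_beta
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a labeled region BED (as written by [write_region_bed()] or any
#' BED with the state label in column 4)
#'
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive
#'   span, converted back from BED), `state`, and where present `n_cpg`,
#'   `mean_beta`.
#' @export
read_region_bed <- function(path) {
  bed <- read_bed3(path, extra_cols = 5L)
  if (nrow(bed) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    chrom = bed$chrom, start = bed$start + 1L, end = bed$end,
    state = if (!is.null(bed$V4)) bed$V4 else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(bed$V7)) out$n_cpg <- suppressWarnings(as.integer(bed$V7))
  if (!is.null(bed$V8)) out$mean_beta <- suppressWarnings(as.numeric(bed$V8))
  ord <- order(out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
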