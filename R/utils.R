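# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic half-up rounding, used for human-readable percentages so
#' that e.g. 6/33 prints as 18.2%. `base::round()` rounds half to even,
#' which is the wrong convention for reported percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Strip a leading "chr" prefix so "chr14" and "14" compare equal.
normalize_chrom_names <- function(x) {
  sub("^chr", "", x, ignore.case = TRUE)
}

# Convert an interval tibble (chrom/start/end[, region_id]) to a GRanges.
# BED half-open [start, end) becomes the 1-based closed IRanges convention.
as_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
}

# Overlap join between two interval tibbles; returns a tibble of row index
# pairs (query_idx, subject_idx). Any-overlap, strand-agnostic.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query_idx = integer(), subject_idx = integer()))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject))
  )
  tibble(
    query_idx = S4Vectors::queryHits(hits),
    subject_idx = S4Vectors::subjectHits(hits)
  )
}

# Validate an interval tibble: required columns, coordinate sanity,
# unique region ids.
validate_intervals <- function(x, arg = "intervals") {
  required <- c("chrom", "start", "end", "region_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` must have columns %s; missing: %s",
      arg, paste(required, collapse = ", "), paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(x$start < 0)) {
    abort(sprintf("`%s` has negative start coordinates", arg))
  }
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf(
      "`%s` has start >= end at row %d (%s:%d-%d)",
      arg, bad, x$chrom[bad], x$start[bad], x$end[bad]
    ))
  }
  if (anyDuplicated(x$region_id)) {
    dup <- x$region_id[duplicated(x$region_id)][1]
    abort(sprintf("`%s` has duplicated region_id '%s'", arg, dup))
  }
  invisible(x)
}
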