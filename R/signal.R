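# Region x cell-type accessibility matrix and the correlation primitive.
# The matrix is a tibble: a `region_id` column followed by one numeric
# column per cell type. Masked cells (region on a chromosome absent from
# that cell type's signal track) are NA; all unmasked values are >= 0.

#' Aggregate per-base signal over regions
#'
#' Builds the region x cell-type accessibility matrix from per-cell-type
#' coverage tracks in bedGraph form. The cell value is the mean per-base
#' signal over the half-open region `[start, end)`; bases with no coverage
#' record contribute 0 (so a region entirely outside the track scores 0).
#' A region whose chromosome is absent from a track altogether is masked
#' (NA) with a warning, since absence of the chromosome usually means the
#' assay and the region set disagree, not that the region is silent.
#'
#' @param regions Interval tibble of regions to quantify.
#' @param signals Named list of bedGraph tibbles (columns `chrom`, `start`,
#'   `end`, `value`; 0-based half-open), one per cell type. Names become
#'   the matrix's cell-type columns.
#' @param stat Aggregation statistic: `"mean"` (default, per-base mean) or
#'   `"sum"` (total signal).
#' @return A signal-matrix tibble: `region_id` plus one column per cell
#'   type, rows in `regions` order.
#' @export
aggregate_signal <- function(regions, signals, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  validate_intervals(regions, "regions")
  stopifnot(is.list(signals), !is.null(names(signals)),
            all(nzchar(names(signals))))
  cols <- purrr::imap(signals, function(bg, ct) {
    stopifnot(all(c("chrom", "start", "end", "value") %in% names(bg)))
    if (any(bg$value < 0, na.rm = TRUE)) {
      abort(sprintf("negative signal values in track '%s'", ct))
    }
    vals <- numeric(nrow(regions))
    present <- regions$chrom %in% unique(bg$chrom)
    if (any(!present)) {
      warn(sprintf(
        "%d region(s) on chromosomes absent from track '%s'; cells masked",
        sum(!present), ct
      ))
      vals[!present] <- NA_real_
    }
    for (i in which(present)) {
      sel <- bg$chrom == regions$chrom[i] &
        bg$start < regions$end[i] & bg$end > regions$start[i]
      if (any(sel)) {
        ov <- pmin(bg$end[sel], regions$end[i]) -
          pmax(bg$start[sel], regions$start[i])
        total <- sum(ov * bg$value[sel])
      } else {
        total <- 0
      }
      width <- regions$end[i] - regions$start[i]
      vals[i] <- if (stat == "mean") total / width else total
    }
    vals
  })
  dplyr::bind_cols(tibble(region_id = regions$region_id), as_tibble(cols))
}

#' Pearson correlation with validity guards
#'
#' Product-moment correlation of two vectors after pairwise removal of
#' missing entries. Returns NA (rather than an error) when fewer than
#' `min_pairs` complete pairs remain or either vector is constant, so
#' callers can flag undefined correlations instead of dropping regions
#' silently.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum complete pairs for a defined value (default 3).
#' @return The correlation in `[-1, 1]`, or NA if undefined.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
pearson_cor <- function(x, y, min_pairs = 3) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = "pearson")
}

#' Correlate every region with an anchor region
#'
#' Computes, for each row of a signal matrix, the Pearson correlation of
#' its accessibility profile across cell types with the profile of a
#' designated anchor region (typically the target gene's promoter).
#' Regions failing the correlation preconditions (too few unmasked cell
#' types in common with the anchor, or a constant profile) are reported
#' with `r = NA` and a reason code, never dropped.
#'
#' @param m Signal-matrix tibble (`region_id` + one column per cell type).
#' @param anchor_id Region identifier of the anchor; must be present.
#' @param min_pairs Minimum complete cell-type pairs for a defined r.
#' @return A tibble with columns `region_id`, `r`, `n_used` (cell types
#'   contributing), `reason` (NA when r is defined; otherwise
#'   `"too_few_pairs"` or `"zero_variance"`).
#' @export
correlate_with_anchor <- function(m, anchor_id, min_pairs = 3) {
  stopifnot("region_id" %in% names(m))
  if (!anchor_id %in% m$region_id) {
    abort(sprintf("anchor region '%s' not found in the signal matrix",
                  anchor_id))
  }
  ct_cols <- setdiff(names(m), "region_id")
  if (length(ct_cols) < min_pairs) {
    abort(sprintf("signal matrix has %d cell types; need >= %d",
                  length(ct_cols), min_pairs))
  }
  vals <- as.matrix(m[, ct_cols])
  anchor <- vals[match(anchor_id, m$region_id), ]
  res <- purrr::map(seq_len(nrow(vals)), function(i) {
    row <- vals[i, ]
    ok <- !is.na(row) & !is.na(anchor)
    n_used <- sum(ok)
    if (n_used < min_pairs) {
      return(list(r = NA_real_, n_used = n_used, reason = "too_few_pairs"))
    }
    if (sd(row[ok]) == 0 || sd(anchor[ok]) == 0) {
      return(list(r = NA_real_, n_used = n_used, reason = "zero_variance"))
    }
    list(r = cor(row[ok], anchor[ok]), n_used = n_used, reason = NA_character_)
  })
  tibble(
    region_id = m$region_id,
    r = purrr::map_dbl(res, "r"),
    n_used = purrr::map_int(res, ~ as.integer(.x$n_used)),
    reason = purrr::map_chr(res, "reason")
  )
}

#' Read / write a signal matrix as TSV
#'
#' The on-disk layout is one `region_id` column followed by one numeric
#' column per cell type.
#'
#' @param path File path.
#' @return For `read_signal_matrix`, the signal-matrix tibble.
#' @export
read_signal_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(m)[1] != "region_id") {
    names(m)[1] <- "region_id"
  }
  m$region_id <- as.character(m$region_id)
  if (anyDuplicated(m$region_id)) {
    abort("duplicated region_id in signal matrix")
  }
  m
}

#' @rdname read_signal_matrix
#' @param m Signal-matrix tibble.
#' @export
write_signal_matrix <- function(m, path) {
  readr::write_tsv(m, path, progress = FALSE)
  invisible(path)
}
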