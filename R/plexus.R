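# TAD-constrained candidate selection and correlation-threshold plexus
# inference: the CRE-prediction stage.

#' Select candidate regions inside a padded TAD window
#'
#' Returns the accessible regions (DHS) overlapping the window
#' `[tad$start - padding_bp, tad$end + padding_bp)`, clipped at zero.
#' Any overlap with the window counts; the half-open convention means a
#' DHS starting exactly at the padded window end is excluded. The default
#' padding of 40 kb matches one Hi-C bin on either side of the TAD call,
#' absorbing the resolution limit of TAD boundaries.
#'
#' @param dhs Interval tibble of accessible regions.
#' @param tad A single-row interval tibble (the TAD).
#' @param padding_bp Non-negative padding in bp added to both TAD edges.
#' @return The subset of `dhs` overlapping the padded window, input order.
#' @export
candidate_regions <- function(dhs, tad, padding_bp = 40000) {
  validate_intervals(dhs, "dhs")
  validate_intervals(tad, "tad")
  stopifnot(nrow(tad) == 1, padding_bp >= 0)
  window <- genomic_intervals(
    tad$chrom,
    max(0L, tad$start - as.integer(padding_bp)),
    tad$end + as.integer(padding_bp),
    "window"
  )
  dhs[interval_overlaps(dhs, window), , drop = FALSE]
}

#' Infer a regulatory plexus by anchored correlation thresholding
#'
#' The plexus of an anchor region (a gene promoter) is the set of
#' candidate regions whose cross-cell-type accessibility profile
#' correlates with the anchor's profile at Pearson r strictly above the
#' threshold. The default threshold of 0.7 is the conventional cutoff for
#' calling a candidate CRE linked to the promoter. Candidates with an
#' undefined correlation (constant profile, too few shared cell types)
#' are reported with a reason code and never included.
#'
#' @param m Signal-matrix tibble (`region_id` + one column per cell type).
#' @param anchor_id Identifier of the anchor region; must be in `m`.
#' @param candidates Interval tibble of candidate regions, all present in
#'   `m`. The anchor may be among them; it is never a member of its own
#'   plexus.
#' @param threshold Correlation threshold in (-1, 1); membership requires
#'   `r > threshold`, strictly.
#' @param padding_bp Recorded in the result for provenance (the padding
#'   used to select `candidates`, if any).
#' @return A `plexus_result` object: a list with `anchor_id`, `threshold`,
#'   `padding_bp`, and `candidates`, a tibble with per-candidate `r`,
#'   `n_used`, `reason` and logical `included`.
#' @examples
#' m <- tibble::tibble(
#'   region_id = c("P", "E1", "BG"),
#'   a = c(1, 1.1, 5), b = c(2, 2.2, 1), c = c(3, 3.1, 4), d = c(4, 4.2, 2)
#' )
#' cand <- genomic_intervals("chr1", c(0, 100), c(50, 150), c("E1", "BG"))
#' infer_plexus(m, "P", cand, threshold = 0.7)
#' @export
infer_plexus <- function(m, anchor_id, candidates, threshold = 0.7,
                         padding_bp = NA_integer_) {
  if (threshold <= -1 || threshold >= 1) {
    abort("`threshold` must lie strictly inside (-1, 1)")
  }
  validate_intervals(candidates, "candidates")
  missing_regions <- setdiff(candidates$region_id, m$region_id)
  if (length(missing_regions) > 0) {
    abort(sprintf("candidate region(s) absent from the signal matrix: %s",
                  paste(head(missing_regions, 5), collapse = ", ")))
  }
  rvec <- correlate_with_anchor(m, anchor_id)
  cand <- candidates |>
    dplyr::filter(.data$region_id != anchor_id) |>
    dplyr::left_join(rvec, by = "region_id") |>
    dplyr::mutate(included = !is.na(.data$r) & .data$r > threshold)
  structure(
    list(
      anchor_id = anchor_id,
      threshold = threshold,
      padding_bp = padding_bp,
      candidates = cand
    ),
    class = "plexus_result"
  )
}

#' Plexus member regions
#'
#' @param x A `plexus_result`.
#' @return Interval tibble of included members.
#' @export
plexus_members <- function(x) {
  stopifnot(inherits(x, "plexus_result"))
  dplyr::filter(x$candidates, .data$included)
}

#' @export
print.plexus_result <- function(x, ...) {
  cat(sprintf(
    "Regulatory plexus of anchor '%s'\n  threshold r > %g\n  %d candidate(s): %d member(s), %d undefined r\n",
    x$anchor_id, x$threshold, nrow(x$candidates),
    sum(x$candidates$included), sum(is.na(x$candidates$r))
  ))
  invisible(x)
}

#' @rdname infer_plexus
#' @param x A `plexus_result`.
#' @param ... Unused.
#' @method tidy plexus_result
#' @export
tidy.plexus_result <- function(x, ...) {
  x$candidates
}

#' @rdname infer_plexus
#' @method glance plexus_result
#' @export
glance.plexus_result <- function(x, ...) {
  tibble(
    anchor_id = x$anchor_id,
    threshold = x$threshold,
    padding_bp = x$padding_bp,
    n_candidates = nrow(x$candidates),
    n_members = sum(x$candidates$included),
    n_undefined = sum(is.na(x$candidates$r))
  )
}

#' @rdname infer_plexus
#' @param object A `plexus_result`.
#' @method autoplot plexus_result
#' @export
autoplot.plexus_result <- function(object, ...) {
  df <- object$candidates |>
    dplyr::mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$r,
                                   colour = .data$included)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey50"),
      name = "plexus member"
    ) +
    ggplot2::labs(
      x = "genomic position (bp)",
      y = "Pearson r with anchor",
      title = sprintf("Regulatory plexus of %s", object$anchor_id)
    ) +
    ggplot2::theme_minimal()
}

#' Write the plexus candidate table as TSV
#'
#' Columns: region_id, chrom, start, end, r, included.
#'
#' @param x A `plexus_result`.
#' @param path Output path.
#' @export
write_plexus_tsv <- function(x, path) {
  stopifnot(inherits(x, "plexus_result"))
  out <- x$candidates[, c("region_id", "chrom", "start", "end", "r",
                          "included")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
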