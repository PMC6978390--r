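# Region x track annotation, the active-CRE and mutated-CRE filters, and
# the stage-count cascade report.

#' Construct a chromatin track
#'
#' A track is a named set of intervals from one assay: a histone-mark or
#' transcription-factor ChIP-seq peak set, a DHS catalogue, etc. Tracks
#' are stored as one-row tibbles with an interval list-column so that a
#' track collection is just `dplyr::bind_rows()` of tracks.
#'
#' @param name Track label, unique within a collection.
#' @param category One of `"histone"`, `"tf"`, `"dhs"`, `"other"`.
#' @param intervals Interval tibble of peaks.
#' @return A one-row track tibble with columns `name`, `category`,
#'   `intervals` (list-column).
#' @export
chromatin_track <- function(name, category = c("other", "histone", "tf", "dhs"),
                            intervals) {
  category <- match.arg(category)
  validate_intervals(intervals, "intervals")
  tibble(name = name, category = category, intervals = list(intervals))
}

#' Build the region x track annotation matrix
#'
#' One logical column per track: TRUE iff the region overlaps at least
#' one interval of that track (any overlap, strand-agnostic). Row and
#' column order follow the inputs, so the matrix is deterministic.
#'
#' @param regions Interval tibble.
#' @param tracks Track collection (rows of [chromatin_track()]).
#' @return Tibble: `region_id` plus one logical column per track.
#' @export
build_annotation_matrix <- function(regions, tracks) {
  validate_intervals(regions, "regions")
  if (nrow(tracks) > 0 && anyDuplicated(tracks$name)) {
    abort("track names must be unique within a collection")
  }
  out <- tibble(region_id = regions$region_id)
  for (i in seq_len(nrow(tracks))) {
    peaks <- tracks$intervals[[i]]
    hit <- logical(nrow(regions))
    if (nrow(peaks) > 0 && nrow(regions) > 0) {
      hit[unique(overlap_pairs(regions, peaks)$query_idx)] <- TRUE
    }
    out[[tracks$name[i]]] <- hit
  }
  out
}

#' Filter plexus members to those marked by an activity track
#'
#' "Active" means overlapping at least one peak of the designated
#' activity track — in the motivating analysis, H3K27ac profiled in
#' primary tumors, the canonical mark of active enhancers and promoters.
#' Other tracks (TF binding) annotate but never filter.
#'
#' @param members Interval tibble of plexus members.
#' @param activity_track A single track row with `category == "histone"`.
#' @return The subset of `members` overlapping >= 1 activity peak.
#' @export
call_active <- function(members, activity_track) {
  stopifnot(nrow(activity_track) == 1)
  if (activity_track$category != "histone") {
    abort("the activity track must have category 'histone'")
  }
  validate_intervals(members, "members")
  peaks <- activity_track$intervals[[1]]
  if (nrow(peaks) == 0 || nrow(members) == 0) {
    return(members[integer(), , drop = FALSE])
  }
  members[unique(overlap_pairs(members, peaks)$query_idx), , drop = FALSE]
}

#' Run the CRE filter cascade
#'
#' Composes the full prediction cascade: DHS in the padded TAD window ->
#' plexus members (anchored correlation `r > threshold`) -> active members
#' (marked by the activity track) -> mutated members (harboring >= 1
#' somatic SNV), tallying the variants and distinct tumors involved.
#' The counts are monotone non-increasing across stages by construction.
#'
#' @param dhs Interval tibble of accessible regions.
#' @param tad Single-row interval tibble.
#' @param m Signal-matrix tibble.
#' @param anchor_id Anchor region identifier.
#' @param activity_track Single histone track row ([chromatin_track()]).
#' @param variants Variant tibble (see [read_variants()]); may be empty.
#' @param threshold Correlation threshold (default 0.7).
#' @param padding_bp Window padding in bp (default 40000).
#' @param normalize_chrom Passed to [assign_variants()].
#' @return A `cascade_report` object with counts `n_dhs_in_window`,
#'   `n_plexus_members`, `n_active`, `n_mutated`, `n_variants`,
#'   `n_tumors`, `fraction_mutated` (NA when no member is active), and
#'   the underlying component results.
#' @export
run_cascade <- function(dhs, tad, m, anchor_id, activity_track, variants,
                        threshold = 0.7, padding_bp = 40000,
                        normalize_chrom = FALSE) {
  window_dhs <- candidate_regions(dhs, tad, padding_bp)
  plexus <- infer_plexus(m, anchor_id, window_dhs, threshold, padding_bp)
  members <- plexus_members(plexus)[, c("chrom", "start", "end", "region_id",
                                        "strand")]
  active <- call_active(members, activity_track)
  assignments <- assign_variants(variants, active,
                                 normalize_chrom = normalize_chrom)
  mutated_ids <- unique(assignments$region_id)
  n_active <- nrow(active)
  n_mutated <- length(mutated_ids)
  structure(
    list(
      n_dhs_in_window = nrow(window_dhs),
      n_plexus_members = nrow(members),
      n_active = n_active,
      n_mutated = n_mutated,
      n_variants = nrow(assignments),
      n_tumors = length(unique(assignments$tumor_id)),
      fraction_mutated = if (n_active > 0) n_mutated / n_active else NA_real_,
      anchor_id = anchor_id,
      threshold = threshold,
      padding_bp = padding_bp,
      plexus = plexus,
      active = active,
      assignments = assignments
    ),
    class = "cascade_report"
  )
}

#' Mutated-CRE percentage, printed convention
#'
#' The fraction of active CREs harboring >= 1 SNV, as a percentage
#' rounded half-up to one decimal (so 6 of 33 prints as 18.2).
#'
#' @param n_mutated,n_active Stage counts.
#' @return Percentage (one decimal) or NA when `n_active` is 0.
#' @examples
#' mutated_percent(6, 33) # 18.2
#' @export
mutated_percent <- function(n_mutated, n_active) {
  if (n_active == 0) return(NA_real_)
  round_half_up(100 * n_mutated / n_active, 1)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.cascade_report <- function(x, ...) {
  pct <- if (is.na(x$fraction_mutated)) {
    "n/a (no active CREs)"
  } else {
    sprintf("%.1f%%", mutated_percent(x$n_mutated, x$n_active))
  }
  c(
    sprintf("CRE filter cascade (anchor '%s', r > %g, padding %d bp)",
            x$anchor_id, x$threshold, as.integer(x$padding_bp)),
    sprintf("  DHS in TAD window        : %d", x$n_dhs_in_window),
    sprintf("  plexus members           : %d", x$n_plexus_members),
    sprintf("  active (marked) members  : %d", x$n_active),
    sprintf("  mutated active members   : %d", x$n_mutated),
    sprintf("  SNVs in mutated members  : %d", x$n_variants),
    sprintf("  distinct tumors          : %d", x$n_tumors),
    sprintf("  mutated fraction         : %s", pct)
  )
}

#' @rdname run_cascade
#' @param x A `cascade_report`.
#' @param ... Unused.
#' @method tidy cascade_report
#' @export
tidy.cascade_report <- function(x, ...) {
  tibble(
    stage = c("dhs_in_window", "plexus_members", "active", "mutated"),
    count = c(x$n_dhs_in_window, x$n_plexus_members, x$n_active, x$n_mutated)
  )
}

#' @rdname run_cascade
#' @method glance cascade_report
#' @export
glance.cascade_report <- function(x, ...) {
  tibble(
    n_dhs_in_window = x$n_dhs_in_window,
    n_plexus_members = x$n_plexus_members,
    n_active = x$n_active,
    n_mutated = x$n_mutated,
    n_variants = x$n_variants,
    n_tumors = x$n_tumors,
    fraction_mutated = x$fraction_mutated
  )
}

#' @rdname run_cascade
#' @param object A `cascade_report`.
#' @method autoplot cascade_report
#' @export
autoplot.cascade_report <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "regions surviving",
                  title = "CRE filter cascade") +
    ggplot2::theme_minimal()
}

#' Serialize a cascade report to JSON
#'
#' @param x A `cascade_report`.
#' @param path Output path.
#' @export
write_cascade_json <- function(x, path) {
  stopifnot(inherits(x, "cascade_report"))
  out <- list(
    anchor = x$anchor_id,
    threshold = x$threshold,
    padding_bp = x$padding_bp,
    n_dhs_in_window = x$n_dhs_in_window,
    n_plexus_members = x$n_plexus_members,
    n_active = x$n_active,
    n_mutated = x$n_mutated,
    n_variants = x$n_variants,
    n_tumors = x$n_tumors,
    fraction_mutated_pct = mutated_percent(x$n_mutated, x$n_active)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
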