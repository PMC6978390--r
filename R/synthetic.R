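# Synthetic-data generators. They produce inputs with the statistical
# structure the analysis assumes -- a multi-cell-type accessibility
# matrix with a planted correlated member set, TAD and peak intervals,
# somatic SNVs, essentiality scores -- plus a truth manifest, so every
# pipeline stage is testable without external downloads.

# Lay out fixed-width regions: an anchor and planted members inside a
# synthetic TAD, background inside the TAD, in the padding zone, and
# beyond the padded window (so window selection is exercised). Slot-based
# placement guarantees >= 120 bp between neighbouring regions, leaving
# room for jittered activity peaks that cover exactly one region.
layout_regions <- function(n_members, n_background, region_width = 500L,
                           tad_start = 1000000L, tad_width = 440000L,
                           padding_bp = 40000L, chrom = "chrS") {
  tad_end <- tad_start + tad_width
  n_bg_tad <- ceiling(0.6 * n_background)
  n_bg_pad <- ceiling(0.2 * n_background)
  n_bg_out <- n_background - n_bg_tad - n_bg_pad

  place_in <- function(lo, hi, n) {
    if (n == 0) return(integer())
    slot <- (hi - lo) %/% n
    stopifnot(slot >= region_width + 120L)
    lo + (seq_len(n) - 1L) * slot + 60L +
      floor(runif(n) * (slot - region_width - 120L))
  }

  n_inside <- 1L + n_members + n_bg_tad
  starts_in <- place_in(tad_start, tad_end, n_inside)
  anchor_slot <- (n_inside + 1L) %/% 2L
  member_slots <- sort(sample(setdiff(seq_len(n_inside), anchor_slot),
                              n_members))
  bg_tad_slots <- setdiff(seq_len(n_inside), c(anchor_slot, member_slots))

  starts_pad <- c(
    place_in(tad_start - padding_bp, tad_start, ceiling(n_bg_pad / 2)),
    place_in(tad_end, tad_end + padding_bp, n_bg_pad %/% 2)
  )
  starts_out <- if (n_bg_out > 0) {
    tad_end + padding_bp + 2000L + (seq_len(n_bg_out) - 1L) * 2000L
  } else {
    integer()
  }

  ids_member <- sprintf("M%03d", seq_len(n_members))
  ids_bg <- sprintf("BG%03d", seq_len(n_bg_tad + length(starts_pad) +
                                        length(starts_out)))
  starts <- c(starts_in[anchor_slot], starts_in[member_slots],
              starts_in[bg_tad_slots], starts_pad, starts_out)
  ids <- c("anchor_promoter", ids_member, ids_bg)
  regions <- genomic_intervals(chrom, starts, starts + region_width, ids)
  list(
    regions = regions,
    tad = genomic_intervals(chrom, tad_start, tad_end, "TAD1"),
    anchor_id = "anchor_promoter",
    member_ids = ids_member,
    in_window_ids = ids[starts < tad_end + padding_bp &
                          starts + region_width > tad_start - padding_bp],
    padding_bp = padding_bp
  )
}

#' Simulate a multi-cell-type accessibility panel with a planted plexus
#'
#' Generates a region x cell-type signal matrix in which a designated
#' anchor (a synthetic promoter) and `n_members` planted member regions
#' share a common accessibility profile at generation correlation `rho`,
#' while background regions are independent. Latent profiles are
#' Gaussian: the anchor profile is i.i.d. standard normal over cell
#' types, each member is `rho * anchor + sqrt(1 - rho^2) * noise`, and a
#' single global affine shift maps all values onto a non-negative scale
#' (Pearson correlation is location/scale invariant, so planted
#' correlations are preserved exactly).
#'
#' Regions are 500 bp wide, laid out inside a synthetic 440-kb TAD with
#' background both inside the TAD, in the 40-kb padding zone flanking it,
#' and beyond the padded window, so downstream window selection is
#' exercised.
#'
#' @param n_background Number of independent background regions.
#' @param n_members Number of planted plexus members.
#' @param n_celltypes Number of cell types (>= 5).
#' @param rho Generation correlation in (0, 1].
#' @param seed Integer seed; all randomness in the call flows from it.
#' @return A list: `matrix` (signal-matrix tibble), `regions` (interval
#'   tibble), `tad` (single-row interval tibble), and `truth`, the
#'   planted-truth manifest (`anchor_id`, `member_ids`, `rho`,
#'   `in_window_ids`, `padding_bp`, counts).
#' @export
simulate_accessibility_panel <- function(n_background = 200, n_members = 10,
                                         n_celltypes = 50, rho = 0.95,
                                         seed = 1L) {
  if (n_celltypes < 5) abort("`n_celltypes` must be >= 5")
  if (rho <= 0 || rho > 1) abort("`rho` must lie in (0, 1]")
  set.seed(seed)
  lay <- layout_regions(n_members, n_background)
  n_regions <- nrow(lay$regions)

  anchor_profile <- rnorm(n_celltypes)
  z <- matrix(rnorm(n_regions * n_celltypes), nrow = n_regions)
  rownames(z) <- lay$regions$region_id
  z[lay$anchor_id, ] <- anchor_profile
  for (mid in lay$member_ids) {
    z[mid, ] <- rho * anchor_profile + sqrt(1 - rho^2) * z[mid, ]
  }
  vals <- z - min(z) + 0.1  # one global affine shift; correlations intact

  m <- dplyr::bind_cols(
    tibble(region_id = lay$regions$region_id),
    as_tibble(setNames(
      as.data.frame(vals, optional = TRUE),
      sprintf("CT%02d", seq_len(n_celltypes))
    ))
  )
  truth <- list(
    anchor_id = lay$anchor_id,
    member_ids = lay$member_ids,
    rho = rho,
    padding_bp = lay$padding_bp,
    in_window_ids = lay$in_window_ids,
    n_members = length(lay$member_ids),
    n_dhs_in_window = length(lay$in_window_ids),
    seed = as.integer(seed)
  )
  list(matrix = m, regions = lay$regions, tad = lay$tad, truth = truth)
}

#' Simulate activity peaks and somatic SNVs over a planted plexus
#'
#' Marks a chosen fraction of the planted members with an activity track
#' (peaks jittered to extend 10-50 bp past the region edges, but never
#' far enough to touch a neighbouring region), then plants SNVs
#' uniformly inside a subset of the marked members. Tumor identifiers
#' come from a pool of `n_tumors`; when there are at least as many
#' variants as tumors, every tumor in the pool contributes at least one
#' variant, so the realized distinct-tumor count equals `n_tumors`.
#'
#' @param panel Output of [simulate_accessibility_panel()].
#' @param marked_fraction Fraction of members marked by the activity
#'   track (count = `round(marked_fraction * n_members)`).
#' @param mutated_count Number of marked members receiving SNVs; must
#'   not exceed the marked count.
#' @param variants_per_region Integer vector recycled over the mutated
#'   members (a constant 1 yields one SNV per mutated member).
#' @param n_tumors Size of the tumor-identifier pool.
#' @param seed Integer seed.
#' @return A list: `activity_track` (one-row track tibble, H3K27ac-like),
#'   `tf_tracks` (annotation-only TF track collection), `variants`
#'   (variant tibble), and `truth` extended with `marked_ids`,
#'   `mutated_ids`, `n_active`, `n_mutated`, `n_variants`, `n_tumors`.
#' @export
simulate_tracks_and_variants <- function(panel, marked_fraction = 0.6,
                                         mutated_count = 2,
                                         variants_per_region = 1,
                                         n_tumors = 2, seed = 1L) {
  if (marked_fraction < 0 || marked_fraction > 1) {
    abort("`marked_fraction` must lie in [0, 1]")
  }
  set.seed(seed)
  truth <- panel$truth
  regions <- panel$regions
  members <- truth$member_ids
  n_marked <- round(marked_fraction * length(members))
  if (mutated_count > n_marked) {
    abort("`mutated_count` exceeds the number of marked members")
  }
  marked <- sort(sample(members, n_marked))
  mutated <- sort(sample(marked, mutated_count))

  mk <- regions[match(marked, regions$region_id), , drop = FALSE]
  ext_l <- 10L + floor(runif(nrow(mk)) * 41)
  ext_r <- 10L + floor(runif(nrow(mk)) * 41)
  peaks <- if (nrow(mk) > 0) {
    genomic_intervals(mk$chrom, mk$start - ext_l, mk$end + ext_r,
                      sprintf("peak_%s", mk$region_id))
  } else {
    genomic_intervals(character(), integer(), integer(), character())
  }
  activity <- chromatin_track("H3K27ac_tumor", "histone", peaks)

  # An annotation-only TF track over a random half of the members.
  tf_members <- sort(sample(members, max(1, length(members) %/% 2)))
  tfm <- regions[match(tf_members, regions$region_id), , drop = FALSE]
  tf_tracks <- chromatin_track(
    "TF_pioneer", "tf",
    genomic_intervals(tfm$chrom, tfm$start, tfm$end,
                      sprintf("tfpeak_%s", tfm$region_id))
  )

  vpr <- rep_len(as.integer(variants_per_region), length(mutated))
  bases <- c("A", "C", "G", "T")
  var_rows <- purrr::map2_dfr(mutated, vpr, function(rid, nv) {
    reg <- regions[regions$region_id == rid, ]
    offs <- sample.int(reg$end - reg$start, nv, replace = FALSE)
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    tibble(chrom = reg$chrom, pos = reg$start + offs, ref = ref, alt = alt)
  })
  n_var <- nrow(var_rows)
  pool <- sprintf("T%03d", seq_len(n_tumors))
  tumor_id <- if (n_var >= n_tumors) {
    sample(c(pool, sample(pool, n_var - n_tumors, replace = TRUE)))
  } else {
    sample(pool, n_var)
  }
  variants <- dplyr::bind_cols(var_rows, tibble(tumor_id = tumor_id))

  truth$marked_ids <- marked
  truth$mutated_ids <- mutated
  truth$n_active <- length(marked)
  truth$n_mutated <- length(mutated)
  truth$n_variants <- n_var
  truth$n_tumors <- length(unique(variants$tumor_id))
  list(activity_track = activity, tf_tracks = tf_tracks,
       variants = variants, truth = truth)
}

#' Simulate an essentiality score table with a shifted group
#'
#' Background cell-line scores are i.i.d. standard normal (the scale of
#' normalized Z essentiality scores); the designated group is shifted by
#' `-effect_delta`, i.e. toward essentiality (lower = more essential).
#' With `force_extreme = TRUE` the group's scores are instead placed
#' strictly below the background minimum, the configuration in which the
#' permutation test bottoms out at its resolution floor.
#'
#' @param n_lines Total number of cell lines.
#' @param group_size Size of the designated group.
#' @param effect_delta Mean shift of the group toward essentiality.
#' @param seed Integer seed.
#' @param force_extreme Place group scores strictly below all background
#'   scores instead of shifting.
#' @return A list: `scores` (tibble `id`, `score`), `group` (ids), and
#'   `truth` (`effect_delta`, `force_extreme`, `seed`).
#' @export
simulate_essentiality <- function(n_lines = 707, group_size = 8,
                                  effect_delta = 0, seed = 1L,
                                  force_extreme = FALSE) {
  if (group_size > n_lines) abort("`group_size` must be <= `n_lines`")
  set.seed(seed)
  ids <- sprintf("CL%04d", seq_len(n_lines))
  group <- sprintf("CL%04d", seq_len(group_size))
  score <- rnorm(n_lines)
  if (force_extreme) {
    floor_val <- min(score[-seq_len(group_size)])
    score[seq_len(group_size)] <- floor_val - runif(group_size, 0.1, 1)
  } else {
    score[seq_len(group_size)] <- score[seq_len(group_size)] - effect_delta
  }
  list(
    scores = tibble(id = ids, score = score),
    group = group,
    truth = list(effect_delta = effect_delta, force_extreme = force_extreme,
                 seed = as.integer(seed))
  )
}

#' Simulate a complete plexus study fixture
#'
#' Bundles the accessibility panel and the track/variant layer into one
#' fixture with a single seed. The defaults plant 12 members among 200
#' background regions over 50 cell types at generation correlation 0.95,
#' mark 8 of the 12 with the activity track, and mutate 3 of the 8 with
#' 5 SNVs drawn from a pool of 4 tumors.
#'
#' @param seed Integer seed.
#' @param n_background,n_members,n_celltypes,rho See
#'   [simulate_accessibility_panel()].
#' @param marked_fraction,mutated_count,variants_per_region,n_tumors See
#'   [simulate_tracks_and_variants()].
#' @return A list combining both generators' outputs, with the merged
#'   truth manifest under `$truth`.
#' @export
simulate_plexus_study <- function(seed = 1L, n_background = 200,
                                  n_members = 12, n_celltypes = 50,
                                  rho = 0.95, marked_fraction = 8 / 12,
                                  mutated_count = 3,
                                  variants_per_region = c(2, 2, 1),
                                  n_tumors = 4) {
  panel <- simulate_accessibility_panel(
    n_background = n_background, n_members = n_members,
    n_celltypes = n_celltypes, rho = rho, seed = seed
  )
  layer <- simulate_tracks_and_variants(
    panel, marked_fraction = marked_fraction, mutated_count = mutated_count,
    variants_per_region = variants_per_region, n_tumors = n_tumors,
    seed = seed + 1000L
  )
  list(
    matrix = panel$matrix, regions = panel$regions, tad = panel$tad,
    activity_track = layer$activity_track, tf_tracks = layer$tf_tracks,
    variants = layer$variants, truth = layer$truth
  )
}

#' Write a simulated study to fixture files
#'
#' Writes `dhs.bed`, `tads.bed`, `tracks/H3K27ac_tumor.bed`,
#' `tracks/TF_pioneer.bed`, `matrix.tsv`, `snvs.tsv` and `truth.json`
#' under `dir`. File contents are deterministic: the same fixture
#' produces byte-identical files.
#'
#' @param study Output of [simulate_plexus_study()].
#' @param dir Output directory (created if needed).
#' @param scores Optional essentiality simulation
#'   ([simulate_essentiality()]); when given, `scores.csv` and
#'   `group.txt` are written too.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(study, dir, scores = NULL) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  write_bed(study$regions, file.path(dir, "dhs.bed"))
  write_bed(study$tad, file.path(dir, "tads.bed"))
  write_bed(study$activity_track$intervals[[1]],
            file.path(dir, "tracks", "H3K27ac_tumor.bed"))
  write_bed(study$tf_tracks$intervals[[1]],
            file.path(dir, "tracks", "TF_pioneer.bed"))
  write_signal_matrix(study$matrix, file.path(dir, "matrix.tsv"))
  readr::write_tsv(
    setNames(study$variants, c("CHROM", "POS", "REF", "ALT", "TUMOR_ID")),
    file.path(dir, "snvs.tsv"), progress = FALSE
  )
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(scores)) {
    readr::write_csv(scores$scores, file.path(dir, "scores.csv"),
                     progress = FALSE)
    writeLines(scores$group, file.path(dir, "group.txt"))
  }
  invisible(dir)
}
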