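# Genomic interval model, BED / variant I/O, and the overlap primitives
# that every downstream stage builds on. Intervals are plain tibbles in
# BED convention: 0-based, half-open [start, end).

#' Construct a genomic interval tibble
#'
#' Builds and validates a tibble of genomic intervals in BED convention
#' (0-based half-open coordinates). This is the common currency of the
#' package: DNase I hypersensitive sites (DHS), TADs, ChIP-seq peaks and
#' candidate cis-regulatory elements are all interval tibbles.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start (bp).
#' @param end Integer vector, 0-based exclusive end (bp); must exceed `start`.
#' @param region_id Character vector of unique identifiers. Defaults to
#'   `"chrom:start-end"`.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unspecified). Carried
#'   through but ignored by all overlap logic.
#' @return A tibble with columns `chrom`, `start`, `end`, `region_id`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr14", 37720002, 38160000, "TAD1")
#' @export
genomic_intervals <- function(chrom, start, end,
                              region_id = NULL, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  out <- tibble(
    chrom = as.character(rep_len(chrom, n)),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(end, n)),
    region_id = if (is.null(region_id)) {
      sprintf("%s:%d-%d", rep_len(chrom, n), as.integer(rep_len(start, n)),
              as.integer(rep_len(end, n)))
    } else {
      as.character(rep_len(region_id, n))
    },
    strand = as.character(rep_len(strand, n))
  )
  validate_intervals(out)
  out
}

#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED4/BED6 (tab-separated, 0-based half-open). Track and
#' browser header lines and comment lines are skipped. Intervals are
#' returned in file order; a missing name column is auto-filled with
#' `"chrom:start-end"`.
#'
#' @param path Path to a BED file.
#' @return An interval tibble (see [genomic_intervals()]).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr14\t37720002\t38160000\tTAD1", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path))
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                  line_no[bad]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d: non-numeric coordinates",
                  line_no[bad]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 character(1)), NA_character_)
  name[!nzchar(name) | is.na(name) | name == "."] <- NA_character_
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                   character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf("invalid interval at BED line %d: start (%d) >= end (%d)",
                  line_no[bad], start[bad], end[bad]))
  }
  if (any(start < 0)) {
    bad <- which(start < 0)[1]
    abort(sprintf("invalid interval at BED line %d: negative start",
                  line_no[bad]))
  }
  name[is.na(name)] <- sprintf("%s:%d-%d", chrom[is.na(name)],
                               start[is.na(name)], end[is.na(name)])
  genomic_intervals(chrom, start, end, name, strand)
}

#' Read somatic variants
#'
#' Reads single-nucleotide variants either from a 5-column tab-separated
#' table (`CHROM`, `POS`, `REF`, `ALT`, `TUMOR_ID`, with or without a
#' header) or from a minimal VCF 4.x file whose per-record tumor/donor
#' identifier sits in the column after ALT (VCF `ID` conventions differ
#' between callers; here the sixth column is taken as the tumor id when
#' it is non-empty and non-numeric, otherwise the third).
#'
#' Positions are 1-based (VCF convention); [assign_variants()] converts
#' at assignment time.
#'
#' @param path Path to the variant table.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `tumor_id`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("variant file not found: %s", path))
  }
  lines <- readLines(path)
  is_vcf <- any(grepl("^##fileformat=VCF", lines))
  lines <- lines[!grepl("^##", lines) & nzchar(trimws(lines))]
  header <- grepl("^#", lines) |
    grepl("^CHROM\\b", lines, ignore.case = TRUE)
  lines <- lines[!header]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), tumor_id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    abort("variant table needs >= 5 tab-separated columns per record")
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  if (is_vcf) {
    # VCF layout: CHROM POS ID REF ALT ...; tumor id from ID column.
    out <- tibble(chrom = get(1), pos = as.integer(get(2)),
                  ref = get(4), alt = get(5), tumor_id = get(3))
  } else {
    out <- tibble(chrom = get(1), pos = as.integer(get(2)),
                  ref = get(3), alt = get(4), tumor_id = get(5))
  }
  if (anyNA(out$pos) || any(out$pos < 1)) {
    abort("variant positions must be integers >= 1 (1-based convention)")
  }
  bad <- out$ref == out$alt
  if (any(bad)) {
    abort(sprintf("variant %s:%d has identical REF and ALT",
                  out$chrom[which(bad)[1]], out$pos[which(bad)[1]]))
  }
  out
}

#' Pairwise interval overlap predicate
#'
#' Two intervals in half-open coordinates overlap iff they are on the same
#' chromosome and `max(start) < min(end)`. Abutting intervals (one ending
#' where the other starts) do not overlap. Strand is ignored.
#'
#' @param a,b Interval tibbles of equal length (or length 1, recycled).
#' @return Logical vector.
#' @examples
#' a <- genomic_intervals("chr1", 10, 20)
#' b <- genomic_intervals("chr1", 19, 25)
#' interval_overlaps(a, b)
#' @export
interval_overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  a$chrom[idx_a] == b$chrom[idx_b] &
    pmax(a$start[idx_a], b$start[idx_b]) < pmin(a$end[idx_a], b$end[idx_b])
}

#' Assign variants to regions
#'
#' Maps each variant to every region containing it. A variant at 1-based
#' position `pos` falls in a half-open region `[start, end)` iff
#' `pos - 1` is in `[start, end)`. A variant inside several overlapping
#' regions is assigned to all of them; regions without variants get zero
#' rows in the assignment table.
#'
#' Chromosome names are matched exactly by default. When the two inputs
#' use different dialects ("chr14" vs "14") nothing matches; a warning is
#' emitted in that case unless `normalize_chrom = TRUE`, which strips the
#' "chr" prefix on both sides before matching.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param regions Interval tibble.
#' @param normalize_chrom Normalize "chr" prefixes before matching?
#' @return A tibble with one row per (region, variant) assignment:
#'   `region_id`, `chrom`, `pos`, `ref`, `alt`, `tumor_id`. Regions with
#'   no variants are absent; recover the full map with a join.
#' @export
assign_variants <- function(variants, regions, normalize_chrom = FALSE) {
  validate_intervals(regions, "regions")
  empty <- tibble(region_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  tumor_id = character())
  if (nrow(variants) == 0 || nrow(regions) == 0) {
    return(empty)
  }
  vc <- variants$chrom
  rc <- regions$chrom
  if (normalize_chrom) {
    vc <- normalize_chrom_names(vc)
    rc <- normalize_chrom_names(rc)
  } else if (length(intersect(unique(vc), unique(rc))) == 0 &&
             length(intersect(unique(normalize_chrom_names(vc)),
                              unique(normalize_chrom_names(rc)))) > 0) {
    warn(paste0(
      "no chromosome names shared between variants and regions, but they ",
      "match after removing 'chr' prefixes; set `normalize_chrom = TRUE` ",
      "if the inputs use different naming dialects"
    ))
  }
  # 1-based pos -> 0-based base index; containment in [start, end).
  pos0 <- variants$pos - 1L
  hits <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    in_region <- vc == rc[i] & pos0 >= regions$start[i] & pos0 < regions$end[i]
    if (!any(in_region)) return(NULL)
    dplyr::bind_cols(
      tibble(region_id = regions$region_id[i]),
      variants[in_region, c("chrom", "pos", "ref", "alt", "tumor_id")]
    )
  })
  if (nrow(hits) == 0) empty else as_tibble(hits)
}

#' Write intervals as BED
#'
#' @param intervals Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  df <- intervals[, c("chrom", "start", "end", "region_id")]
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
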