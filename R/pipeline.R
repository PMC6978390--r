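# Orchestration: configuration validation and the end-to-end run that
# ties plexus inference, the annotation cascade and the essentiality
# test into one reproducible report.

#' Build and validate a run configuration
#'
#' A configuration bundles the input paths and analysis parameters for a
#' full run. It can also be loaded from a YAML file with
#' [read_run_config()]; arguments given here override file values.
#'
#' @param dhs,tads,matrix,activity,variants Input file paths (BED, BED,
#'   signal-matrix TSV, BED, variant TSV/VCF). `variants` may be NULL.
#' @param scores,group Optional essentiality inputs: score table path and
#'   group-id file (one id per line).
#' @param anchor_id Anchor region identifier (required).
#' @param threshold Correlation threshold in (-1, 1); default 0.7.
#' @param padding_bp Window padding in bp; default 40000.
#' @param n_perm Monte-Carlo draws for the essentiality test; default 1e6.
#' @param seed Integer seed.
#' @param out_dir Output directory, or NULL to skip writing files.
#' @param normalize_chrom Normalize "chr" prefixes when assigning
#'   variants.
#' @return A validated `run_config` list.
#' @export
run_config <- function(dhs, tads, matrix, activity, variants = NULL,
                       scores = NULL, group = NULL, anchor_id,
                       threshold = 0.7, padding_bp = 40000, n_perm = 1e6,
                       seed = 1L, out_dir = NULL, normalize_chrom = FALSE) {
  cfg <- list(
    dhs = dhs, tads = tads, matrix = matrix, activity = activity,
    variants = variants, scores = scores, group = group,
    anchor_id = anchor_id, threshold = threshold,
    padding_bp = padding_bp, n_perm = n_perm, seed = as.integer(seed),
    out_dir = out_dir, normalize_chrom = isTRUE(normalize_chrom)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$anchor_id) || !nzchar(cfg$anchor_id)) {
    abort("config error: `anchor_id` is required")
  }
  if (cfg$threshold <= -1 || cfg$threshold >= 1) {
    abort("config error: `threshold` must lie strictly inside (-1, 1)")
  }
  if (cfg$padding_bp < 0) {
    abort("config error: `padding_bp` must be >= 0")
  }
  if (cfg$n_perm < 1) {
    abort("config error: `n_perm` must be >= 1")
  }
  for (field in c("dhs", "tads", "matrix", "activity", "variants",
                  "scores", "group")) {
    path <- cfg[[field]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("config error: input `%s` not found: %s", field, path))
    }
  }
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()].
#' @param ... Overrides; a value given here wins over the file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  file_cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  merged <- utils::modifyList(file_cfg, overrides)
  do.call(run_config, merged)
}

#' Run the full pipeline
#'
#' Executes the stages in fixed order: read inputs, select candidates in
#' the padded TAD window, infer the plexus by anchored correlation,
#' filter to active members, assign variants and tally the cascade, then
#' (when score inputs are configured) the permutation essentiality test.
#' When `out_dir` is set, a deterministic report bundle is written:
#' `plexus.tsv`, `cascade.json`, `cascade.txt`, `permutation.json` (if
#' run) and `provenance.json` (configuration hash, seed, package
#' version). Rerunning with the same configuration produces
#' byte-identical files.
#'
#' @param cfg A `run_config`.
#' @param quiet Suppress progress messages.
#' @return A list with `cascade` (a `cascade_report`), `plexus` (a
#'   `plexus_result`), `permutation` (a `permutation_result` or NULL),
#'   and `provenance`.
#' @export
run_all <- function(cfg, quiet = FALSE) {
  validate_run_config(cfg)
  say <- function(...) if (!quiet) inform(sprintf(...))

  say("reading inputs")
  dhs <- read_bed(cfg$dhs)
  tads <- read_bed(cfg$tads)
  if (nrow(tads) != 1) {
    abort("expected exactly one TAD interval for an anchored run")
  }
  m <- read_signal_matrix(cfg$matrix)
  activity <- chromatin_track("activity", "histone", read_bed(cfg$activity))
  variants <- if (is.null(cfg$variants)) {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), tumor_id = character())
  } else {
    read_variants(cfg$variants)
  }

  say("running cascade (anchor '%s', r > %g, padding %d bp)",
      cfg$anchor_id, cfg$threshold, as.integer(cfg$padding_bp))
  cascade <- run_cascade(
    dhs, tads, m, cfg$anchor_id, activity, variants,
    threshold = cfg$threshold, padding_bp = cfg$padding_bp,
    normalize_chrom = cfg$normalize_chrom
  )

  permutation <- NULL
  if (!is.null(cfg$scores)) {
    if (is.null(cfg$group)) {
      abort("config error: `group` is required when `scores` is given")
    }
    say("running permutation essentiality test (%d draws)",
        as.integer(cfg$n_perm))
    scores <- read_score_table(cfg$scores)
    group <- readLines(cfg$group)
    group <- group[nzchar(trimws(group))]
    permutation <- permutation_median_test(
      scores, group, n_perm = cfg$n_perm, seed = cfg$seed
    )
  }

  provenance <- list(
    package = "regplexus",
    version = as.character(utils::packageVersion("regplexus")),
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  )

  if (!is.null(cfg$out_dir)) {
    say("writing report to %s", cfg$out_dir)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_plexus_tsv(cascade$plexus, file.path(cfg$out_dir, "plexus.tsv"))
    write_cascade_json(cascade, file.path(cfg$out_dir, "cascade.json"))
    writeLines(format(cascade), file.path(cfg$out_dir, "cascade.txt"))
    if (!is.null(permutation)) {
      jsonlite::write_json(
        tidy(permutation), file.path(cfg$out_dir, "permutation.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(cascade = cascade, plexus = cascade$plexus,
       permutation = permutation, provenance = provenance)
}
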