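# Percentile ranking and the permutation median test for group gene
# essentiality. Essentiality scores follow the knockdown-screen
# convention: normalized Z scores where lower means the gene is more
# required for proliferation, so the test is one-sided, lower tail.

#' Percentile rank of a value within a reference distribution
#'
#' Inclusive convention: `100 * #(reference <= value) / length(reference)`.
#'
#' @param value A single numeric value.
#' @param reference Non-empty numeric vector.
#' @return Percentile in `[0, 100]`.
#' @examples
#' percentile_rank(3, c(1, 2, 3, 4, 5)) # 60
#' @export
percentile_rank <- function(value, reference) {
  if (length(reference) == 0) {
    abort("`reference` must be non-empty")
  }
  stopifnot(length(value) == 1, is.finite(value), all(is.finite(reference)))
  100 * sum(reference <= value) / length(reference)
}

# Draw n_perm uniform k-subsets (without replacement within a draw) of
# seq_len(n) and return the row-wise medians of scores[subset].
# Vectorized: oversample with replacement, redraw rows containing
# duplicates until none remain. Deterministic for a fixed RNG state.
draw_subset_medians <- function(scores, n, k, n_perm) {
  if (k == 1) {
    return(scores[sample.int(n, n_perm, replace = TRUE)])
  }
  idx <- matrix(sample.int(n, n_perm * k, replace = TRUE), nrow = n_perm)
  repeat {
    srt <- matrix(idx[order(row(idx), idx)], ncol = k, byrow = TRUE)
    bad <- rowSums(srt[, -1, drop = FALSE] ==
                     srt[, -k, drop = FALSE]) > 0
    if (!any(bad)) break
    idx[bad, ] <- matrix(sample.int(n, sum(bad) * k, replace = TRUE), ncol = k)
  }
  v <- matrix(scores[idx], nrow = n_perm)
  vs <- matrix(v[order(row(v), v)], ncol = k, byrow = TRUE)
  if (k %% 2 == 1) {
    vs[, (k + 1) %/% 2]
  } else {
    (vs[, k %/% 2] + vs[, k %/% 2 + 1]) / 2
  }
}

#' Permutation median test for group essentiality
#'
#' Tests whether a designated group of cell lines (e.g. all prostate
#' cancer lines) is more essential for a gene than expected by chance.
#' The observed statistic is the median score of the group; the null
#' distribution is built by repeatedly drawing groups of the same size
#' uniformly at random (without replacement within a draw) from all cell
#' lines and recording their medians. The one-sided, lower-tail p-value
#' counts background medians at or below the observed median.
#'
#' In `montecarlo` mode, `p = max(b, 1) / n_perm` where `b` is the count
#' of background medians `<=` observed: a zero count is reported at the
#' resolution floor `1 / n_perm` rather than as zero, so one million
#' draws bottom out at p = 1e-6. In `exhaustive` mode all
#' `choose(n, k)` subsets are enumerated and `p = b / choose(n, k)`
#' exactly.
#'
#' @param scores A tibble with columns `id` and `score` (normalized Z
#'   essentiality scores; lower = more essential), or a named numeric
#'   vector.
#' @param target_group Character vector of ids forming the group; must be
#'   a subset of the table ids.
#' @param n_perm Number of Monte-Carlo draws (default 1e6).
#' @param seed Integer seed; all randomness in the call flows from it.
#' @param mode `"montecarlo"` (default) or `"exhaustive"`. Exhaustive
#'   mode refuses more than 1e6 subsets; use Monte Carlo there.
#' @param exclude_group If TRUE, background draws sample only from
#'   non-group lines. Default FALSE: draws come from all lines, group
#'   included, matching the convention of drawing from the full panel.
#' @return A `permutation_result` with `observed_median`, `group_size`,
#'   `n_perm`, `b`, `p_value`, `seed`, `mode`, `at_floor` (TRUE when the
#'   Monte-Carlo count was zero), and a down-sampled `null_medians`
#'   vector for plotting.
#' @examples
#' scores <- tibble::tibble(id = letters[1:5], score = 1:5)
#' permutation_median_test(scores, c("a", "b"), mode = "exhaustive")
#' @export
permutation_median_test <- function(scores, target_group, n_perm = 1e6,
                                    seed = 1L,
                                    mode = c("montecarlo", "exhaustive"),
                                    exclude_group = FALSE) {
  mode <- match.arg(mode)
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(id = names(scores), score = unname(scores))
  }
  stopifnot(all(c("id", "score") %in% names(scores)),
            !anyDuplicated(scores$id), all(is.finite(scores$score)))
  missing_ids <- setdiff(target_group, scores$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("target group id(s) not in the score table: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  k <- length(target_group)
  if (k < 1) abort("`target_group` must contain at least one id")
  observed <- median(scores$score[scores$id %in% target_group])

  pool <- if (exclude_group) {
    scores$score[!scores$id %in% target_group]
  } else {
    scores$score
  }
  n <- length(pool)
  if (k > n) {
    abort("group size exceeds the number of background lines")
  }

  if (mode == "exhaustive") {
    total <- choose(n, k)
    if (total > 1e6) {
      abort(sprintf(
        "exhaustive mode would enumerate %.3g subsets (> 1e6); use mode = 'montecarlo'",
        total
      ))
    }
    meds <- apply(combn(n, k), 2, function(ix) median(pool[ix]))
    b <- sum(meds <= observed)
    p <- b / total
    null_medians <- meds
    n_perm_used <- as.integer(total)
    at_floor <- FALSE
  } else {
    if (n_perm < 1) abort("`n_perm` must be >= 1")
    n_perm_used <- as.integer(n_perm)
    set.seed(seed)
    meds <- draw_subset_medians(pool, n, k, n_perm_used)
    b <- sum(meds <= observed)
    at_floor <- b == 0
    p <- max(b, 1) / n_perm_used
    keep <- min(length(meds), 10000L)
    null_medians <- meds[seq_len(keep)]
  }

  structure(
    list(
      observed_median = observed,
      group_size = k,
      n_perm = n_perm_used,
      b = as.integer(b),
      p_value = p,
      seed = as.integer(seed),
      mode = mode,
      exclude_group = exclude_group,
      at_floor = at_floor,
      null_medians = null_medians
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    paste0("Permutation median test (%s, one-sided lower tail)\n",
           "  observed group median : %.4g  (group size %d)\n",
           "  background draws      : %d  (medians <= observed: %d)\n",
           "  p-value               : %.3g%s\n"),
    x$mode, x$observed_median, x$group_size, x$n_perm, x$b, x$p_value,
    if (isTRUE(x$at_floor)) "  [at resolution floor 1/n_perm]" else ""
  ))
  invisible(x)
}

#' @rdname permutation_median_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(
    observed_median = x$observed_median,
    group_size = x$group_size,
    n_perm = x$n_perm,
    b = x$b,
    p_value = x$p_value,
    mode = x$mode,
    at_floor = x$at_floor
  )
}

#' @rdname permutation_median_test
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tidy(x)
}

#' @rdname permutation_median_test
#' @param object A `permutation_result`.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(null_median = object$null_medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_median)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_median,
                        colour = "#D55E00", linewidth = 1) +
    ggplot2::labs(
      x = "background group median",
      y = "draws",
      title = sprintf("Permutation null (p = %.3g, %s)",
                      object$p_value, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Read an id/score table
#'
#' Delimited table with an id column and one score column. Extra columns
#' are ignored.
#'
#' @param path File path (comma- or tab-separated by extension).
#' @param id_col,score_col Column names (defaults: first two columns).
#' @return Tibble with columns `id`, `score`.
#' @export
read_score_table <- function(path, id_col = NULL, score_col = NULL) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  id_col <- id_col %||% names(df)[1]
  score_col <- score_col %||% names(df)[2]
  tibble(id = as.character(df[[id_col]]), score = as.numeric(df[[score_col]]))
}
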