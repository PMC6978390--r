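# Normalization and hypothesis-test statistics for perturbation,
# reporter and allele-specific experiments on tabulated measurements.

#' Housekeeping-normalized relative expression
#'
#' qPCR-style normalization: each replicate's target abundance is divided
#' by its housekeeping abundance (e.g. TBP), then by the mean basal
#' ratio, so the basal condition averages 1. The percent change of a
#' treated condition is `100 * (1 - mean(treated normalized))` — positive
#' for a knockdown. The whole computation is invariant to rescaling all
#' abundances by a common factor.
#'
#' @param measurements Tibble with columns `sample_id`, `condition`,
#'   `target_abundance`, `housekeeping_abundance` (all abundances > 0).
#'   One condition must be `"basal"`.
#' @param treated_label The condition to contrast with basal.
#' @return A list with `replicates` (per-replicate `ratio` and
#'   `normalized`), `percent_change`, and `p_value` from the pooled
#'   two-sample t test on normalized values (NA when either condition
#'   has < 2 replicates).
#' @examples
#' d <- tibble::tibble(
#'   sample_id = paste0("s", 1:4),
#'   condition = c("basal", "basal", "kd", "kd"),
#'   target_abundance = c(10, 10, 6, 8),
#'   housekeeping_abundance = c(10, 10, 10, 10)
#' )
#' relative_expression(d, "kd")$percent_change # 30
#' @export
relative_expression <- function(measurements, treated_label) {
  req <- c("sample_id", "condition", "target_abundance",
           "housekeeping_abundance")
  stopifnot(all(req %in% names(measurements)))
  if (any(measurements$target_abundance <= 0) ||
      any(measurements$housekeeping_abundance <= 0)) {
    abort("abundances must be strictly positive")
  }
  keep <- measurements$condition %in% c("basal", treated_label)
  d <- measurements[keep, , drop = FALSE]
  if (sum(d$condition == "basal") < 1 ||
      sum(d$condition == treated_label) < 1) {
    abort("need >= 1 basal and >= 1 treated replicate")
  }
  d <- d |>
    dplyr::mutate(ratio = .data$target_abundance /
                    .data$housekeeping_abundance)
  basal_mean <- mean(d$ratio[d$condition == "basal"])
  d <- dplyr::mutate(d, normalized = .data$ratio / basal_mean)
  treated_norm <- d$normalized[d$condition == treated_label]
  basal_norm <- d$normalized[d$condition == "basal"]
  p <- if (length(treated_norm) >= 2 && length(basal_norm) >= 2) {
    tryCatch(student_t_two_sample(treated_norm, basal_norm)$p_value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  list(
    replicates = as_tibble(d[, c("sample_id", "condition", "ratio",
                                 "normalized")]),
    percent_change = 100 * (1 - mean(treated_norm)),
    p_value = p
  )
}

#' Pooled two-sample Student's t test
#'
#' Equal-variance two-sample t with `df = n_a + n_b - 2`, two-sided.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return A tibble with `t`, `df`, `p_value`.
#' @examples
#' student_t_two_sample(c(1, 2, 3), c(2, 3, 4)) # t = -1.2247, df = 4
#' @export
student_t_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs >= 2 values")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    abort("pooled variance is zero; the t statistic is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The p-value is exact (by enumeration over
#' rank assignments) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction is used. `U` is reported for the
#' first sample; `U_a + U_b = n_a * n_b` always.
#'
#' @param a,b Numeric vectors, each with >= 1 value.
#' @return A tibble with `U`, `p_value`, `method` ("exact" or "normal").
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("each group needs >= 1 value")
  }
  no_ties <- !anyDuplicated(c(a, b))
  exact <- (length(a) + length(b)) <= 12 && no_ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  tibble(U = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal")
}

#' Allele-specific enrichment log2 fold-change
#'
#' Contrasts pulldown enrichment of a factor on the variant allele
#' against the wild-type allele, as in allele-specific ChIP-qPCR.
#' When every replicate id is present for both alleles, fold-changes are
#' computed per matched replicate pair, `log2(variant / wildtype)`;
#' otherwise each variant replicate is divided by the mean wild-type
#' enrichment (unpaired fallback). Significance comes from the pooled
#' two-sample t test on `log2(enrichment)` between the allele groups.
#'
#' @param enrichments Tibble with columns `factor`, `allele` (values
#'   `"wildtype"` / `"variant"`), `replicate`, `enrichment` (> 0).
#' @param factor_name Which factor to analyse.
#' @return A list with `log2fc` (per-replicate tibble), `mean_log2fc`,
#'   `p_value`, and `paired` (logical).
#' @export
allele_log2fc <- function(enrichments, factor_name) {
  req <- c("factor", "allele", "replicate", "enrichment")
  stopifnot(all(req %in% names(enrichments)))
  d <- enrichments[enrichments$factor == factor_name, , drop = FALSE]
  if (any(d$enrichment <= 0)) {
    abort("enrichment values must be strictly positive")
  }
  wt <- d[d$allele == "wildtype", , drop = FALSE]
  var <- d[d$allele == "variant", , drop = FALSE]
  if (nrow(wt) < 2 || nrow(var) < 2) {
    abort(sprintf("factor '%s' needs >= 2 replicates per allele",
                  factor_name))
  }
  paired <- setequal(wt$replicate, var$replicate) &&
    !anyDuplicated(wt$replicate) && !anyDuplicated(var$replicate)
  if (paired) {
    wt_ord <- wt[match(var$replicate, wt$replicate), , drop = FALSE]
    fc <- tibble(
      replicate = var$replicate,
      log2fc = log2(var$enrichment / wt_ord$enrichment)
    )
  } else {
    fc <- tibble(
      replicate = var$replicate,
      log2fc = log2(var$enrichment / mean(wt$enrichment))
    )
  }
  p <- student_t_two_sample(log2(var$enrichment), log2(wt$enrichment))$p_value
  list(
    factor = factor_name,
    log2fc = fc,
    mean_log2fc = mean(fc$log2fc),
    p_value = p,
    paired = paired
  )
}

#' Editing-efficiency vs expression correlation
#'
#' Pearson correlation between per-construct genome-editing efficiency
#' and the resulting expression change, with the two-sided p-value from
#' the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param editing_efficiency,expression Paired numeric vectors, length >= 3.
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
efficiency_expression_correlation <- function(editing_efficiency, expression) {
  n <- length(editing_efficiency)
  if (n != length(expression)) {
    abort("vectors must be paired (equal length)")
  }
  if (n < 3) abort("need >= 3 paired observations")
  r <- pearson_cor(editing_efficiency, expression)
  if (is.na(r)) {
    abort("correlation undefined (constant input or too few complete pairs)")
  }
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(r = r, p_value = p, n = n)
}

#' Benjamini-Hochberg adjustment helper
#'
#' Unadjusted p-values are the default everywhere in the package; this
#' wrapper is for callers who test many elements at once.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, `stats::p.adjust(p, "BH")`.
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}
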