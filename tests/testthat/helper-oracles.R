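# Independent oracles used across the suite. Each one solves the same
# question as the implementation by brute force (base-set enumeration,
# exhaustive rank assignment, per-base sums), never by calling the code
# path it checks.

# Overlap by materializing both intervals' base sets and intersecting.
oracle_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) return(FALSE)
  length(intersect(seq(start_a, end_a - 1), seq(start_b, end_b - 1))) > 0
}

# Mean per-base signal of a step function over [start, end); bases
# without coverage contribute 0.
oracle_mean_signal <- function(bg, chrom, start, end) {
  bases <- seq(start, end - 1)
  per_base <- numeric(length(bases))
  for (i in seq_len(nrow(bg))) {
    if (bg$chrom[i] != chrom) next
    hit <- bases >= bg$start[i] & bases < bg$end[i]
    per_base[hit] <- per_base[hit] + bg$value[i]
  }
  mean(per_base)
}

# Pearson r straight from the covariance/variance definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exact two-sided Mann-Whitney p by enumeration of all group-label
# assignments to the combined sample (no ties assumed).
oracle_mann_whitney_p <- function(a, b) {
  n_a <- length(a)
  combined <- c(a, b)
  u_stat <- function(ix) {
    x <- combined[ix]; y <- combined[-ix]
    sum(outer(x, y, ">"))
  }
  u_obs <- u_stat(seq_len(n_a))
  all_u <- apply(combn(length(combined), n_a), 2, u_stat)
  mu <- n_a * (length(combined) - n_a) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu))
}

# Random interval tibble on a couple of chromosomes with coordinates in
# [0, max_coord); width >= 1.
random_intervals <- function(n, max_coord = 500, chroms = c("chr1", "chr2"),
                             prefix = "R") {
  start <- sample.int(max_coord - 1, n, replace = TRUE) - 1L
  width <- sample.int(50, n, replace = TRUE)
  genomic_intervals(
    sample(chroms, n, replace = TRUE),
    start, pmin(start + width, max_coord),
    sprintf("%s%04d", prefix, seq_len(n))
  )
}
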