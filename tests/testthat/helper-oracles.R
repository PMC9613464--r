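# Independent oracles and small fixture builders used across the suite.

# The fully printed engraftment table: doses 30000/7500/1875/469,
# tested 3/4/6/5, responders 3/4/6/4.
table2_assay <- function() {
  read_assay(system.file("extdata", "table2_assay.csv", package = "lsctools"))
}

# Exact two-sided rank-sum p-value by enumeration of all C(m+n, m)
# rank allocations: the null probability of a Mann-Whitney U at least as
# far from its mean as observed. Independent of the package's pwilcox
# route.
brute_force_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  rk <- rank(c(x, y))
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  Us <- colSums(combs) - m * (m + 1) / 2
  mean(abs(Us - m * n / 2) >= abs(U_obs - m * n / 2) - 1e-9)
}

# Best single changepoint of a numeric vector by exhaustive residual
# sum-of-squares search (oracle for the binary segmentation).
brute_force_single_split <- function(x) {
  n <- length(x)
  rss <- vapply(1:(n - 1), function(k)
    sum((x[1:k] - mean(x[1:k]))^2) + sum((x[(k + 1):n] - mean(x[(k + 1):n]))^2),
    numeric(1))
  which.min(rss)
}

# A sparse regularly spaced background with one tight planted run:
# geometry for the worked CORE-calling example.
planted_run_peaks <- function(run_start = 5e7, n_run = 7, run_width = 200,
                              run_spacing = 2200, n_bg = 200,
                              bg_spacing = 2e6) {
  run <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = run_start + (0:(n_run - 1)) * run_spacing + 1,
                             width = run_width))
  bg_starts <- seq(1, n_bg * bg_spacing, by = bg_spacing)
  bg_starts <- bg_starts[abs(bg_starts - run_start) > 1e6]
  bg <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = bg_starts, width = run_width))
  sort(c(run, bg))
}

# Two-level group table for hand-built detection matrices.
toy_groups <- function(n_pos, n_neg) {
  data.frame(sample_id = c(sprintf("P%d", seq_len(n_pos)),
                           sprintf("N%d", seq_len(n_neg))),
             group = factor(rep(c("LSC+", "LSC-"), c(n_pos, n_neg)),
                            levels = c("LSC+", "LSC-")))
}
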