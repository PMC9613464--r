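## Subclonal copy-number detection: project a reference sample's segments
## onto a query's 1-kb binned copy-number track and rank-test adjacent
## segments. A significant adjacent-segment difference whose direction
## matches the reference's own gain pattern is evidence that the
## reference clone's amplifications are present subclonally in the query.

#' Construct / validate a binned copy-number track
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `cn`
#'   (0-based half-open bins).
#' @param bin_size Nominal bin width in bp.
#' @return A `cn_track` data frame, sorted, with `bin_size` attribute.
#' @export
cn_track <- function(x, bin_size = 1000) {
  x <- as.data.frame(x)
  need <- c("chrom", "start", "end", "cn")
  if (!all(need %in% names(x))) abort("track needs columns chrom, start, end, cn")
  x <- x[need]
  if (nrow(x) == 0) abort("empty copy-number track")
  if (any(!is.finite(x$cn))) abort("cn values must be finite")
  if (any(x$end <= x$start)) abort("bin end must exceed start")
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  by_ch <- split(seq_len(nrow(x)), x$chrom)
  for (idx in by_ch) {
    if (length(idx) > 1 && any(x$start[idx][-1] < x$end[idx][-length(idx)]))
      abort("bins must not overlap")
  }
  rownames(x) <- NULL
  attr(x, "bin_size") <- bin_size
  class(x) <- c("cn_track", "data.frame")
  x
}

#' Segment a binned copy-number track
#'
#' Binary segmentation under a Gaussian cost: a changepoint is accepted
#' when it reduces the residual sum of squares by more than
#' `penalty * sigma^2`, where `sigma` is a robust noise estimate from
#' first differences (`mad(diff(cn)) / sqrt(2)`). Deterministic. This is a
#' built-in changepoint segmenter for workflows where an external
#' HMM-based segmentation of the reference sample is not available.
#'
#' @param track A [cn_track()] on a single chromosome with `>= 2` bins.
#' @param penalty Per-changepoint penalty in units of `sigma^2`; default
#'   `3 * log(n)` (BIC-style).
#' @param min_seg_bins Minimum bins per segment (default 2).
#' @return A `segment_set` data frame: `chrom`, `start`, `end`, `label`,
#'   `mean_cn`, `n_bins`.
#' @export
segment_track <- function(track, penalty = NULL, min_seg_bins = 2) {
  track <- if (inherits(track, "cn_track")) track else cn_track(track)
  if (length(unique(track$chrom)) != 1)
    abort("segment_track expects a single-chromosome track")
  x <- track$cn
  n <- length(x)
  if (n < 2) abort("need at least 2 bins to segment")
  if (is.null(penalty)) penalty <- 3 * log(n)
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- max(stats::sd(x) * 1e-8, 1e-12)
  thresh <- penalty * sigma^2

  ## best single split of x[l..r] by RSS reduction, via cumulative sums;
  ## gains at floating-point cancellation scale are treated as zero
  best_split <- function(l, r) {
    m <- r - l + 1
    if (m < 2 * min_seg_bins) return(NULL)
    xs <- x[l:r]
    cs <- cumsum(xs)
    tot <- cs[m]
    k <- min_seg_bins:(m - min_seg_bins)      # left part sizes
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (m - k) - tot^2 / m
    gain[gain < 1e-9 * (tot^2 / m + 1)] <- 0
    i <- which.max(gain)
    list(gain = gain[i], at = l + k[i] - 1)   # last index of left part
  }
  cps <- integer(0)
  queue <- list(c(1L, n))
  while (length(queue)) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(seg[1], seg[2])
    if (!is.null(sp) && sp$gain > thresh) {
      cps <- c(cps, sp$at)
      queue <- c(queue, list(c(seg[1], sp$at)), list(c(sp$at + 1L, seg[2])))
    }
  }
  bounds <- sort(unique(c(0L, cps, n)))
  segs <- data.frame(
    chrom = track$chrom[1],
    start = track$start[bounds[-length(bounds)] + 1L],
    end = track$end[bounds[-1]],
    label = seq_len(length(bounds) - 1L))
  segs$mean_cn <- vapply(seq_len(nrow(segs)), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  segs$n_bins <- diff(bounds)
  segment_set(segs, source_sample = attr(track, "source_sample"))
}

#' Construct / validate a segment set
#'
#' @param x Data frame with `chrom`, `start`, `end` and optional `label`,
#'   `mean_cn` columns; segments must be sorted and non-overlapping.
#' @param source_sample Optional id of the sample the segments came from.
#' @return A `segment_set` data frame.
#' @export
segment_set <- function(x, source_sample = NULL) {
  x <- as.data.frame(x)
  if (!all(c("chrom", "start", "end") %in% names(x)))
    abort("segments need columns chrom, start, end")
  if (nrow(x) == 0) abort("empty segment set")
  if (any(x$end <= x$start)) abort("segment end must exceed start")
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  if (length(unique(x$chrom)) == 1 && nrow(x) > 1 &&
      any(x$start[-1] < x$end[-nrow(x)]))
    abort("segments must not overlap")
  if (is.null(x$label)) x$label <- seq_len(nrow(x))
  rownames(x) <- NULL
  attr(x, "source_sample") <- source_sample
  class(x) <- c("segment_set", "data.frame")
  x
}

#' Project reference segments onto a query copy-number track
#'
#' Assigns every query bin to the reference segment containing its
#' midpoint. Bins outside all segments are reported and excluded.
#'
#' @param reference A [segment_set()] (e.g. from the cultured/pure-clone
#'   sample).
#' @param query A [cn_track()] on the same chromosome.
#' @return A `segment_projection` list: `segments` (the reference set),
#'   `bins` (query bins with a `segment` column), `n_dropped`.
#' @export
project_segments <- function(reference, query) {
  reference <- if (inherits(reference, "segment_set")) reference else segment_set(reference)
  query <- if (inherits(query, "cn_track")) query else cn_track(query)
  if (nrow(query) == 0) {
    return(structure(list(segments = reference,
                          bins = cbind(as.data.frame(query), segment = integer(0)),
                          n_dropped = 0L),
                     class = "segment_projection"))
  }
  if (!all(query$chrom %in% reference$chrom))
    abort("chromosome mismatch between reference segments and query track")
  mid <- (query$start + query$end) / 2
  idx <- findInterval(mid, reference$start)
  inside <- idx >= 1 & idx <= nrow(reference) &
    ifelse(idx >= 1, mid < reference$end[pmax(idx, 1)], FALSE)
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    warning(sprintf("%d query bins fall outside all reference segments; excluded",
                    n_dropped), call. = FALSE)
  bins <- as.data.frame(query)[inside, , drop = FALSE]
  bins$segment <- reference$label[idx[inside]]
  structure(list(segments = reference, bins = bins, n_dropped = n_dropped),
            class = "segment_projection")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Mann-Whitney statistic `U` for `x` relative to `y`. The p-value uses
#' the exact null distribution when both samples have at most `exact_max`
#' observations and there are no ties, and the normal approximation with
#' tie correction (and continuity correction) otherwise. The two-sided
#' exact p-value is the null probability of a `U` at least as far from
#' its mean as observed.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two.sided"` (default), `"greater"` (`x` tends
#'   larger), or `"less"`.
#' @param exact_max Per-side size limit for the exact distribution
#'   (default 25).
#' @return A list: `statistic` (U), `p_value`, `exact` (logical).
#' @export
ranksum_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_max = 25) {
  alternative <- match.arg(alternative)
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  exact <- (m <= exact_max && n <= exact_max && !has_ties)
  if (exact) {
    p <- switch(alternative,
      two.sided = {
        u_low <- min(U, m * n - U)
        min(1, 2 * stats::pwilcox(u_low, m, n))
      },
      greater = stats::pwilcox(U - 1, m, n, lower.tail = FALSE),
      less = stats::pwilcox(U, m, n))
  } else {
    N <- m + n
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sig <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sig == 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      cc <- 0.5  # continuity correction
      p <- switch(alternative,
        two.sided = {
          z <- (U - mu - sign(U - mu) * cc) / sig
          min(1, 2 * stats::pnorm(-abs(z)))
        },
        greater = stats::pnorm((U - mu - cc) / sig, lower.tail = FALSE),
        less = stats::pnorm((U - mu + cc) / sig))
    }
  }
  list(statistic = U, p_value = p, exact = exact)
}

#' Rank-test adjacent projected segments
#'
#' For each consecutive pair of reference segments, runs a two-sample
#' Wilcoxon rank-sum test on the query bin copy-number values, reporting
#' the p-value, significance stars (`p < 0.05` *, `< 0.01` **,
#' `< 0.001` ***) and the direction of the shift (sign of the median
#' difference, second segment minus first).
#'
#' @param projection A [project_segments()] result with `>= 2` populated
#'   segments.
#' @param alternative Passed to [ranksum_test()].
#' @param exact_max Passed to [ranksum_test()].
#' @return A data frame of adjacent comparisons: `pair`, `n_left`,
#'   `n_right`, `statistic`, `p_value`, `stars`, `direction`.
#' @export
compare_adjacent_segments <- function(projection,
                                      alternative = "two.sided",
                                      exact_max = 25) {
  stopifnot(inherits(projection, "segment_projection"))
  segs <- projection$segments
  bins <- split(projection$bins$cn, factor(projection$bins$segment,
                                           levels = segs$label))
  counts <- lengths(bins)
  if (any(counts == 0)) {
    warning(sprintf("segments with 0 bins skipped: %s",
                    paste(segs$label[counts == 0], collapse = ", ")),
            call. = FALSE)
    segs <- segs[counts > 0, , drop = FALSE]
    bins <- bins[counts > 0]
  }
  if (length(bins) < 2)
    abort("need at least 2 segments with bins to compare")
  out <- lapply(seq_len(length(bins) - 1), function(i) {
    a <- bins[[i]]; b <- bins[[i + 1]]
    tst <- ranksum_test(a, b, alternative = alternative, exact_max = exact_max)
    data.frame(pair = sprintf("%s to %s", segs$label[i], segs$label[i + 1]),
               n_left = length(a), n_right = length(b),
               statistic = tst$statistic, p_value = tst$p_value,
               stars = p_stars(tst$p_value),
               direction = sign(stats::median(b) - stats::median(a)))
  })
  do.call(rbind, out)
}

#' Derive the expected adjacent-pair direction pattern from a segment set
#'
#' @param segments A [segment_set()] with `mean_cn` filled in (e.g. from
#'   [segment_track()] on the reference sample).
#' @param flat_tol Absolute mean difference below which a pair is called
#'   `"flat"` (default 0.25 copies).
#' @return Character vector over adjacent pairs: `"up"`, `"down"`, or
#'   `"flat"` (second segment relative to first).
#' @export
reference_pattern <- function(segments, flat_tol = 0.25) {
  stopifnot(inherits(segments, "segment_set"), !is.null(segments$mean_cn))
  d <- diff(segments$mean_cn)
  ifelse(abs(d) < flat_tol, "flat", ifelse(d > 0, "up", "down"))
}

#' Decide whether the reference's amplification pattern is detectable
#' subclonally in the query
#'
#' A directional (`up`/`down`) adjacent pair is concordant when its test
#' is significant (`p < alpha`) and its direction matches the reference
#' pattern. `flat` pairs carry no directional information and are
#' excluded from the concordance fraction. The region-level verdict is
#' `"detected"` when the concordant fraction reaches `threshold`.
#'
#' @param comparisons Output of [compare_adjacent_segments()].
#' @param pattern Character vector (`"up"`/`"down"`/`"flat"`) per pair,
#'   e.g. from [reference_pattern()].
#' @param alpha Significance level (default 0.05).
#' @param threshold Concordant-pair fraction required (default 0.75).
#' @return A list: `verdict` (`"detected"`/`"not_detected"`),
#'   `concordance`, `n_informative`, `per_pair` data frame.
#' @export
detect_subclonal_pattern <- function(comparisons, pattern, alpha = 0.05,
                                     threshold = 0.75) {
  if (nrow(comparisons) != length(pattern))
    abort("pattern length must match the number of adjacent comparisons")
  dir_num <- c(up = 1, down = -1, flat = 0)[pattern]
  if (any(is.na(dir_num))) abort("pattern entries must be up, down or flat")
  informative <- pattern != "flat"
  concordant <- informative & comparisons$p_value < alpha &
    comparisons$direction == dir_num
  frac <- if (any(informative)) mean(concordant[informative]) else NA_real_
  list(verdict = if (isTRUE(frac >= threshold)) "detected" else "not_detected",
       concordance = frac,
       n_informative = sum(informative),
       per_pair = cbind(comparisons,
                        expected = pattern,
                        concordant = concordant))
}

#' Call copy-number gains and losses from segment means
#'
#' A segment is a loss when its mean copy number is below 1.5 and a gain
#' when above 2.5; the boundary values themselves are neutral.
#'
#' @param segments A [segment_set()] with `mean_cn`.
#' @return The segment data frame with an added `call` column
#'   (`loss`/`neutral`/`gain`).
#' @export
call_gain_loss <- function(segments) {
  stopifnot(!is.null(segments$mean_cn))
  out <- as.data.frame(segments)
  out$call <- ifelse(out$mean_cn < 1.5, "loss",
              ifelse(out$mean_cn > 2.5, "gain", "neutral"))
  out
}
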