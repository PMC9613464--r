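## CORE discovery: call clusters of cis-regulatory elements (COREs) from
## per-sample peak sets, build a cross-sample catalog, and rank catalog
## COREs by their power to discriminate LSC+ from LSC- fractions.
##
## A CORE is a maximal run of neighboring peaks whose inter-peak gaps are
## all below a data-adaptive threshold. Under a Poisson background the
## gaps between unclustered peaks are approximately exponential; the
## threshold is the lower alpha-quantile of that fitted null, so genuinely
## clustered elements sit far below it while, in expectation, only a
## fraction alpha of background gaps slip through.

#' Data-adaptive gap threshold for CORE calling
#'
#' Fits an exponential null to the sample's inter-peak gaps by a robust
#' rate estimate (`median(gap) / log(2)` estimates the mean) and returns
#' the lower `alpha` quantile, `-mean * log(1 - alpha)`.
#'
#' @param peaks A `GRanges` of peaks (one sample).
#' @param alpha Null quantile defining "closer than background expects"
#'   (default 0.05).
#' @return Threshold in bp, or `NA` with fewer than 3 peaks.
#' @export
core_gap_threshold <- function(peaks, alpha = 0.05) {
  stopifnot(methods::is(peaks, "GRanges"), alpha > 0, alpha < 1)
  v <- peak_vectors(peaks)
  gaps <- peak_gaps(v)
  if (length(gaps) < 2) return(NA_real_)
  mean_hat <- max(stats::median(gaps) / log(2), 1)
  -mean_hat * log(1 - alpha)
}

## plain-vector view of a peak GRanges, sorted by (chrom, start);
## S4 accessors are called once so the scan loops stay cheap
peak_vectors <- function(peaks) {
  ch <- as.vector(GenomicRanges::seqnames(peaks))
  ps <- GenomicRanges::start(peaks)
  pe <- GenomicRanges::end(peaks)
  o <- order(ch, ps)
  list(chrom = ch[o], start = ps[o], end = pe[o], order = o)
}

## gaps between consecutive same-chromosome peaks (bp, clamped at 0)
peak_gaps <- function(v) {
  n <- length(v$start)
  if (n < 2) return(numeric(0))
  same <- v$chrom[-1] == v$chrom[-n]
  pmax(v$start[-1] - v$end[-n] - 1, 0)[same]
}

#' Call COREs from one sample's peak set
#'
#' Peaks are sorted and scanned chromosome by chromosome; maximal runs of
#' peaks whose consecutive gaps are all at most the gap threshold (see
#' [core_gap_threshold()]) become COREs. The *order* of a CORE is its
#' number of member CREs; runs below `min_order` or above `max_order` are
#' discarded. Called COREs are non-overlapping by construction and carry
#' their member peaks.
#'
#' @param peaks A `GRanges` of peaks; sorted internally.
#' @param min_order Minimum number of member CREs (default 2).
#' @param max_order Maximum order retained (default `Inf`).
#' @param gap_threshold Fixed clustering distance in bp; by default
#'   estimated from the data via [core_gap_threshold()].
#' @param alpha Null quantile used when estimating the threshold.
#' @param keep_members Attach each CORE's member peaks as a `GRangesList`
#'   column (default TRUE; disable for large screens where only the CORE
#'   spans are needed).
#' @return A `GRanges` of COREs spanning first member start to last member
#'   end, with metadata columns `order` and (optionally) `members`.
#' @export
call_cores <- function(peaks, min_order = 2, max_order = Inf,
                       gap_threshold = NULL, alpha = 0.05,
                       keep_members = TRUE) {
  stopifnot(methods::is(peaks, "GRanges"), min_order >= 2)
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty)$order <- integer(0)
  if (keep_members)
    S4Vectors::mcols(empty)$members <- GenomicRanges::GRangesList()
  if (length(peaks) < min_order) return(empty)
  v <- peak_vectors(peaks)
  if (is.null(gap_threshold)) gap_threshold <- core_gap_threshold(peaks, alpha)
  if (!is.finite(gap_threshold)) return(empty)

  n <- length(v$start)
  ## linkage between consecutive peaks; chromosome changes never link
  same <- v$chrom[-1] == v$chrom[-n]
  gaps <- pmax(v$start[-1] - v$end[-n] - 1, 0)
  linked <- same & gaps <= gap_threshold
  ## run-length encode: a TRUE run over gap indices a..b links peaks a..b+1
  r <- rle(linked)
  pos <- cumsum(c(1, r$lengths))
  j <- which(r$values)
  if (!length(j)) return(empty)
  first <- pos[j]
  last <- pos[j + 1]
  k <- last - first + 1
  ok <- k >= min_order & k <= max_order
  if (!any(ok)) return(empty)
  first <- first[ok]; last <- last[ok]; k <- k[ok]
  ## run end = max member end (cummax guards rare nested long peaks;
  ## a containing peak is always linked to the run it engulfs)
  ce <- cummax_by_chrom(v$end, v$chrom)
  out <- GenomicRanges::GRanges(
    v$chrom[first],
    IRanges::IRanges(start = v$start[first], end = ce[last]))
  S4Vectors::mcols(out)$order <- as.integer(k)
  if (keep_members) {
    member_idx <- sequence(k, from = first)
    mem <- GenomicRanges::GRanges(
      v$chrom[member_idx],
      IRanges::IRanges(start = v$start[member_idx], end = v$end[member_idx]))
    S4Vectors::mcols(out)$members <- methods::as(
      IRanges::relist(mem, IRanges::PartitioningByEnd(cumsum(k))),
      "GRangesList")
  }
  attr(out, "gap_threshold") <- gap_threshold
  out
}

## running max of end coordinates, restarted at each chromosome block
cummax_by_chrom <- function(ends, chrom) {
  out <- numeric(length(ends))
  for (idx in split(seq_along(ends), chrom)) out[idx] <- cummax(ends[idx])
  out
}

#' Build a cross-sample CORE catalog
#'
#' Union-merges the COREs called in each sample (single linkage on >= 1 bp
#' overlap) into catalog entries, recording which samples contributed.
#' Entry ids render 1-based coordinates, e.g. `CORE-chr9-2014811-2032652`.
#'
#' @param core_list Named list of per-sample CORE `GRanges` (from
#'   [call_cores()]).
#' @return A `GRanges` catalog with metadata `id`, `n_contributors`,
#'   `contributors` (a `CharacterList`).
#' @export
build_catalog <- function(core_list) {
  stopifnot(is.list(core_list), length(core_list) >= 1,
            !is.null(names(core_list)))
  spans <- lapply(core_list, GenomicRanges::granges)
  all_cores <- do.call(c, unname(spans))
  if (length(all_cores) == 0) {
    cat <- GenomicRanges::GRanges()
    S4Vectors::mcols(cat)$id <- character(0)
    S4Vectors::mcols(cat)$n_contributors <- integer(0)
    return(cat)
  }
  cat <- GenomicRanges::reduce(sort(all_cores))
  sample_of <- rep(seq_along(spans), lengths(spans))
  ov <- GenomicRanges::findOverlaps(cat, all_cores)
  hit_m <- matrix(FALSE, length(cat), length(core_list))
  hit_m[cbind(S4Vectors::queryHits(ov),
              sample_of[S4Vectors::subjectHits(ov)])] <- TRUE
  hits <- lapply(seq_len(length(cat)), function(i)
    names(core_list)[hit_m[i, ]])
  S4Vectors::mcols(cat)$id <- sprintf(
    "CORE-%s-%d-%d", as.character(GenomicRanges::seqnames(cat)),
    GenomicRanges::start(cat), GenomicRanges::end(cat))
  S4Vectors::mcols(cat)$n_contributors <- lengths(hits)
  S4Vectors::mcols(cat)$contributors <- methods::as(hits, "CharacterList")
  cat
}

#' Tabulate which samples detect each catalog CORE
#'
#' A sample detects a catalog entry when one of its called COREs overlaps
#' it by at least 1 bp, or — if `min_reciprocal > 0` — when the overlap
#' covers at least that fraction of both intervals.
#'
#' @param catalog Output of [build_catalog()].
#' @param core_list Named list of per-sample CORE `GRanges`.
#' @param groups Data frame `sample_id`, `group` (two levels, positive
#'   class first), as produced by [simulate_peak_atlas()] or
#'   [read_sample_sheet()].
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0,
#'   i.e. any overlap).
#' @return A `detection_matrix` list: `matrix` (catalog x sample logical),
#'   `catalog`, `groups`.
#' @export
detection_matrix <- function(catalog, core_list, groups,
                             min_reciprocal = 0) {
  stopifnot(all(names(core_list) %in% groups$sample_id),
            min_reciprocal >= 0, min_reciprocal <= 1)
  m <- matrix(FALSE, nrow = length(catalog), ncol = length(core_list),
              dimnames = list(S4Vectors::mcols(catalog)$id, names(core_list)))
  spans <- lapply(core_list, GenomicRanges::granges)
  all_cores <- do.call(c, unname(spans))
  sample_of <- rep(seq_along(spans), lengths(spans))
  if (length(all_cores)) {
    ov <- GenomicRanges::findOverlaps(catalog, all_cores)
    if (min_reciprocal > 0 && length(ov)) {
      q <- GenomicRanges::granges(catalog)[S4Vectors::queryHits(ov)]
      su <- all_cores[S4Vectors::subjectHits(ov)]
      w <- GenomicRanges::width(GenomicRanges::pintersect(q, su))
      keep <- w >= min_reciprocal * GenomicRanges::width(q) &
              w >= min_reciprocal * GenomicRanges::width(su)
      ov <- ov[keep]
    }
    m[cbind(S4Vectors::queryHits(ov),
            sample_of[S4Vectors::subjectHits(ov)])] <- TRUE
  }
  groups <- groups[match(colnames(m), groups$sample_id), , drop = FALSE]
  structure(list(matrix = m, catalog = catalog, groups = groups),
            class = "detection_matrix")
}

#' Rank catalog COREs by LSC+/LSC- predictability
#'
#' The predictability coefficient (PC) of a catalog CORE is the balanced
#' accuracy of the classification rule "detected implies positive group":
#' `PC = (freq_pos + (1 - freq_neg)) / 2`, where `freq_pos` and
#' `freq_neg` are the detection frequencies in the two groups. `PC = 0.5`
#' whenever the frequencies are equal; `PC = 1` for perfect separation.
#' Results are sorted by descending PC, ties broken by descending
#' `|freq_pos - freq_neg|` then by coordinate.
#'
#' @param dm A [detection_matrix()] result.
#' @param positive Label of the positive group (default: first factor
#'   level of `groups$group`).
#' @return A data frame: `id`, `chrom`, `start`, `end`, `freq_pos`,
#'   `freq_neg`, `pc`, `rank`.
#' @export
rank_predictability <- function(dm, positive = NULL) {
  stopifnot(inherits(dm, "detection_matrix"))
  grp <- dm$groups$group
  if (is.null(positive)) positive <- levels(factor(grp))[1]
  is_pos <- grp == positive
  if (!any(is_pos) || all(is_pos))
    abort("both groups must be non-empty to rank predictability")
  m <- dm$matrix
  freq_pos <- rowMeans(m[, is_pos, drop = FALSE])
  freq_neg <- rowMeans(m[, !is_pos, drop = FALSE])
  pc <- (freq_pos + (1 - freq_neg)) / 2
  res <- data.frame(
    id = S4Vectors::mcols(dm$catalog)$id,
    chrom = as.character(GenomicRanges::seqnames(dm$catalog)),
    start = GenomicRanges::start(dm$catalog),
    end = GenomicRanges::end(dm$catalog),
    freq_pos = freq_pos, freq_neg = freq_neg, pc = pc,
    row.names = NULL)
  o <- order(-res$pc, -abs(res$freq_pos - res$freq_neg), res$chrom, res$start)
  res <- res[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Per-member-CRE accessibility frequencies for one catalog CORE
#'
#' The consensus member CREs of a catalog entry are the union-merged
#' member peaks of every called CORE that overlaps the entry. A CRE is
#' accessible in a sample when any of that sample's peaks overlaps it by
#' at least 1 bp; frequencies are reported per group.
#'
#' @param catalog_entry A length-1 `GRanges` (one catalog row).
#' @param core_list Named list of per-sample CORE `GRanges` (with
#'   `members`).
#' @param peak_list Named list of per-sample peak `GRanges`.
#' @param groups Data frame `sample_id`, `group`.
#' @return A data frame: `cre` (coordinates), one frequency column per
#'   group level.
#' @export
cre_accessibility_frequency <- function(catalog_entry, core_list, peak_list,
                                        groups) {
  stopifnot(methods::is(catalog_entry, "GRanges"), length(catalog_entry) == 1)
  member_pool <- list()
  for (cores in core_list) {
    if (length(cores) == 0) next
    ov <- GenomicRanges::findOverlaps(cores, catalog_entry)
    for (i in unique(S4Vectors::queryHits(ov)))
      member_pool[[length(member_pool) + 1]] <-
        S4Vectors::mcols(cores)$members[[i]]
  }
  if (!length(member_pool))
    abort("no called CORE overlaps this catalog entry")
  cres <- GenomicRanges::reduce(sort(do.call(c, member_pool)))
  lv <- levels(factor(groups$group))
  freq <- sapply(lv, function(g) {
    ids <- groups$sample_id[groups$group == g]
    if (!length(ids)) return(rep(NA_real_, length(cres)))
    acc <- vapply(ids, function(s)
      GenomicRanges::countOverlaps(cres, peak_list[[s]]) > 0,
      logical(length(cres)))
    rowMeans(matrix(acc, nrow = length(cres)))
  })
  out <- data.frame(cre = sprintf("%s:%d-%d",
                                  as.character(GenomicRanges::seqnames(cres)),
                                  GenomicRanges::start(cres),
                                  GenomicRanges::end(cres)))
  out <- cbind(out, as.data.frame(freq))
  names(out)[-1] <- paste0("freq_", lv)
  out
}
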