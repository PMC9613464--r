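## Stemness signature scoring: per-sample scores that quantify how
## stem-like a sample's expression profile is, using three procedures —
## Spearman correlation to a reference LSC+ profile (LSC104-style),
## a fixed weighted sum over signature genes (LSC17-style), and a
## rank-based single-sample running-sum enrichment score.

#' Construct / validate a gene signature
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene ids.
#' @param weights Optional numeric weights, one per gene; absent means
#'   unweighted.
#' @return A `gene_signature` list.
#' @export
gene_signature <- function(name, genes, weights = NULL) {
  stopifnot(is.character(genes), length(genes) >= 1)
  if (anyDuplicated(genes)) abort("signature genes must be unique")
  if (!is.null(weights)) {
    if (length(weights) != length(genes))
      abort("weights must align 1:1 with genes")
    stopifnot(is.numeric(weights), all(is.finite(weights)))
    names(weights) <- genes
  }
  structure(list(name = name, genes = genes, weights = weights),
            class = "gene_signature")
}

## pull one sample column as a named vector
sample_column <- function(expr, sample) {
  if (is.matrix(expr) || is.data.frame(expr)) {
    x <- expr[, sample]
    names(x) <- rownames(expr)
    x
  } else expr
}

#' Spearman correlation score against a reference profile
#'
#' Rank correlation between a sample's expression of the signature genes
#' and a reference profile (e.g. the mean expression of those genes
#' across a panel of functionally validated LSC+ fractions). Ties take
#' average ranks. Invariant under any strictly increasing transform of
#' the sample's values.
#'
#' @param x Named expression vector for one sample (log scale expected),
#'   or a matrix plus `sample`.
#' @param reference Named numeric vector covering the signature genes.
#' @param sample Column to extract when `x` is a matrix.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
signature_correlation_score <- function(x, reference, sample = NULL) {
  if (!is.null(sample)) x <- sample_column(x, sample)
  shared <- intersect(names(reference), names(x))
  if (length(shared) < 3) {
    missing <- setdiff(names(reference), names(x))
    abort(sprintf(
      "need >= 3 shared signature genes; missing from sample: %s",
      paste(missing, collapse = ", ")))
  }
  stats::cor(x[shared], reference[shared], method = "spearman")
}

#' Weighted signature score
#'
#' The weighted sum `sum_i w_i * x_i` over signature genes (an
#' LSC17-style score when given the published weights).
#'
#' @param x Named expression vector for one sample, or matrix plus
#'   `sample`.
#' @param signature A [gene_signature()] with weights (unweighted
#'   signatures use weight 1 for every gene).
#' @param missing Policy for signature genes absent from `x`: `"fail"`
#'   (default) errors; `"drop"` drops them with a warning.
#' @param sample Column to extract when `x` is a matrix.
#' @return The weighted score.
#' @export
weighted_signature_score <- function(x, signature,
                                     missing = c("fail", "drop"),
                                     sample = NULL) {
  missing <- match.arg(missing)
  stopifnot(inherits(signature, "gene_signature"))
  if (!is.null(sample)) x <- sample_column(x, sample)
  w <- signature$weights
  if (is.null(w)) w <- stats::setNames(rep(1, length(signature$genes)),
                                       signature$genes)
  absent <- setdiff(names(w), names(x))
  if (length(absent)) {
    if (missing == "fail")
      abort(sprintf("signature genes missing from expression data: %s",
                    paste(absent, collapse = ", ")))
    warning(sprintf("dropping %d missing signature genes", length(absent)),
            call. = FALSE)
    w <- w[setdiff(names(w), absent)]
  }
  sum(w * x[names(w)])
}

#' Single-sample running-sum enrichment score
#'
#' Genes are ranked by descending expression. A running sum steps up at
#' each signature gene and down by `1/(N - n)` at each non-signature
#' gene, where `N` is the total gene count and `n` the signature size.
#' Up-steps are proportional to the descending rank weight raised to
#' `tau` and normalized to sum to one (`tau = 0` gives equal up-steps of
#' `1/n`). The score is the sum of the running-sum values over all gene
#' positions, so coordinated high expression of the signature gives a
#' large positive score and coordinated low expression a negative one.
#' Ties in expression are broken by stable input order.
#'
#' @param x Named expression vector for one sample, or matrix plus
#'   `sample`.
#' @param signature A [gene_signature()] or character vector of genes;
#'   must cover at least one and fewer than all genes of `x`.
#' @param tau Rank-weight exponent (default 0.25).
#' @param sample Column to extract when `x` is a matrix.
#' @return The enrichment score.
#' @export
enrichment_score <- function(x, signature, tau = 0.25, sample = NULL) {
  if (!is.null(sample)) x <- sample_column(x, sample)
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else signature
  stopifnot(tau >= 0)
  N <- length(x)
  in_sig <- names(x) %in% genes
  n <- sum(in_sig)
  if (n == 0) abort("no signature gene present in the expression vector")
  if (n == N) abort("signature covers every gene; down-step undefined")
  ord <- order(x, decreasing = TRUE)   # ties: stable input order
  sig_sorted <- in_sig[ord]
  rank_weight <- (N:1)^tau             # descending rank weight, top gene largest
  up <- rank_weight * sig_sorted
  up <- up / sum(up)
  steps <- ifelse(sig_sorted, up, -1 / (N - n))
  sum(cumsum(steps))
}

#' Score every sample of an expression matrix across a declared hierarchy
#'
#' Computes the three stemness scores for each sample and, per score,
#' whether the group medians decrease monotonically along the hierarchy
#' order declared by the levels of `fractions` (stem tier first).
#' Monotonicity is not evaluated when fewer than two tiers are present.
#'
#' @param expr Gene x sample matrix (log scale expected).
#' @param fractions Factor of tier labels per sample; its level order is
#'   the hierarchy order.
#' @param signature A [gene_signature()] used for the weighted and
#'   enrichment scores.
#' @param reference Named reference profile for the correlation score.
#' @param tau Passed to [enrichment_score()].
#' @return A list: `scores` (data frame with `sample`, `fraction`,
#'   `spearman_score`, `weighted_score`, `enrichment_score`) and
#'   `monotone` (named logical per score, `NA` when not evaluated).
#' @export
score_hierarchy <- function(expr, fractions, signature, reference,
                            tau = 0.25) {
  stopifnot(is.matrix(expr), ncol(expr) >= 1)
  if (length(fractions) != ncol(expr))
    abort("fractions must annotate every sample column")
  fractions <- as.factor(fractions)
  if (anyNA(fractions)) abort("unknown fraction label (NA) in annotations")
  scores <- data.frame(
    sample = colnames(expr),
    fraction = fractions,
    spearman_score = vapply(colnames(expr), function(s)
      signature_correlation_score(expr, reference, sample = s), numeric(1)),
    weighted_score = vapply(colnames(expr), function(s)
      weighted_signature_score(expr, signature, sample = s), numeric(1)),
    enrichment_score = vapply(colnames(expr), function(s)
      enrichment_score(expr, signature, tau = tau, sample = s), numeric(1)),
    row.names = NULL)
  present <- levels(fractions)[levels(fractions) %in% fractions]
  monotone <- c(spearman_score = NA, weighted_score = NA,
                enrichment_score = NA)
  if (length(present) >= 2) {
    for (sc in names(monotone)) {
      med <- vapply(present, function(tier)
        stats::median(scores[[sc]][fractions == tier]), numeric(1))
      monotone[sc] <- all(diff(med) < 0)
    }
  }
  list(scores = scores, monotone = monotone)
}

#' Build a reference profile from a group of reference samples
#'
#' Mean expression of the signature genes across the reference columns
#' (log scale), the convention used for LSC104-style reference profiles.
#'
#' @param expr Gene x sample matrix.
#' @param samples Columns to average over.
#' @param signature A [gene_signature()] or character vector of genes.
#' @return Named numeric vector over signature genes present in `expr`.
#' @export
reference_profile <- function(expr, samples, signature) {
  genes <- if (inherits(signature, "gene_signature")) signature$genes
           else signature
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) abort("no signature gene present in the matrix")
  rowMeans(expr[genes, samples, drop = FALSE])
}
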