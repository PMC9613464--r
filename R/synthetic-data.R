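## Synthetic-data module: generates every input the pipeline consumes, with
## the statistical structure the downstream analyses assume, so that all
## stages can be exercised without access-restricted patient data.

#' Single-hit response probability
#'
#' Under the single-hit Poisson model, the probability that a transplanted
#' dose of `d` cells engrafts is `1 - exp(-f * d)`, where `f` is the
#' frequency of active (stem) cells.
#'
#' @param f Active-cell frequency, `f > 0`.
#' @param dose Cells injected per animal, `dose >= 0`.
#' @return Numeric vector of response probabilities.
#' @examples
#' lda_response_prob(1 / 286.4, 469)  # ~0.806
#' @export
lda_response_prob <- function(f, dose) {
  stopifnot(is.numeric(f), all(f > 0), is.numeric(dose), all(dose >= 0))
  1 - exp(-f * dose)
}

#' Simulate a limiting-dilution xenograft assay
#'
#' Draws the number of engrafted animals at each dose from
#' `Binomial(mice, 1 - exp(-f * dose))`, the single-hit model underlying
#' limiting-dilution stem-cell frequency estimation.
#'
#' @param f True active-cell frequency (`f > 0`).
#' @param doses Vector of cell doses, all `> 0`.
#' @param mice_per_dose Number of animals injected per dose; recycled to
#'   `length(doses)` if scalar.
#' @param seed Optional integer seed; identical seed and arguments give
#'   identical assays.
#' @return An `lda_assay` data frame with columns `dose`, `tested`,
#'   `responders`.
#' @seealso [estimate_frequency()]
#' @export
simulate_lda_assay <- function(f, doses, mice_per_dose, seed = NULL) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
  if (f <= 0) abort("'f' must be positive")
  if (!is.numeric(doses) || any(doses <= 0)) abort("all doses must be positive")
  if (length(mice_per_dose) == 1L) mice_per_dose <- rep(mice_per_dose, length(doses))
  stopifnot(length(mice_per_dose) == length(doses), all(mice_per_dose >= 1))
  r <- with_seed(seed, stats::rbinom(length(doses), size = mice_per_dose,
                                     prob = lda_response_prob(f, doses)))
  lda_assay(data.frame(dose = doses, tested = mice_per_dose, responders = r))
}

#' Define a copy-number simulation profile
#'
#' One row per segment of the synthetic chromosome. Segments must tile the
#' chromosome contiguously without overlap (0-based half-open bounds).
#'
#' @param start,end Segment bounds in bp.
#' @param base_cn Copy number of the major clone.
#' @param subclone_cn Copy number of the subclone.
#' @param phi Subclone fraction in `[0, 1]`.
#' @param noise_sd Per-bin Gaussian noise standard deviation, `>= 0`.
#' @return A `cn_profile` data frame.
#' @export
cn_profile <- function(start, end, base_cn, subclone_cn, phi, noise_sd) {
  p <- data.frame(start = start, end = end, base_cn = base_cn,
                  subclone_cn = subclone_cn, phi = phi, noise_sd = noise_sd)
  if (any(p$end <= p$start)) abort("segment end must exceed start")
  if (any(p$phi < 0 | p$phi > 1)) abort("phi must lie in [0, 1]")
  if (any(p$noise_sd < 0)) abort("noise_sd must be >= 0")
  o <- order(p$start)
  p <- p[o, , drop = FALSE]
  if (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)]))
    abort("profile segments must tile the chromosome without overlap or gaps")
  rownames(p) <- NULL
  class(p) <- c("cn_profile", "data.frame")
  p
}

#' Simulate paired reference and query copy-number tracks
#'
#' The reference track emulates a pure-subclone sample (the expanded,
#' cultured clone): each bin is `Normal(subclone_cn, noise_sd)`. The query
#' track emulates a bulk sample carrying the subclone at fraction `phi`:
#' each bin is `Normal(base_cn * (1 - phi) + subclone_cn * phi, noise_sd)`.
#'
#' @param profile A [cn_profile()] data frame.
#' @param bin_size Bin width in bp (default 1000).
#' @param seed Optional integer seed.
#' @param chrom Chromosome name for the synthetic tracks.
#' @return A list with elements `reference` and `query`, each a `cn_track`
#'   data frame (`chrom`, `start`, `end`, `cn`).
#' @export
simulate_cn_tracks <- function(profile, bin_size = 1000, seed = NULL,
                               chrom = "chrS") {
  if (!inherits(profile, "cn_profile")) profile <- do.call(cn_profile, as.list(profile))
  total <- max(profile$end)
  starts <- seq(0, total - 1, by = bin_size)
  ends <- pmin(starts + bin_size, total)
  mid <- (starts + ends) / 2
  seg <- findInterval(mid, profile$start)
  stopifnot(all(seg >= 1 & seg <= nrow(profile)))
  mu_q <- profile$base_cn[seg] * (1 - profile$phi[seg]) +
          profile$subclone_cn[seg] * profile$phi[seg]
  mu_r <- profile$subclone_cn[seg]
  sd_b <- profile$noise_sd[seg]
  n <- length(starts)
  vals <- with_seed(seed, list(r = stats::rnorm(n, mu_r, sd_b),
                               q = stats::rnorm(n, mu_q, sd_b)))
  list(
    reference = cn_track(data.frame(chrom = chrom, start = starts, end = ends,
                                    cn = vals$r), bin_size = bin_size),
    query = cn_track(data.frame(chrom = chrom, start = starts, end = ends,
                                cn = vals$q), bin_size = bin_size)
  )
}

#' Describe a planted cluster of cis-regulatory elements
#'
#' A planted CORE is a run of `n_cres` equally spaced fixed-width peaks that
#' a sample carries with a group-specific probability; it is the ground
#' truth against which CORE discovery is evaluated.
#'
#' @param chrom Chromosome name.
#' @param start Start of the first member CRE (0-based bp).
#' @param n_cres Number of member CREs (`>= 2`), e.g. 7.
#' @param cre_width Width of each CRE in bp.
#' @param gap Gap between consecutive CREs in bp.
#' @param presence_prob_pos,presence_prob_neg Probability that an LSC+ /
#'   LSC- sample carries the whole cluster, each in `[0, 1]`.
#' @return A `planted_core` list.
#' @export
planted_core <- function(chrom = "chrS", start, n_cres = 7, cre_width = 300,
                         gap = 2000, presence_prob_pos = 0.75,
                         presence_prob_neg = 0.20) {
  if (n_cres < 2) abort("a planted CORE needs at least 2 CREs")
  if (any(c(presence_prob_pos, presence_prob_neg) < 0) ||
      any(c(presence_prob_pos, presence_prob_neg) > 1))
    abort("presence probabilities must lie in [0, 1]")
  stopifnot(start >= 0, cre_width > 0, gap >= 0)
  structure(list(chrom = chrom, start = start, n_cres = n_cres,
                 cre_width = cre_width, gap = gap,
                 presence_prob_pos = presence_prob_pos,
                 presence_prob_neg = presence_prob_neg),
            class = "planted_core")
}

planted_core_span <- function(pc) {
  c(pc$start, pc$start + pc$n_cres * pc$cre_width + (pc$n_cres - 1) * pc$gap)
}

planted_core_peaks <- function(pc) {
  starts <- pc$start + (seq_len(pc$n_cres) - 1) * (pc$cre_width + pc$gap)
  GenomicRanges::GRanges(pc$chrom,
                         IRanges::IRanges(start = starts + 1,
                                          width = pc$cre_width))
}

#' Configuration for a synthetic peak atlas
#'
#' Defaults emulate the design of the study the pipeline targets: 41 LSC+
#' and 52 LSC- fractions, one discriminative planted CORE of seven CREs
#' (presence 0.75 in LSC+ vs 0.20 in LSC-) among non-discriminative decoy
#' COREs, on a Poisson background of fixed-width peaks.
#'
#' @param seed Root integer seed.
#' @param n_lsc_pos,n_lsc_neg Group sizes.
#' @param genome_length Length of the synthetic chromosome in bp.
#' @param background_peak_rate Background peaks per Mb.
#' @param peak_width Width of background peaks in bp.
#' @param planted_cores List of [planted_core()] objects; they must not
#'   overlap one another and must lie within the genome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_lsc_pos = 41L, n_lsc_neg = 52L,
                       genome_length = 2e7, background_peak_rate = 15,
                       peak_width = 300, planted_cores = list()) {
  stopifnot(n_lsc_pos >= 0, n_lsc_neg >= 0, genome_length > 0,
            background_peak_rate >= 0, peak_width > 0)
  if (length(planted_cores)) {
    spans <- t(vapply(planted_cores, planted_core_span, numeric(2)))
    chs <- vapply(planted_cores, `[[`, character(1), "chrom")
    if (any(spans[, 2] > genome_length) || any(spans[, 1] < 0))
      abort("planted CORE outside genome bounds")
    o <- order(chs, spans[, 1])
    same <- chs[o][-1] == chs[o][-length(o)]
    if (any(same & spans[o, 1][-1] < spans[o, 2][-length(o)]))
      abort("planted COREs must not overlap each other")
  }
  structure(list(seed = seed, n_lsc_pos = n_lsc_pos, n_lsc_neg = n_lsc_neg,
                 genome_length = genome_length,
                 background_peak_rate = background_peak_rate,
                 peak_width = peak_width, planted_cores = planted_cores),
            class = "sim_config")
}

#' Simulate a grouped atlas of accessible-region peak sets
#'
#' Each sample receives `Poisson(rate * genome_length / 1e6)` background
#' peaks with uniform starts and fixed width, plus — with its group's
#' presence probability — every planted CORE as a run of regularly spaced
#' CREs. Peaks are returned sorted with non-negative coordinates.
#'
#' @param config A [sim_config()] object.
#' @return A list with `peaks` (named list of `GRanges`, one per sample)
#'   and `groups` (data frame `sample_id`, `group` with levels
#'   `LSC+`/`LSC-`).
#' @export
simulate_peak_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- c(sprintf("LSCpos_%02d", seq_len(config$n_lsc_pos)),
           sprintf("LSCneg_%02d", seq_len(config$n_lsc_neg)))
  grp <- rep(c("LSC+", "LSC-"), c(config$n_lsc_pos, config$n_lsc_neg))
  lambda <- config$background_peak_rate * config$genome_length / 1e6
  planted <- lapply(config$planted_cores, function(pc) {
    s <- pc$start + (seq_len(pc$n_cres) - 1) * (pc$cre_width + pc$gap)
    list(chrom = rep(pc$chrom, pc$n_cres), start = s + 1,
         end = s + pc$cre_width,
         p_pos = pc$presence_prob_pos, p_neg = pc$presence_prob_neg)
  })
  peaks <- with_seed(config$seed, {
    lapply(seq_along(ids), function(i) {
      n_bg <- stats::rpois(1, lambda)
      bg_start <- if (n_bg > 0)
        floor(stats::runif(n_bg, 0, config$genome_length - config$peak_width)) + 1
      else numeric(0)
      ch <- rep("chrS", n_bg)
      st <- bg_start
      en <- bg_start + config$peak_width - 1
      for (pl in planted) {
        p_carry <- if (grp[i] == "LSC+") pl$p_pos else pl$p_neg
        if (stats::runif(1) < p_carry) {
          ch <- c(ch, pl$chrom); st <- c(st, pl$start); en <- c(en, pl$end)
        }
      }
      o <- order(ch, st)
      GenomicRanges::GRanges(ch[o], IRanges::IRanges(start = st[o], end = en[o]))
    })
  })
  names(peaks) <- ids
  list(peaks = peaks,
       groups = data.frame(sample_id = ids,
                           group = factor(grp, levels = c("LSC+", "LSC-"))))
}

#' Simulate a hierarchical expression matrix with graded stemness signal
#'
#' Emulates a 4-tier immunophenotypic hierarchy (stem at tier 1, mature at
#' tier `n_tiers`): signature genes receive an additive effect that
#' decreases linearly from full strength at tier 1 to 0 at the last tier;
#' all other genes are pure noise around their per-gene baseline. Per-gene
#' effect magnitudes are spread evenly over `[0.5, 1.5] * effect` (mean
#' `effect`), so that stem-tier samples also *reorder* the signature genes
#' the way the reference profile does — the structure rank-based scores
#' respond to. Values are on the log scale the scoring procedures expect.
#'
#' @param n_genes Total number of genes.
#' @param n_signature_genes Number of signature genes (`<= n_genes`).
#' @param effect Additive tier-1 effect on signature genes (log units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_per_tier Samples per tier.
#' @param n_tiers Number of hierarchy tiers (default 4).
#' @param seed Optional integer seed.
#' @return A list with `expr` (gene x sample matrix), `fractions` (ordered
#'   factor of tier labels, stem first), `signature` (a `gene_signature`
#'   with unit weights), and `reference` (named vector: mean expression of
#'   the signature genes across the tier-1 samples, i.e. the LSC+
#'   reference profile).
#' @export
simulate_expression <- function(n_genes = 1000, n_signature_genes = 50,
                                effect = 1, noise_sd = 0.5, n_per_tier = 5,
                                n_tiers = 4, seed = NULL) {
  if (n_signature_genes > n_genes)
    abort("n_signature_genes must not exceed n_genes")
  stopifnot(n_tiers >= 1, n_per_tier >= 1, noise_sd >= 0)
  genes <- sprintf("g%04d", seq_len(n_genes))
  sig_genes <- genes[seq_len(n_signature_genes)]
  tiers <- paste0("tier", seq_len(n_tiers))
  fr <- factor(rep(tiers, each = n_per_tier), levels = tiers, ordered = TRUE)
  samples <- paste0(rep(tiers, each = n_per_tier), "_s",
                    rep(seq_len(n_per_tier), n_tiers))
  tier_scale <- if (n_tiers == 1) 0 else
    (n_tiers - as.integer(fr)) / (n_tiers - 1)  # 1 at tier1, 0 at last tier
  gene_effect <- if (n_signature_genes == 1) effect else
    effect * seq(0.5, 1.5, length.out = n_signature_genes)
  out <- with_seed(seed, {
    baseline <- stats::rnorm(n_genes, mean = 5, sd = 1)
    mu <- matrix(baseline, n_genes, length(samples))
    mu[seq_len(n_signature_genes), ] <- mu[seq_len(n_signature_genes), ] +
      outer(gene_effect, tier_scale)
    mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
  })
  dimnames(out) <- list(genes, samples)
  ref <- rowMeans(out[sig_genes, as.integer(fr) == 1, drop = FALSE])
  list(expr = out, fractions = fr,
       signature = gene_signature("synthetic_stemness", sig_genes,
                                  weights = rep(1, n_signature_genes)),
       reference = ref)
}
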