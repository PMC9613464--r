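test_that("single-hit response probabilities follow the closed form", {
  expect_equal(lda_response_prob(1 / 286.4, 0), 0)
  expect_equal(lda_response_prob(1 / 286.4, 469), 1 - exp(-469 / 286.4))
  expect_equal(lda_response_prob(1 / 286.4, 469), 0.806, tolerance = 0.001)
})

test_that("simulated assays converge to the single-hit law", {
  # saturating doses: f*d >> 1, so nearly every animal responds
  a <- simulate_lda_assay(1 / 286.4, doses = c(30000, 7500),
                          mice_per_dose = 10000, seed = 11)
  expect_true(all(a$responders / a$tested > 0.99))
  # moderate dose: empirical fraction within 3-sigma binomial band
  d <- 200
  p <- lda_response_prob(1 / 286.4, d)
  a2 <- simulate_lda_assay(1 / 286.4, doses = d, mice_per_dose = 10000,
                           seed = 12)
  expect_lt(abs(a2$responders / a2$tested - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(simulate_lda_assay(0, 100, 5), "positive")
  expect_error(simulate_lda_assay(0.01, c(100, -1), 5), "positive")
})

test_that("copy-number tracks mix clones with the stated segment means", {
  prof <- cn_profile(start = c(0, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
                     base_cn = 2, subclone_cn = c(2, 5, 4),
                     phi = c(0, 0.3, 1), noise_sd = 0.3)
  tr <- simulate_cn_tracks(prof, seed = 5)
  q <- tr$query
  seg_mean <- function(track, lo, hi) mean(track$cn[track$start >= lo & track$start < hi])
  band <- 3 * 0.3 / sqrt(100)
  expect_lt(abs(seg_mean(q, 0, 1e5) - 2), band)        # phi = 0: base only
  expect_lt(abs(seg_mean(q, 1e5, 2e5) - 2.9), band)    # 2*0.7 + 5*0.3
  expect_lt(abs(seg_mean(q, 2e5, 3e5) - 4), band)      # pure subclone
  # reference is the pure subclone everywhere
  expect_lt(abs(seg_mean(tr$reference, 1e5, 2e5) - 5), band)
  expect_error(cn_profile(start = c(0, 5e4), end = c(1e5, 1.5e5), base_cn = 2,
                          subclone_cn = 4, phi = 0.5, noise_sd = 0.1),
               "tile")
})

test_that("peak atlases honour presence probabilities and peak counts", {
  span <- GenomicRanges::GRanges("chrS", IRanges::IRanges(2e6 + 1, 2e6 + 14100))
  # degenerate probabilities: every LSC+ sample carries, no LSC- sample does
  cfg <- sim_config(seed = 3, n_lsc_pos = 10, n_lsc_neg = 10,
                    planted_cores = list(planted_core(
                      start = 2e6, presence_prob_pos = 1, presence_prob_neg = 0)))
  atlas <- simulate_peak_atlas(cfg)
  carries <- vapply(atlas$peaks, function(p)
    sum(GenomicRanges::countOverlaps(p, span)) >= 7, logical(1))
  expect_true(all(carries[atlas$groups$group == "LSC+"]))
  expect_false(any(carries[atlas$groups$group == "LSC-"]))
  # no background, one 7-CRE cluster: carriers have exactly 7 peaks
  cfg0 <- sim_config(seed = 4, n_lsc_pos = 5, n_lsc_neg = 0,
                     background_peak_rate = 0,
                     planted_cores = list(planted_core(
                       start = 2e6, presence_prob_pos = 1, presence_prob_neg = 1)))
  atlas0 <- simulate_peak_atlas(cfg0)
  expect_true(all(lengths(atlas0$peaks) == 7))
  # carrier counts near expectation under the defaults (0.75 / 0.20)
  cfg2 <- sim_config(seed = 9, planted_cores = list(planted_core(start = 2e6)))
  atlas2 <- simulate_peak_atlas(cfg2)
  carries2 <- vapply(atlas2$peaks, function(p)
    sum(GenomicRanges::countOverlaps(p, span)) >= 7, logical(1))
  n_pos <- sum(carries2[atlas2$groups$group == "LSC+"])
  n_neg <- sum(carries2[atlas2$groups$group == "LSC-"])
  expect_true(abs(n_pos - 41 * 0.75) <= 2 * sqrt(41 * 0.75 * 0.25))
  expect_true(abs(n_neg - 52 * 0.20) <= 2 * sqrt(52 * 0.20 * 0.80))
  expect_error(sim_config(planted_cores = list(planted_core(start = 3e7))),
               "bounds")
  expect_error(sim_config(planted_cores = list(planted_core(start = 1e6),
                                               planted_core(start = 1e6 + 5000))),
               "overlap")
})

test_that("expression tiers carry a linearly graded signature signal", {
  sim <- simulate_expression(n_genes = 400, n_signature_genes = 20,
                             effect = 1, noise_sd = 0.5, n_per_tier = 30,
                             seed = 21)
  w1 <- vapply(which(sim$fractions == "tier1"), function(j)
    sum(sim$expr[sim$signature$genes, j]), numeric(1))
  w4 <- vapply(which(sim$fractions == "tier4"), function(j)
    sum(sim$expr[sim$signature$genes, j]), numeric(1))
  # per-gene unit weights: expected tier1 - tier4 difference = 20 * effect
  mc_err <- 3 * sqrt(2 * 20 * 0.25 / 30)
  expect_lt(abs(mean(w1) - mean(w4) - 20), mc_err)
  # null effect: no tier separation beyond noise
  sim0 <- simulate_expression(n_genes = 400, n_signature_genes = 20,
                              effect = 0, noise_sd = 0.5, n_per_tier = 30,
                              seed = 22)
  w1_0 <- vapply(which(sim0$fractions == "tier1"), function(j)
    sum(sim0$expr[sim0$signature$genes, j]), numeric(1))
  w4_0 <- vapply(which(sim0$fractions == "tier4"), function(j)
    sum(sim0$expr[sim0$signature$genes, j]), numeric(1))
  expect_lt(abs(mean(w1_0) - mean(w4_0)), mc_err)
  # strong effect, no noise: a tier-1 sample ranks all signature genes high
  sim2 <- simulate_expression(n_genes = 100, n_signature_genes = 10,
                              effect = 20, noise_sd = 0, n_per_tier = 1,
                              seed = 23)
  top <- names(sort(sim2$expr[, 1], decreasing = TRUE))[1:10]
  expect_setequal(top, sim2$signature$genes)
  expect_error(simulate_expression(n_genes = 10, n_signature_genes = 11),
               "exceed")
})

test_that("identical seed and configuration give identical outputs", {
  cfg <- sim_config(seed = 42, n_lsc_pos = 5, n_lsc_neg = 5,
                    planted_cores = list(planted_core(start = 2e6)))
  a1 <- simulate_peak_atlas(cfg)
  a2 <- simulate_peak_atlas(cfg)
  expect_identical(lapply(a1$peaks, as.data.frame),
                   lapply(a2$peaks, as.data.frame))
  prof <- cn_profile(0, 1e5, 2, 5, 0.3, 0.2)
  expect_identical(simulate_cn_tracks(prof, seed = 7),
                   simulate_cn_tracks(prof, seed = 7))
  expect_identical(simulate_expression(seed = 7)$expr,
                   simulate_expression(seed = 7)$expr)
  expect_identical(simulate_lda_assay(0.01, c(100, 10), 5, seed = 7),
                   simulate_lda_assay(0.01, c(100, 10), 5, seed = 7))
  # a different seed changes the draw
  expect_false(identical(simulate_expression(seed = 7)$expr,
                         simulate_expression(seed = 8)$expr))
})
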