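test_that("a tight run of seven CREs on a sparse background is one order-7 CORE", {
  peaks <- planted_run_peaks()
  cores <- call_cores(peaks)
  expect_equal(length(cores), 1)
  expect_equal(S4Vectors::mcols(cores)$order, 7L)
  # span: first member start to last member end
  expect_equal(GenomicRanges::start(cores), 5e7 + 1)
  expect_equal(GenomicRanges::end(cores), 5e7 + 6 * 2200 + 200)
  expect_equal(length(S4Vectors::mcols(cores)$members[[1]]), 7)
  # oracle: the planted gaps are the only adjacent gaps below the
  # threshold, so no other run of any order can be called
  th <- attr(cores, "gap_threshold")
  st <- GenomicRanges::start(peaks); en <- GenomicRanges::end(peaks)
  gaps <- st[-1] - en[-length(en)] - 1
  expect_equal(sum(gaps <= th), 6)
  # isolated peaks alone yield nothing
  expect_equal(length(call_cores(peaks[1])), 0)
  expect_equal(length(call_cores(GenomicRanges::GRanges())), 0)
})

test_that("CORE calling is invariant to peak order and respects order bounds", {
  peaks <- planted_run_peaks()
  set.seed(5)
  shuffled <- peaks[sample(length(peaks))]
  expect_identical(as.data.frame(call_cores(shuffled)),
                   as.data.frame(call_cores(peaks)))
  # max_order filter drops the run
  expect_equal(length(call_cores(peaks, max_order = 6)), 0)
  expect_equal(length(call_cores(peaks, min_order = 8)), 0)
  # called COREs never overlap within a sample
  cfg <- sim_config(seed = 13, n_lsc_pos = 3, n_lsc_neg = 3,
                    planted_cores = default_planted_cores())
  atlas <- simulate_peak_atlas(cfg)
  for (p in atlas$peaks) {
    cc <- call_cores(p)
    if (length(cc) > 1)
      expect_true(all(GenomicRanges::countOverlaps(cc, cc) == 1))
  }
})

test_that("the catalog union-merges overlapping COREs across samples", {
  gr <- function(st, en) GenomicRanges::GRanges("chr9",
    IRanges::IRanges(start = st, end = en))
  # identical COREs in two samples: one entry, two contributors
  cat1 <- build_catalog(list(a = gr(100, 200), b = gr(100, 200)))
  expect_equal(length(cat1), 1)
  expect_equal(S4Vectors::mcols(cat1)$n_contributors, 2L)
  # chaining overlap merges into one entry
  cat2 <- build_catalog(list(a = gr(1, 10000), b = gr(9000, 20000)))
  expect_equal(length(cat2), 1)
  expect_equal(GenomicRanges::start(cat2), 1)
  expect_equal(GenomicRanges::end(cat2), 20000)
  # different chromosomes stay separate, ids render coordinates
  cat3 <- build_catalog(list(
    a = GenomicRanges::GRanges(c("chr9", "chr11"),
                               IRanges::IRanges(c(100, 100), c(200, 200)))))
  expect_equal(length(cat3), 2)
  expect_equal(S4Vectors::mcols(cat3)$id,
               c("CORE-chr9-100-200", "CORE-chr11-100-200"))
})

test_that("detection frequencies and predictability ranking are exact arithmetic", {
  gr <- function(st, en) GenomicRanges::GRanges("chr9",
    IRanges::IRanges(start = st, end = en))
  groups <- toy_groups(41, 52)
  # 31/41 positives and 10/52 negatives carry the CORE
  core_list <- setNames(lapply(seq_len(93), function(i) {
    carry <- (i <= 31) || (i > 41 && i <= 51)
    if (carry) gr(1000, 2000) else gr(50000, 51000)
  }), groups$sample_id)
  dm <- detection_matrix(build_catalog(core_list), core_list, groups)
  rk <- rank_predictability(dm)
  row <- rk[rk$start == 1000, ]
  expect_equal(row$freq_pos, 31 / 41)
  expect_equal(row$freq_neg, 10 / 52)
  expect_equal(row$pc, (31 / 41 + 1 - 10 / 52) / 2)
  expect_equal(round(row$pc, 3), 0.782)
  expect_equal(row$rank, 1)
  # uninformative detection everywhere: PC = 0.5
  all_list <- setNames(lapply(1:93, function(i) gr(1, 100)), groups$sample_id)
  rk2 <- rank_predictability(detection_matrix(build_catalog(all_list),
                                              all_list, groups))
  expect_equal(rk2$pc, 0.5)
  # perfect separation: PC = 1
  sep_list <- setNames(lapply(1:93, function(i)
    if (i <= 41) gr(1, 100) else gr(9000, 9100)), groups$sample_id)
  rk3 <- rank_predictability(detection_matrix(build_catalog(sep_list),
                                              sep_list, groups))
  expect_equal(rk3$pc[rk3$start == 1], 1)
  # a sample with zero COREs yields an all-false column
  none_list <- setNames(c(lapply(1:92, function(i) gr(1, 100)),
                          list(call_cores(GenomicRanges::GRanges()))),
                        groups$sample_id)
  dm4 <- detection_matrix(build_catalog(none_list), none_list, groups)
  expect_false(any(dm4$matrix[, 93]))
  # one-group data cannot be ranked
  expect_error(rank_predictability(detection_matrix(
    build_catalog(all_list[1:41]), all_list[1:41], groups[1:41, ])),
    "non-empty")
})

test_that("PC is 0.5 whenever group frequencies coincide and stays in [0, 1]", {
  set.seed(88)
  for (i in 1:20) {
    n_pos <- sample(3:10, 1); n_neg <- sample(3:10, 1)
    m <- matrix(runif((n_pos + n_neg) * 5) < 0.5, nrow = 5)
    groups <- toy_groups(n_pos, n_neg)
    colnames(m) <- groups$sample_id
    rownames(m) <- sprintf("CORE-chrS-%d-%d", 1:5 * 1000, 1:5 * 1000 + 500)
    dm <- structure(list(
      matrix = m,
      catalog = GenomicRanges::GRanges(rep("chrS", 5),
        IRanges::IRanges(1:5 * 1000, width = 500), id = rownames(m)),
      groups = groups), class = "detection_matrix")
    rk <- rank_predictability(dm)
    expect_true(all(rk$pc >= 0 & rk$pc <= 1))
    same <- abs(rk$freq_pos - rk$freq_neg) < 1e-12
    expect_true(all(abs(rk$pc[same] - 0.5) < 1e-12))
  }
})

test_that("a planted discriminative CORE wins the predictability ranking", {
  hits <- vapply(1:5, function(rep) {
    cfg <- sim_config(seed = 3000 + rep, planted_cores = default_planted_cores())
    atlas <- simulate_peak_atlas(cfg)
    cores <- lapply(atlas$peaks, call_cores, keep_members = FALSE)
    dm <- detection_matrix(build_catalog(cores), cores, atlas$groups)
    rk <- rank_predictability(dm)
    disc_start <- default_planted_cores()[[1]]$start
    top <- rk[1, ]
    top$start <= disc_start + 14100 && top$end >= disc_start + 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("member-CRE accessibility frequencies track planted presence", {
  cfg <- sim_config(seed = 71, n_lsc_pos = 20, n_lsc_neg = 20,
                    background_peak_rate = 2,
                    planted_cores = list(planted_core(
                      start = 2e6, presence_prob_pos = 1,
                      presence_prob_neg = 0)))
  atlas <- simulate_peak_atlas(cfg)
  cores <- lapply(atlas$peaks, call_cores)
  catalog <- build_catalog(cores)
  hit <- which(GenomicRanges::start(catalog) <= 2e6 + 1 &
               GenomicRanges::end(catalog) >= 2e6 + 14100)
  expect_equal(length(hit), 1)
  freq <- cre_accessibility_frequency(catalog[hit], cores, atlas$peaks,
                                      atlas$groups)
  # the 7 planted CREs are always among the consensus members (background
  # peaks caught inside the cluster region may add a few more)
  expect_gte(nrow(freq), 7)
  planted_starts <- 2e6 + (0:6) * 2300 + 1
  planted_rows <- vapply(planted_starts, function(s)
    which(grepl(sprintf(":%d-", s), freq$cre))[1], integer(1))
  expect_false(anyNA(planted_rows))
  expect_true(all(freq$`freq_LSC+`[planted_rows] == 1))
  expect_true(all(freq$`freq_LSC-`[planted_rows] < 0.3))
})
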