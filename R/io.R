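## Readers and writers for the plain-text formats the pipeline consumes
## and produces: BED/narrowPeak peak files, bedGraph-style copy-number
## tracks, CSV assay tables, TSV expression matrices, GMT signatures, TSV
## sample sheets, and the JSON run manifest. Every reader validates the
## invariants of the object it builds.

#' Read a limiting-dilution assay CSV
#'
#' Expects a header `dose,tested,responders`.
#'
#' @param path CSV file path.
#' @return An [lda_assay()] data frame.
#' @export
read_assay <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("dose", "tested", "responders")) {
    if (!col %in% names(x)) abort(sprintf("assay file lacks column '%s'", col))
    if (!is.numeric(x[[col]]))
      abort(sprintf("non-numeric values in assay column '%s'", col))
  }
  lda_assay(x)
}

#' Write a limiting-dilution assay CSV
#' @param assay An [lda_assay()].
#' @param path Output path.
#' @export
write_assay <- function(assay, path) {
  utils::write.csv(as.data.frame(assay), path, row.names = FALSE, quote = FALSE)
}

#' Read a binned copy-number track
#'
#' Tab-separated `chrom start end cn` (bedGraph-compatible, 0-based
#' half-open), with or without a header line. Gaps between consecutive
#' bins are tolerated with a warning.
#'
#' @param path TSV file path.
#' @param bin_size Nominal bin size (default 1000).
#' @return A [cn_track()].
#' @export
read_cn_track <- function(path, bin_size = 1000) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, ignore.case = TRUE)
  x <- utils::read.table(path, header = has_header, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 4) abort("copy-number track needs 4 columns: chrom start end cn")
  names(x)[1:4] <- c("chrom", "start", "end", "cn")
  if (!is.numeric(x$cn)) abort("non-numeric cn values in track")
  tr <- cn_track(x[1:4], bin_size = bin_size)
  gaps <- unlist(lapply(split(tr, tr$chrom), function(p)
    if (nrow(p) > 1) p$start[-1] - p$end[-nrow(p)] else numeric(0)))
  if (any(gaps > 0))
    warning(sprintf("%d gaps between consecutive bins", sum(gaps > 0)),
            call. = FALSE)
  tr
}

#' Write a copy-number track as bedGraph-style TSV
#' @param track A [cn_track()].
#' @param path Output path.
#' @param header Write a header line (default TRUE).
#' @export
write_cn_track <- function(track, path, header = TRUE) {
  utils::write.table(as.data.frame(track)[c("chrom", "start", "end", "cn")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
}

#' Read a peak file (BED3/BED6/narrowPeak)
#'
#' Comment and track lines are skipped. narrowPeak extra columns are
#' preserved as metadata. Intervals are returned sorted as a `GRanges`
#' (1-based closed, converted from the file's 0-based half-open
#' coordinates by the underlying importer).
#'
#' @param path File path; dialect chosen from the column count.
#' @return A sorted `GRanges`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(body)) return(GenomicRanges::GRanges())
  ncols <- length(strsplit(body[1], "\t")[[1]])
  gr <- tryCatch({
    if (ncols >= 10) {
      rtracklayer::import(path, format = "BED",
        extraCols = c(signalValue = "numeric", pValue = "numeric",
                      qValue = "numeric", peak = "integer"))
    } else {
      rtracklayer::import(path, format = "BED")
    }
  }, error = function(e)
    abort(sprintf("malformed peak file '%s': %s", path, conditionMessage(e))))
  if (any(GenomicRanges::width(gr) < 1))
    abort(sprintf("interval with end <= start in '%s'", path))
  sort(gr)
}

#' Write intervals as BED
#' @param gr A `GRanges`.
#' @param path Output path (0-based half-open BED).
#' @export
write_peaks <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
}

#' Read gene signatures from a GMT file
#'
#' Each line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of [gene_signature()] objects (unweighted).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3)
      abort(sprintf("GMT line %d has fewer than 3 fields", i))
    gene_signature(f[1], unique(f[-(1:2)]))
  })
  stats::setNames(sigs, vapply(sigs, `[[`, character(1), "name"))
}

#' Write gene signatures to a GMT file
#' @param signatures List of [gene_signature()] objects.
#' @param path Output path.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(signatures, function(s)
    paste(c(s$name, "na", s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Read a weighted signature from a two-column TSV (`gene`, `weight`)
#'
#' @param path TSV path with header.
#' @param name Signature name (default: file base name).
#' @return A [gene_signature()] with weights.
#' @export
read_weighted_signature <- function(path, name = NULL) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2 || !is.numeric(x[[2]]))
    abort("weighted signature needs columns gene, weight (numeric)")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_signature(name, as.character(x[[1]]), weights = x[[2]])
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column: gene ids (must be unique); remaining columns numeric.
#'
#' @param path TSV path with header.
#' @return A numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  genes <- as.character(x[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    abort(sprintf("duplicate gene ids: %s", paste(unique(dup), collapse = ", ")))
  m <- as.matrix(x[-1])
  if (!is.numeric(m)) {
    bad <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))]
    abort(sprintf("non-numeric expression column: %s",
                  paste(bad, collapse = ", ")))
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#' @param expr Gene x sample matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet TSV
#'
#' Columns `sample_id`, `path`, `group` (and optionally `fraction`).
#' Sample ids must be unique; when `check_files = TRUE` every referenced
#' file must exist.
#'
#' @param path TSV path with header.
#' @param check_files Verify referenced files exist (default TRUE).
#' @return A data frame.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "group")
  if (!all(need %in% names(x)))
    abort("sample sheet needs columns sample_id, path, group")
  if (anyDuplicated(x$sample_id))
    abort("sample_id values must be unique")
  if (check_files) {
    missing <- !file.exists(x$path)
    if (any(missing))
      abort(sprintf("missing input file for sample sheet row(s): %s",
                    paste(x$sample_id[missing], collapse = ", ")))
  }
  x
}

#' Run the full synthetic pipeline and write a reproducibility manifest
#'
#' Generates every synthetic input (peak atlas, copy-number tracks,
#' limiting-dilution assay, expression matrix), writes them under
#' `outdir/inputs`, runs each analysis stage (frequency estimation,
#' subclone detection, CORE discovery and predictability ranking,
#' stemness scoring), writes the stage outputs under `outdir/results`,
#' and records a JSON manifest (package version, seed, parameter hash)
#' sufficient to reproduce the outputs byte-for-byte.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Root seed; stages use [child_seed()] offsets.
#' @param atlas_config A [sim_config()]; default plants one
#'   discriminative CORE among five decoys.
#' @param lda_truth True frequency for the simulated assay.
#' @param profile A [cn_profile()] for the copy-number stage.
#' @return Invisibly, a list of the stage results plus the manifest.
#' @export
run_synthetic_pipeline <- function(outdir, seed = 1,
                                   atlas_config = NULL,
                                   lda_truth = 1 / 286.4,
                                   profile = NULL) {
  dir.create(file.path(outdir, "inputs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "results"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(atlas_config))
    atlas_config <- sim_config(seed = child_seed(seed, 1),
                               planted_cores = default_planted_cores())
  if (is.null(profile))
    profile <- cn_profile(start = seq(0, 7) * 5e5,
                          end = seq(1, 8) * 5e5,
                          base_cn = 2,
                          subclone_cn = rep(c(2, 5), 4),
                          phi = 0.3, noise_sd = 0.3)

  ## stage 1: limiting dilution
  assay <- simulate_lda_assay(lda_truth, doses = c(30000, 7500, 1875, 469),
                              mice_per_dose = c(3, 4, 6, 5),
                              seed = child_seed(seed, 2))
  write_assay(assay, file.path(outdir, "inputs", "assay.csv"))
  est <- estimate_frequency(assay)
  utils::write.table(format_frequency_table(est),
                     file.path(outdir, "results", "frequency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 2: copy-number subclone detection
  tracks <- simulate_cn_tracks(profile, seed = child_seed(seed, 3))
  write_cn_track(tracks$reference, file.path(outdir, "inputs", "reference_cn.tsv"))
  write_cn_track(tracks$query, file.path(outdir, "inputs", "query_cn.tsv"))
  segs <- segment_track(tracks$reference)
  comps <- compare_adjacent_segments(project_segments(segs, tracks$query))
  verdict <- detect_subclonal_pattern(comps, reference_pattern(segs))
  utils::write.table(comps[c("pair", "p_value", "stars")],
                     file.path(outdir, "results", "adjacent_segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: CORE discovery
  atlas <- simulate_peak_atlas(atlas_config)
  cores <- lapply(atlas$peaks, call_cores)
  catalog <- build_catalog(cores)
  dm <- detection_matrix(catalog, cores, atlas$groups)
  ranking <- rank_predictability(dm)
  utils::write.table(ranking, file.path(outdir, "results", "core_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: stemness scoring
  sim <- simulate_expression(seed = child_seed(seed, 4))
  write_expression_matrix(sim$expr, file.path(outdir, "inputs", "expression.tsv"))
  scored <- score_hierarchy(sim$expr, sim$fractions, sim$signature,
                            sim$reference)
  utils::write.table(scored$scores,
                     file.path(outdir, "results", "stemness_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "lsctools",
    version = as.character(utils::packageVersion("lsctools")),
    seed = seed,
    parameter_hash = param_hash(list(atlas_config = atlas_config,
                                     lda_truth = lda_truth,
                                     profile = profile)),
    outputs = list(
      frequency_denom = est$denom_hat,
      subclone_verdict = verdict$verdict,
      top_core = ranking$id[1],
      top_core_pc = ranking$pc[1],
      monotone = as.list(scored$monotone)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(frequency = est, comparisons = comps, verdict = verdict,
                 ranking = ranking, scores = scored, manifest = manifest))
}

#' Default planted-CORE layout used by the synthetic pipeline
#'
#' One discriminative CORE (presence 0.75 in LSC+ vs 0.20 in LSC-) and
#' five non-discriminative decoys carried by half of the samples in both
#' groups, spaced well apart along the synthetic chromosome.
#'
#' @param genome_length Genome length the layout must fit in.
#' @return List of [planted_core()] objects.
#' @export
default_planted_cores <- function(genome_length = 2e7) {
  starts <- round(seq(0.1, 0.9, length.out = 6) * genome_length)
  cores <- lapply(starts[-1], function(s)
    planted_core(start = s, presence_prob_pos = 0.5, presence_prob_neg = 0.5))
  c(list(planted_core(start = starts[1])), cores)
}

## md5 of a canonical serialization, for the run manifest
param_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(params, tmp, compress = FALSE, version = 3)
  unname(tools::md5sum(tmp))
}
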