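# lsctools

Quantitative analysis of leukemia stem cell (LSC) driven AML hierarchies.

Acute myeloid leukemia is organized as a cellular hierarchy with
self-renewing LSCs at its apex. Characterizing such a hierarchy requires
several quantitative procedures that are usually scattered across tools:
estimating the frequency of functional stem cells from xenograft
limiting-dilution assays, asking whether a reference clone's copy-number
amplifications are present subclonally in a bulk sample, finding
clusters of cis-regulatory elements (COREs) in chromatin accessibility
data that discriminate LSC-containing from LSC-depleted fractions, and
scoring samples for stemness with published gene signatures. `lsctools`
implements all four stages as tested R functions, together with a
synthetic-data module that generates every input with the statistical
structure the analyses assume — so the full pipeline runs and validates
without access-restricted patient data.

## The models in brief

* **Limiting dilution** — single-hit Poisson model: an animal injected
  with *d* cells engrafts with probability 1 − exp(−*f d*), where *f* is
  the active-cell frequency. `estimate_frequency()` maximizes the
  per-animal Bernoulli likelihood (equivalently a binomial GLM with
  complementary log-log link and log-dose offset) and reports Wald or
  likelihood-ratio bounds on the log scale, as denominators 1/*f*.
* **Subclonal copy number** — reference segments are projected onto a
  query's 1-kb binned track by bin midpoint; adjacent segments are
  compared with Wilcoxon rank-sum tests (exact for ≤ 25 tie-free bins
  per side, corrected normal approximation otherwise); a region is
  called `detected` when at least 75% of directional adjacent pairs are
  significant with the direction the reference's own segment means
  predict. Gains/losses use the conventional 2.5/1.5 thresholds.
* **CORE discovery** — a CORE is a maximal run of peaks whose
  consecutive gaps fall below the lower 5% quantile of an exponential
  null fitted to the sample's own inter-peak gaps. Catalog entries
  (union-merged across samples) are ranked by the predictability
  coefficient PC = (freq₊ + (1 − freq₋))/2, the balanced accuracy of
  "detected ⇒ LSC+".
* **Stemness scoring** — Spearman correlation to an LSC+ reference
  profile (LSC104-style), weighted signature sums (LSC17-style), and a
  rank-based running-sum single-sample enrichment score.

See the methods vignette (`vignettes/lsc-hierarchy-methods.Rmd`) for
assumptions, parameter defaults and design decisions.

## Worked example

Fit the single-hit model to the shipped engraftment table (doses
30,000/7,500/1,875/469 cells with 3/3, 4/4, 6/6 and 4/5 engrafted
animals):

```r
library(lsctools)
assay <- read_assay(system.file("extdata", "table2_assay.csv", package = "lsctools"))
estimate_frequency(assay)
#> Single-hit limiting-dilution frequency estimate
#>   Estimated frequency: 1/286.4
#>   95% interval: 1/803.9 (lower) - 1/102 (upper)
#>   se(log f) = 0.5266 [wald]
```

About one cell in 286 of the assayed fraction is a functional LSC, with
a 95% interval from 1/804 to 1/102 — a very high stem-cell content.

Discover discriminative COREs in a synthetic two-group peak atlas (41
LSC+ vs 52 LSC− samples, one planted discriminative CORE among five
group-balanced decoys on a Poisson background):

```r
cfg   <- sim_config(seed = 1, planted_cores = default_planted_cores())
atlas <- simulate_peak_atlas(cfg)
cores <- lapply(atlas$peaks, call_cores, keep_members = FALSE)
dm    <- detection_matrix(build_catalog(cores), cores, atlas$groups)
head(rank_predictability(dm), 3)
#>                          id chrom    start      end   freq_pos  freq_neg        pc rank
#> 1   CORE-chrS-1997392-2015932  chrS  1997392  2015932 0.80487805 0.1730769 0.8159006    1
#> 2 CORE-chrS-14797558-14815096  chrS 14797558 14815096 0.60975610 0.4807692 0.5644934    2
#> 3   CORE-chrS-7703954-7709472  chrS  7703954  7709472 0.07317073 0.0000000 0.5365854    3
```

The top-ranked entry is the planted discriminative CORE (locus 2.00–2.01
Mb): detected in 80% of LSC+ but only 17% of LSC− samples, giving a
predictability coefficient of 0.82; the decoys and background clusters
sit near the uninformative value 0.5.

`run_synthetic_pipeline(outdir, seed)` chains every stage (assay fit,
subclone detection, CORE ranking, stemness scoring), writes all inputs
and outputs as plain-text files and records a JSON manifest that makes
the run byte-for-byte reproducible.

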