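# zingerscan

Detection of **zinger motifs** in ChIP-seq peak sets: transcription factor
(TF) binding motifs — CTCF-like, ETS-like, JUN-like and THAP11-like — that
are recurrently enriched near peak maxima in datasets where the
corresponding factor was *not* the immunoprecipitation target. Zingers
contaminate motif discovery, binding-site catalogs and regulatory network
inference; this package detects them, maps their enrichment zones,
classifies the affected peaks and characterizes their recurrence
neighborhoods.

## The model

1. **Motif models.** JASPAR-format position frequency matrices are
   converted to log2-odds weight matrices with a `sqrt(N)` pseudocount and
   scored on a 0–100 relative scale. A C++ scanner returns hits above a
   threshold under a greedy overlap-exclusion rule: retained hits may
   overlap by at most `floor(width / 5)` bp, ties broken leftmost.
2. **Over-representation.** Per dataset and motif profile, a one-tailed
   Fisher exact test on motif-containing sequence counts versus a
   GC-matched background, reported as −ln *p* (6.91 ⇔ *p* = 0.001), plus a
   Kolmogorov–Smirnov score on hit distances to the region center. A
   profile is *called* enriched in a TF row when Fisher ≥ mean + 2 SD and
   KS ≥ mean + 1 SD of that row; enriched-dataset counts are corrected for
   motif-family redundancy (raw 20 with 9 same-family datasets keeps 12).
3. **Enrichment zones.** For each 1001 bp peak region the best hit at
   relative score ≥ 70 enters a binding-site landscape; distance
   boundaries come from a 3-bin moving average of 5 bp bins above the
   175–500 bp distal baseline, and a score threshold from the smallest
   integer at which in-zone hit density is ≥ 1.2× the flanking density
   (defaults ±90 bp / 82).
4. **Peak classification.** Peaks with the ChIPped TF's motif in zone are
   `CHIPPED`; otherwise an in-zone zinger motif makes them `ZINGER`; the
   rest are `UNIDENTIFIED`. Fractions are corrected against a matched
   distal control zone.
5. **Recurrence neighborhoods.** Peak maxima pooled across datasets are
   single-linkage merged at ≤ 50 bp, de-classed by 300 bp overlap removal,
   and tested for cohesin-track proximity (Fisher, 500 bp window).
6. **Shuffled-matrix null.** Internal PFM columns are permuted, the corpus
   rescored against the original call thresholds, and the null
   enriched-TF counts modeled with a zero-adjusted logarithmic
   distribution (ZALG) whose upper tail calibrates the observed count.

Because the package ships no genomic data, a deterministic synthetic
generator provides the study conditions: 10 TFs × 2 cell lines × 5,000
peaks, 55% planted ChIPped motifs and 12% zingers (5/3/2/2%) within
±90 bp at relative score ≥ 85, a 2,000-region shared zinger pool
(sharing rate 0.5, ±20 bp jitter), and cohesin placed near 77% of shared
regions versus 13% of background.

## Worked example

A small corpus runs in seconds:

```r
library(zingerscan)
cfg <- defaultSimConfig(tfs = c("TFA", "TFB"), cellLines = "cellA",
                        nPeaks = 600L)
res <- runPipeline(cfg, seed = 42)
res$composition        # corrected chipped/zinger fractions per dataset
res$recurrence         # neighborhood counts and multi-TF fractions
res$proximity$zinger_vs_chipped[c("frac_a", "frac_b", "p")]
```

At the full default scale (`runPipeline(defaultSimConfig(), seed = 1)`,
~3 minutes) the pipeline recovers the planted structure:

- corrected chipped fraction: mean **0.551** across the 20 datasets
  (range 0.548–0.554; planted 0.55)
- corrected zinger fraction: mean **0.111** (range 0.099–0.121;
  planted 0.12) — every dataset within ±0.03 of the planted rates
- zinger neighborhoods recur across more TFs than chipped ones
  (multi-TF fraction 0.204 vs 0.044; rank-sum p < 1e-300)
- cohesin proximity: 29.9% of zinger vs 11.6% of chipped neighborhoods
  (Fisher p ≈ 1.8e-297), rising to 80.2% for multi-TF zinger
  neighborhoods — recovering the planted 77%/13% contrast

## Reproduction

The acceptance script runs the full pipeline, a 20-configuration
enrichment-zone recovery experiment, a reduced over-representation
analysis, and the shuffled-matrix/ZALG null, writing all main computed
quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`, so repeated runs with the same
seed reproduce the same results. See `vignettes/zinger-detection.Rmd` for the methods
narrative, design notes and known limitations.
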