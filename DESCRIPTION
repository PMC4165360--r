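Package: zingerscan
Title: Detection of Recurrently Enriched Non-Targeted Motifs in ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterize 'zinger' motifs: transcription
    factor binding motifs (CTCF-like, ETS-like, JUN-like, THAP11) that are
    recurrently enriched near ChIP-seq peak maxima in datasets where the
    corresponding factor was not the immunoprecipitation target. The package
    provides position frequency matrix parsing and log-odds scanning with an
    overlap-exclusion rule, per-dataset motif over-representation scoring
    (Fisher-log and Kolmogorov-Smirnov centrality scores with standard
    deviation based enrichment calls and motif-family correction), heuristic
    enrichment-zone determination from binding-site landscapes, peak
    classification and co-occurrence testing, single-linkage merging of peak
    maxima into recurrence neighborhoods with proximity tests against
    cohesin/polycomb tracks, a column-shuffled matrix null calibrated with a
    zero-adjusted logarithmic distribution, and a deterministic synthetic-data
    generator so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
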