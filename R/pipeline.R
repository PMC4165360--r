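#' Landscapes, zones, composition and classification for one dataset
#'
#' Builds the 1001 bp binding-site landscape of the ChIPped TF's profile and
#' of every zinger profile, derives each profile's enrichment zone, and
#' returns the dataset's motif composition and per-peak classification.
#'
#' @param dataset One element of `generateCorpus()$datasets` (or any list
#'   with `sequences` and `peaks`).
#' @param pfms Named list of [PFM]s.
#' @param zingers Zinger profile names (default [zingerNames()]).
#' @param floorScore Landscape floor score (default 70).
#' @return A list with `landscapes`, `zones`, `composition`, `classified`.
#' @export
analyzeDataset <- function(dataset, pfms, zingers = zingerNames(),
                           floorScore = 70) {
  tf <- dataset$peaks$tf[1L]
  seqs <- as.character(dataset$sequences)
  profiles <- unique(c(tf, zingers))
  landscapes <- lapply(profiles, function(p) {
    buildLandscape(seqs, pfmToPwm(pfms[[p]]), floorScore,
                   peakIds = dataset$peaks$peak_id)
  })
  names(landscapes) <- profiles
  zones <- lapply(landscapes, enrichmentZone)
  zl <- landscapes[zingers]
  zz <- zones[zingers]
  comp <- peakComposition(landscapes[[tf]], zl, zones[[tf]], zz)
  cls <- classifyPeaks(landscapes[[tf]], zl, zones[[tf]], zz)
  list(tf = tf, landscapes = landscapes, zones = zones, composition = comp,
       classified = cls)
}

#' Pool classified peaks across datasets into the three neighborhood sets
#'
#' Zinger motif peaks require a zone zinger motif with relative score above
#' `minScore`; ChIPped-TF peaks require a zone ChIPped motif above
#' `minScore` and no zone zinger motif; unidentified peaks have neither
#' motif.
#'
#' @param corpus From [generateCorpus()].
#' @param analyses Named list of [analyzeDataset()] results, parallel to
#'   `corpus$datasets`.
#' @param minScore Strong-motif threshold (default 85).
#' @return A list of data.frames `zinger`, `chipped`, `unidentified` with
#'   columns `chrom`, `peakMax`, `tf`, `cell_line`, `peak_id`, `score`.
#' @export
poolClassifiedPeaks <- function(corpus, analyses, minScore = 85) {
  pools <- list(zinger = list(), chipped = list(), unidentified = list())
  for (nm in names(corpus$datasets)) {
    d <- corpus$datasets[[nm]]
    a <- analyses[[nm]]
    cl <- a$classified
    zingers <- zingerNames()
    strongZinger <- Reduce(`|`, lapply(zingers, function(z) {
      cl[[paste0("in_zone_", z)]] & !is.na(cl[[paste0("score_", z)]]) &
        cl[[paste0("score_", z)]] > minScore
    }))
    anyZoneZinger <- Reduce(`|`, lapply(zingers, function(z)
      cl[[paste0("in_zone_", z)]]))
    chipL <- a$landscapes[[a$tf]]
    strongChip <- cl$class == "CHIPPED" & !is.na(chipL$rel_score) &
      chipL$rel_score > minScore
    sel <- list(
      zinger = cl$class == "ZINGER" & strongZinger,
      chipped = strongChip & !anyZoneZinger,
      unidentified = cl$class == "UNIDENTIFIED")
    for (k in names(sel)) {
      pools[[k]][[nm]] <- d$peaks[sel[[k]],
        c("chrom", "peakMax", "tf", "cell_line", "peak_id", "score")]
    }
  }
  lapply(pools, function(x) do.call(rbind, c(x, make.row.names = FALSE)))
}

#' Build the 401 bp over-representation corpus
#'
#' Trims each dataset's regions to 401 bp around the peak maximum and
#' generates a GC-matched background set of equal size per dataset.
#'
#' @param corpus From [generateCorpus()].
#' @param length Analysis length (default 401).
#' @param seed Seed for background generation.
#' @return A list (one element per dataset) with `tf`, `target`,
#'   `background`.
#' @export
buildEnrichmentCorpus <- function(corpus, length = 401L, seed = 1) {
  out <- lapply(seq_along(corpus$datasets), function(i) {
    d <- corpus$datasets[[i]]
    target <- trimSequences(d$sequences, length)
    list(tf = d$peaks$tf[1L], target = target,
         background = generateBackgroundSet(target, seed = seed + i))
  })
  names(out) <- names(corpus$datasets)
  out
}

#' Over-representation analysis of a profile set across a corpus
#'
#' Computes per-dataset Fisher-log and KS centrality scores for every
#' profile, caps infinite scores, averages per ChIPped TF, and derives the
#' SD-based enrichment calls, per-profile family-corrected dataset counts,
#' and the per-TF row thresholds reused by the shuffled-matrix null.
#'
#' @param ecorpus From [buildEnrichmentCorpus()].
#' @param pfms Named list of [PFM]s (the profiles to test).
#' @param familyMap Passed to [profileDatasetCounts()].
#' @param scanThreshold Relative-score scan threshold (default 85).
#' @return A list with `scores` (per dataset x profile), `perTf`, `calls`,
#'   `counts`, `thresholds`.
#' @export
overrepresentationAnalysis <- function(ecorpus, pfms,
                                       familyMap = character(),
                                       scanThreshold = 85) {
  pwms <- lapply(pfms, pfmToPwm)
  rows <- list()
  for (nm in names(ecorpus)) {
    d <- ecorpus[[nm]]
    for (p in names(pwms)) {
      sc <- enrichmentScores(pwms[[p]], d$target, d$background,
                             scanThreshold)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = nm, tf = d$tf, profile_id = p,
        fisher_log = sc$fisher_log, ks_log = sc$ks_log)
    }
  }
  scores <- do.call(rbind, rows)
  scores$fisher_log <- capInfinite(scores$fisher_log, "fisher")
  scores$ks_log <- capInfinite(scores$ks_log, "ks")
  perTf <- aggregateByTF(scores)
  calls <- enrichmentCalls(perTf)
  list(scores = scores, perTf = perTf, calls = calls,
       counts = profileDatasetCounts(calls, familyMap),
       thresholds = rowThresholds(perTf))
}

#' Run the zinger-detection pipeline on a synthetic corpus
#'
#' Generates a corpus, analyzes every dataset (landscapes, enrichment
#' zones, composition, classification), pools the classified peaks, merges
#' them into neighborhoods, de-overlaps the ChIPped-TF neighborhoods, and
#' tests neighborhood proximity to the cohesin and polycomb tracks.
#'
#' @param config From [defaultSimConfig()].
#' @param seed Integer seed driving every stage (mandatory).
#' @return A list bundle with `corpus`, `analyses`, `composition` (per
#'   dataset raw/corrected fractions), `pools`, `neighborhoods`,
#'   `recurrence`, `multiTfTest`, `proximity` and `seed`.
#' @export
runPipeline <- function(config = defaultSimConfig(), seed) {
  stopifnot(!is.null(seed))
  corpus <- generateCorpus(config, seed)
  pfms <- zingerProfiles()
  analyses <- lapply(corpus$datasets, analyzeDataset, pfms = pfms)
  composition <- do.call(rbind, lapply(names(analyses), function(nm) {
    comp <- analyses[[nm]]$composition
    data.frame(dataset_id = nm, tf = analyses[[nm]]$tf,
               raw_chipped = comp$raw["chipped"],
               raw_zinger = comp$raw["zinger"],
               raw_unidentified = comp$raw["unidentified"],
               corrected_chipped = comp$corrected["chipped"],
               corrected_zinger = comp$corrected["zinger"],
               row.names = NULL)
  }))
  pools <- poolClassifiedPeaks(corpus, analyses)
  nb <- list(
    zinger = mergeNeighborhoods(pools$zinger, class = "ZINGER"),
    chipped = mergeNeighborhoods(pools$chipped, class = "CHIPPED_TF"),
    unidentified = mergeNeighborhoods(pools$unidentified,
                                      class = "UNIDENTIFIED"))
  nb$chipped <- declassOverlaps(nb$chipped, nb$zinger, nb$unidentified)
  recurrence <- do.call(rbind, lapply(nb, recurrenceSummary))
  recurrence$class <- names(nb)
  multiTf <- comparePeakScores(nb$chipped$n_unique_tfs,
                               nb$zinger$n_unique_tfs)
  track <- corpus$tracks$cohesin
  names(track) <- c("chrom", "pos")
  zMulti <- nb$zinger[nb$zinger$n_unique_tfs >= 2L, ]
  proximity <- list(
    zinger_vs_chipped = proximityTest(nb$zinger, nb$chipped, track),
    multiTf_zinger_vs_chipped = proximityTest(zMulti, nb$chipped, track),
    unidentified_vs_chipped = proximityTest(nb$unidentified, nb$chipped,
                                            track))
  list(corpus = corpus, analyses = analyses, composition = composition,
       pools = pools, neighborhoods = nb, recurrence = recurrence,
       multiTfTest = multiTf, proximity = proximity, seed = seed)
}
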