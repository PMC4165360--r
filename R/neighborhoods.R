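#' Merge peak maxima into recurrence neighborhoods
#'
#' Peaks pooled across datasets are sorted by position per chromosome and
#' consecutive peak maxima within `mergeBp` of their nearest neighbor are
#' chained into a single neighborhood (single linkage, so a neighborhood can
#' grow wider than `mergeBp`). Each neighborhood records its member peaks
#' and the number of unique contributing TFs and cell lines.
#'
#' @param peaks data.frame with columns `chrom`, `peakMax`, `tf`,
#'   `cell_line` (and optionally `dataset_id`, `peak_id`).
#' @param mergeBp Maximum gap between consecutive peak maxima (default 50).
#' @param class Optional class label attached to every neighborhood.
#' @return A data.frame with one row per neighborhood: `chrom`, `start`,
#'   `end` (envelope of member peak maxima), `center`, `width`, `n_peaks`,
#'   `n_unique_tfs`, `n_unique_cell_lines`, `class`, and a list-column
#'   `members` of member row indices into `peaks`.
#' @export
mergeNeighborhoods <- function(peaks, mergeBp = 50, class = NA_character_) {
  stopifnot(all(c("chrom", "peakMax", "tf", "cell_line") %in% names(peaks)))
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), center = numeric(), width = numeric(),
                      n_peaks = integer(), n_unique_tfs = integer(),
                      n_unique_cell_lines = integer(), class = character()))
  }
  ord <- order(peaks$chrom, peaks$peakMax)
  ch <- peaks$chrom[ord]
  pos <- peaks$peakMax[ord]
  newGroup <- c(TRUE, ch[-1L] != ch[-length(ch)] | diff(pos) > mergeBp)
  grp <- cumsum(newGroup)
  idx <- split(ord, grp)
  out <- data.frame(
    chrom = vapply(idx, function(i) peaks$chrom[i[1L]], character(1)),
    start = vapply(idx, function(i) min(peaks$peakMax[i]), numeric(1)),
    end = vapply(idx, function(i) max(peaks$peakMax[i]), numeric(1)),
    n_peaks = lengths(idx),
    n_unique_tfs = vapply(idx, function(i)
      length(unique(peaks$tf[i])), integer(1)),
    n_unique_cell_lines = vapply(idx, function(i)
      length(unique(peaks$cell_line[i])), integer(1)),
    class = class,
    row.names = NULL
  )
  out$center <- (out$start + out$end) / 2
  out$width <- out$end - out$start
  out$members <- unname(idx)
  out[, c("chrom", "start", "end", "center", "width", "n_peaks",
          "n_unique_tfs", "n_unique_cell_lines", "class", "members")]
}

#' Recurrence summary of a neighborhood set
#'
#' @param nbhds Output of [mergeNeighborhoods()].
#' @return A one-row data.frame: number of neighborhoods, number and
#'   fraction with two or more unique TFs, mean width, fraction of multi-TF
#'   neighborhoods spanning two or more cell lines, and total bp covered by
#'   multi-TF neighborhoods.
#' @export
recurrenceSummary <- function(nbhds) {
  multi <- nbhds$n_unique_tfs >= 2L
  data.frame(
    n_neighborhoods = nrow(nbhds),
    n_multi_tf = sum(multi),
    frac_multi_tf = if (nrow(nbhds)) mean(multi) else NA_real_,
    mean_width = if (nrow(nbhds)) mean(nbhds$width) else NA_real_,
    mean_width_multi_tf = if (any(multi)) mean(nbhds$width[multi])
      else NA_real_,
    frac_multi_cell_line = if (any(multi))
      mean(nbhds$n_unique_cell_lines[multi] >= 2L) else NA_real_,
    total_bp_multi_tf = sum(nbhds$width[multi])
  )
}

#' Remove ChIPped-TF neighborhoods near other neighborhood classes
#'
#' ChIPped-TF neighborhoods whose center lies within `exclusionBp` (center
#' to center) of any zinger or unidentified neighborhood are removed, so
#' that class comparisons are made between distinct genomic region sets.
#'
#' @param chipped,zinger,unidentified Neighborhood data.frames.
#' @param exclusionBp Center-to-center exclusion distance (default 300).
#' @return The filtered `chipped` data.frame.
#' @export
declassOverlaps <- function(chipped, zinger, unidentified,
                            exclusionBp = 300) {
  refChrom <- c(zinger$chrom, unidentified$chrom)
  refPos <- c(zinger$center, unidentified$center)
  if (length(refPos) == 0L || nrow(chipped) == 0L) return(chipped)
  d <- .nearestDistance(chipped$chrom, chipped$center, refChrom, refPos)
  chipped[d > exclusionBp, , drop = FALSE]
}

#' Proximity of two neighborhood sets to a genomic track
#'
#' Computes, per neighborhood set, the fraction of neighborhoods whose
#' center lies within `window` bp of a track reference point (e.g. a
#' cohesin ChIP-seq peak maximum), and compares the proximal/distal counts
#' of the two sets with a one-tailed Fisher exact test (alternative: set A
#' more proximal).
#'
#' @param nbhdsA,nbhdsB Neighborhood data.frames.
#' @param track data.frame with `chrom` and `pos` reference points.
#' @param window Proximity window in bp (default 500).
#' @return A list with `frac_a`, `frac_b`, `p`, and the 2x2 count table.
#' @export
proximityTest <- function(nbhdsA, nbhdsB, track, window = 500) {
  stopifnot(nrow(track) > 0L)
  proxOf <- function(nb) {
    if (nrow(nb) == 0L) return(logical())
    .nearestDistance(nb$chrom, nb$center, track$chrom, track$pos) <= window
  }
  pa <- proxOf(nbhdsA)
  pb <- proxOf(nbhdsB)
  tab <- matrix(c(sum(pa), sum(!pa), sum(pb), sum(!pb)), 2L, 2L,
                byrow = TRUE,
                dimnames = list(c("A", "B"), c("proximal", "distal")))
  p <- if (length(pa) && length(pb))
    stats::fisher.test(tab, alternative = "greater")$p.value else NA_real_
  list(frac_a = if (length(pa)) mean(pa) else NA_real_,
       frac_b = if (length(pb)) mean(pb) else NA_real_,
       p = p, table = tab)
}

#' Screen genomic features for consistent zinger proximity differences
#'
#' Per dataset and feature track, compares the counts of zinger motif peaks
#' and ChIPped-TF peaks lying within the feature's window of a reference
#' point (Fisher exact test). Only datasets with at least `minZingerPeaks`
#' zinger motif peaks are eligible. A feature receives a directional verdict
#' ("proximal" or "distal") only when at least `directionRule` of the
#' eligible datasets are significant in that same direction.
#'
#' @param datasets A list; each element a list with `zinger` and `chipped`
#'   data.frames (columns `chrom`, `peakMax`).
#' @param tracks Named list of data.frames with `chrom`, `pos`.
#' @param windows Named numeric vector of window sizes per track; tracks
#'   without an entry use 500 bp.
#' @param minZingerPeaks Eligibility threshold (default 200).
#' @param directionRule Required fraction of agreeing significant datasets
#'   (default 0.60).
#' @param alpha Per-test significance level (default 0.05).
#' @return A data.frame with one row per feature: counts of eligible,
#'   significant-proximal and significant-distal datasets, and the verdict.
#' @export
featureProximityScreen <- function(datasets, tracks, windows = numeric(),
                                   minZingerPeaks = 200,
                                   directionRule = 0.60, alpha = 0.05) {
  eligible <- Filter(function(d) nrow(d$zinger) >= minZingerPeaks, datasets)
  out <- lapply(names(tracks), function(feat) {
    w <- if (feat %in% names(windows)) windows[[feat]] else 500
    tr <- tracks[[feat]]
    sigProx <- 0L
    sigDist <- 0L
    for (d in eligible) {
      za <- .nearestDistance(d$zinger$chrom, d$zinger$peakMax,
                             tr$chrom, tr$pos) <= w
      ca <- .nearestDistance(d$chipped$chrom, d$chipped$peakMax,
                             tr$chrom, tr$pos) <= w
      tab <- matrix(c(sum(za), sum(!za), sum(ca), sum(!ca)), 2L, 2L,
                    byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      if (p < alpha) {
        if (mean(za) > mean(ca)) sigProx <- sigProx + 1L
        else sigDist <- sigDist + 1L
      }
    }
    nEl <- length(eligible)
    verdict <- "none"
    if (nEl > 0L) {
      if (sigProx / nEl >= directionRule) verdict <- "proximal"
      else if (sigDist / nEl >= directionRule) verdict <- "distal"
    }
    data.frame(feature = feat, window = w, n_eligible = nEl,
               n_sig_proximal = sigProx, n_sig_distal = sigDist,
               verdict = verdict)
  })
  do.call(rbind, out)
}
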