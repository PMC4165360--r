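#' Classify peaks by ChIPped-TF and zinger motif content
#'
#' Labels every peak of a dataset as `CHIPPED` (ChIPped TF's motif in its
#' enrichment zone), `ZINGER` (no ChIPped motif, but at least one zinger
#' motif in that zinger's zone), or `UNIDENTIFIED`, and records per-zinger
#' zone flags and best scores for downstream co-occurrence and recurrence
#' analyses.
#'
#' @inheritParams peakComposition
#' @return A data.frame with `peak_id`, `class`, and per-zinger columns
#'   `in_zone_<name>` (logical) and `score_<name>` (top-hit relative score,
#'   `NA` when the peak has no hit for that profile).
#' @export
classifyPeaks <- function(chippedLandscape, zingerLandscapes, chippedZone,
                          zingerZones) {
  comp <- peakComposition(chippedLandscape, zingerLandscapes, chippedZone,
                          zingerZones)
  out <- data.frame(peak_id = zingerLandscapes[[1L]]$peak_id,
                    class = comp$class)
  for (z in names(zingerLandscapes)) {
    out[[paste0("in_zone_", z)]] <-
      inEnrichmentZone(zingerLandscapes[[z]], zingerZones[[z]])
    out[[paste0("score_", z)]] <- zingerLandscapes[[z]]$rel_score
  }
  out
}

#' Pairwise co-occurrence of two zinger motifs within zinger motif peaks
#'
#' Among the zinger motif peaks of a dataset, presence of each zinger is
#' defined as a zone motif with relative score >= 85. The 2x2 presence table
#' is tested with a two-sided Fisher exact test; the log odds ratio (with a
#' Haldane 0.5 correction when any cell is zero) gives the direction. The
#' heatmap encoding is `1 - p` for significant positive associations
#' (p < 0.001, log odds > 0), `-(1 - p)` for significant negative ones, and
#' 0 otherwise.
#'
#' @param classified Output of [classifyPeaks()].
#' @param zingerA,zingerB Names of two zingers (as in the classification
#'   columns).
#' @param minScore Presence score threshold (default 85).
#' @param alpha Significance level for the heatmap encoding (default 0.001).
#' @return A list with `table`, `fisher_p`, `log_odds`, `heatmap_value`,
#'   and `degenerate` (TRUE when a zinger is absent from all peaks).
#' @export
cooccurrenceTest <- function(classified, zingerA, zingerB, minScore = 85,
                             alpha = 0.001) {
  zp <- classified[classified$class == "ZINGER", , drop = FALSE]
  if (nrow(zp) == 0L) stop("no zinger motif peaks in this dataset")
  pres <- function(z) {
    zp[[paste0("in_zone_", z)]] &
      !is.na(zp[[paste0("score_", z)]]) &
      zp[[paste0("score_", z)]] >= minScore
  }
  a <- pres(zingerA)
  b <- pres(zingerB)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("A+", "A-"), c("B+", "B-")))
  degenerate <- all(!a) || all(!b) || all(a) || all(b)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  cells <- as.numeric(tab)
  if (any(cells == 0)) cells <- cells + 0.5
  logOdds <- log((cells[1L] * cells[4L]) / (cells[2L] * cells[3L]))
  hv <- 0
  if (!degenerate && p < alpha) hv <- if (logOdds > 0) 1 - p else -(1 - p)
  list(table = tab, fisher_p = p, log_odds = logOdds, heatmap_value = hv,
       degenerate = degenerate)
}

# Distance from each query position to the nearest reference position on the
# same chromosome (Inf when the chromosome has no reference positions).
.nearestDistance <- function(queryChrom, queryPos, refChrom, refPos) {
  out <- rep(Inf, length(queryPos))
  for (ch in unique(queryChrom)) {
    qi <- which(queryChrom == ch)
    rp <- sort(refPos[refChrom == ch])
    if (length(rp) == 0L) next
    idx <- findInterval(queryPos[qi], rp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(rp))
    out[qi] <- pmin(abs(queryPos[qi] - rp[lo]), abs(queryPos[qi] - rp[hi]))
  }
  out
}

#' Agreement of zinger motif peaks with ChIP-seq for the zinger TF
#'
#' For zinger motif peaks (strong zone motif, score > 85) and the matched
#' distal-zinger control peaks (same score range, motif outside the zone) in
#' a dataset, computes the fraction of each group whose peak maximum lies
#' within `window` bp of a peak maximum in a dataset ChIPped for the zinger
#' TF itself (same cell line), and compares the two groups' nearest-peakMax
#' distances with a one-tailed rank-sum test (zinger group expected closer).
#'
#' @param zingerPeaks,distalPeaks data.frames with `chrom` and `peakMax`
#'   columns for the two groups.
#' @param zingerTfPeaks data.frame with `chrom` and `peakMax` for the zinger
#'   TF's own ChIP-seq dataset.
#' @param window Agreement distance in bp (default 100).
#' @return A list with `frac_zinger`, `frac_distal`, `p` (one-tailed
#'   rank-sum; `NA` when undefined) and the nearest-distance vectors.
#' @export
overlapWithZingerChip <- function(zingerPeaks, distalPeaks, zingerTfPeaks,
                                  window = 100) {
  if (nrow(zingerTfPeaks) == 0L) {
    return(list(frac_zinger = 0, frac_distal = 0, p = NA_real_,
                dist_zinger = numeric(), dist_distal = numeric()))
  }
  dz <- .nearestDistance(zingerPeaks$chrom, zingerPeaks$peakMax,
                         zingerTfPeaks$chrom, zingerTfPeaks$peakMax)
  dd <- .nearestDistance(distalPeaks$chrom, distalPeaks$peakMax,
                         zingerTfPeaks$chrom, zingerTfPeaks$peakMax)
  p <- if (length(dz) && length(dd))
    comparePeakScores(dz, dd)$p else NA_real_
  list(frac_zinger = mean(dz <= window), frac_distal = mean(dd <= window),
       p = p, dist_zinger = dz, dist_distal = dd)
}

#' One-tailed rank-sum comparison of two score groups
#'
#' Two-sample Wilcoxon rank-sum test of the hypothesis that group A's values
#' are stochastically smaller than group B's (used e.g. to show that zinger
#' motif peaks have poorer peak-calling scores than peaks with the ChIPped
#' TF's motif). Exact for small samples without ties, normal approximation
#' with continuity correction otherwise. Fully tied inputs return p = 0.5 by
#' convention, flagged.
#'
#' @param groupA,groupB Numeric vectors.
#' @return A list with `p`, `statistic` and `all_tied`.
#' @export
comparePeakScores <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0L, length(groupB) > 0L)
  if (length(unique(c(groupA, groupB))) == 1L) {
    return(list(p = 0.5, statistic = NA_real_, all_tied = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(groupA, groupB, alternative = "less", correct = TRUE)
  )
  list(p = wt$p.value, statistic = unname(wt$statistic), all_tied = FALSE)
}
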