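LANDSCAPE_LEN <- 1001L
LANDSCAPE_CENTER <- 500L  # 0-based index of the "501st bp"

#' Build a binding-site landscape
#'
#' For each 1001 bp peak region (peak maximum at the 501st bp) the single
#' top-scoring motif window at or above `floorScore` is recorded, with its
#' signed distance from the peak maximum (motif midpoint minus peakMax
#' position; ties on score resolved toward the window closest to the peak
#' maximum). Peaks with no qualifying window are recorded as motif-less.
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet] of
#'   1001 bp regions.
#' @param pwm A [PWM].
#' @param floorScore Minimum relative score for a window to be considered
#'   (default 70).
#' @param peakIds Optional identifiers (default sequence index).
#' @return A data.frame with one row per peak: `peak_id`, `has_hit`,
#'   `signed_distance`, `rel_score`, `strand`.
#' @export
buildLandscape <- function(sequences, pwm, floorScore = 70, peakIds = NULL) {
  stopifnot(is(pwm, "PWM"))
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  if (any(nchar(sequences) != LANDSCAPE_LEN))
    stop("all landscape regions must be exactly ", LANDSCAPE_LEN, " bp")
  if (is.null(peakIds)) peakIds <- seq_along(sequences)
  h <- cpp_top_hits(sequences, weightMatrix(pwm), minScore(pwm),
                    maxScore(pwm), floorScore, LANDSCAPE_CENTER)
  midOff <- (motifWidth(pwm) - 1L) %/% 2L
  data.frame(peak_id = peakIds, has_hit = h$has_hit,
             signed_distance = h$start + midOff - LANDSCAPE_CENTER,
             rel_score = h$rel_score, strand = h$strand)
}

#' Positional density of landscape top hits
#'
#' Counts landscape top hits in 5 bp bins of signed distance to the peak
#' maximum, over [-500, +500].
#'
#' @param landscape Output of [buildLandscape()].
#' @param binBp Bin width in bp (default 5).
#' @return A data.frame with `center` (bin center, bp) and `count`; the
#'   counts sum to the number of peaks with a hit.
#' @export
positionalDensity <- function(landscape, binBp = 5) {
  d <- landscape$signed_distance[landscape$has_hit]
  centers <- seq(-LANDSCAPE_CENTER, LANDSCAPE_CENTER, by = binBp)
  idx <- round(d / binBp) * binBp
  idx <- pmax(pmin(idx, LANDSCAPE_CENTER), -LANDSCAPE_CENTER)
  counts <- table(factor(idx, levels = centers))
  data.frame(center = centers, count = as.integer(counts))
}

#' Heuristic distance boundaries of motif enrichment
#'
#' Per side of the peak maximum, the baseline is the mean bin count over the
#' distal range (175-500 bp by default). Scanning outward from the peak
#' maximum, the boundary is the outermost bin of the maximal contiguous run
#' of bins whose 3-bin moving average exceeds the baseline. When no run
#' exists on a side, the documented default of 90 bp is used and the side is
#' flagged as not found.
#'
#' @param density Output of [positionalDensity()] (5 bp bins).
#' @param distalRange Absolute distance range defining the baseline
#'   (default `c(175, 500)`).
#' @param defaultBp Fallback boundary (default 90 bp).
#' @return A list with `left`, `right` (bp, signed), and `found` (logical,
#'   length 2: left/right run located).
#' @export
findDistanceBoundaries <- function(density, distalRange = c(175, 500),
                                   defaultBp = 90) {
  centers <- density$center
  counts <- density$count
  n <- length(counts)
  ma <- counts
  if (n >= 3L) {
    inner <- 2:(n - 1L)
    ma[inner] <- (counts[inner - 1L] + counts[inner] + counts[inner + 1L]) / 3
  }
  side <- function(sign) {
    distal <- centers * sign >= distalRange[1L] &
      centers * sign <= distalRange[2L]
    baseline <- mean(counts[distal])
    ord <- order(centers * sign)
    sel <- ord[centers[ord] * sign >= 0]  # bins from 0 outward
    run <- 0L
    for (i in sel) {
      if (ma[i] > baseline) run <- run + 1L else break
    }
    if (run == 0L) list(bp = sign * defaultBp, found = FALSE)
    else list(bp = max(abs(centers[sel[run]]), 5) * sign, found = TRUE)
  }
  l <- side(-1)
  r <- side(1)
  list(left = l$bp, right = r$bp, found = c(left = l$found, right = r$found))
}

#' Heuristic motif score threshold
#'
#' The smallest integer score `s` in `[70, 100]` such that the per-bp
#' frequency of landscape hits with relative score at least `s` inside the
#' distance boundaries is at least `ratio` times the per-bp frequency in the
#' distal flanks (175-500 bp on both sides), requiring at least one hit
#' inside the boundaries.
#'
#' @param landscape Output of [buildLandscape()].
#' @param boundaries List with `left` and `right` (bp), e.g. from
#'   [findDistanceBoundaries()].
#' @param ratio Required proximal/flank enrichment ratio (default 1.2, i.e.
#'   20\% above the flanking frequency).
#' @param distalRange Flank range in bp (default `c(175, 500)`).
#' @param scoreRange Candidate integer thresholds (default `70:100`).
#' @return The threshold, or `NA` when no score qualifies.
#' @export
findScoreThreshold <- function(landscape, boundaries, ratio = 1.2,
                               distalRange = c(175, 500),
                               scoreRange = 70:100) {
  d <- landscape$signed_distance[landscape$has_hit]
  s <- landscape$rel_score[landscape$has_hit]
  inZone <- d >= boundaries$left & d <= boundaries$right
  inFlank <- abs(d) >= distalRange[1L] & abs(d) <= distalRange[2L]
  zoneW <- boundaries$right - boundaries$left + 1
  flankW <- 2 * (distalRange[2L] - distalRange[1L] + 1)
  for (thr in sort(scoreRange)) {
    nIn <- sum(inZone & s >= thr)
    nFl <- sum(inFlank & s >= thr)
    if (nIn > 0 && nIn / zoneW >= ratio * nFl / flankW) return(thr)
  }
  NA_real_
}

#' Determine the enrichment zone of a profile in a dataset
#'
#' Combines [findDistanceBoundaries()] and [findScoreThreshold()];
#' components the heuristic cannot locate fall back to the documented
#' defaults of +/-90 bp and a relative score threshold of 82.
#'
#' @param landscape Output of [buildLandscape()].
#' @param ratio,distalRange Passed to the component heuristics.
#' @param defaultBoundary,defaultThreshold Fallback values (90 bp, 82).
#' @return An [EnrichmentZone].
#' @export
enrichmentZone <- function(landscape, ratio = 1.2, distalRange = c(175, 500),
                           defaultBoundary = 90, defaultThreshold = 82) {
  dens <- positionalDensity(landscape)
  b <- findDistanceBoundaries(dens, distalRange, defaultBp = defaultBoundary)
  thr <- findScoreThreshold(landscape, b, ratio, distalRange)
  thrFound <- !is.na(thr)
  if (!thrFound) thr <- defaultThreshold
  new("EnrichmentZone", left = b$left, right = b$right, scoreThreshold = thr,
      boundariesFound = all(b$found), thresholdFound = thrFound)
}

#' Which peaks have their top motif inside an enrichment zone?
#'
#' @param landscape Output of [buildLandscape()].
#' @param zone An [EnrichmentZone].
#' @param minScore Optional additional score floor (e.g. 85 for the
#'   strong-motif convention); the zone's own threshold always applies.
#' @return Logical vector, one element per peak.
#' @export
inEnrichmentZone <- function(landscape, zone, minScore = NULL) {
  thr <- zoneThreshold(zone)
  if (!is.null(minScore)) thr <- max(thr, minScore)
  landscape$has_hit &
    !is.na(landscape$signed_distance) &
    landscape$signed_distance >= zone@left &
    landscape$signed_distance <= zone@right &
    landscape$rel_score >= thr
}

# Count peaks (restricted to `subset`) whose top hit clears the zone
# threshold and lies (a) inside the zone, (b) inside the matched distal
# control zone: two windows of half the zone width each, placed at least
# 50 bp outside the zone boundaries (shifted inward at the region edge so
# the control width always equals the zone width).
.zoneAndDistalCounts <- function(landscape, zone, subset = NULL,
                                 clearance = 50) {
  if (is.null(subset)) subset <- rep(TRUE, nrow(landscape))
  l <- landscape[subset & landscape$has_hit, , drop = FALSE]
  ok <- l$rel_score >= zoneThreshold(zone)
  d <- l$signed_distance
  W <- zone@right - zone@left + 1
  wl <- floor(W / 2)
  wr <- W - wl
  leftHi <- zone@left - clearance - 1
  leftLo <- max(-LANDSCAPE_CENTER, leftHi - wl + 1)
  leftHi <- leftLo + wl - 1
  rightLo <- zone@right + clearance + 1
  rightHi <- min(LANDSCAPE_CENTER, rightLo + wr - 1)
  rightLo <- rightHi - wr + 1
  inDistal <- (d >= leftLo & d <= leftHi) | (d >= rightLo & d <= rightHi)
  inZ <- d >= zone@left & d <= zone@right
  list(zone = sum(ok & inZ), distal = sum(ok & inDistal))
}

#' Background-corrected motif fraction
#'
#' The distal control zone carries the background expectation of motif
#' prediction; the corrected fraction of peaks attributable to genuine
#' proximal motifs is `max(0, zoneCount - distalCount) / nPeaks`.
#'
#' @param zoneCount,distalCount Peaks with a qualifying motif in the
#'   enrichment zone / matched distal zone.
#' @param nPeaks Dataset size.
#' @return The corrected fraction.
#' @examples
#' correctedFraction(300, 100, 1000)  # 0.2
#' @export
correctedFraction <- function(zoneCount, distalCount, nPeaks) {
  if (nPeaks <= 0) stop("nPeaks must be positive")
  max(0, zoneCount - distalCount) / nPeaks
}

#' Motif composition of a ChIP-seq dataset
#'
#' Classifies each peak by its top motifs: peaks with the ChIPped TF's motif
#' in its enrichment zone are "chipped"; among the remainder, peaks with at
#' least one zinger motif in that zinger's zone are "zinger motif peaks";
#' the rest are "unidentified". A peak containing both the ChIPped and a
#' zinger motif counts as chipped (the zinger-peak definition requires the
#' ChIPped motif to be absent). Background-corrected fractions subtract the
#' matched distal-zone counts; the four per-zinger corrected counts are
#' summed before dividing by the dataset size.
#'
#' @param chippedLandscape Landscape of the ChIPped TF's profile, or `NULL`
#'   when no profile is available for the ChIPped TF (raw chipped fraction
#'   undefined; dataset excluded from composition summaries).
#' @param zingerLandscapes Named list of zinger landscapes.
#' @param chippedZone [EnrichmentZone] for the ChIPped profile.
#' @param zingerZones Named list of [EnrichmentZone]s matching
#'   `zingerLandscapes`.
#' @return A list with `class` (per-peak factor), `raw` and `corrected`
#'   fraction vectors, and per-zinger corrected counts.
#' @export
peakComposition <- function(chippedLandscape, zingerLandscapes, chippedZone,
                            zingerZones) {
  stopifnot(length(zingerLandscapes) >= 1L,
            identical(names(zingerLandscapes), names(zingerZones)))
  n <- nrow(zingerLandscapes[[1L]])
  if (is.null(chippedLandscape)) {
    chippedIn <- rep(FALSE, n)
    chippedDefined <- FALSE
  } else {
    chippedIn <- inEnrichmentZone(chippedLandscape, chippedZone)
    chippedDefined <- TRUE
  }
  zingerIn <- vapply(names(zingerLandscapes), function(z) {
    inEnrichmentZone(zingerLandscapes[[z]], zingerZones[[z]])
  }, logical(n))
  anyZinger <- rowSums(as.matrix(zingerIn)) > 0
  cls <- ifelse(chippedIn, "CHIPPED",
                ifelse(anyZinger, "ZINGER", "UNIDENTIFIED"))
  raw <- c(chipped = mean(chippedIn), zinger = mean(!chippedIn & anyZinger),
           unidentified = mean(!chippedIn & !anyZinger))
  if (!chippedDefined) raw["chipped"] <- NA_real_
  corrChipped <- if (chippedDefined) {
    zc <- .zoneAndDistalCounts(chippedLandscape, chippedZone)
    correctedFraction(zc$zone, zc$distal, n)
  } else NA_real_
  zingerCounts <- vapply(names(zingerLandscapes), function(z) {
    zc <- .zoneAndDistalCounts(zingerLandscapes[[z]], zingerZones[[z]],
                               subset = !chippedIn)
    max(0, zc$zone - zc$distal)
  }, numeric(1))
  list(class = factor(cls, levels = c("CHIPPED", "ZINGER", "UNIDENTIFIED")),
       raw = raw,
       corrected = c(chipped = corrChipped,
                     zinger = sum(zingerCounts) / n),
       zinger_counts = zingerCounts)
}
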