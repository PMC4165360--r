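#' Fisher-log over-representation score
#'
#' One-tailed Fisher exact test (hypergeometric) comparing the number of
#' sequences containing at least one motif in a target peak set against a
#' background set, reported as the negative natural log of the p-value. A
#' score of 6.91 or higher corresponds to p <= 0.001. Underflow to p = 0
#' yields `Inf`, to be resolved by [capInfinite()].
#'
#' @param nTargetWith,nTarget Motif-containing and total target sequences.
#' @param nBgWith,nBg Motif-containing and total background sequences.
#' @return The score, with attribute `p` carrying the p-value.
#' @export
fisherLogScore <- function(nTargetWith, nTarget, nBgWith, nBg) {
  counts <- c(nTargetWith, nTarget, nBgWith, nBg)
  if (any(counts < 0)) stop("negative counts")
  if (nTarget <= 0 || nBg <= 0) stop("empty target or background set")
  if (nTargetWith > nTarget || nBgWith > nBg)
    stop("motif-containing counts exceed set sizes")
  # P(X >= nTargetWith) drawing nTarget from nTargetWith+nBgWith successes
  p <- stats::phyper(nTargetWith - 1, nTargetWith + nBgWith,
                     (nTarget - nTargetWith) + (nBg - nBgWith), nTarget,
                     lower.tail = FALSE)
  structure(-log(p), p = p)
}

#' Kolmogorov-Smirnov centrality score
#'
#' Tests whether motif positions in the target set concentrate at the region
#' center relative to the background, using the two-sample KS test on
#' absolute distances to the center. Reported as the negative natural log of
#' the p-value; 6.91 corresponds to p = 0.001. Exact small-sample p-values
#' are used where available (no ties, small n).
#'
#' @param targetDistances,bgDistances Absolute bp distances of motifs to the
#'   region center in the target and background sets.
#' @return The score (`NA` when either sample is empty, excluded from
#'   enrichment calls), with attribute `p`.
#' @export
ksCentralityScore <- function(targetDistances, bgDistances) {
  if (length(targetDistances) == 0L || length(bgDistances) == 0L)
    return(structure(NA_real_, p = NA_real_))
  p <- suppressWarnings(
    stats::ks.test(targetDistances, bgDistances)$p.value
  )
  structure(-log(p), p = p)
}

#' Cap infinite enrichment scores
#'
#' Infinite Fisher-log scores (p-value underflow) are set to 100 past the
#' maximum finite Fisher-log score in the vector, or to 500 when no finite
#' score exists. Infinite KS scores are set to 100.
#'
#' @param scores Numeric vector possibly containing `Inf`.
#' @param type `"fisher"` or `"ks"`.
#' @return The capped vector.
#' @examples
#' capInfinite(c(3.2, 7.5, Inf), "fisher")  # Inf -> 107.5
#' capInfinite(c(Inf, Inf), "fisher")       # both -> 500
#' @export
capInfinite <- function(scores, type = c("fisher", "ks")) {
  type <- match.arg(type)
  inf <- is.infinite(scores) & scores > 0
  if (!any(inf, na.rm = TRUE)) return(scores)
  if (type == "ks") {
    scores[which(inf)] <- 100
  } else {
    finite <- scores[is.finite(scores)]
    scores[which(inf)] <- if (length(finite)) max(finite) + 100 else 500
  }
  scores
}

#' Average enrichment scores over datasets for the same ChIPped TF
#'
#' Datasets ChIPped for the same factor (different cell lines or conditions)
#' are combined by the arithmetic mean of their Fisher-log and KS scores,
#' per profile.
#'
#' @param results A data.frame with columns `dataset_id`, `tf`,
#'   `profile_id`, `fisher_log`, `ks_log` (capped scores).
#' @return A data.frame with one row per `(tf, profile_id)` and the mean
#'   scores, plus `n_datasets`.
#' @export
aggregateByTF <- function(results) {
  stopifnot(all(c("tf", "profile_id", "fisher_log", "ks_log") %in%
                  names(results)))
  key <- interaction(results$tf, results$profile_id, drop = TRUE)
  agg <- function(v) tapply(v, key, function(x) mean(x, na.rm = FALSE))
  out <- data.frame(
    tf = tapply(as.character(results$tf), key, `[`, 1L),
    profile_id = tapply(as.character(results$profile_id), key, `[`, 1L),
    fisher_log = as.numeric(agg(results$fisher_log)),
    ks_log = as.numeric(agg(results$ks_log)),
    n_datasets = as.integer(tapply(results$fisher_log, key, length)),
    row.names = NULL
  )
  out[order(out$tf, out$profile_id), , drop = FALSE]
}

#' Binary enrichment calls from per-TF score vectors
#'
#' Within each ChIPped-TF row, a profile is called enriched (1) when its
#' Fisher-log score is at least `kFisher` standard deviations above the row
#' mean AND its KS score is at least `kKs` standard deviations above the row
#' mean, the mean and SD being computed across the profile scores of that
#' row. Rows whose SD is zero call only scores strictly above the common
#' value (hence never, when all scores are equal). Profiles with undefined
#' (NA) scores are called 0.
#'
#' @param perTfScores Output of [aggregateByTF()].
#' @param kFisher,kKs SD multipliers (defaults 2 and 1).
#' @return A 0/1 integer matrix with TF rows and profile columns.
#' @export
enrichmentCalls <- function(perTfScores, kFisher = 2, kKs = 1) {
  tfs <- sort(unique(perTfScores$tf))
  profiles <- sort(unique(perTfScores$profile_id))
  if (length(profiles) < 3L)
    stop("at least 3 profiles per TF row are required for the SD threshold")
  calls <- matrix(0L, length(tfs), length(profiles),
                  dimnames = list(tfs, profiles))
  for (tf in tfs) {
    rows <- perTfScores[perTfScores$tf == tf, , drop = FALSE]
    f <- rows$fisher_log[match(profiles, rows$profile_id)]
    k <- rows$ks_log[match(profiles, rows$profile_id)]
    calls[tf, ] <- as.integer(.passesSD(f, kFisher) & .passesSD(k, kKs))
  }
  calls
}

.passesSD <- function(scores, k) {
  m <- mean(scores, na.rm = TRUE)
  s <- stats::sd(scores, na.rm = TRUE)
  if (is.na(s)) s <- 0
  pass <- if (s == 0) scores > m else scores >= m + k * s
  pass & !is.na(scores)
}

#' Motif-family correction of enriched-dataset counts
#'
#' Profiles recognizing a shared consensus (e.g. the JUN/FOS/AP1 family)
#' inflate the count of datasets in which a family profile appears enriched.
#' The correction subtracts the number of contributing family-member
#' datasets minus one: a raw count of 20 with 9 family datasets among them
#' loses 8, leaving 12. Counts are floored at zero.
#'
#' @param rawCount Number of TF datasets in which the profile was called
#'   enriched.
#' @param nFamilyDatasets Number of those datasets ChIPped for a TF of the
#'   profile's own motif family (>= 1; 1 means no redundancy).
#' @return The corrected count.
#' @export
familyCorrection <- function(rawCount, nFamilyDatasets) {
  stopifnot(rawCount >= 0, nFamilyDatasets >= 1)
  max(0, rawCount - (nFamilyDatasets - 1))
}

#' Family-corrected per-profile enriched-TF counts
#'
#' Applies [familyCorrection()] to every column of a call matrix: for each
#' profile the raw count is the number of TF rows called enriched, and the
#' family-dataset count is the number of those rows whose ChIPped TF belongs
#' to the profile's own motif family.
#'
#' @param calls Call matrix from [enrichmentCalls()].
#' @param familyMap Named character vector mapping profile ids and TF names
#'   to family labels; entities absent from the map are treated as
#'   single-member families.
#' @return A data.frame with `profile_id`, `raw_count`, `corrected_count`.
#' @export
profileDatasetCounts <- function(calls, familyMap = character()) {
  profiles <- colnames(calls)
  tfs <- rownames(calls)
  famOf <- function(x) {
    f <- unname(familyMap[x])
    ifelse(is.na(f), x, f)
  }
  tfFam <- famOf(tfs)
  out <- data.frame(profile_id = profiles,
                    raw_count = as.integer(colSums(calls)),
                    corrected_count = 0L)
  for (i in seq_along(profiles)) {
    enriched <- calls[, i] == 1L
    nFam <- sum(enriched & tfFam == famOf(profiles[i]))
    out$corrected_count[i] <-
      familyCorrection(out$raw_count[i], max(1L, nFam))
  }
  out
}

#' Per-dataset over-representation scores for one profile
#'
#' Scans the 401 bp target and background sequence sets with a PWM and
#' computes the Fisher-log score on sequences containing at least one hit,
#' and the KS centrality score on the retained hits' absolute distances to
#' the region center.
#'
#' @param pwm A [PWM].
#' @param target,background Character vectors or
#'   [Biostrings::DNAStringSet]s of equal-length sequences.
#' @param threshold Relative-score scan threshold (default 85).
#' @param overlapFraction Passed to the scanner (default 1/5).
#' @return A list with `fisher_log`, `ks_log` (uncapped; may be `Inf` or
#'   `NA`) and the underlying counts.
#' @export
enrichmentScores <- function(pwm, target, background, threshold = 85,
                             overlapFraction = 1 / 5) {
  target <- as.character(target)
  background <- as.character(background)
  len <- unique(nchar(c(target[1L], background[1L])))
  center <- (len[1L] - 1L) %/% 2L
  maxOverlap <- floor(motifWidth(pwm) * overlapFraction)
  st <- cpp_hit_summary(target, weightMatrix(pwm), minScore(pwm),
                        maxScore(pwm), threshold, maxOverlap, center)
  sb <- cpp_hit_summary(background, weightMatrix(pwm), minScore(pwm),
                        maxScore(pwm), threshold, maxOverlap, center)
  fisher <- fisherLogScore(sum(st$with_hit), length(target),
                           sum(sb$with_hit), length(background))
  ks <- ksCentralityScore(st$distances, sb$distances)
  list(fisher_log = as.numeric(fisher), ks_log = as.numeric(ks),
       n_target_with = sum(st$with_hit), n_bg_with = sum(sb$with_hit))
}
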