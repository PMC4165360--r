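#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Position frequency matrix
#'
#' A count matrix over the four DNA bases describing a transcription factor
#' binding profile, as distributed by motif databases such as JASPAR. Rows are
#' ordered A, C, G, T; columns are motif positions.
#'
#' @slot id Profile identifier (e.g. a JASPAR accession).
#' @slot name Transcription factor name.
#' @slot counts 4 x L non-negative numeric matrix with rownames A, C, G, T.
#'
#' @export
setClass("PFM", representation(id = "character", name = "character",
                               counts = "matrix"))

setValidity("PFM", function(object) {
  m <- object@counts
  if (nrow(m) != 4L) return("counts must have 4 rows (A, C, G, T)")
  if (!identical(rownames(m), DNA_BASES4))
    return("counts rownames must be A, C, G, T")
  if (ncol(m) < 4L) return("motif width must be at least 4")
  if (any(m < 0)) return("counts must be non-negative")
  if (any(colSums(m) <= 0)) return("every column must have positive total")
  TRUE
})

#' Position weight matrix
#'
#' Log-odds (bits) transform of a [PFM], together with the minimum and
#' maximum attainable word scores used to rescale raw scores onto the 0-100
#' relative-score scale.
#'
#' @slot id,name Copied from the source PFM.
#' @slot weights 4 x L numeric log-odds matrix (bits).
#' @slot minScore,maxScore Sums of the per-column minima / maxima.
#'
#' @export
setClass("PWM", representation(id = "character", name = "character",
                               weights = "matrix", minScore = "numeric",
                               maxScore = "numeric"))

setValidity("PWM", function(object) {
  if (nrow(object@weights) != 4L) return("weights must have 4 rows")
  if (!identical(rownames(object@weights), DNA_BASES4))
    return("weights rownames must be A, C, G, T")
  if (object@maxScore <= object@minScore)
    return("maxScore must exceed minScore")
  TRUE
})

#' Enrichment zone
#'
#' The region around the peak maximum, plus a motif relative-score threshold,
#' within which a profile's motif predictions are enriched above the distal
#' background. Distances are signed base pairs relative to the peak maximum.
#'
#' @slot left,right Zone boundaries in bp (left < 0 < right).
#' @slot scoreThreshold Relative motif score threshold in [0, 100].
#' @slot boundariesFound,thresholdFound Whether the heuristic located each
#'   component, or the documented defaults were used.
#'
#' @export
setClass("EnrichmentZone",
         representation(left = "numeric", right = "numeric",
                        scoreThreshold = "numeric",
                        boundariesFound = "logical",
                        thresholdFound = "logical"))

setValidity("EnrichmentZone", function(object) {
  if (object@left >= 0 || object@right <= 0)
    return("left must be negative and right positive")
  if (object@scoreThreshold < 0 || object@scoreThreshold > 100)
    return("scoreThreshold must lie in [0, 100]")
  TRUE
})

#' Zero-adjusted logarithmic distribution fit
#'
#' Maximum-likelihood fit of a point mass at zero mixed with a logarithmic
#' series distribution on the positive integers.
#'
#' @slot p0 Probability mass at zero.
#' @slot mu Logarithmic-series parameter in (0, 1); `NA` when no positive
#'   counts were observed.
#' @slot logLik Log-likelihood at the fitted parameters.
#' @slot n Number of observations used in the fit.
#'
#' @export
setClass("ZALGFit", representation(p0 = "numeric", mu = "numeric",
                                   logLik = "numeric", n = "integer"))

setValidity("ZALGFit", function(object) {
  if (object@p0 < 0 || object@p0 > 1) return("p0 must lie in [0, 1]")
  if (!is.na(object@mu) && (object@mu <= 0 || object@mu >= 1))
    return("mu must lie in (0, 1)")
  TRUE
})

#' @describeIn PFM Profile identifier.
#' @param object A `PFM`, `PWM`, `EnrichmentZone` or `ZALGFit` object.
#' @export
setGeneric("motifID", function(object) standardGeneric("motifID"))

#' @describeIn PFM Transcription factor name.
#' @export
setGeneric("motifName", function(object) standardGeneric("motifName"))

#' @describeIn PFM Count matrix.
#' @export
setGeneric("motifCounts", function(object) standardGeneric("motifCounts"))

#' @describeIn PFM Motif width (number of columns).
#' @export
setGeneric("motifWidth", function(object) standardGeneric("motifWidth"))

setMethod("motifID", "PFM", function(object) object@id)
setMethod("motifName", "PFM", function(object) object@name)
setMethod("motifCounts", "PFM", function(object) object@counts)
setMethod("motifWidth", "PFM", function(object) ncol(object@counts))

setMethod("motifID", "PWM", function(object) object@id)
setMethod("motifName", "PWM", function(object) object@name)
setMethod("motifWidth", "PWM", function(object) ncol(object@weights))

#' @describeIn PWM Log-odds weight matrix (bits).
#' @param object A `PWM`.
#' @export
setGeneric("weightMatrix", function(object) standardGeneric("weightMatrix"))

#' @describeIn PWM Minimum attainable raw score.
#' @export
setGeneric("minScore", function(object) standardGeneric("minScore"))

#' @describeIn PWM Maximum attainable raw score.
#' @export
setGeneric("maxScore", function(object) standardGeneric("maxScore"))

setMethod("weightMatrix", "PWM", function(object) object@weights)
setMethod("minScore", "PWM", function(object) object@minScore)
setMethod("maxScore", "PWM", function(object) object@maxScore)

#' @describeIn EnrichmentZone Zone boundaries as `c(left, right)` bp.
#' @export
setGeneric("zoneBoundaries", function(object) standardGeneric("zoneBoundaries"))

#' @describeIn EnrichmentZone Relative motif score threshold.
#' @export
setGeneric("zoneThreshold", function(object) standardGeneric("zoneThreshold"))

setMethod("zoneBoundaries", "EnrichmentZone",
          function(object) c(left = object@left, right = object@right))
setMethod("zoneThreshold", "EnrichmentZone",
          function(object) object@scoreThreshold)

setMethod("show", "PFM", function(object) {
  cat("PFM", object@id, object@name, "| width", ncol(object@counts),
      "| sites ~", round(mean(colSums(object@counts)), 1), "\n")
  print(object@counts)
})

setMethod("show", "PWM", function(object) {
  cat("PWM", object@id, object@name, "| width", ncol(object@weights),
      sprintf("| raw score range [%.2f, %.2f]\n",
              object@minScore, object@maxScore))
})

setMethod("show", "EnrichmentZone", function(object) {
  cat(sprintf("EnrichmentZone [%d, %d] bp, score >= %s%s\n",
              object@left, object@right, format(object@scoreThreshold),
              if (object@boundariesFound && object@thresholdFound) ""
              else " (defaults used)"))
})

setMethod("show", "ZALGFit", function(object) {
  cat(sprintf("ZALGFit p0 = %.4f, mu = %s, n = %d\n", object@p0,
              if (is.na(object@mu)) "NA" else sprintf("%.4f", object@mu),
              object@n))
})

#' Construct a PFM
#'
#' @param counts 4 x L non-negative matrix; rows in A, C, G, T order
#'   (rownames are set automatically).
#' @param id,name Profile identifier and TF name.
#' @return A [PFM] object.
#' @examples
#' pfm <- PFM(matrix(c(10, 0, 0, 0), 4, 6, dimnames = NULL) + 1,
#'            id = "SYN0000", name = "toy")
#' @export
PFM <- function(counts, id = "PFM", name = id) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  rownames(counts) <- DNA_BASES4
  new("PFM", id = id, name = name, counts = counts)
}
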