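#' Read ChIP-seq peak calls
#'
#' Reads BED6, ENCODE narrowPeak or broadPeak files into a
#' [GenomicRanges::GRanges] with a `peakMax` metadata column (absolute
#' 0-based position): for narrowPeak, `start + summit offset` (column 10);
#' when the offset is -1, and for broadPeak/BED6, the region midpoint. The
#' `score` column prefers the q-value field when assigned (> -1), falling
#' back to the p-value field (narrowPeak/broadPeak), or uses the BED score.
#'
#' @param path Input file.
#' @param format One of `"narrowPeak"`, `"broadPeak"`, `"bed6"`.
#' @return A `GRanges` with metadata columns `peakMax` and `score`.
#' @export
readPeaks <- function(path, format = c("narrowPeak", "broadPeak", "bed6")) {
  format <- match.arg(format)
  need <- switch(format, narrowPeak = 10L, broadPeak = 9L, bed6 = 6L)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  bad <- which(nf != need)
  if (length(bad))
    stop("malformed ", format, " line ", bad[1L], " in ", path, ": expected ",
         need, " fields, found ", nf[bad[1L]])
  extra <- switch(format,
    narrowPeak = c(signalValue = "numeric", pValue = "numeric",
                   qValue = "numeric", peak = "integer"),
    broadPeak = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric"),
    bed6 = NULL)
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  bedStart <- GenomicRanges::start(gr) - 1L  # back to 0-based
  bedEnd <- GenomicRanges::end(gr)
  mid <- (bedStart + bedEnd) %/% 2L
  if (format == "narrowPeak") {
    off <- S4Vectors::mcols(gr)$peak
    S4Vectors::mcols(gr)$peakMax <- ifelse(off >= 0L, bedStart + off, mid)
  } else {
    S4Vectors::mcols(gr)$peakMax <- mid
  }
  if (format %in% c("narrowPeak", "broadPeak")) {
    q <- S4Vectors::mcols(gr)$qValue
    p <- S4Vectors::mcols(gr)$pValue
    S4Vectors::mcols(gr)$score <- ifelse(!is.na(q) & q > -1, q, p)
  }
  gr
}

#' Normalize peaks to a constant length centered on the peak maximum
#'
#' Every peak is trimmed or extended to `length` bp centered on its
#' `peakMax` (0-based region
#' `[peakMax - (length-1)/2, peakMax + (length-1)/2]` inclusive). Peaks
#' whose normalized region would be clipped at a contig edge (start < 0, or
#' past the known sequence length) are dropped with a warning.
#'
#' @param peaks `GRanges` from [readPeaks()] (must carry `peakMax`).
#' @param length Target odd length, conventionally 201, 401 or 1001.
#' @return The normalized `GRanges`.
#' @export
normalizeLength <- function(peaks, length = 401L) {
  stopifnot(length %% 2L == 1L, "peakMax" %in%
              names(S4Vectors::mcols(peaks)))
  half <- (length - 1L) %/% 2L
  pm <- S4Vectors::mcols(peaks)$peakMax
  start0 <- pm - half
  end0 <- pm + half + 1L  # half-open
  sl <- GenomeInfoDb::seqlengths(peaks)[as.character(
    GenomicRanges::seqnames(peaks))]
  drop <- start0 < 0L | (!is.na(sl) & end0 > sl)
  if (any(drop))
    warning(sum(drop), " peak(s) dropped: normalized region clipped at a ",
            "contig edge")
  out <- peaks[!drop]
  GenomicRanges::ranges(out) <- IRanges::IRanges(
    start = S4Vectors::mcols(out)$peakMax - half + 1L, width = length)
  out
}

#' Write neighborhoods as BED
#'
#' 0-based half-open intervals; the name column carries the neighborhood
#' class and the score column the number of unique contributing TFs.
#'
#' @param nbhds Output of [mergeNeighborhoods()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeNeighborhoodsBED <- function(nbhds, path) {
  bed <- data.frame(chrom = nbhds$chrom, start = nbhds$start,
                    end = nbhds$end + 1L, name = nbhds$class,
                    score = nbhds$n_unique_tfs, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
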