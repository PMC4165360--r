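#' @useDynLib zingerscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Information content of a PFM
#'
#' Total information content in bits: the sum over columns of
#' `2 - H(column frequencies)` where `H` is the Shannon entropy (base 2).
#' Profiles are conventionally retained for scanning only when their IC
#' exceeds 8 bits.
#'
#' @param pfm A [PFM].
#' @param pseudocount Added to every cell before normalization (default 0).
#' @return Information content in bits.
#' @examples
#' informationContent(PFM(matrix(5, 4, 4)))       # 0: uniform columns
#' @export
informationContent <- function(pfm, pseudocount = 0) {
  stopifnot(is(pfm, "PFM"), pseudocount >= 0)
  m <- motifCounts(pfm) + pseudocount
  f <- sweep(m, 2L, colSums(m), "/")
  h <- apply(f, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(2 - h)
}

#' Convert a PFM to a log-odds PWM
#'
#' Column counts are converted to log2 odds against a background base
#' distribution with a square-root-of-N pseudocount:
#' `w[b, j] = log2(((c[b, j] + p_b * sqrt(N)) / (N + sqrt(N))) / p_b)` where
#' `N` is the column total. The total pseudocount is configurable.
#'
#' @param pfm A [PFM].
#' @param background Base probabilities (A, C, G, T); default uniform.
#' @param pseudocount Total pseudocount added per column, split by the
#'   background; `NULL` (default) uses `sqrt(N)`.
#' @return A [PWM] with `minScore`/`maxScore` populated.
#' @export
pfmToPwm <- function(pfm, background = rep(0.25, 4), pseudocount = NULL) {
  stopifnot(is(pfm, "PFM"), length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  m <- motifCounts(pfm)
  N <- colSums(m)
  if (any(N <= 0)) stop("zero-total column in PFM ", motifID(pfm))
  alpha <- if (is.null(pseudocount)) sqrt(N) else rep_len(pseudocount, ncol(m))
  w <- m
  for (j in seq_len(ncol(m))) {
    p <- (m[, j] + background * alpha[j]) / (N[j] + alpha[j])
    w[, j] <- log2(p / background)
  }
  new("PWM", id = motifID(pfm), name = motifName(pfm), weights = w,
      minScore = sum(apply(w, 2L, min)), maxScore = sum(apply(w, 2L, max)))
}

#' Relative score of a word under a PWM
#'
#' The raw log-odds score rescaled to [0, 100] between the matrix's minimum
#' and maximum attainable word scores:
#' `100 * (raw - min) / (max - min)`. `N` bases contribute the column
#' minimum.
#'
#' @param pwm A [PWM].
#' @param word A character string over A, C, G, T, N with `nchar == width`.
#' @return Relative score in [0, 100].
#' @export
relativeScore <- function(pwm, word) {
  stopifnot(is(pwm, "PWM"))
  word <- toupper(as.character(word))
  L <- motifWidth(pwm)
  if (nchar(word) != L)
    stop("word length ", nchar(word), " != matrix width ", L)
  chars <- strsplit(word, "")[[1L]]
  bad <- !chars %in% c(DNA_BASES4, "N")
  if (any(bad)) stop("invalid characters in word: ",
                     paste(unique(chars[bad]), collapse = ", "))
  w <- weightMatrix(pwm)
  raw <- sum(vapply(seq_len(L), function(j) {
    if (chars[j] == "N") min(w[, j]) else w[chars[j], j]
  }, numeric(1)))
  100 * (raw - minScore(pwm)) / (maxScore(pwm) - minScore(pwm))
}

#' Scan a sequence for motif hits with overlap exclusion
#'
#' Scores every window on both strands, keeps windows whose relative score is
#' at or above `threshold`, and greedily retains hits in order of descending
#' score (ties broken leftmost, then plus strand) such that any two retained
#' hits overlap by at most `floor(width * overlapFraction)` bp. The default
#' one-fifth overlap allowance means a 7 bp motif may overlap a neighboring
#' retained motif by at most 1 bp.
#'
#' @param pwm A [PWM].
#' @param sequence A character string or [Biostrings::DNAString].
#' @param threshold Relative score threshold in [0, 100] (default 85, the
#'   conventional scanning threshold).
#' @param overlapFraction Maximum permitted overlap as a fraction of the
#'   motif width (default 1/5).
#' @return A data.frame with columns `start` and `end` (1-based, inclusive),
#'   `strand`, `rel_score`, ordered by position. Hits are retained greedily
#'   by descending score (compared at 1e-6 resolution), breaking ties by
#'   leftmost position and then `'+'` strand. Sequences shorter than the
#'   motif yield zero rows.
#' @export
scanSequence <- function(pwm, sequence, threshold = 85,
                         overlapFraction = 1 / 5) {
  stopifnot(is(pwm, "PWM"), threshold >= 0, threshold <= 100)
  sequence <- as.character(sequence)
  maxOverlap <- floor(motifWidth(pwm) * overlapFraction)
  h <- cpp_scan_hits(sequence, weightMatrix(pwm), minScore(pwm),
                     maxScore(pwm), threshold, maxOverlap)
  data.frame(start = h$start + 1L, end = h$start + motifWidth(pwm),
             strand = h$strand, rel_score = h$rel_score)
}

#' Column-shuffled null matrix
#'
#' Randomly permutes the internal columns of a PFM while holding the
#' low-information edge columns fixed (2 per side by default, 3 per side for
#' wide matrices of width >= 18, operationalizing the wider CTCF profile).
#' The multiset of columns is preserved exactly.
#'
#' @param pfm A [PFM].
#' @param fixedEdgeColumns Columns held fixed on each side; `NULL` (default)
#'   chooses 2, or 3 when the width is >= 18.
#' @param seed Optional integer seed for a reproducible permutation; the
#'   caller's RNG stream is left untouched.
#' @return A [PFM] with permuted internal columns and id suffixed
#'   `"_shuf"`.
#' @export
shufflePFM <- function(pfm, fixedEdgeColumns = NULL, seed = NULL) {
  stopifnot(is(pfm, "PFM"))
  L <- motifWidth(pfm)
  if (is.null(fixedEdgeColumns)) fixedEdgeColumns <- if (L >= 18L) 3L else 2L
  if (L <= 2L * fixedEdgeColumns + 1L)
    stop("matrix width ", L, " too small for ", fixedEdgeColumns,
         " fixed edge columns per side")
  internal <- (fixedEdgeColumns + 1L):(L - fixedEdgeColumns)
  perm <- withSeed(seed, sample(length(internal)))
  m <- motifCounts(pfm)
  m[, internal] <- m[, internal[perm], drop = FALSE]
  PFM(m, id = paste0(motifID(pfm), "_shuf"), name = motifName(pfm))
}
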