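# Shared fixtures and independent reference implementations ("oracles")
# used to validate the package against brute-force calculations.

# -- toy matrices -------------------------------------------------------------

# 7 bp toy PFM (distinct columns, N = 20 per column)
toyCounts7 <- function() {
  m <- matrix(c(
    # A   C   G   T  (columns are positions, built by row below)
    14,  2, 16,  1,  3,  2, 12,
     2, 15,  1,  2, 14,  3,  4,
     3,  2,  2, 16,  1, 13,  3,
     1,  1,  1,  1,  2,  2,  1), nrow = 4, byrow = TRUE)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

toyPFM7 <- function() PFM(toyCounts7(), id = "TOY7", name = "toy7")

randomSeq <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# -- PWM / scanning oracles ---------------------------------------------------

# Independent PWM conversion: direct transcription of the log2 odds formula
# with square-root-of-N pseudocount shares no code with pfmToPwm().
oraclePwmWeights <- function(counts, bg = rep(0.25, 4), pseudo = NULL) {
  N <- sum(counts[, 1])
  if (is.null(pseudo)) pseudo <- sqrt(N)
  w <- counts
  for (j in seq_len(ncol(counts))) {
    for (b in 1:4) {
      p <- (counts[b, j] + bg[b] * pseudo) / (N + pseudo)
      w[b, j] <- log2(p / bg[b])
    }
  }
  w
}

oracleRelScore <- function(w, word) {
  L <- ncol(w)
  idx <- match(strsplit(word, "")[[1L]], c("A", "C", "G", "T"))
  raw <- 0
  for (j in seq_len(L)) {
    raw <- raw + if (is.na(idx[j])) min(w[, j]) else w[idx[j], j]
  }
  mn <- sum(apply(w, 2, min))
  mx <- sum(apply(w, 2, max))
  unname(100 * (raw - mn) / (mx - mn))
}

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}

# Exhaustive-window scan with greedy overlap exclusion, all in plain R.
oracleScan <- function(w, sequence, threshold, overlapFraction = 1 / 5) {
  L <- ncol(w)
  n <- nchar(sequence)
  if (n < L) return(data.frame(start = integer(), end = integer(),
                               strand = character(), rel_score = numeric()))
  cand <- list()
  for (s in 1:(n - L + 1)) {
    word <- substr(sequence, s, s + L - 1)
    for (strand in c("+", "-")) {
      word2 <- if (strand == "+") word else oracleRevComp(word)
      sc <- oracleRelScore(w, word2)
      if (sc >= threshold)
        cand[[length(cand) + 1L]] <- data.frame(
          start = s, end = s + L - 1, strand = strand, rel_score = sc)
    }
  }
  if (!length(cand)) return(data.frame(start = integer(), end = integer(),
                                       strand = character(),
                                       rel_score = numeric()))
  cand <- do.call(rbind, cand)
  # rank: score desc (quantized at 1e-6, matching the scanner's tie rule),
  # then leftmost, then '+' strand
  cand <- cand[order(-round(cand$rel_score * 1e6), cand$start, cand$strand), ]
  maxOverlap <- floor(L * overlapFraction)
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in keep) {
      ov <- L - abs(cand$start[i] - cand$start[k])
      if (ov > maxOverlap) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  out <- cand[keep, ]
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Per-peak best hit (ties: closest to center, then leftmost, then '+').
oracleTopHit <- function(w, sequence, floorScore, center) {
  L <- ncol(w)
  n <- nchar(sequence)
  best <- NULL
  midOff <- (L - 1) %/% 2
  for (s in 1:(n - L + 1)) {
    word <- substr(sequence, s, s + L - 1)
    for (strand in c("+", "-")) {
      word2 <- if (strand == "+") word else oracleRevComp(word)
      sc <- oracleRelScore(w, word2)
      if (sc < floorScore) next
      d <- abs(s - 1 + midOff - center)
      cand <- list(start = s, strand = strand, score = sc, dist = d)
      if (is.null(best)) { best <- cand; next }
      eps <- 1e-9
      if (sc > best$score + eps) best <- cand
      else if (abs(sc - best$score) <= eps) {
        if (d < best$dist ||
            (d == best$dist && (s < best$start ||
              (s == best$start && strand == "+" && best$strand == "-"))))
          best <- cand
      }
    }
  }
  best
}

# -- Fisher oracle ------------------------------------------------------------

# One-tailed hypergeometric p by explicit enumeration over all tables at
# least as extreme (no phyper).
oracleFisherP <- function(aT, nT, aB, nB) {
  K <- aT + aB            # total successes
  N <- nT + nB
  ks <- max(0, K - nB):min(K, nT)
  probs <- exp(lchoose(K, ks) + lchoose(N - K, nT - ks) - lchoose(N, nT))
  sum(probs[ks >= aT])
}

# -- neighborhood merge oracle ------------------------------------------------

# O(n^2) transitive closure: peaks i, j linked when same chrom and
# |peakMax_i - peakMax_j| <= mergeBp; neighborhoods are connected components.
oracleMergeGroups <- function(peaks, mergeBp = 50) {
  n <- nrow(peaks)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (grp[i] != grp[j] && peaks$chrom[i] == peaks$chrom[j] &&
            abs(peaks$peakMax[i] - peaks$peakMax[j]) <= mergeBp) {
          g <- min(grp[i], grp[j])
          grp[grp == grp[i] | grp == grp[j]] <- g
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  grp
}

# Canonical signature of a grouping: sorted list of sorted member sets.
groupSignature <- function(grp) {
  unname(sort(vapply(split(seq_along(grp), grp), function(i)
    paste(sort(i), collapse = ","), character(1))))
}

# -- ZALG oracle --------------------------------------------------------------

oracleZalgPmf <- function(y, p0, mu) {
  if (y == 0) return(p0)
  (1 - p0) * mu^y / (y * (-log(1 - mu)))
}
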