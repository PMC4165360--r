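#' Zero-adjusted logarithmic distribution
#'
#' Mixture of a point mass `p0` at zero and a logarithmic series
#' distribution with parameter `mu` on the positive integers:
#' `P(Y = 0) = p0` and, for `y >= 1`,
#' `P(Y = y) = (1 - p0) * mu^y / (y * (-log(1 - mu)))`.
#'
#' @param x Non-negative integer quantiles.
#' @param p0 Probability mass at zero.
#' @param mu Logarithmic-series parameter in (0, 1).
#' @param n Number of random draws.
#' @return `dZALG` the probability mass, `rZALG` random draws.
#' @name ZALG
NULL

#' @rdname ZALG
#' @export
dZALG <- function(x, p0, mu) {
  stopifnot(p0 >= 0, p0 <= 1)
  out <- numeric(length(x))
  zero <- !is.na(x) & x == 0
  pos <- !is.na(x) & x >= 1 & x == round(x)
  out[zero] <- p0
  if (any(pos)) {
    if (is.na(mu)) stop("mu is undefined (fit had no positive counts)")
    stopifnot(mu > 0, mu < 1)
    out[pos] <- (1 - p0) * mu^x[pos] / (x[pos] * (-log1p(-mu)))
  }
  out
}

#' @rdname ZALG
#' @export
rZALG <- function(n, p0, mu) {
  zero <- stats::runif(n) < p0
  out <- integer(n)
  k <- sum(!zero)
  if (k > 0L) {
    stopifnot(!is.na(mu), mu > 0, mu < 1)
    # invert the logarithmic-series CDF; support capped where the tail
    # mass drops below 1e-12
    pmax <- 1 - 1e-12
    y <- 1L
    cum <- mu / (-log1p(-mu))
    cdf <- cum
    while (cdf < pmax && y < 100000L) {
      y <- y + 1L
      cum <- cum * mu * (y - 1) / y
      cdf <- cdf + cum
    }
    support <- seq_len(y)
    pmf <- mu^support / (support * (-log1p(-mu)))
    out[!zero] <- sample(support, k, replace = TRUE, prob = pmf)
  }
  out
}

.logSeriesMean <- function(mu) -mu / ((1 - mu) * log1p(-mu))

#' Fit a zero-adjusted logarithmic distribution
#'
#' Maximum-likelihood fit: `p0` is the observed fraction of zeros (its ML
#' estimate), and `mu` solves the logarithmic-series mean equation
#' `mean(positive counts) = -mu / ((1 - mu) * log(1 - mu))` by bisection to
#' a tolerance of 1e-10.
#'
#' @param counts Non-negative integer counts (e.g. enriched-dataset counts
#'   of shuffled profiles); at least 20 observations.
#' @return A [ZALGFit].
#' @export
fitZALG <- function(counts) {
  stopifnot(length(counts) >= 20L, all(counts >= 0),
            all(counts == round(counts)))
  n <- length(counts)
  p0 <- mean(counts == 0)
  pos <- counts[counts > 0]
  if (length(pos) == 0L) {
    return(new("ZALGFit", p0 = 1, mu = NA_real_, logLik = 0, n = n))
  }
  m <- mean(pos)
  lo <- 1e-9
  hi <- 1 - 1e-9
  mu <- if (m <= 1 + 1e-12) {
    lo  # boundary: all positive counts are 1
  } else {
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (.logSeriesMean(mid) < m) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  ll <- sum(log(dZALG(counts, p0, mu)))
  new("ZALGFit", p0 = p0, mu = mu, logLik = ll, n = n)
}

#' Goodness of fit of a ZALG fit by simulation
#'
#' Bins the observed counts so that every expected bin count under the fit
#' is at least 5 (pooling the upper tail), computes a chi-squared statistic,
#' and calibrates it against `nSim` datasets drawn from the fitted
#' distribution itself.
#'
#' @param fit A [ZALGFit].
#' @param counts The observed counts.
#' @param nSim Number of simulated reference datasets (default 200).
#' @param seed Optional seed for the simulation (caller's RNG untouched).
#' @return A list with `p`, `statistic`, the bin `breaks`, and `expected`;
#'   `p` is `NA` (flagged by `defined = FALSE`) when fewer than 2 bins
#'   remain after pooling.
#' @export
zalgGof <- function(fit, counts, nSim = 200, seed = NULL) {
  stopifnot(is(fit, "ZALGFit"))
  n <- length(counts)
  maxY <- max(counts, 10L)
  pmf <- dZALG(0:maxY, fit@p0, fit@mu)
  pmf <- c(pmf, max(0, 1 - sum(pmf)))  # analytic tail remainder for > maxY
  expv <- n * pmf                      # expected count per value 0..maxY+1
  # pool the upper tail (values >= hiCut - 1) so the top bin, and every
  # singleton bin below it, expects >= 5; the log-series pmf is monotone
  # decreasing on the positive integers, so under-filled singletons are
  # always adjacent to the pooled tail
  hiCut <- length(expv)
  while (hiCut > 2L &&
         (sum(expv[hiCut:length(expv)]) < 5 || expv[hiCut - 1L] < 5)) {
    hiCut <- hiCut - 1L
  }
  # pool the bottom (values <= loCut - 1) when the zero mass is small
  loCut <- 1L
  while (loCut < hiCut - 1L && sum(expv[1:loCut]) < 5) loCut <- loCut + 1L
  nbin <- (hiCut - 1L) - loCut + 2L  # bottom bin + singletons + top bin
  if (nbin < 2L || sum(expv[hiCut:length(expv)]) < 5 ||
      sum(expv[1:loCut]) < 5) {
    return(list(p = NA_real_, statistic = NA_real_, defined = FALSE))
  }
  expected <- c(sum(expv[1:loCut]),
                if (hiCut - 1L >= loCut + 1L) expv[(loCut + 1L):(hiCut - 1L)],
                sum(expv[hiCut:length(expv)]))
  binOf <- function(x) {
    v <- pmin(x, maxY + 1L)
    ifelse(v <= loCut - 1L, 1L,
           ifelse(v >= hiCut - 1L, nbin, v - loCut + 2L))
  }
  obsStat <- function(x) {
    o <- tabulate(binOf(x), nbins = nbin)
    sum((o - expected)^2 / expected)
  }
  s0 <- obsStat(counts)
  sims <- withSeed(seed, vapply(seq_len(nSim), function(i) {
    obsStat(rZALG(n, fit@p0, fit@mu))
  }, numeric(1)))
  list(p = (1 + sum(sims >= s0)) / (nSim + 1), statistic = s0,
       defined = TRUE, expected = expected)
}

#' Upper-tail probability under a fitted ZALG
#'
#' The probability of a result at least as extreme as the observed
#' enriched-dataset count, `P(Y >= observed)`, under the fitted
#' distribution. The point-mass density is available behind a flag.
#'
#' @param fit A [ZALGFit].
#' @param observed Observed count (non-negative integer).
#' @param pointMass If `TRUE`, return the density `P(Y = observed)` instead
#'   of the tail.
#' @return The probability.
#' @export
zalgTailProbability <- function(fit, observed, pointMass = FALSE) {
  stopifnot(is(fit, "ZALGFit"), observed >= 0)
  if (pointMass) return(dZALG(observed, fit@p0, fit@mu))
  if (observed == 0) return(1)
  if (fit@p0 >= 1 || is.na(fit@mu)) return(0)
  # sum the logarithmic-series pmf from `observed` to convergence
  mu <- fit@mu
  term <- mu^observed / observed
  total <- term
  y <- observed
  repeat {
    y <- y + 1
    term <- term * mu * (y - 1) / y
    total <- total + term
    if (term < 1e-16 * max(total, 1e-300)) break
  }
  (1 - fit@p0) * total / (-log1p(-mu))
}

#' Null distribution of cross-dataset enrichment counts for a profile
#'
#' Generates column-shuffled versions of a PFM, scores each shuffled profile
#' across all datasets of a corpus with [enrichmentScores()], averages per
#' ChIPped TF, applies the enrichment-score thresholds derived from the
#' original (unshuffled) analysis, and counts the TFs in which each
#' shuffled profile is enriched.
#'
#' @param pfm The original [PFM].
#' @param corpus A list of datasets; each a list with `tf`, `target` and
#'   `background` equal-length sequence sets (401 bp convention).
#' @param thresholds data.frame with `tf`, `fisher_thresh`, `ks_thresh`
#'   columns: the row thresholds (mean + k SD of the original profile score
#'   vectors) from the original analysis.
#' @param nShuffles Number of shuffled matrices (default 100).
#' @param seed Seed for the shuffle stream (each matrix uses `seed + i`).
#' @param scanThreshold Relative-score scan threshold (default 85).
#' @return A list with `counts` (one enriched-TF count per shuffle),
#'   `profile_id`, `n_shuffles` and `seed`.
#' @export
nullCounts <- function(pfm, corpus, thresholds, nShuffles = 100, seed = 1,
                       scanThreshold = 85) {
  stopifnot(is(pfm, "PFM"),
            all(c("tf", "fisher_thresh", "ks_thresh") %in% names(thresholds)))
  tfs <- vapply(corpus, function(d) d$tf, character(1))
  counts <- integer(nShuffles)
  for (i in seq_len(nShuffles)) {
    shuf <- shufflePFM(pfm, seed = seed + i)
    pwm <- pfmToPwm(shuf)
    sc <- lapply(corpus, function(d) {
      enrichmentScores(pwm, d$target, d$background, scanThreshold)
    })
    fisher <- capInfinite(vapply(sc, `[[`, numeric(1), "fisher_log"),
                          "fisher")
    ks <- capInfinite(vapply(sc, `[[`, numeric(1), "ks_log"), "ks")
    perTf <- data.frame(tf = tfs, fisher_log = fisher, ks_log = ks)
    fMean <- tapply(perTf$fisher_log, perTf$tf, mean)
    kMean <- tapply(perTf$ks_log, perTf$tf, mean)
    rows <- thresholds$tf
    enriched <- !is.na(fMean[rows]) & !is.na(kMean[rows]) &
      fMean[rows] >= thresholds$fisher_thresh &
      kMean[rows] >= thresholds$ks_thresh
    # shuffled profiles carry no family structure: correction is identity
    counts[i] <- familyCorrection(sum(enriched, na.rm = TRUE), 1L)
  }
  list(counts = counts, profile_id = motifID(pfm), n_shuffles = nShuffles,
       seed = seed)
}

#' Enrichment-score row thresholds from an original analysis
#'
#' For each ChIPped-TF row of a per-TF score table, the thresholds that the
#' SD-based enrichment call applies: `mean + kFisher * SD` of the Fisher-log
#' scores and `mean + kKs * SD` of the KS scores, across profiles.
#'
#' @inheritParams enrichmentCalls
#' @return data.frame with `tf`, `fisher_thresh`, `ks_thresh`.
#' @export
rowThresholds <- function(perTfScores, kFisher = 2, kKs = 1) {
  tfs <- sort(unique(perTfScores$tf))
  out <- lapply(tfs, function(tf) {
    rows <- perTfScores[perTfScores$tf == tf, ]
    f <- rows$fisher_log
    k <- rows$ks_log
    data.frame(tf = tf,
               fisher_thresh = mean(f, na.rm = TRUE) +
                 kFisher * stats::sd(f, na.rm = TRUE),
               ks_thresh = mean(k, na.rm = TRUE) +
                 kKs * stats::sd(k, na.rm = TRUE))
  })
  do.call(rbind, out)
}
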