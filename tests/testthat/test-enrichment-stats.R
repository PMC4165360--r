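test_that("fisherLogScore matches the hypergeometric enumeration oracle", {
  # [DERIVED] frozen value: enumeration over all tables with aT in 0..10,
  # p = 0.011507068783 for 8/10 targets vs 2/10 background
  s <- fisherLogScore(8, 10, 2, 10)
  expect_equal(as.numeric(s), 4.4647937557, tolerance = 1e-9)
  expect_equal(attr(s, "p"), 0.011507068783, tolerance = 1e-9)
  # [DERIVED] grid of small tables vs the enumeration oracle
  for (nT in c(4, 7, 12)) for (nB in c(5, 9)) {
    for (aT in 0:nT) for (aB in c(0, 1, nB %/% 2, nB)) {
      expect_equal(as.numeric(fisherLogScore(aT, nT, aB, nB)),
                   -log(oracleFisherP(aT, nT, aB, nB)), tolerance = 1e-9)
    }
  }
  # input validation
  expect_error(fisherLogScore(5, 4, 0, 10))
  expect_error(fisherLogScore(1, 0, 0, 10))
  expect_error(fisherLogScore(-1, 4, 0, 10))
})

test_that("a score of 6.91 corresponds to p = 0.001 for both score types", {
  expect_equal(round(-log(0.001), 2), 6.91)
  # a table whose Fisher p is just below 0.001 scores above 6.91
  s <- fisherLogScore(15, 20, 2, 20)
  expect_true((attr(s, "p") < 0.001) == (as.numeric(s) > 6.9077552790))
})

test_that("ksCentralityScore matches the exact two-sample KS p-value", {
  # [DERIVED] n = m = 3, D = 1: exact two-sided p = 2 * 3!3!/6! = 0.1
  s <- ksCentralityScore(c(0, 10, 20), c(100, 200, 300))
  expect_equal(attr(s, "p"), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(s), 2.3025850930, tolerance = 1e-9)
  # identical samples: p = 1, score 0
  s1 <- ksCentralityScore(c(1, 5, 9), c(1, 5, 9))
  expect_equal(attr(s1, "p"), 1)
  # empty sample: NA sentinel
  expect_true(is.na(ksCentralityScore(numeric(), c(1, 2, 3))))
  expect_true(is.na(ksCentralityScore(c(1, 2, 3), numeric())))
})

test_that("capInfinite applies the documented caps", {
  expect_equal(capInfinite(c(3.2, 7.5, Inf), "fisher"), c(3.2, 7.5, 107.5))
  expect_equal(capInfinite(c(Inf, Inf), "fisher"), c(500, 500))
  expect_equal(capInfinite(c(2, Inf, 50), "ks"), c(2, 100, 50))
  expect_equal(capInfinite(c(1, 2, 3), "fisher"), c(1, 2, 3))
  # NA passes through untouched
  expect_equal(capInfinite(c(NA, Inf, 4), "fisher"), c(NA, 104, 4))
  expect_equal(capInfinite(c(NA, 4), "ks"), c(NA, 4))
})

test_that("aggregateByTF averages dataset scores per (TF, profile)", {
  res <- data.frame(
    dataset_id = c("d1", "d2", "d3", "d1", "d2", "d3"),
    tf = c("X", "X", "Y", "X", "X", "Y"),
    profile_id = rep(c("P", "Q"), each = 3),
    fisher_log = c(2, 4, 10, 1, 3, 7),
    ks_log = c(0.5, 1.5, 2, NA, 1, 3))
  out <- aggregateByTF(res)
  expect_equal(nrow(out), 4L)
  xp <- out[out$tf == "X" & out$profile_id == "P", ]
  expect_equal(xp$fisher_log, 3)        # mean(2, 4)
  expect_equal(xp$ks_log, 1)
  expect_equal(xp$n_datasets, 2L)
  xq <- out[out$tf == "X" & out$profile_id == "Q", ]
  expect_true(is.na(xq$ks_log))         # NA propagates (na.rm = FALSE)
  yq <- out[out$tf == "Y" & out$profile_id == "Q", ]
  expect_equal(yq$fisher_log, 7)
})

test_that("enrichmentCalls applies the mean + k*SD rule per TF row", {
  # row X: profiles P..T with fisher c(100, 10, 10, 10, 10):
  # mean 28, sd 40.249..., mean + 2sd = 108.498 -> P NOT called on fisher
  # ks c(50, 1, 1, 1, 1): mean 10.8, sd 21.91..., mean + sd = 32.71 -> P yes
  f <- c(100, 10, 10, 10, 10)
  k <- c(50, 1, 1, 1, 1)
  perTf <- data.frame(tf = "X", profile_id = paste0("P", 1:5),
                      fisher_log = f, ks_log = k)
  calls <- enrichmentCalls(perTf)
  want <- as.integer(f >= mean(f) + 2 * sd(f) & k >= mean(k) + sd(k))
  expect_equal(as.integer(calls["X", paste0("P", 1:5)]), want)
  # a clearly separated profile among many near-null ones is called
  # (with only a handful of profiles a single outlier can never exceed
  # mean + 2 SD: the maximum z-score of n values is (n-1)/sqrt(n))
  f2 <- c(500, rep(10, 19) + seq(-0.9, 0.9, length.out = 19))
  k2 <- c(80, rep(1, 19) + seq(-0.4, 0.4, length.out = 19))
  calls2 <- enrichmentCalls(data.frame(tf = "X",
                                       profile_id = sprintf("P%02d", 1:20),
                                       fisher_log = f2, ks_log = k2))
  expect_equal(unname(calls2["X", "P01"]), 1L)
  expect_equal(sum(calls2), 1L)
  # SD = 0 row: equal scores are never "strictly above" the mean
  calls3 <- enrichmentCalls(data.frame(tf = "X",
                                       profile_id = paste0("P", 1:4),
                                       fisher_log = rep(5, 4),
                                       ks_log = rep(2, 4)))
  expect_equal(sum(calls3), 0L)
  # NA scores are called 0
  f4 <- c(500, 10, 11, 9, 10)
  calls4 <- enrichmentCalls(data.frame(tf = "X",
                                       profile_id = paste0("P", 1:5),
                                       fisher_log = f4,
                                       ks_log = c(NA, 1, 2, 1, 1)))
  expect_equal(unname(calls4["X", "P1"]), 0L)
  expect_error(enrichmentCalls(data.frame(tf = "X", profile_id = c("A", "B"),
                                          fisher_log = 1:2, ks_log = 1:2)))
})

test_that("familyCorrection subtracts family redundancy and floors at zero", {
  expect_equal(familyCorrection(20, 9), 12)   # worked example: 20 - 8
  expect_equal(familyCorrection(5, 1), 5)     # no redundancy
  expect_equal(familyCorrection(3, 10), 0)    # floored
  expect_equal(familyCorrection(0, 1), 0)
  expect_error(familyCorrection(-1, 1))
  expect_error(familyCorrection(5, 0))
})

test_that("profileDatasetCounts applies the family correction per column", {
  calls <- matrix(0L, 4, 2,
                  dimnames = list(c("JUN", "FOS", "GATA1", "CTCF"),
                                  c("JUNP", "CTCFP")))
  calls[c("JUN", "FOS", "GATA1"), "JUNP"] <- 1L
  calls[c("CTCF", "GATA1"), "CTCFP"] <- 1L
  fam <- c(JUN = "AP1", FOS = "AP1", JUNP = "AP1")
  out <- profileDatasetCounts(calls, fam)
  junp <- out[out$profile_id == "JUNP", ]
  # raw 3; JUN and FOS are AP1-family rows among the called -> minus 1
  expect_equal(junp$raw_count, 3L)
  expect_equal(junp$corrected_count, 2)
  ctcfp <- out[out$profile_id == "CTCFP", ]
  # raw 2; only CTCF itself shares the (singleton) family -> minus 0
  expect_equal(ctcfp$raw_count, 2L)
  expect_equal(ctcfp$corrected_count, 2)
})

test_that("enrichmentScores counts hit-bearing sequences and hit distances", {
  pwm <- pfmToPwm(toyPFM7())
  set.seed(31)
  # 41 bp regions, center index 20 (0-based); plant the consensus centered
  # in 6 of 10 targets, none in the background
  mkSeq <- function(withSite) {
    s <- randomSeq(41, gc = 0.2)  # AT-rich: few chance hits for this matrix
    if (withSite) s <- paste0(substr(s, 1, 17), "ACAGCGA", substr(s, 25, 41))
    s
  }
  target <- vapply(c(rep(TRUE, 6), rep(FALSE, 4)), mkSeq, character(1))
  background <- vapply(rep(FALSE, 10), mkSeq, character(1))
  sc <- enrichmentScores(pwm, target, background, threshold = 99)
  expect_equal(sc$n_target_with, 6L)
  expect_equal(sc$n_bg_with, 0L)
  # [DERIVED] fisher on 6/10 vs 0/10 via the enumeration oracle
  expect_equal(sc$fisher_log, -log(oracleFisherP(6, 10, 0, 10)),
               tolerance = 1e-9)
  # no background hits: KS undefined
  expect_true(is.na(sc$ks_log))
  # centered sites: all target distances 0 (motif midpoint at the center)
  sc2 <- enrichmentScores(pwm, target, target, threshold = 99)
  expect_equal(attr(ksCentralityScore(0, 0), "p"), 1)
})
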