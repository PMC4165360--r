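smallConfig <- function(...) {
  defaultSimConfig(tfs = c("TFA", "TFB"), cellLines = "cellA",
                   nPeaks = 400L, nSharedRegions = 200L, ...)
}

test_that("defaultSimConfig carries the study conditions and validates overrides", {
  cfg <- defaultSimConfig()
  expect_equal(length(cfg$tfs), 10L)
  expect_equal(cfg$cellLines, c("cellA", "cellB"))
  expect_equal(cfg$nPeaks, 5000L)
  expect_equal(cfg$chippedFraction, 0.55)
  expect_equal(unname(cfg$zingerFractions), c(0.05, 0.03, 0.02, 0.02))
  expect_equal(names(cfg$zingerFractions), zingerNames())
  expect_equal(cfg$plantHalfWidth, 90)
  expect_equal(cfg$plantScoreFloor, 85)
  expect_equal(cfg$cohesinProximalFraction, 0.77)
  expect_equal(cfg$backgroundProximalRate, 0.13)
  expect_equal(defaultSimConfig(nPeaks = 10L)$nPeaks, 10L)
  expect_error(defaultSimConfig(nonexistentOption = 1))
  expect_error(defaultSimConfig(chippedFraction = 0.9,
                                zingerFractions = c(CTCFZ = 0.2)))
})

test_that("zingerProfiles ships the four zingers, ten TFs and decoy matrices", {
  pfms <- zingerProfiles()
  expect_true(all(zingerNames() %in% names(pfms)))
  expect_true(all(paste0("TF", LETTERS[1:10]) %in% names(pfms)))
  expect_gte(length(pfms), 50L)
  expect_true(all(vapply(pfms, is, logical(1), "PFM")))
  # the CTCF-like profile is the wide one
  expect_gte(motifWidth(pfms$CTCFZ), 18L)
  # every profile passes the conventional IC > 8 bit retention rule
  ic <- vapply(pfms, informationContent, numeric(1))
  expect_true(all(ic > 8))
})

test_that("sampleSite draws from the PFM and honors the score floor", {
  pfms <- zingerProfiles()
  pwm <- pfmToPwm(pfms$JUNZ)
  set.seed(7)
  w <- sampleSite(pfms$JUNZ)
  expect_equal(nchar(w), motifWidth(pfms$JUNZ))
  expect_true(all(strsplit(w, "")[[1]] %in% c("A", "C", "G", "T")))
  set.seed(7)
  scores <- vapply(1:25, function(i)
    relativeScore(pwm, sampleSite(pfms$JUNZ, floorScore = 85, pwm = pwm)),
    numeric(1))
  expect_true(all(scores >= 85))
})

test_that("generateDataset is deterministic and plants at the configured rates", {
  cfg <- smallConfig()
  pfms <- zingerProfiles()
  shared <- data.frame(region_id = 1:200, chrom = "chr1",
                       pos = seq(10000, 2000000, length.out = 200))
  d1 <- generateDataset("TFA", "cellA", cfg, shared, pfms, seed = 21)
  d2 <- generateDataset("TFA", "cellA", cfg, shared, pfms, seed = 21)
  expect_identical(d1$peaks, d2$peaks)
  expect_identical(as.character(d1$sequences), as.character(d2$sequences))
  expect_identical(d1$truth, d2$truth)
  # planted class counts are exact (rounded fractions of n)
  n <- cfg$nPeaks
  expect_equal(sum(d1$truth$class == "CHIPPED"), round(0.55 * n))
  expect_equal(as.integer(table(d1$truth$planted_zinger)[zingerNames()]),
               as.integer(round(n * cfg$zingerFractions)))
  # planted distances respect the +/-90 bp half width
  pd <- d1$truth$planted_distance
  expect_true(all(abs(pd[!is.na(pd)]) <= cfg$plantHalfWidth + 10))
  # regions are 1001 bp; peaks carry the dataset labels
  expect_true(all(Biostrings::width(d1$sequences) == 1001L))
  expect_equal(unique(d1$peaks$tf), "TFA")
  expect_equal(unique(d1$peaks$dataset_id), "TFA_cellA")
  # planted chipped sites score >= the floor in the landscape
  chip <- which(d1$truth$class == "CHIPPED")[1:50]
  l <- buildLandscape(as.character(d1$sequences[chip]), pfmToPwm(pfms$TFA),
                      floorScore = 70)
  expect_true(all(l$has_hit))
  expect_true(mean(l$rel_score >= 85) > 0.95)
  # caller's RNG stream untouched
  set.seed(3); before <- runif(1)
  set.seed(3)
  invisible(generateDataset("TFA", "cellA", cfg, shared, pfms, seed = 22))
  expect_identical(runif(1), before)
})

test_that("zinger peaks recur in shared regions at the sharing rate", {
  cfg <- smallConfig(nPeaks = 2000L)
  pfms <- zingerProfiles()
  shared <- data.frame(region_id = 1:200, chrom = "chr2",
                       pos = round(seq(10000, 5e6, length.out = 200)))
  d <- generateDataset("TFB", "cellA", cfg, shared, pfms, seed = 31)
  zi <- d$truth$class == "ZINGER"
  sharedFrac <- mean(!is.na(d$truth$shared_region[zi]))
  # binomial draw over ~240 zinger peaks: allow ~3 SE absolute slack
  expect_lt(abs(sharedFrac - cfg$sharingRate), 0.1)
  # shared peaks sit within the jitter of their region
  si <- which(!is.na(d$truth$shared_region))
  off <- abs(d$peaks$peakMax[si] -
               shared$pos[d$truth$shared_region[si]])
  expect_true(all(off <= cfg$sharedJitter))
  expect_true(all(d$peaks$chrom[si] == "chr2"))
  # chipped peaks score higher than the rest on average
  expect_gt(mean(d$peaks$score[d$truth$class == "CHIPPED"]),
            mean(d$peaks$score[d$truth$class != "CHIPPED"]) + 1)
})

test_that("generateTracks places cohesin near shared regions at the target rate", {
  cfg <- defaultSimConfig()
  set.seed(12)
  shared <- data.frame(region_id = 1:2000,
                       chrom = sample(names(cfg$chromLengths), 2000, TRUE),
                       pos = round(runif(2000, 1000, 1e7 - 1000)))
  tracks <- generateTracks(shared, cfg, seed = 5)
  expect_named(tracks, c("cohesin", "PRC1", "PRC2"))
  near <- vapply(seq_len(nrow(shared)), function(i) {
    any(tracks$cohesin$chrom == shared$chrom[i] &
          abs(tracks$cohesin$pos - shared$pos[i]) <= 500)
  }, logical(1))
  expect_equal(mean(near), cfg$cohesinProximalFraction, tolerance = 0.05)
  # background proximity rate at random positions ~ 13%
  set.seed(99)
  rnd <- data.frame(chrom = sample(names(cfg$chromLengths), 800, TRUE),
                    pos = round(runif(800, 1000, 1e7 - 1000)))
  nearBg <- vapply(seq_len(nrow(rnd)), function(i) {
    any(tracks$cohesin$chrom == rnd$chrom[i] &
          abs(tracks$cohesin$pos - rnd$pos[i]) <= 500)
  }, logical(1))
  expect_lt(abs(mean(nearBg) - cfg$backgroundProximalRate), 0.05)
})

test_that("generateCorpus builds one dataset per TF x cell line, deterministically", {
  cfg <- smallConfig(nPeaks = 50L)
  c1 <- generateCorpus(cfg, seed = 8)
  c2 <- generateCorpus(cfg, seed = 8)
  expect_equal(names(c1$datasets), c("TFA_cellA", "TFB_cellA"))
  expect_identical(c1$datasets$TFA_cellA$peaks, c2$datasets$TFA_cellA$peaks)
  expect_identical(c1$sharedRegions, c2$sharedRegions)
  expect_identical(c1$tracks$cohesin, c2$tracks$cohesin)
  c3 <- generateCorpus(cfg, seed = 9)
  expect_false(identical(as.character(c1$datasets$TFA_cellA$sequences),
                         as.character(c3$datasets$TFA_cellA$sequences)))
  expect_error(generateCorpus(cfg))
})

test_that("generateBackgroundSet matches the per-sequence GC distribution", {
  set.seed(41)
  target <- vapply(1:60, function(i) randomSeq(401, gc = 0.55),
                   character(1))
  bg <- generateBackgroundSet(target, seed = 4)
  expect_equal(length(bg), 60L)
  expect_true(all(nchar(bg) == 401L))
  gcOf <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  expect_equal(mean(vapply(bg, gcOf, numeric(1))),
               mean(vapply(target, gcOf, numeric(1))), tolerance = 0.03)
  expect_identical(bg, generateBackgroundSet(target, seed = 4))
})

test_that("trimSequences keeps the centered window", {
  s <- paste(c(rep("A", 500), "G", rep("T", 500)), collapse = "")
  t3 <- trimSequences(s, 3)
  expect_equal(t3, "AGT")
  t401 <- trimSequences(s, 401)
  expect_equal(nchar(t401), 401L)
  expect_equal(substr(t401, 201, 201), "G")
  expect_error(trimSequences(s, 400))     # even length
  expect_error(trimSequences("ACGT", 11)) # longer than input
})

test_that("writeCorpus writes FASTA, narrowPeak, truth and track files", {
  dir <- tempfile("corpus")
  cfg <- smallConfig(nPeaks = 20L)
  corpus <- generateCorpus(cfg, seed = 14)
  writeCorpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "TFA_cellA.fa")))
  expect_true(file.exists(file.path(dir, "TFA_cellA.narrowPeak")))
  expect_true(file.exists(file.path(dir, "TFA_cellA_truth.tsv")))
  expect_true(file.exists(file.path(dir, "cohesin.bed")))
  # narrowPeak round trip: peakMax reconstructed from start + offset
  gr <- readPeaks(file.path(dir, "TFA_cellA.narrowPeak"), "narrowPeak")
  expect_equal(S4Vectors::mcols(gr)$peakMax,
               corpus$datasets$TFA_cellA$peaks$peakMax)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "TFA_cellA.fa"))
  expect_equal(as.character(unname(fa)),
               as.character(corpus$datasets$TFA_cellA$sequences))
  unlink(dir, recursive = TRUE)
})
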