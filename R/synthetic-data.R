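#' Default simulation configuration
#'
#' The study conditions emulated by the synthetic corpus: 10 ChIPped TFs in
#' 2 cell lines (20 datasets) of 5,000 peaks each; 1001 bp regions with the
#' peak maximum at the 501st bp; the ChIPped TF's motif planted within
#' +/-90 bp of the peak maximum in 55% of peaks; four zinger motifs planted
#' in a further 12% of peaks (5/3/2/2% for the CTCF-like, ETS-like,
#' JUN-like and THAP11-like profiles); planted sites rejection-sampled to a
#' relative score of at least 85 (the strong-motif convention); half of the
#' zinger peaks drawn from a pool of 2,000 genomic "zinger regions" shared
#' across datasets; cohesin placed within 500 bp of 77% of the shared
#' regions against a 13% background proximity rate; peak-calling scores
#' drawn lower for zinger/unidentified peaks than for peaks with the
#' ChIPped TF's motif.
#'
#' @param ... Named overrides of any default.
#' @return A named list of simulation parameters.
#' @export
defaultSimConfig <- function(...) {
  cfg <- list(
    tfs = paste0("TF", LETTERS[1:10]),
    cellLines = c("cellA", "cellB"),
    nPeaks = 5000L,
    chippedFraction = 0.55,
    zingerFractions = c(CTCFZ = 0.05, ETSZ = 0.03, JUNZ = 0.02,
                        THAPZ = 0.02),
    plantHalfWidth = 90,
    plantScoreFloor = 85,
    gc = 0.41,
    chromLengths = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7, chr4 = 1e7,
                     chr5 = 1e7),
    nSharedRegions = 2000L,
    sharingRate = 0.5,
    sharedJitter = 20,
    cohesinProximalFraction = 0.77,
    backgroundProximalRate = 0.13,
    prcFraction = 0.3,
    peakScoreMeanChipped = 10,
    peakScoreMeanOther = 7,
    peakScoreSD = 2
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  fr <- cfg$chippedFraction + sum(cfg$zingerFractions)
  if (any(c(cfg$chippedFraction, cfg$zingerFractions) < 0) || fr > 1)
    stop("planted fractions must be in [0, 1] and sum to at most 1")
  cfg
}

#' Bundled synthetic binding profiles
#'
#' Loads the package's synthetic position frequency matrices: four
#' zinger-like profiles (`CTCFZ`, a wide high-information CTCF-like matrix;
#' `ETSZ`, GGAA-core ETS-like; `JUNZ`, TGACTCA-core bZIP-like; `THAPZ`,
#' THAP11-like) and ten generic TF profiles (`TFA`..`TFJ`) used as ChIPped
#' TFs in simulations. These matrices are synthetic constructions shipped
#' with the package, not database profiles.
#'
#' @return A named list of [PFM] objects.
#' @export
zingerProfiles <- function() {
  readJasparPFM(system.file("extdata", "synthetic_pfms.txt",
                            package = "zingerscan", mustWork = TRUE))
}

#' Names of the zinger profiles
#' @return Character vector `c("CTCFZ", "ETSZ", "JUNZ", "THAPZ")`.
#' @export
zingerNames <- function() c("CTCFZ", "ETSZ", "JUNZ", "THAPZ")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

reverseComplement_chr <- function(word) {
  paste(rev(.COMPLEMENT[strsplit(word, "")[[1L]]]), collapse = "")
}

#' Sample a binding site from a PFM
#'
#' Draws a word column-independently from the normalized count frequencies.
#' With `floorScore`, draws are rejection-sampled until the relative score
#' under the PFM's PWM reaches the floor (best draw returned after
#' `maxTries`).
#'
#' @param pfm A [PFM].
#' @param floorScore Optional minimum relative score of the returned word.
#' @param pwm Optional pre-computed [PWM] (avoids reconversion).
#' @param maxTries Rejection-sampling cap (default 200).
#' @return A character word of the motif's width.
#' @export
sampleSite <- function(pfm, floorScore = NULL, pwm = NULL, maxTries = 200) {
  stopifnot(is(pfm, "PFM"))
  m <- motifCounts(pfm)
  draw <- function() {
    paste(vapply(seq_len(ncol(m)), function(j) {
      sample(DNA_BASES4, 1L, prob = m[, j])
    }, character(1)), collapse = "")
  }
  if (is.null(floorScore)) return(draw())
  if (is.null(pwm)) pwm <- pfmToPwm(pfm)
  best <- draw()
  bestScore <- relativeScore(pwm, best)
  tries <- 1L
  while (bestScore < floorScore && tries < maxTries) {
    w <- draw()
    s <- relativeScore(pwm, w)
    if (s > bestScore) {
      best <- w
      bestScore <- s
    }
    tries <- tries + 1L
  }
  best
}

# Random DNA as a character vector of per-base letters.
.randomBases <- function(n, gc) {
  sample(DNA_BASES4, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate one synthetic ChIP-seq dataset
#'
#' Produces `nPeaks` 1001 bp peak regions with background base composition,
#' plants the ChIPped TF's site within `plantHalfWidth` bp of the 501st bp
#' in a `chippedFraction` of peaks, plants each zinger's site (in peaks
#' without the ChIPped site) at its configured fraction, assigns genomic
#' peak-maximum coordinates (zinger peaks fall into shared zinger regions at
#' the configured sharing rate), and draws peak-calling scores so that
#' peaks with the ChIPped motif score higher than zinger and unidentified
#' peaks.
#'
#' @param tf,cellLine Dataset labels; `tf` must name a profile in `pfms`.
#' @param config From [defaultSimConfig()].
#' @param sharedRegions data.frame with `region_id`, `chrom`, `pos` of the
#'   shared zinger regions.
#' @param pfms Named list of [PFM]s covering `tf` and all zinger names.
#' @param seed Integer seed (mandatory; the caller's RNG is untouched).
#' @return A list with `peaks` (data.frame: `peak_id`, `chrom`, `peakMax`,
#'   `score`, `tf`, `cell_line`, `dataset_id`), `sequences`
#'   ([Biostrings::DNAStringSet]) and `truth` (per-peak planted class,
#'   planted distance, shared region id).
#' @export
generateDataset <- function(tf, cellLine, config, sharedRegions, pfms,
                            seed) {
  stopifnot(!is.null(seed), tf %in% names(pfms),
            all(names(config$zingerFractions) %in% names(pfms)))
  withSeed(seed, {
    n <- config$nPeaks
    len <- LANDSCAPE_LEN
    zf <- config$zingerFractions
    nChip <- round(n * config$chippedFraction)
    nZing <- round(n * zf)
    if (nChip + sum(nZing) > n) stop("planted fractions exceed dataset size")
    cls <- rep("UNIDENTIFIED", n)
    pool <- sample(n)
    cls[pool[seq_len(nChip)]] <- "CHIPPED"
    off <- nChip
    plantedZinger <- rep(NA_character_, n)
    for (z in names(zf)) {
      if (nZing[[z]] > 0L) {
        idx <- pool[off + seq_len(nZing[[z]])]
        cls[idx] <- "ZINGER"
        plantedZinger[idx] <- z
        off <- off + nZing[[z]]
      }
    }
    bases <- .randomBases(n * len, config$gc)
    plantDist <- rep(NA_integer_, n)
    pwmCache <- list()
    plant <- function(i, profile) {
      pfm <- pfms[[profile]]
      if (is.null(pwmCache[[profile]]))
        pwmCache[[profile]] <<- pfmToPwm(pfm)
      word <- sampleSite(pfm, config$plantScoreFloor, pwmCache[[profile]])
      if (stats::runif(1) < 0.5) word <- reverseComplement_chr(word)
      L <- nchar(word)
      d <- round(stats::runif(1, -config$plantHalfWidth,
                              config$plantHalfWidth))
      start0 <- LANDSCAPE_CENTER + d - (L - 1L) %/% 2L  # 0-based in region
      start0 <- max(0L, min(len - L, start0))
      at <- (i - 1L) * len + start0
      bases[at + seq_len(L)] <<- strsplit(word, "")[[1L]]
      plantDist[i] <<- start0 + (L - 1L) %/% 2L - LANDSCAPE_CENTER
    }
    for (i in which(cls == "CHIPPED")) plant(i, tf)
    for (i in which(cls == "ZINGER")) plant(i, plantedZinger[i])
    big <- paste(bases, collapse = "")
    seqs <- substring(big, (seq_len(n) - 1L) * len + 1L, seq_len(n) * len)
    # genomic placement: zinger peaks recur at shared regions
    chroms <- names(config$chromLengths)
    chrom <- sample(chroms, n, replace = TRUE)
    peakMax <- vapply(chrom, function(ch)
      round(stats::runif(1, 1000, config$chromLengths[[ch]] - 1000)),
      numeric(1))
    regionId <- rep(NA_integer_, n)
    zi <- which(cls == "ZINGER")
    shared <- zi[stats::runif(length(zi)) < config$sharingRate]
    if (length(shared) && nrow(sharedRegions)) {
      pick <- sample(nrow(sharedRegions), length(shared), replace = TRUE)
      chrom[shared] <- sharedRegions$chrom[pick]
      peakMax[shared] <- sharedRegions$pos[pick] +
        round(stats::runif(length(shared), -config$sharedJitter,
                           config$sharedJitter))
      regionId[shared] <- sharedRegions$region_id[pick]
    }
    score <- ifelse(cls == "CHIPPED",
                    stats::rnorm(n, config$peakScoreMeanChipped,
                                 config$peakScoreSD),
                    stats::rnorm(n, config$peakScoreMeanOther,
                                 config$peakScoreSD))
    datasetId <- paste(tf, cellLine, sep = "_")
    list(
      peaks = data.frame(
        peak_id = paste0(datasetId, "_p", seq_len(n)),
        chrom = unname(chrom), peakMax = unname(peakMax), score = score,
        tf = tf, cell_line = cellLine, dataset_id = datasetId),
      sequences = Biostrings::DNAStringSet(seqs),
      truth = data.frame(
        peak_id = paste0(datasetId, "_p", seq_len(n)),
        class = cls, planted_zinger = plantedZinger,
        planted_distance = plantDist, shared_region = regionId)
    )
  })
}

#' Generate cohesin and polycomb tracks around shared zinger regions
#'
#' Cohesin reference points are placed within 500 bp of a configurable
#' fraction of the shared zinger regions, plus uniformly placed background
#' points calibrated so that a random genomic position is proximal (within
#' 500 bp) at the configured background rate. PRC1/PRC2 points are placed
#' preferentially near cohesin.
#'
#' @param sharedRegions data.frame with `chrom`, `pos`.
#' @param config From [defaultSimConfig()].
#' @param seed Integer seed.
#' @return A named list of data.frames (`cohesin`, `PRC1`, `PRC2`) with
#'   `chrom` and `pos`.
#' @export
generateTracks <- function(sharedRegions, config, seed) {
  withSeed(seed, {
    prox <- sharedRegions[
      stats::runif(nrow(sharedRegions)) < config$cohesinProximalFraction, ]
    proxPos <- data.frame(
      chrom = prox$chrom,
      pos = prox$pos + round(stats::runif(nrow(prox), -450, 450)))
    Lg <- sum(config$chromLengths)
    # Poisson-corrected count so P(random point within 500 bp) ~ rate
    nBg <- max(0L, round(-log1p(-config$backgroundProximalRate) * Lg / 1000)
               - nrow(proxPos))
    chroms <- names(config$chromLengths)
    bgChrom <- sample(chroms, nBg, replace = TRUE,
                      prob = config$chromLengths / Lg)
    bgPos <- vapply(bgChrom, function(ch)
      round(stats::runif(1, 1, config$chromLengths[[ch]])), numeric(1))
    cohesin <- rbind(proxPos,
                     data.frame(chrom = bgChrom, pos = unname(bgPos)))
    prc <- function() {
      keep <- cohesin[stats::runif(nrow(cohesin)) < config$prcFraction, ]
      data.frame(chrom = keep$chrom,
                 pos = keep$pos + round(stats::runif(nrow(keep), -400, 400)))
    }
    list(cohesin = cohesin, PRC1 = prc(), PRC2 = prc())
  })
}

#' Generate a full synthetic corpus
#'
#' One dataset per (TF, cell line) pair, a shared-region set reused across
#' datasets, and the cohesin/PRC tracks. Fully deterministic under `seed`.
#'
#' @param config From [defaultSimConfig()].
#' @param seed Integer seed (mandatory).
#' @return A list with `datasets` (named list from [generateDataset()]),
#'   `sharedRegions`, `tracks` and `config`.
#' @export
generateCorpus <- function(config = defaultSimConfig(), seed) {
  stopifnot(!is.null(seed))
  pfms <- zingerProfiles()
  sharedRegions <- withSeed(seed, {
    chroms <- names(config$chromLengths)
    ch <- sample(chroms, config$nSharedRegions, replace = TRUE)
    data.frame(region_id = seq_len(config$nSharedRegions), chrom = ch,
               pos = vapply(ch, function(c)
                 round(stats::runif(1, 1000, config$chromLengths[[c]] - 1000)),
                 numeric(1)))
  })
  grid <- expand.grid(tf = config$tfs, cellLine = config$cellLines,
                      stringsAsFactors = FALSE)
  datasets <- lapply(seq_len(nrow(grid)), function(i) {
    generateDataset(grid$tf[i], grid$cellLine[i], config, sharedRegions,
                    pfms, seed = seed + i)
  })
  names(datasets) <- paste(grid$tf, grid$cellLine, sep = "_")
  tracks <- generateTracks(sharedRegions, config,
                           seed = seed + nrow(grid) + 1L)
  list(datasets = datasets, sharedRegions = sharedRegions, tracks = tracks,
       config = config)
}

#' GC-matched background sequences
#'
#' Generates random sequences of the same lengths as the target set, whose
#' per-sequence GC content is sampled with replacement from the target
#' set's per-sequence GC values (matching the mononucleotide GC composition
#' distribution).
#'
#' @param sequences Target set (character vector or
#'   [Biostrings::DNAStringSet]).
#' @param seed Optional integer seed.
#' @return A character vector of background sequences.
#' @export
generateBackgroundSet <- function(sequences, seed = NULL) {
  seqs <- as.character(sequences)
  stopifnot(length(seqs) > 0L)
  gc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), "GC",
                                    as.prob = TRUE)[, 1L]
  withSeed(seed, {
    pickGc <- sample(gc, length(seqs), replace = TRUE)
    vapply(seq_along(seqs), function(i) {
      paste(.randomBases(nchar(seqs[i]), pickGc[i]), collapse = "")
    }, character(1))
  })
}

#' Trim equal-length regions to a shorter centered length
#'
#' Keeps `length` bp centered on the region center (e.g. 1001 bp landscape
#' regions trimmed to the 401 bp over-representation input).
#'
#' @param sequences Character vector or [Biostrings::DNAStringSet].
#' @param length Target odd length (e.g. 201, 401).
#' @return A character vector.
#' @export
trimSequences <- function(sequences, length) {
  seqs <- as.character(sequences)
  w <- nchar(seqs[1L])
  stopifnot(length <= w, length %% 2L == 1L)
  lo <- (w - 1L) %/% 2L - (length - 1L) %/% 2L + 1L
  substring(seqs, lo, lo + length - 1L)
}

#' Write a corpus to disk in standard formats
#'
#' FASTA sequences, narrowPeak peak calls (summit offset 500 within the
#' 1001 bp region), a truth TSV per dataset, and BED tracks.
#'
#' @param corpus From [generateCorpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  half <- (LANDSCAPE_LEN - 1L) %/% 2L
  for (nm in names(corpus$datasets)) {
    d <- corpus$datasets[[nm]]
    seqs <- d$sequences
    names(seqs) <- d$peaks$peak_id
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(nm, ".fa")))
    np <- data.frame(chrom = d$peaks$chrom,
                     start = d$peaks$peakMax - half,
                     end = d$peaks$peakMax + half + 1L,
                     name = d$peaks$peak_id,
                     score = 0L, strand = ".",
                     signalValue = round(d$peaks$score, 4), pValue = -1,
                     qValue = -1, peak = half)
    utils::write.table(np, file.path(dir, paste0(nm, ".narrowPeak")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(d$truth, file.path(dir, paste0(nm, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (tr in names(corpus$tracks)) {
    t <- corpus$tracks[[tr]]
    bed <- data.frame(chrom = t$chrom, start = t$pos, end = t$pos + 1L,
                      name = tr, score = 0L, strand = ".")
    utils::write.table(bed, file.path(dir, paste0(tr, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
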