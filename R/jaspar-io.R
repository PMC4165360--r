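#' Read position frequency matrices in JASPAR raw text format
#'
#' Parses the plain-text PFM dialect used by JASPAR: a header line starting
#' with `>` carrying the matrix identifier and name, followed by four rows of
#' whitespace-separated counts in A, C, G, T order. Rows may optionally be
#' decorated as `A [ 1 2 3 ]`.
#'
#' @param path Path to a PFM text file (may contain several matrices).
#' @param text Character vector of lines, as an alternative to `path`.
#' @return A named list of [PFM] objects (named by identifier).
#' @examples
#' txt <- c(">MA0001 test", "5 5 5 5", "5 5 5 5", "5 5 5 5", "5 5 5 5")
#' readJasparPFM(text = txt)
#' @export
readJasparPFM <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(path)
  text <- trimws(text)
  text <- text[nzchar(text)]
  hdr <- grep("^>", text)
  if (length(hdr) == 0L) stop("no '>' header lines found")
  ends <- c(hdr[-1L] - 1L, length(text))
  out <- vector("list", length(hdr))
  nm <- character(length(hdr))
  for (i in seq_along(hdr)) {
    head <- sub("^>\\s*", "", text[hdr[i]])
    toks <- strsplit(head, "\\s+")[[1L]]
    id <- toks[1L]
    name <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    body <- text[(hdr[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop("matrix ", id, ": expected 4 count rows, found ", length(body))
    rows <- lapply(body, .parsePfmRow, id = id)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("matrix ", id, ": ragged columns (row lengths ",
           paste(lens, collapse = ", "), ")")
    counts <- do.call(rbind, rows)
    # honor explicit base labels if present, otherwise assume A,C,G,T order
    labels <- toupper(sub("^\\s*([ACGTacgt])\\b.*$", "\\1", body))
    if (all(labels %in% DNA_BASES4) && !anyDuplicated(labels)) {
      counts <- counts[match(DNA_BASES4, labels), , drop = FALSE]
    }
    out[[i]] <- PFM(counts, id = id, name = name)
    nm[i] <- id
  }
  names(out) <- nm
  out
}

.parsePfmRow <- function(line, id) {
  line <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", line)
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1L]]))
  if (anyNA(vals)) stop("matrix ", id, ": non-numeric counts in row: ", line)
  vals
}

#' Write PFMs in JASPAR raw text format
#'
#' @param pfms A [PFM] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeJasparPFM <- function(pfms, path) {
  if (is(pfms, "PFM")) pfms <- list(pfms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", motifID(p), " ", motifName(p)), con)
    m <- motifCounts(p)
    for (b in seq_len(4L)) {
      writeLines(paste(format(m[b, ], trim = TRUE), collapse = " "), con)
    }
  }
  invisible(path)
}
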