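# Motif file I/O: MEME minimal motif format and a simple 4-column TSV.
# Internally PFMs are 4 x L (rows A,C,G,T); MEME stores the transpose.

#' Write PFMs in MEME minimal motif format
#'
#' @param pfms A named list of `pfm` matrices (or a single `pfm`).
#' @param path Output file.
#' @param background Named base frequencies written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfms, path, background = uniform_background()) {
  if (inherits(pfms, "pfm")) pfms <- list(motif1 = pfms)
  if (is.null(names(pfms)) || any(!nzchar(names(pfms))))
    names(pfms) <- paste0("motif", seq_along(pfms))
  b <- background[DNA_BASES]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", b[1], b[2], b[3], b[4]),
               ""), con)
  for (nm in names(pfms)) {
    m <- as_base_matrix(unclass(pfms[[nm]]), nm)
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", ncol(m)),
      con)
    writeLines(apply(m, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PFMs from a MEME minimal motif file
#'
#' @param path MEME file written by [write_meme()] or compatible.
#' @return Named list of `pfm` matrices.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s+", lines)
  if (!length(motif_at)) stop("no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (i in motif_at) {
    nm <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- i + grep("letter-probability matrix",
                    lines[(i + 1):min(i + 5, length(lines))])[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                     function(x) as.numeric(x[1:4]), numeric(4)))
    m <- t(vals)
    rownames(m) <- DNA_BASES
    out[[nm]] <- structure(m, class = "pfm", source = "file")
  }
  out
}

#' Write / read a PFM as a 4-column TSV
#'
#' One row per position, columns A, C, G, T.
#'
#' @param pfm A `pfm`.
#' @param path File path.
#' @return `path` (write) or a `pfm` (read).
#' @export
write_pfm_tsv <- function(pfm, path) {
  m <- as_base_matrix(unclass(pfm), "pfm")
  df <- as.data.frame(t(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pfm_tsv
#' @export
read_pfm_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- t(as.matrix(df[, DNA_BASES]))
  rownames(m) <- DNA_BASES
  colnames(m) <- NULL
  structure(m, class = "pfm", source = "file")
}
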