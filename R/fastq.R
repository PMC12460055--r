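## FASTQ input/output: strict 4-line records, gzip-transparent, with exact
## byte-level round-tripping of names, sequences and qualities.

#' Read a FASTQ file
#'
#' @param source Path to a FASTQ file, plain or gzip-compressed.
#' @return A data.frame with columns \code{name} (header without "@"),
#'   \code{seq} and \code{qual}.
#' @export
readFastq <- function(source) {
  con <- gzfile(source, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (!length(lines)) stop("empty FASTQ", call. = FALSE)
  if (length(lines) %% 4L != 0L)
    stopf("truncated FASTQ record %d", length(lines) %/% 4L + 1L)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seq <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  badHdr <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(badHdr))
    stopf("malformed FASTQ record %d", badHdr[1L])
  badLen <- which(nchar(seq) != nchar(qual))
  if (length(badLen))
    stopf("sequence/quality length mismatch in FASTQ record %d", badLen[1L])
  data.frame(name = sub("^@", "", hdr), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param records A data.frame as returned by [readFastq()].
#' @param destination Output path (".gz" suffix compresses).
#' @return Invisibly, \code{destination}.
#' @export
writeFastq <- function(records, destination) {
  stopifnot(all(c("name", "seq", "qual") %in% names(records)))
  lines <- as.vector(rbind(paste0("@", records$name), records$seq,
                           "+", records$qual))
  con <- if (grepl("\\.gz$", destination)) gzfile(destination, "wt")
         else file(destination, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(destination)
}
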