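## FASTA input/output, via Biostrings (gzip-transparent).

#' Read a directory (or files) of assemblies
#'
#' Reads each FASTA file as one input assembly. The assembly id is the file
#' name stem (extension and any .gz suffix removed).
#'
#' @param path A directory containing FASTA files, or a character vector of
#'   FASTA file paths.
#' @param pattern File pattern when \code{path} is a directory.
#' @return Named list of named character vectors of contig sequences, suitable
#'   for [buildUnitigGraph()].
#' @export
readAssemblies <- function(path,
                           pattern = "\\.(fa|fasta|fna)(\\.gz)?$") {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = pattern, full.names = TRUE)
  else path
  if (!length(files)) stop("no sequences", call. = FALSE)
  files <- sort(files, method = "radix")
  out <- list()
  for (f in files) {
    ss <- Biostrings::readDNAStringSet(f)
    ## first whitespace-delimited word of the header is the contig name
    names(ss) <- sub("\\s.*$", "", names(ss))
    stem <- sub("\\.gz$", "", basename(f))
    stem <- sub("\\.(fa|fasta|fna)$", "", stem)
    out[[stem]] <- as.character(ss)
  }
  out
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path (".gz" suffix compresses).
#' @param width Line width for wrapping (default 70).
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write decompressed contigs of a graph to per-assembly FASTA files
#'
#' @param graph A [UnitigGraph-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeDecompressed <- function(graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  byAsm <- decompressContigs(graph)
  files <- character(0)
  for (a in names(byAsm)) {
    f <- file.path(dir, paste0(a, ".fasta"))
    writeFasta(byAsm[[a]], f)
    files <- c(files, f)
  }
  invisible(files)
}
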