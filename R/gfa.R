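## GFA 1.0 serialization of the unitig graph.
##
## Dialect: S-lines carry the unitig sequence plus an integer depth tag
## (DP:i:); L-lines carry explicit "(k-1)M" CIGAR overlaps; P-lines carry the
## contig paths, with the start/end offsets and original assembly name in
## reserved tags (SO:i:, EO:i:, AS:Z:). The k-mer size is stored in a header
## tag (KM:i:), which also marks the file as produced by this package.

#' Write a unitig graph as GFA 1.0
#'
#' @param graph A [UnitigGraph-class].
#' @param destination Path of the GFA file to write (or a connection).
#' @return Invisibly, \code{destination}.
#' @seealso [readGFA()]
#' @export
writeGFA <- function(graph, destination) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  k <- graph@k
  lines <- c(sprintf("H\tVN:Z:1.0\tKM:i:%d", k))
  n <- length(graph@unitigs)
  if (n) {
    lines <- c(lines, sprintf("S\t%d\t%s\tDP:i:%d", seq_len(n),
                              as.character(graph@unitigs), graph@depth))
  }
  lk <- graph@links
  if (nrow(lk)) {
    ## links are stored in both directions; write one line per adjacency
    flip <- function(o) ifelse(o == "+", "-", "+")
    key <- paste(lk$from, lk$fromOrient, lk$to, lk$toOrient)
    twin <- paste(lk$to, flip(lk$toOrient), lk$from, flip(lk$fromOrient))
    keep <- key <= twin
    lk <- lk[keep, , drop = FALSE]
    lines <- c(lines, sprintf("L\t%d\t%s\t%d\t%s\t%dM", lk$from, lk$fromOrient,
                              lk$to, lk$toOrient, k - 1L))
  }
  for (p in graph@paths) {
    lines <- c(lines, sprintf("P\t%s\t%s\t*\tSO:i:%d\tEO:i:%d\tAS:Z:%s",
                              paste0(p$assembly, ":", p$contig),
                              paste0(p$steps, p$strand, collapse = ","),
                              p$startOffset, p$endOffset, p$assembly))
  }
  writeLines(lines, destination)
  invisible(destination)
}

#' Read a GFA 1.0 unitig graph written by [writeGFA()]
#'
#' Restores the graph exactly: same unitigs, links, contig paths and k.
#'
#' @param source Path of the GFA file (or a connection).
#' @return A [UnitigGraph-class].
#' @export
readGFA <- function(source) {
  lines <- readLines(source)
  if (!length(lines) || !startsWith(lines[1L], "H"))
    stop("not a graph produced by this tool: missing header", call. = FALSE)
  htags <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  kmTag <- grep("^KM:i:", htags, value = TRUE)
  if (!length(kmTag))
    stop("not a graph produced by this tool: missing k header tag",
         call. = FALSE)
  k <- as.integer(sub("^KM:i:", "", kmTag[1L]))

  segId <- integer(0); segSeq <- character(0); segDepth <- integer(0)
  links <- list()
  paths <- list()
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    type <- f[1L]
    if (type == "S") {
      if (length(f) < 3L) stopf("malformed S line at line %d", i)
      segId <- c(segId, as.integer(f[2L]))
      segSeq <- c(segSeq, f[3L])
      dp <- grep("^DP:i:", f, value = TRUE)
      segDepth <- c(segDepth, if (length(dp)) as.integer(sub("^DP:i:", "", dp[1L])) else 0L)
    } else if (type == "L") {
      if (length(f) < 6L) stopf("malformed L line at line %d", i)
      links[[length(links) + 1L]] <- data.frame(
        from = as.integer(f[2L]), fromOrient = f[3L],
        to = as.integer(f[4L]), toOrient = f[5L], stringsAsFactors = FALSE)
    } else if (type == "P") {
      if (length(f) < 3L) stopf("malformed P line at line %d", i)
      stepTok <- strsplit(f[2L + 1L], ",", fixed = TRUE)[[1L]]
      if (!all(grepl("^[0-9]+[+-]$", stepTok)))
        stopf("malformed P line at line %d", i)
      so <- grep("^SO:i:", f, value = TRUE)
      eo <- grep("^EO:i:", f, value = TRUE)
      asmTag <- grep("^AS:Z:", f, value = TRUE)
      name <- f[2L]
      assembly <- if (length(asmTag)) sub("^AS:Z:", "", asmTag[1L]) else
        sub(":.*$", "", name)
      contig <- sub(paste0("^", assembly, ":"), "", name, fixed = FALSE)
      paths[[length(paths) + 1L]] <- list(
        assembly = assembly, contig = contig,
        steps = as.integer(sub("[+-]$", "", stepTok)),
        strand = sub("^[0-9]+", "", stepTok),
        startOffset = if (length(so)) as.integer(sub("^SO:i:", "", so[1L])) else 0L,
        endOffset = if (length(eo)) as.integer(sub("^EO:i:", "", eo[1L])) else 0L,
        length = NA_integer_)
    } else if (!type %in% c("H", "#")) {
      stopf("malformed line at line %d: unknown record type '%s'", i, type)
    }
  }
  ord <- order(segId)
  segSeq <- segSeq[ord]; segDepth <- segDepth[ord]; segId <- segId[ord]
  if (length(segId) && !identical(segId, seq_along(segId)))
    stop("malformed GFA: segment ids must be 1..n", call. = FALSE)
  us <- Biostrings::DNAStringSet(segSeq)
  names(us) <- as.character(segId)
  linkDf <- if (length(links)) do.call(rbind, links) else
    data.frame(from = integer(0), fromOrient = character(0),
               to = integer(0), toOrient = character(0),
               stringsAsFactors = FALSE)
  ## restore both directions
  if (nrow(linkDf)) {
    flip <- function(o) ifelse(o == "+", "-", "+")
    rev <- data.frame(from = linkDf$to, fromOrient = flip(linkDf$toOrient),
                      to = linkDf$from, toOrient = flip(linkDf$fromOrient),
                      stringsAsFactors = FALSE)
    linkDf <- rbind(linkDf, rev)
    linkDf <- linkDf[!duplicated(linkDf), , drop = FALSE]
    linkDf <- linkDf[order(linkDf$from, linkDf$fromOrient, linkDf$to,
                           linkDf$toOrient, method = "radix"), , drop = FALSE]
    rownames(linkDf) <- NULL
  }
  g <- methods::new("UnitigGraph", k = k, unitigs = us, depth = segDepth,
                    links = linkDf, paths = paths, metadata = list(k = k))
  ## fill in path lengths from reconstruction
  g@paths <- lapply(g@paths, function(p) {
    p$length <- nchar(reconstructContig(g, p))
    p
  })
  g
}
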