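## Compacted De Bruijn graph construction.
##
## The graph is built from the k-mers observed in the input contigs.
## Nodes are canonical k-mers (lexicographic minimum of a k-mer and its
## reverse complement; k is odd, so no k-mer is its own reverse complement).
## Edges are the (k-1)-overlap adjacencies observed between consecutive
## k-mers of an input contig. Maximal non-branching chains of nodes are
## merged into unitigs, and every input contig is annotated as an oriented
## walk (path) through the unitigs, with start/end offsets so reconstruction
## is byte-exact.

#' Build a compacted De Bruijn graph from input assemblies
#'
#' Collapses one or more whole-genome assemblies of the same isolate into a
#' lossless compacted De Bruijn graph. Shared regions across assemblies merge
#' into common unitigs; every input contig is recorded as a path through the
#' graph so that [reconstructContig()] recovers it exactly.
#'
#' Sequences are uppercased. Contigs containing non-ACGT characters are split
#' at those characters into sub-contigs (a De Bruijn graph needs unambiguous
#' k-mers); sub-contigs shorter than \code{k} are dropped, and both events are
#' recorded in \code{metadata(g)$splits}.
#'
#' @param assemblies A named list with one element per input assembly, each a
#'   named character vector or [Biostrings::DNAStringSet] of contig sequences.
#'   A bare named character vector is treated as a single assembly named
#'   "assembly1".
#' @param k Odd integer k-mer length, >= 11. Default 51.
#' @return A [UnitigGraph-class].
#' @examples
#' g <- buildUnitigGraph(list(a1 = c(c1 = "ACGTTGCAAGCTTGGACGATCGA")), k = 11)
#' g
#' @export
buildUnitigGraph <- function(assemblies, k = 51L) {
  k <- as.integer(k)
  if (is.na(k) || k < 11L || k %% 2L == 0L)
    stopf("k must be an odd integer >= 11 (got %s)", k)
  if (is.character(assemblies) || methods::is(assemblies, "DNAStringSet"))
    assemblies <- list(assembly1 = assemblies)
  if (!length(assemblies)) stop("no sequences", call. = FALSE)
  if (is.null(names(assemblies)) || any(!nzchar(names(assemblies))))
    names(assemblies) <- paste0("assembly", seq_along(assemblies))

  ## flatten to per-contig records, uppercase, split at ambiguous bases
  recs <- list()   # each: list(assembly, contig, seq)
  splits <- list()
  for (a in names(assemblies)) {
    ss <- assemblies[[a]]
    if (methods::is(ss, "DNAStringSet")) ss <- as.character(ss)
    if (!length(ss)) next
    if (is.null(names(ss)) || any(!nzchar(names(ss))))
      names(ss) <- paste0("contig", seq_along(ss))
    ss <- toupper(ss)
    for (cn in names(ss)) {
      s <- ss[[cn]]
      pieces <- strsplit(s, "[^ACGT]+")[[1]]
      pieces <- pieces[nzchar(pieces)]
      if (length(pieces) == 1L && nchar(pieces) == nchar(s)) {
        recs[[length(recs) + 1L]] <- list(assembly = a, contig = cn, seq = s)
      } else {
        keep <- nchar(pieces) >= k
        splits[[length(splits) + 1L]] <- list(
          assembly = a, contig = cn, pieces = length(pieces),
          dropped = sum(!keep))
        pieces <- pieces[keep]
        for (i in seq_along(pieces))
          recs[[length(recs) + 1L]] <- list(
            assembly = a, contig = paste0(cn, ".", i), seq = pieces[[i]])
      }
    }
  }
  if (!length(recs)) stop("no sequences", call. = FALSE)
  seqLens <- vapply(recs, function(r) nchar(r$seq), integer(1))
  if (all(seqLens < k)) stop("k too large for input", call. = FALSE)
  if (any(seqLens < k)) {
    drop <- which(seqLens < k)
    for (i in drop)
      splits[[length(splits) + 1L]] <- list(
        assembly = recs[[i]]$assembly, contig = recs[[i]]$contig,
        pieces = 1L, dropped = 1L)
    recs <- recs[-drop]
  }

  g <- .buildGraphCore(recs, k)
  g@metadata <- list(k = k, splits = splits,
                     nAssemblies = length(unique(vapply(recs, `[[`, "", "assembly"))),
                     totalInputBases = sum(vapply(recs, function(r) nchar(r$seq), integer(1))))
  g
}

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("graphMetadata", function(x) standardGeneric("graphMetadata"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("graphMetadata", "UnitigGraph", function(x) x@metadata)

## core construction from a list of records list(assembly, contig, seq)
.buildGraphCore <- function(recs, k) {
  twin <- function(v) v + (v %% 2L) * 2L - 1L
  idOf <- function(v) (v + 1L) %/% 2L

  kmerFwd <- lapply(recs, function(r) kmersOf(r$seq, k))
  kmerRc <- lapply(recs, function(r) kmersRcOf(r$seq, k))
  allK <- unlist(kmerFwd, use.names = FALSE)
  allRc <- unlist(kmerRc, use.names = FALSE)
  isFwd <- allK <= allRc
  canon <- ifelse(isFwd, allK, allRc)
  K <- sort(unique(canon), method = "radix")
  nK <- length(K)
  vAll <- 2L * match(canon, K) - ifelse(isFwd, 1L, 0L)  # oriented node ids
  lens <- lengths(kmerFwd)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  vList <- lapply(seq_along(lens), function(i) vAll[starts[i]:ends[i]])

  ## observed oriented edges, closed under reverse complement, deduplicated
  oFrom <- unlist(lapply(vList, function(v) v[-length(v)]), use.names = FALSE)
  oTo <- unlist(lapply(vList, function(v) v[-1L]), use.names = FALSE)
  eFrom <- c(oFrom, twin(oTo))
  eTo <- c(oTo, twin(oFrom))
  keep <- !duplicated(eFrom * (2 * nK + 1) + eTo)
  eFrom <- eFrom[keep]; eTo <- eTo[keep]

  outdeg <- tabulate(eFrom, nbins = 2L * nK)
  succ <- integer(2L * nK)
  succ[eFrom] <- eTo  # trusted only where outdeg == 1

  ## merge rule: v -> succ(v) iff out-degree(v) == 1, in-degree(succ(v)) == 1
  ## (== out-degree(twin(succ(v)))), and the two nodes are distinct k-mers
  sv <- pmax(succ, 1L)
  mergeOut <- outdeg == 1L & succ > 0L & outdeg[twin(sv)] == 1L &
    idOf(sv) != idOf(seq_len(2L * nK))
  hasValidIn <- logical(2L * nK)
  hasValidIn[succ[mergeOut]] <- TRUE

  present <- logical(2L * nK)
  present[vAll] <- TRUE
  present[twin(unique(vAll))] <- TRUE

  startNodes <- which(present & !hasValidIn)
  ord <- order(K[idOf(startNodes)], startNodes %% 2L == 0L, method = "radix")
  startNodes <- startNodes[ord]

  claimed <- logical(nK)
  walk <- function(v0) {
    nodes <- integer(256L); nodes[1L] <- v0; m <- 1L
    cur <- v0
    while (mergeOut[cur]) {
      nxt <- succ[cur]
      if (claimed[idOf(nxt)] || nxt == v0) break  # palindrome/cycle guard
      m <- m + 1L
      if (m > length(nodes)) nodes <- c(nodes, integer(length(nodes)))
      nodes[m] <- nxt
      claimed[idOf(nxt)] <<- TRUE
      cur <- nxt
    }
    nodes[seq_len(m)]
  }
  chains <- vector("list", 0L)
  for (v0 in startNodes) {
    if (claimed[idOf(v0)]) next
    claimed[idOf(v0)] <- TRUE
    chains[[length(chains) + 1L]] <- walk(v0)
  }
  ## remaining ids lie on pure cycles; break each at its smallest k-mer
  rem <- which(!claimed)
  while (length(rem)) {
    v0 <- 2L * rem[1L] - 1L   # K is sorted: rem[1] is the smallest k-mer
    claimed[rem[1L]] <- TRUE
    chains[[length(chains) + 1L]] <- walk(v0)
    rem <- which(!claimed)
  }

  ## chain sequences (first k-mer + one base per further node)
  lastChar <- substring(K, k, k)
  firstChar <- substring(K, 1L, 1L)
  chainSeq <- vapply(chains, function(ch) {
    ids <- idOf(ch); plus <- ch %% 2L == 1L
    head <- if (plus[1L]) K[ids[1L]] else revcompChar(K[ids[1L]])
    if (length(ch) == 1L) return(head)
    lc <- ifelse(plus[-1L], lastChar[ids[-1L]], complementBase(firstChar[ids[-1L]]))
    paste0(head, paste(lc, collapse = ""))
  }, character(1))

  ## stored orientation: lexicographically smaller of sequence / revcomp
  chainRc <- revcompChar(chainSeq)
  flip <- chainRc < chainSeq
  chainSeq[flip] <- chainRc[flip]
  chains[flip] <- lapply(chains[flip], function(ch) rev(twin(ch)))

  ## unitig ids: decreasing length, ties broken by sequence
  ulen <- nchar(chainSeq)
  uord <- order(-ulen, chainSeq, method = "radix")
  chains <- chains[uord]; chainSeq <- chainSeq[uord]; ulen <- ulen[uord]
  nU <- length(chains)
  uKm <- ulen - k + 1L

  uOf <- integer(nK); uPos <- integer(nK); uStr <- integer(nK)
  for (u in seq_len(nU)) {
    ch <- chains[[u]]; ids <- idOf(ch)
    uOf[ids] <- u
    uPos[ids] <- seq_along(ch)
    uStr[ids] <- ifelse(ch %% 2L == 1L, 1L, -1L)
  }

  ## contig paths: run-length decomposition of each node walk into unitigs
  paths <- vector("list", length(vList))
  for (i in seq_along(vList)) {
    v <- vList[[i]]
    ids <- idOf(v); sgn <- ifelse(v %% 2L == 1L, 1L, -1L)
    u <- uOf[ids]; trav <- sgn * uStr[ids]; pos <- uPos[ids]
    m <- length(v)
    newStep <- if (m == 1L) TRUE else
      c(TRUE, !(u[-1L] == u[-m] & trav[-1L] == trav[-m] &
                pos[-1L] == pos[-m] + trav[-m]))
    idx <- which(newStep)
    paths[[i]] <- list(
      assembly = recs[[i]]$assembly, contig = recs[[i]]$contig,
      steps = u[idx],
      strand = ifelse(trav[idx] == 1L, "+", "-"),
      startOffset = if (trav[1L] == 1L) pos[1L] - 1L else uKm[u[1L]] - pos[1L],
      endOffset = if (trav[m] == 1L) uKm[u[m]] - pos[m] else pos[m] - 1L,
      length = nchar(recs[[i]]$seq))
  }
  depth <- tabulate(unlist(lapply(paths, `[[`, "steps")), nbins = nU)

  ## links: observed edges not consumed by compaction
  idV <- idOf(eFrom); idW <- idOf(eTo)
  travV <- ifelse(eFrom %% 2L == 1L, 1L, -1L) * uStr[idV]
  travW <- ifelse(eTo %% 2L == 1L, 1L, -1L) * uStr[idW]
  internal <- uOf[idV] == uOf[idW] & travV == travW &
    uPos[idW] == uPos[idV] + travV
  lf <- uOf[idV][!internal]; lt <- uOf[idW][!internal]
  lfo <- ifelse(travV[!internal] == 1L, "+", "-")
  lto <- ifelse(travW[!internal] == 1L, "+", "-")
  links <- data.frame(from = as.integer(lf), fromOrient = as.character(lfo),
                      to = as.integer(lt), toOrient = as.character(lto),
                      stringsAsFactors = FALSE)
  links <- links[!duplicated(links), , drop = FALSE]
  links <- links[order(links$from, links$fromOrient, links$to, links$toOrient,
                       method = "radix"), , drop = FALSE]
  rownames(links) <- NULL

  us <- Biostrings::DNAStringSet(chainSeq)
  names(us) <- as.character(seq_len(nU))
  methods::new("UnitigGraph", k = k, unitigs = us, depth = depth,
               links = links, paths = paths, metadata = list(k = k))
}

#' Reconstruct an input contig from its graph path
#'
#' Concatenates the oriented unitig sequences of a contig path, honouring the
#' (k-1)-base overlaps between consecutive steps, and trims the start/end
#' offsets. The result is byte-identical to the original (uppercased) contig.
#'
#' @param graph A [UnitigGraph-class].
#' @param path One element of \code{contigPaths(graph)}, or an integer index
#'   into that list.
#' @return Character scalar: the reconstructed contig sequence.
#' @examples
#' g <- buildUnitigGraph(list(a = c(c1 = "ACGTTGCAAGCTTGGACGATCGA")), k = 11)
#' reconstructContig(g, 1)
#' @export
reconstructContig <- function(graph, path) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  if (is.numeric(path)) path <- graph@paths[[path]]
  n <- length(graph@unitigs)
  if (any(path$steps < 1L) || any(path$steps > n))
    stop("corrupt path: unknown unitig id", call. = FALSE)
  k <- graph@k
  s <- as.character(graph@unitigs[path$steps])
  flip <- path$strand == "-"
  s[flip] <- revcompChar(s[flip])
  if (length(s) > 1L)
    s[-1L] <- substring(s[-1L], k, nchar(s[-1L]))
  full <- paste(s, collapse = "")
  substr(full, path$startOffset + 1L, nchar(full) - path$endOffset)
}

#' Decompress all contig paths of a graph back to sequences
#'
#' @param graph A [UnitigGraph-class].
#' @return A named list (one element per assembly) of named character vectors
#'   of contig sequences.
#' @export
decompressContigs <- function(graph) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  out <- list()
  for (p in graph@paths) {
    s <- reconstructContig(graph, p)
    if (is.null(out[[p$assembly]])) out[[p$assembly]] <- character(0)
    out[[p$assembly]][[p$contig]] <- s
  }
  out
}

## sequence spelled by an oriented unitig walk (ids + strands), honouring
## (k-1)-overlaps; circular=TRUE drops the final k-1 wrap-around bases
walkSequence <- function(graph, steps, strand, circular = FALSE) {
  if (!length(steps)) return("")
  k <- graph@k
  s <- as.character(graph@unitigs[steps])
  flip <- strand == "-"
  s[flip] <- revcompChar(s[flip])
  if (length(s) > 1L)
    s[-1L] <- substring(s[-1L], k, nchar(s[-1L]))
  out <- paste(s, collapse = "")
  if (circular) out <- substr(out, 1L, nchar(out) - (k - 1L))
  out
}
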