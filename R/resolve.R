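## Consensus resolution of one trimmed cluster.
##
## A fresh k-mer graph is built from the trimmed member contigs. Anchors are
## unitigs occurring exactly once in every contig with consistent relative
## (cyclic) order and orientation; they scaffold the consensus. Between
## consecutive anchors the member contigs vote: identical intervening unitig
## walks are grouped, and the most supported walk (the bridge) is selected.
## The consensus concatenates anchors and winning bridges honouring the
## (k-1)-base overlaps.

## normalized oriented step view of a path: optionally flipped to the
## reference orientation; for paths that wrap (first and last step are the
## two halves of one unitig split at the contig origin) the duplicate last
## step is removed and `wraps` is TRUE
stepView <- function(graph, p, flip = FALSE) {
  steps <- p$steps; strand <- p$strand
  if (flip) {
    steps <- rev(steps)
    strand <- rev(ifelse(strand == "+", "-", "+"))
  }
  m <- length(steps)
  wraps <- FALSE
  if (m >= 2L && steps[1L] == steps[m] && strand[1L] == strand[m]) {
    ## a full cyclic traversal splits one unitig at the contig origin: the
    ## partial first and last steps then tile that unitig exactly once
    ## (the contig itself lacks the k-1 origin-spanning k-mers, so the
    ## condition is on bases, not k-mers)
    uLen <- Biostrings::width(graph@unitigs)[steps[1L]]
    if (p$startOffset + p$endOffset == uLen) {
      steps <- steps[-m]; strand <- strand[-m]
      wraps <- TRUE
    }
  }
  closes <- wraps
  if (!closes && p$startOffset == 0L && p$endOffset == 0L && m >= 1L) {
    ## closed if the path's last oriented end links back to its first start
    lk <- graph@links
    closes <- any(lk$from == steps[length(steps)] &
                  lk$fromOrient == strand[length(strand)] &
                  lk$to == steps[1L] & lk$toOrient == strand[1L])
  }
  list(steps = steps, strand = strand, wraps = wraps, closes = closes)
}

## longest increasing subsequence (indices) of a numeric vector
lisIndices <- function(x) {
  n <- length(x)
  if (n <= 1L) return(seq_len(n))
  best <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L; prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(0)
  while (i > 0L) { out <- c(i, out); i <- prev[i] }
  out
}

#' Find consensus anchors in a cluster graph
#'
#' Anchors are unitigs that occur exactly once in every contig path of the
#' cluster, with pairwise order (cyclic order for circular clusters) and
#' relative orientation consistent across all contigs. Inconsistent
#' candidates are dropped greedily, smallest unitig first, until the
#' remaining set is consistent. The result is ordered along the first
#' contig's path.
#'
#' @param graph A per-cluster [UnitigGraph-class] built from the trimmed
#'   member contigs.
#' @return List with \code{anchors} (integer unitig ids in reference order),
#'   \code{circular} (logical), \code{flip} (per-path orientation flags) and
#'   \code{paths} (the normalized per-path step views). Zero anchors are
#'   reported as \code{anchors = integer(0)}.
#' @export
findAnchors <- function(graph) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  ps <- graph@paths
  nP <- length(ps)
  stopifnot(nP >= 1L)
  norm0 <- lapply(ps, function(p) stepView(graph, p, flip = FALSE))
  ## a path whose origin falls near one of its own private variants starts
  ## and ends in different unitigs, so the unitig-level wrap test fails even
  ## though the contig is circular; accept a junction witness instead: the
  ## wrap-around window occurs contiguously in another member contig
  k <- graph@k
  if (nP > 1L && !all(vapply(norm0, `[[`, TRUE, "closes"))) {
    seqsAll <- vapply(ps, function(p) reconstructContig(graph, p),
                      character(1))
    rcAll <- revcompChar(seqsAll)
    ## the witness tolerates scattered private errors on either side of the
    ## junction (in this contig or the witness): short exact words anywhere
    ## in the window seed the search, then the whole window is verified with
    ## a mismatch allowance
    win <- 2L * (k - 1L)
    maxMM <- max(4L, ceiling(0.05 * win))
    w0 <- 20L
    fuzzyWitness <- function(window, host) {
      offs <- unique(c(seq(1L, win - w0 + 1L, by = w0 %/% 2L), win - w0 + 1L))
      for (off in offs) {
        word <- substr(window, off, off + w0 - 1L)
        hits <- gregexpr(word, host, fixed = TRUE)[[1L]]
        if (hits[1L] == -1L) next
        for (q in hits) {
          start <- q - off + 1L
          if (start < 1L) next
          s2 <- substr(host, start, start + win - 1L)
          if (nchar(s2) == win && hammingDist(window, s2) <= maxMM)
            return(TRUE)
        }
      }
      FALSE
    }
    for (i in seq_len(nP)) {
      if (norm0[[i]]$closes) next
      n <- nchar(seqsAll[i])
      if (n < win) next
      window <- paste0(substr(seqsAll[i], n - k + 2L, n),
                       substr(seqsAll[i], 1L, k - 1L))
      for (j in seq_len(nP)[-i]) {
        if (fuzzyWitness(window, seqsAll[j]) ||
            fuzzyWitness(window, rcAll[j])) {
          norm0[[i]]$closes <- TRUE
          break
        }
      }
    }
  }
  circular <- all(vapply(norm0, `[[`, TRUE, "closes"))

  nU <- length(graph@unitigs)
  counts <- vapply(norm0, function(np) tabulate(np$steps, nbins = nU),
                   integer(nU))
  counts <- matrix(counts, nrow = nU)
  cand <- which(apply(counts == 1L, 1L, all))
  if (!length(cand))
    return(list(anchors = integer(0), circular = circular,
                flip = rep(FALSE, nP), paths = norm0))

  ## orient every path to the reference (path 1) by majority candidate strand
  refStrand <- vapply(cand, function(u)
    norm0[[1L]]$strand[match(u, norm0[[1L]]$steps)], character(1))
  flip <- vapply(seq_len(nP), function(i) {
    s <- vapply(cand, function(u)
      norm0[[i]]$strand[match(u, norm0[[i]]$steps)], character(1))
    mean(s != refStrand) > 0.5
  }, logical(1))
  flip[1L] <- FALSE
  norm <- lapply(seq_len(nP), function(i)
    if (flip[i]) stepView(graph, ps[[i]], flip = TRUE) else norm0[[i]])

  ## drop candidates whose orientation still disagrees with the reference
  agree <- vapply(cand, function(u) {
    s <- vapply(norm, function(np) np$strand[match(u, np$steps)], character(1))
    all(s == s[1L])
  }, logical(1))
  cand <- cand[agree]

  ## order consistency: each path's candidate order must equal the reference
  ## order (a rotation of it, for circular clusters); offenders are removed
  ## smallest-unitig-first
  uLen <- Biostrings::width(graph@unitigs)
  repeat {
    if (length(cand) <= 1L) break
    refPos <- match(cand, norm[[1L]]$steps)
    refOrder <- cand[order(refPos)]
    rank <- stats::setNames(seq_along(refOrder), refOrder)
    offenders <- integer(0)
    for (i in seq_len(nP)[-1L]) {
      pos <- match(refOrder, norm[[i]]$steps)
      seqAlong <- refOrder[order(pos)]       # candidate order in path i
      r <- rank[as.character(seqAlong)]
      if (circular) {
        ## rotate so the smallest reference rank comes first
        j <- which.min(r)
        r <- c(r[j:length(r)], r[seq_len(j - 1L)])
        seqAlong <- c(seqAlong[j:length(seqAlong)],
                      seqAlong[seq_len(j - 1L)])
      }
      keepIdx <- lisIndices(r)
      offenders <- c(offenders, seqAlong[-keepIdx])
    }
    offenders <- unique(offenders)
    if (!length(offenders)) break
    drop <- offenders[order(uLen[offenders], -offenders)][1L]
    cand <- setdiff(cand, drop)
  }
  refPos <- match(cand, norm[[1L]]$steps)
  list(anchors = cand[order(refPos)], circular = circular, flip = flip,
       paths = norm)
}

## walk between two cyclic positions (exclusive) of a normalized path
gapWalk <- function(np, from, to, circular) {
  m <- length(np$steps)
  if (circular) {
    if (to == from) idx <- integer(0)      # single-anchor full cycle
    else if (to > from) idx <- if (to - from > 1L) (from + 1L):(to - 1L) else integer(0)
    else idx <- c(if (from < m) (from + 1L):m else integer(0),
                  if (to > 1L) seq_len(to - 1L) else integer(0))
    if (to == from && m > 1L)              # whole cycle between the anchor and itself
      idx <- c(if (from < m) (from + 1L):m else integer(0),
               if (from > 1L) seq_len(from - 1L) else integer(0))
  } else {
    idx <- if (to - from > 1L) (from + 1L):(to - 1L) else integer(0)
  }
  list(steps = np$steps[idx], strand = np$strand[idx])
}

walkKey <- function(w) paste(paste0(w$steps, w$strand), collapse = ",")

## per-edge majority walk from oriented anchor (a, sa) to (b, sb): at every
## step take the oriented edge traversed by the most member contigs.
## Recovers the site-wise majority when whole-gap walks are all distinct
## (dense bubbles). Returns NULL when (b, sb) is unreachable within the cap.
greedyGapWalk <- function(fullWalks, a, sa, b, sb) {
  eFrom <- character(0); eTo <- character(0)
  for (w in fullWalks) {
    m <- length(w$steps)
    if (m < 2L) next
    keys <- paste0(w$steps, w$strand)
    eFrom <- c(eFrom, keys[-m]); eTo <- c(eTo, keys[-1L])
  }
  if (!length(eFrom)) return(NULL)
  ek <- paste(eFrom, eTo)
  cnt <- table(ek)
  uniq <- !duplicated(ek)
  edges <- data.frame(from = eFrom[uniq], to = eTo[uniq],
                      n = as.integer(cnt[ek[uniq]]),
                      stringsAsFactors = FALSE)
  adj <- split(edges[c("to", "n")], edges$from)
  target <- paste0(b, sb)
  cur <- paste0(a, sa)
  cap <- 3L * max(lengths(lapply(fullWalks, `[[`, "steps"))) + 50L
  steps <- integer(0); strand <- character(0)
  for (it in seq_len(cap)) {
    opts <- adj[[cur]]
    if (is.null(opts) || !nrow(opts)) return(NULL)
    oid <- as.integer(sub("[+-]$", "", opts$to))
    ostr <- sub("^[0-9]+", "", opts$to)
    ord <- order(-opts$n, oid, ostr == "-")
    nxt <- opts$to[ord[1L]]
    if (nxt == target)
      return(list(steps = steps, strand = strand))
    steps <- c(steps, as.integer(sub("[+-]$", "", nxt)))
    strand <- c(strand, sub("^[0-9]+", "", nxt))
    cur <- nxt
  }
  NULL
}

## bases a walk adds to the consensus (each step adds len - (k-1))
walkAddedBases <- function(graph, steps)
  if (!length(steps)) 0L else
    sum(Biostrings::width(graph@unitigs)[steps]) - length(steps) * (graph@k - 1L)

#' Build majority-vote bridges between consecutive anchors
#'
#' For each consecutive anchor pair (cyclically for circular clusters) the
#' intervening unitig walk is collected from every contig, identical walks
#' are grouped, and the group size is the candidate's support. A bridge is
#' ambiguous when its top candidate is not strictly most common or is
#' supported by fewer than \code{bridgeMinFraction} of the contigs. Ties are
#' broken by highest support, then shortest walk in bases, then
#' lexicographically smallest spelled sequence.
#'
#' @param graph The cluster [UnitigGraph-class].
#' @param anchorInfo Result of [findAnchors()].
#' @param bridgeMinFraction Minimum support fraction for a confident bridge
#'   (default 0.25).
#' @return List of bridges: \code{fromAnchor}, \code{toAnchor},
#'   \code{candidates} (walks with support), \code{chosen} (index),
#'   \code{support}, \code{total}, \code{ambiguous}, \code{lowSupport}.
#' @export
buildBridges <- function(graph, anchorInfo, bridgeMinFraction = 0.25) {
  anc <- anchorInfo$anchors
  stopifnot(length(anc) >= 1L)
  norm <- anchorInfo$paths
  nP <- length(norm)
  circular <- anchorInfo$circular
  nGaps <- if (circular) length(anc) else length(anc) - 1L
  bridges <- vector("list", max(nGaps, 0L))
  for (gi in seq_len(max(nGaps, 0L))) {
    a <- anc[gi]
    b <- anc[if (gi == length(anc)) 1L else gi + 1L]
    walks <- lapply(norm, function(np)
      gapWalk(np, match(a, np$steps), match(b, np$steps), circular))
    keys <- vapply(walks, walkKey, character(1))
    grp <- split(seq_len(nP), keys)
    cands <- lapply(grp, function(ix) walks[[ix[1L]]])
    support <- lengths(grp)
    bases <- vapply(cands, function(w) walkAddedBases(graph, w$steps),
                    numeric(1))
    spelled <- vapply(cands, function(w)
      if (length(w$steps)) walkSequence(graph, w$steps, w$strand) else "",
      character(1))
    ord <- order(-support, bases, spelled, method = "radix")
    cands <- cands[ord]; support <- as.integer(support[ord])
    chosen <- 1L
    lowSupport <- support[1L] < bridgeMinFraction * nP
    ambiguous <- (length(support) > 1L && support[2L] == support[1L]) ||
      lowSupport
    walk <- cands[[chosen]]
    chosenSupport <- support[1L]
    method <- "vote"
    if (lowSupport) {
      ## no whole-gap candidate is convincing; fall back to the per-edge
      ## majority walk through the gap subgraph
      aStr <- vapply(norm, function(np) np$strand[match(a, np$steps)],
                     character(1))
      bStr <- vapply(norm, function(np) np$strand[match(b, np$steps)],
                     character(1))
      fullWalks <- lapply(seq_len(nP), function(i)
        list(steps = c(a, walks[[i]]$steps, b),
             strand = c(aStr[i], walks[[i]]$strand, bStr[i])))
      gw <- greedyGapWalk(fullWalks, a, aStr[1L], b, bStr[1L])
      if (!is.null(gw)) {
        walk <- gw
        method <- "edge_majority"
        lowSupport <- FALSE
        chosenSupport <- as.integer(sum(keys == walkKey(gw)))
      }
    }
    bridges[[gi]] <- list(
      fromAnchor = a, toAnchor = b, candidates = cands,
      supportCounts = support, chosen = chosen, walk = walk,
      method = method, support = chosenSupport, total = nP,
      ambiguous = ambiguous, lowSupport = lowSupport)
  }
  bridges
}

#' Resolve one cluster to a consensus sequence
#'
#' Builds the cluster graph from the trimmed member contigs, finds anchors,
#' votes on bridges (unambiguous bridges first, then ambiguous ones in
#' decreasing support order) and concatenates the winning walks into a single
#' consensus. Circular consensus sequences are rotated to begin at the
#' largest anchor. With no anchors, the longest retained contig is returned
#' with a fallback flag; a winning bridge below \code{bridgeMinFraction}
#' support marks the cluster unresolved.
#'
#' @param seqs Named character vector: trimmed, retained member contigs (one
#'   per input assembly).
#' @param k K-mer size for the cluster graph (default 51).
#' @param clusterId Integer id recorded in the result.
#' @param bridgeMinFraction See [buildBridges()].
#' @return A [ConsensusSeq-class]. The cluster graph is attached as attribute
#'   \code{"graph"}.
#' @export
resolveCluster <- function(seqs, k = 51L, clusterId = 1L,
                           bridgeMinFraction = 0.25) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  g <- buildUnitigGraph(lapply(seqs, function(s) c(contig = s)), k = k)
  info <- findAnchors(g)
  nP <- length(g@paths)
  emptyBr <- data.frame(fromAnchor = integer(0), toAnchor = integer(0),
                        support = integer(0), total = integer(0),
                        ambiguous = logical(0))
  if (!length(info$anchors)) {
    ## fallback: longest retained contig
    lens <- nchar(seqs)
    pick <- which.max(lens)
    cons <- methods::new("ConsensusSeq", clusterId = as.integer(clusterId),
                         sequence = unname(toupper(seqs[[pick]])),
                         topology = if (info$circular) "circular" else "linear",
                         status = "fallback", anchors = integer(0),
                         bridges = emptyBr)
    attr(cons, "graph") <- g
    return(cons)
  }
  bridges <- buildBridges(g, info, bridgeMinFraction)
  if (any(vapply(bridges, `[[`, TRUE, "lowSupport"))) {
    cons <- methods::new("ConsensusSeq", clusterId = as.integer(clusterId),
                         sequence = "", topology = "linear",
                         status = "unresolved", anchors = info$anchors,
                         bridges = emptyBr)
    attr(cons, "graph") <- g
    return(cons)
  }
  anc <- info$anchors
  uLen <- Biostrings::width(g@unitigs)
  ref <- info$paths[[1L]]
  ancStrand <- vapply(anc, function(u) ref$strand[match(u, ref$steps)],
                      character(1))
  if (info$circular) {
    ## rotate cyclic anchor order to start at the largest anchor
    start <- which(uLen[anc] == max(uLen[anc]))
    start <- start[order(anc[start])][1L]
    rot <- function(x, s) if (s == 1L) x else c(x[s:length(x)], x[seq_len(s - 1L)])
    anc <- rot(anc, start); ancStrand <- rot(ancStrand, start)
    bridges <- rot(bridges, start)
    steps <- integer(0); strand <- character(0)
    for (i in seq_along(anc)) {
      w <- bridges[[i]]$walk
      steps <- c(steps, anc[i], w$steps)
      strand <- c(strand, ancStrand[i], w$strand)
    }
    seqOut <- walkSequence(g, steps, strand, circular = TRUE)
    topo <- "circular"
  } else {
    ## linear: resolve the two terminal segments by the same vote
    m <- length(anc)
    termWalk <- function(np, side) {
      pos <- match(if (side == "pre") anc[1L] else anc[m], np$steps)
      if (side == "pre") {
        idx <- if (pos > 1L) seq_len(pos - 1L) else integer(0)
      } else {
        idx <- if (pos < length(np$steps)) (pos + 1L):length(np$steps)
        else integer(0)
      }
      list(steps = np$steps[idx], strand = np$strand[idx])
    }
    vote <- function(side, offField) {
      walks <- lapply(info$paths, termWalk, side = side)
      offs <- vapply(seq_along(walks), function(i) {
        p <- g@paths[[i]]
        if (side == "pre") { if (info$flip[i]) p$endOffset else p$startOffset }
        else { if (info$flip[i]) p$startOffset else p$endOffset }
      }, integer(1))
      keys <- paste(vapply(walks, walkKey, character(1)), offs)
      grp <- split(seq_along(walks), keys)
      ord <- order(-lengths(grp),
                   vapply(grp, function(ix)
                     walkAddedBases(g, walks[[ix[1L]]]$steps), numeric(1)),
                   method = "radix")
      ix <- grp[[ord[1L]]][1L]
      list(walk = walks[[ix]], off = offs[ix])
    }
    pre <- vote("pre"); post <- vote("post")
    steps <- c(pre$walk$steps, anc[1L])
    strand <- c(pre$walk$strand, ancStrand[1L])
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        w <- bridges[[i]]$walk
        steps <- c(steps, w$steps, anc[i + 1L])
        strand <- c(strand, w$strand, ancStrand[i + 1L])
      }
    }
    steps <- c(steps, post$walk$steps)
    strand <- c(strand, post$walk$strand)
    full <- walkSequence(g, steps, strand, circular = FALSE)
    seqOut <- substr(full, pre$off + 1L, nchar(full) - post$off)
    topo <- "linear"
  }
  brDf <- if (length(bridges)) data.frame(
    fromAnchor = vapply(bridges, `[[`, 1L, "fromAnchor"),
    toAnchor = vapply(bridges, `[[`, 1L, "toAnchor"),
    support = vapply(bridges, `[[`, 1L, "support"),
    total = vapply(bridges, `[[`, 1L, "total"),
    ambiguous = vapply(bridges, `[[`, TRUE, "ambiguous")) else emptyBr
  cons <- methods::new("ConsensusSeq", clusterId = as.integer(clusterId),
                       sequence = seqOut, topology = topo,
                       status = "resolved", anchors = anc, bridges = brDf)
  attr(cons, "graph") <- g
  cons
}

#' Manually remove or duplicate unitigs in a graph
#'
#' Removal deletes a unitig and its links and splices every affected contig
#' path (a path traversing the unitig splits into fragments). Duplication
#' copies a unitig under a fresh id, including its links.
#'
#' @param graph A [UnitigGraph-class].
#' @param removeIds,duplicateIds Integer unitig ids.
#' @return The edited [UnitigGraph-class].
#' @export
cleanGraph <- function(graph, removeIds = integer(0),
                       duplicateIds = integer(0)) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  n <- length(graph@unitigs)
  bad <- setdiff(c(removeIds, duplicateIds), seq_len(n))
  if (length(bad))
    stopf("unknown unitig id(s) %s; valid ids are 1..%d", fmtIds(bad), n)
  us <- as.character(graph@unitigs)
  depth <- graph@depth
  links <- graph@links
  paths <- graph@paths

  for (d in duplicateIds) {
    us <- c(us, us[d])
    depth <- c(depth, 0L)
    newId <- length(us)
    dl <- links[links$from == d | links$to == d, , drop = FALSE]
    if (nrow(dl)) {
      dl$from[dl$from == d] <- newId
      dl$to[dl$to == d] <- newId
      links <- rbind(links, dl)
    }
  }
  if (length(removeIds)) {
    links <- links[!(links$from %in% removeIds | links$to %in% removeIds), ,
                   drop = FALSE]
    newPaths <- list()
    for (p in paths) {
      hit <- p$steps %in% removeIds
      if (!any(hit)) { newPaths[[length(newPaths) + 1L]] <- p; next }
      runs <- rle(!hit)
      endIdx <- cumsum(runs$lengths); startIdx <- endIdx - runs$lengths + 1L
      kept <- which(runs$values)
      for (fi in seq_along(kept)) {
        i0 <- startIdx[kept[fi]]; i1 <- endIdx[kept[fi]]
        frag <- p
        frag$contig <- if (length(kept) == 1L) p$contig else
          paste0(p$contig, ".", fi)
        frag$steps <- p$steps[i0:i1]
        frag$strand <- p$strand[i0:i1]
        frag$startOffset <- if (i0 == 1L) p$startOffset else 0L
        frag$endOffset <- if (i1 == length(p$steps)) p$endOffset else 0L
        frag$length <- NA_integer_
        newPaths[[length(newPaths) + 1L]] <- frag
      }
    }
    paths <- newPaths
    ## reindex remaining unitigs
    keep <- setdiff(seq_along(us), removeIds)
    remap <- integer(length(us)); remap[keep] <- seq_along(keep)
    us <- us[keep]; depth <- depth[keep]
    links$from <- remap[links$from]; links$to <- remap[links$to]
    paths <- lapply(paths, function(p) { p$steps <- remap[p$steps]; p })
  }
  uss <- Biostrings::DNAStringSet(us)
  names(uss) <- as.character(seq_along(us))
  rownames(links) <- NULL
  g <- methods::new("UnitigGraph", k = graph@k, unitigs = uss,
                    depth = tabulate(unlist(lapply(paths, `[[`, "steps")),
                                     nbins = length(us)),
                    links = links, paths = paths,
                    metadata = graph@metadata)
  g@paths <- lapply(g@paths, function(p) {
    if (is.na(p$length)) p$length <- nchar(reconstructContig(g, p))
    p
  })
  g
}
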