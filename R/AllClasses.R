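#' UnitigGraph: a lossless compacted De Bruijn graph of input assemblies
#'
#' A compacted De Bruijn graph (cDBG) built from one or more bacterial genome
#' assemblies. Segments are maximal non-branching unitigs; adjacent unitigs
#' overlap by exactly \code{k - 1} bases. Every input contig is recorded as an
#' oriented walk through the graph (a contig path) together with start/end
#' offsets, so the original sequence can be reconstructed byte-exactly.
#'
#' @slot k Integer, the k-mer length (odd, >= 11).
#' @slot unitigs A [Biostrings::DNAStringSet] of unitig sequences, named by
#'   unitig id ("1", "2", ...). Ids are assigned in decreasing order of unitig
#'   length (ties broken by sequence), so numbering is deterministic and
#'   independent of input order.
#' @slot depth Integer vector parallel to \code{unitigs}: number of contig-path
#'   steps traversing each unitig.
#' @slot links A data.frame with columns \code{from}, \code{fromOrient},
#'   \code{to}, \code{toOrient} holding oriented (k-1)-overlap adjacencies.
#'   Every link is stored in both directions (a link and its reverse-complement
#'   twin are the same adjacency).
#' @slot paths A list of contig paths; each element is a list with fields
#'   \code{assembly}, \code{contig}, \code{steps} (integer unitig ids),
#'   \code{strand} (character "+"/"-"), \code{startOffset}, \code{endOffset}
#'   (bases trimmed from the oriented first/last unitig) and \code{length}.
#' @slot metadata List of build provenance: parameters and any contig splits
#'   performed at ambiguous (non-ACGT) bases.
#'
#' @seealso [buildUnitigGraph()], [reconstructContig()], [writeGFA()]
#' @name UnitigGraph-class
#' @rdname UnitigGraph-class
#' @exportClass UnitigGraph
setClass("UnitigGraph",
  representation(
    k = "integer",
    unitigs = "DNAStringSet",
    depth = "integer",
    links = "data.frame",
    paths = "list",
    metadata = "list"
  )
)

setValidity("UnitigGraph", function(object) {
  msg <- character(0)
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 11L || k %% 2L == 0L)
    msg <- c(msg, "k must be a single odd integer >= 11")
  n <- length(object@unitigs)
  if (length(object@depth) != n)
    msg <- c(msg, "depth must be parallel to unitigs")
  if (n && any(Biostrings::width(object@unitigs) < k))
    msg <- c(msg, "all unitigs must be at least k bases long")
  lk <- object@links
  need <- c("from", "fromOrient", "to", "toOrient")
  if (!all(need %in% names(lk))) {
    msg <- c(msg, "links must have from/fromOrient/to/toOrient columns")
  } else if (nrow(lk)) {
    if (any(lk$from < 1L | lk$from > n | lk$to < 1L | lk$to > n))
      msg <- c(msg, "links reference unknown unitig ids")
    ## mirrored-link invariant: twin of (a,oa,b,ob) is (b,flip(ob),a,flip(oa))
    flip <- function(o) ifelse(o == "+", "-", "+")
    key <- paste(lk$from, lk$fromOrient, lk$to, lk$toOrient)
    twin <- paste(lk$to, flip(lk$toOrient), lk$from, flip(lk$fromOrient))
    if (!all(twin %in% key))
      msg <- c(msg, "links are not mirrored on partner unitigs")
  }
  for (p in object@paths) {
    if (length(p$steps) && (any(p$steps < 1L) || any(p$steps > n))) {
      msg <- c(msg, "a contig path references unknown unitig ids")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClusterSet: UPGMA tree plus QC-filtered contig clusters
#'
#' Result of clustering the contig paths of a [UnitigGraph-class] into groups
#' that ideally correspond one-to-one with the replicons of the genome
#' (chromosome, plasmids). Holds the pairwise graph-path distance matrix, the
#' UPGMA tree built from it, and the refined, QC-filtered clusters.
#'
#' @slot labels Character vector of contig identifiers ("assembly:contig").
#' @slot distances Symmetric numeric matrix of path distances in [0, 1].
#' @slot tree The UPGMA tree as returned by [buildUpgma()] (list with
#'   \code{merge}, \code{height} (ultrametric node heights, i.e. half the merge
#'   distance) and \code{labels}).
#' @slot clusters List of clusters; each is a list with fields \code{id},
#'   \code{members} (contig identifiers), \code{status} ("pass"/"fail"),
#'   \code{failReason} ("none", "too_few_assemblies", "contained",
#'   "user_excluded") and \code{perAssembly} (named member counts).
#' @slot parameters List of the clustering parameters used.
#'
#' @seealso [clusterContigs()], [cutTree()], [qcFilter()]
#' @name ClusterSet-class
#' @rdname ClusterSet-class
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(
    labels = "character",
    distances = "matrix",
    tree = "list",
    clusters = "list",
    parameters = "list"
  )
)

setValidity("ClusterSet", function(object) {
  msg <- character(0)
  d <- object@distances
  if (nrow(d) != length(object@labels) || ncol(d) != length(object@labels))
    msg <- c(msg, "distance matrix dimensions must match labels")
  if (length(d) && (any(d < 0) || any(d > 1) || any(abs(d - t(d)) > 1e-12) ||
                    any(diag(d) != 0)))
    msg <- c(msg, "distances must be symmetric, zero-diagonal, in [0,1]")
  passMembers <- unlist(lapply(object@clusters, function(cl)
    if (identical(cl$status, "pass")) cl$members else character(0)))
  if (anyDuplicated(passMembers))
    msg <- c(msg, "passing clusters must be disjoint")
  for (cl in object@clusters) {
    if (!all(cl$members %in% object@labels)) {
      msg <- c(msg, "cluster members must be known contig labels")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusSeq: one resolved consensus sequence for a contig cluster
#'
#' The product of [resolveCluster()]: a single consensus sequence for one
#' replicon, with topology, the anchors used as scaffold points, and
#' per-bridge support provenance.
#'
#' @slot clusterId Integer cluster id.
#' @slot sequence Character scalar, the consensus DNA sequence.
#' @slot topology "circular" or "linear".
#' @slot status "resolved" (anchor/bridge consensus), "fallback" (no anchors;
#'   longest retained contig used) or "unresolved".
#' @slot anchors Integer vector of anchor unitig ids in consensus order.
#' @slot bridges data.frame of bridge provenance: \code{fromAnchor},
#'   \code{toAnchor}, \code{support}, \code{total}, \code{ambiguous}.
#'
#' @seealso [resolveCluster()], [combineClusters()]
#' @name ConsensusSeq-class
#' @rdname ConsensusSeq-class
#' @exportClass ConsensusSeq
setClass("ConsensusSeq",
  representation(
    clusterId = "integer",
    sequence = "character",
    topology = "character",
    status = "character",
    anchors = "integer",
    bridges = "data.frame"
  )
)

setValidity("ConsensusSeq", function(object) {
  msg <- character(0)
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  if (!object@status %in% c("resolved", "fallback", "unresolved"))
    msg <- c(msg, "status must be resolved/fallback/unresolved")
  if (object@status != "unresolved" &&
      (length(object@sequence) != 1L || !nzchar(object@sequence)))
    msg <- c(msg, "resolved consensus must carry a non-empty sequence")
  if (length(msg)) msg else TRUE
})

#' @describeIn UnitigGraph-class Compact summary of the graph.
#' @param object A \code{UnitigGraph}.
#' @export
setMethod("show", "UnitigGraph", function(object) {
  n <- length(object@unitigs)
  cat("UnitigGraph (k=", object@k, "): ", n, " unitigs, ",
      sum(Biostrings::width(object@unitigs)), " bp, ",
      nrow(object@links), " oriented links, ",
      length(object@paths), " contig paths\n", sep = "")
})

#' @describeIn ClusterSet-class Compact summary of the clustering.
#' @param object A \code{ClusterSet}.
#' @export
setMethod("show", "ClusterSet", function(object) {
  st <- vapply(object@clusters, `[[`, "", "status")
  cat("ClusterSet: ", length(object@labels), " contigs, ",
      length(object@clusters), " clusters (", sum(st == "pass"), " pass, ",
      sum(st != "pass"), " fail)\n", sep = "")
})

#' @describeIn ConsensusSeq-class Compact summary of the consensus.
#' @param object A \code{ConsensusSeq}.
#' @export
setMethod("show", "ConsensusSeq", function(object) {
  cat("ConsensusSeq cluster ", object@clusterId, ": ",
      if (object@status == "unresolved") "unresolved"
      else paste0(nchar(object@sequence), " bp, ", object@topology,
                  " (", object@status, ")"),
      ", ", length(object@anchors), " anchors\n", sep = "")
})
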