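#' Accessors for UnitigGraph objects
#'
#' \code{kmerSize} returns the k-mer length, \code{unitigSeqs} the unitig
#' sequences as a [Biostrings::DNAStringSet], \code{unitigDepth} the per-unitig
#' traversal counts, \code{unitigLinks} the oriented link table,
#' \code{contigPaths} the list of contig paths and \code{pathNames} their
#' "assembly:contig" identifiers.
#'
#' @param x A [UnitigGraph-class].
#' @return See individual descriptions above.
#' @examples
#' g <- buildUnitigGraph(c(asm1.contig1 = "ACGTTGCAAGCTTGGACGATCGA"), k = 11)
#' kmerSize(g)
#' unitigSeqs(g)
#' @name UnitigGraph-accessors
NULL

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("kmerSize", "UnitigGraph", function(x) x@k)

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("unitigSeqs", function(x) standardGeneric("unitigSeqs"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("unitigSeqs", "UnitigGraph", function(x) x@unitigs)

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("unitigDepth", function(x) standardGeneric("unitigDepth"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("unitigDepth", "UnitigGraph", function(x) x@depth)

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("unitigLinks", function(x) standardGeneric("unitigLinks"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("unitigLinks", "UnitigGraph", function(x) x@links)

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("contigPaths", function(x) standardGeneric("contigPaths"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("contigPaths", "UnitigGraph", function(x) x@paths)

#' @rdname UnitigGraph-accessors
#' @export
setGeneric("pathNames", function(x) standardGeneric("pathNames"))
#' @rdname UnitigGraph-accessors
#' @export
setMethod("pathNames", "UnitigGraph", function(x)
  vapply(x@paths, function(p) paste0(p$assembly, ":", p$contig), character(1)))

#' Accessors for ClusterSet objects
#'
#' \code{clusters} returns the cluster list, \code{clusterLabels} the contig
#' identifiers, \code{clusterDistances} the pairwise distance matrix and
#' \code{upgmaTree} the UPGMA tree structure.
#'
#' @param x A [ClusterSet-class].
#' @name ClusterSet-accessors
NULL

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname ClusterSet-accessors
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterLabels", "ClusterSet", function(x) x@labels)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterDistances", function(x) standardGeneric("clusterDistances"))
#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterDistances", "ClusterSet", function(x) x@distances)

#' @rdname ClusterSet-accessors
#' @export
setGeneric("upgmaTree", function(x) standardGeneric("upgmaTree"))
#' @rdname ClusterSet-accessors
#' @export
setMethod("upgmaTree", "ClusterSet", function(x) x@tree)

#' Accessors for ConsensusSeq objects
#'
#' @param x A [ConsensusSeq-class].
#' @name ConsensusSeq-accessors
NULL

#' @rdname ConsensusSeq-accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname ConsensusSeq-accessors
#' @export
setMethod("consensusSeq", "ConsensusSeq", function(x) x@sequence)

#' @rdname ConsensusSeq-accessors
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))
#' @rdname ConsensusSeq-accessors
#' @export
setMethod("topology", "ConsensusSeq", function(x) x@topology)

#' @rdname ConsensusSeq-accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname ConsensusSeq-accessors
#' @export
setMethod("anchors", "ConsensusSeq", function(x) x@anchors)

#' @rdname ConsensusSeq-accessors
#' @export
setGeneric("bridgeSupport", function(x) standardGeneric("bridgeSupport"))
#' @rdname ConsensusSeq-accessors
#' @export
setMethod("bridgeSupport", "ConsensusSeq", function(x) x@bridges)

#' @rdname ConsensusSeq-accessors
#' @export
setGeneric("resolutionStatus", function(x) standardGeneric("resolutionStatus"))
#' @rdname ConsensusSeq-accessors
#' @export
setMethod("resolutionStatus", "ConsensusSeq", function(x) x@status)
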