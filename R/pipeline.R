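## Fully automated end-to-end consensus assembly:
## compress -> cluster -> trim -> resolve -> combine.
## Every stage leaves its intermediate files and a YAML metrics document in
## the run directory, so any stage can be inspected or re-run with manual
## edits (cluster override file, cleaned graphs) in place of the automatic
## result.

#' Run the full consensus-assembly pipeline
#'
#' Builds the compacted De Bruijn graph from all input assemblies, clusters
#' contigs into per-replicon groups, trims overlaps, resolves one consensus
#' sequence per passing cluster, and combines them into the final assembly.
#' All intermediate artifacts (GFA graphs, per-cluster FASTAs, newick tree,
#' distance matrix, metrics YAML) are preserved under \code{outDir}.
#'
#' @param assemblies A directory of FASTA files (one assembly each) or a
#'   named list as for [buildUnitigGraph()]. At least two assemblies.
#' @param outDir Output run directory (created; existing files overwritten).
#' @param k K-mer size (default 51).
#' @param cutoff,lambda,minAssemblyFraction,containmentFraction Clustering
#'   parameters, see [clusterContigs()].
#' @param trim Trimming parameters from [trimParams()].
#' @param bridgeMinFraction See [buildBridges()].
#' @param manual Optional manual cluster assignment, see [clusterContigs()].
#' @param verbose Print stage progress to stderr.
#' @return Invisibly, a list with the final \code{fasta}/\code{gfa} paths,
#'   the [ClusterSet-class] and the list of [ConsensusSeq-class] results.
#' @export
runFull <- function(assemblies, outDir, k = 51L, cutoff = 0.5,
                    lambda = 0.5, minAssemblyFraction = 0.25,
                    containmentFraction = 0.9, trim = trimParams(),
                    bridgeMinFraction = 0.25, manual = NULL,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  if (is.character(assemblies)) assemblies <- readAssemblies(assemblies)
  if (length(assemblies) < 2L)
    stop("need multiple input assemblies", call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  mdir <- file.path(outDir, "metrics")

  ## -- compress --
  say("compress: building unitig graph (k=", k, ")")
  g <- buildUnitigGraph(assemblies, k = k)
  writeGFA(g, file.path(outDir, "input.gfa"))
  md <- graphMetadata(g)
  writeMetrics(stepMetrics("compress",
    parameters = list(k = k),
    values = list(n_assemblies = md$nAssemblies,
                  n_contigs = length(contigPaths(g)),
                  n_unitigs = length(unitigSeqs(g)),
                  total_input_bases = md$totalInputBases,
                  total_unitig_bases = sum(Biostrings::width(unitigSeqs(g))),
                  n_split_contigs = length(md$splits))),
    file.path(mdir, "compress.yaml"))

  ## -- cluster --
  say("cluster: distances, UPGMA, QC")
  cs <- clusterContigs(g, cutoff = cutoff, lambda = lambda,
                       minAssemblyFraction = minAssemblyFraction,
                       containmentFraction = containmentFraction,
                       manual = manual)
  writeTreeNewick(upgmaTree(cs), file.path(outDir, "tree.newick"))
  utils::write.table(clusterDistances(cs), file.path(outDir, "distances.tsv"),
                     sep = "\t", quote = FALSE)
  cls <- clusters(cs)
  st <- vapply(cls, `[[`, "", "status")
  writeMetrics(stepMetrics("cluster",
    parameters = cs@parameters[c("cutoff", "lambda", "minAssemblyFraction",
                                 "containmentFraction")],
    values = list(n_contigs = length(clusterLabels(cs)),
                  n_clusters = length(cls),
                  n_pass = sum(st == "pass"),
                  n_fail = sum(st != "pass"),
                  fail_reasons = as.list(table(vapply(cls, `[[`, "",
                                                      "failReason"))),
                  members = lapply(stats::setNames(
                    cls, paste0("cluster_", vapply(cls, `[[`, 1L, "id"))),
                    function(cl) as.list(cl$members)))),
    file.path(mdir, "cluster.yaml"))

  ## -- trim + resolve per passing cluster --
  seqsByLabel <- stats::setNames(
    lapply(contigPaths(g), function(p) reconstructContig(g, p)),
    pathNames(g))
  resolved <- list()
  for (cl in cls) {
    if (cl$status != "pass") next
    cdir <- file.path(outDir, sprintf("cluster_%03d", cl$id))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    memberSeqs <- unlist(seqsByLabel[cl$members])
    writeFasta(memberSeqs, file.path(cdir, "members.fasta"))

    say("trim: cluster ", cl$id, " (", length(memberSeqs), " contigs)")
    tr <- trimCluster(memberSeqs, params = trim)
    writeFasta(tr$seqs, file.path(cdir, "trimmed.fasta"))
    utils::write.table(tr$report, file.path(cdir, "trim_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeMetrics(stepMetrics("trim",
      parameters = trim,
      values = list(cluster = cl$id,
                    n_in = nrow(tr$report),
                    n_kept = sum(tr$report$kept),
                    n_trimmed = sum(tr$report$trimmedBases > 0),
                    total_trimmed_bases = sum(tr$report$trimmedBases),
                    detections = as.list(table(tr$report$detected)))),
      file.path(mdir, sprintf("trim_cluster_%03d.yaml", cl$id)))

    say("resolve: cluster ", cl$id)
    cons <- resolveCluster(tr$seqs, k = k, clusterId = cl$id,
                           bridgeMinFraction = bridgeMinFraction)
    writeGFA(attr(cons, "graph"), file.path(cdir, "merged.gfa"))
    br <- bridgeSupport(cons)
    writeMetrics(stepMetrics("resolve",
      parameters = list(k = k, bridgeMinFraction = bridgeMinFraction),
      values = list(cluster = cl$id,
                    status = resolutionStatus(cons),
                    topology = topology(cons),
                    n_anchors = length(anchors(cons)),
                    n_bridges = nrow(br),
                    n_ambiguous_bridges = sum(br$ambiguous),
                    min_bridge_support = if (nrow(br)) min(br$support) else NA,
                    consensus_length = nchar(consensusSeq(cons)))),
      file.path(mdir, sprintf("resolve_cluster_%03d.yaml", cl$id)))
    if (resolutionStatus(cons) != "unresolved")
      writeFasta(stats::setNames(consensusSeq(cons),
                                 sprintf("cluster_%d", cl$id)),
                 file.path(cdir, "consensus.fasta"))
    resolved[[length(resolved) + 1L]] <- cons
  }
  if (!length(resolved) ||
      all(vapply(resolved, resolutionStatus, "") == "unresolved"))
    stop("no cluster could be resolved", call. = FALSE)

  ## -- combine --
  say("combine: writing final assembly")
  res <- combineClusters(resolved, file.path(outDir, "consensus"))
  writeMetrics(stepMetrics("combine", parameters = list(),
                           values = res$metrics),
               file.path(mdir, "combine.yaml"))
  say("done: ", res$fasta)
  invisible(list(fasta = res$fasta, gfa = res$gfa, graph = g,
                 clusterSet = cs, resolved = resolved))
}
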