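## Contig clustering: graph-path distances, UPGMA, tree cutting, refinement
## and quality-control filtering. Each passing cluster should correspond to
## one replicon of the genome.

#' Graph-path distance between two contigs
#'
#' Length-weighted multiset Dice distance on unitig content:
#' \deqn{d = 1 - 2S / (L_a + L_b)} where \eqn{L_a, L_b} are the total
#' unitig-step lengths of the two paths (each step contributes its full unitig
#' length, strand-insensitive) and \eqn{S = \sum_u \min(c_a(u), c_b(u))
#' \cdot \mathrm{len}(u)} over unitig ids \eqn{u} with step counts \eqn{c}.
#' Identical paths give 0; unitig-disjoint paths give 1.
#'
#' @param a,b Contig paths (elements of \code{contigPaths(graph)} or indices).
#' @param graph The [UnitigGraph-class] both paths belong to.
#' @return Distance in [0, 1].
#' @export
contigDistance <- function(a, b, graph) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  if (is.numeric(a)) a <- graph@paths[[a]]
  if (is.numeric(b)) b <- graph@paths[[b]]
  n <- length(graph@unitigs)
  if (any(c(a$steps, b$steps) < 1L) || any(c(a$steps, b$steps) > n))
    stop("path not in graph", call. = FALSE)
  len <- Biostrings::width(graph@unitigs)
  ca <- tabulate(a$steps, nbins = n)
  cb <- tabulate(b$steps, nbins = n)
  La <- sum(ca * len); Lb <- sum(cb * len)
  S <- sum(pmin(ca, cb) * len)
  1 - 2 * S / (La + Lb)
}

#' Pairwise graph-path distance matrix for all contigs of a graph
#'
#' @param graph A [UnitigGraph-class].
#' @return Symmetric numeric matrix with dimnames "assembly:contig".
#' @export
contigDistanceMatrix <- function(graph) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  labs <- pathNames(graph)
  nP <- length(labs)
  nU <- length(graph@unitigs)
  len <- Biostrings::width(graph@unitigs)
  counts <- vapply(graph@paths, function(p) tabulate(p$steps, nbins = nU),
                   integer(nU))
  counts <- matrix(counts, nrow = nU)   # nU x nP
  L <- as.numeric(crossprod(counts, len))
  d <- matrix(0, nP, nP, dimnames = list(labs, labs))
  if (nP > 1L) {
    for (i in seq_len(nP - 1L)) {
      for (j in (i + 1L):nP) {
        S <- sum(pmin(counts[, i], counts[, j]) * len)
        d[i, j] <- d[j, i] <- 1 - 2 * S / (L[i] + L[j])
      }
    }
  }
  d
}

#' Build a UPGMA tree from a distance matrix
#'
#' Standard unweighted average-linkage agglomeration. Node heights are
#' ultrametric: half the merge distance. Ties between candidate merges are
#' broken deterministically: the pair whose smallest leaf label is
#' lexicographically least wins (then the pair's other smallest label).
#'
#' @param d Symmetric numeric matrix in [0, 1] with zero diagonal and labelled
#'   dimnames (or an object coercible via [as.matrix()]).
#' @return A list of class \code{"upgma"} with elements \code{merge} (hclust
#'   convention), \code{height} (ultrametric node heights = merge distance/2),
#'   \code{mergeDist} (full merge distances), \code{labels}.
#' @seealso [cutTree()], [asHclust()]
#' @export
buildUpgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (!n) stop("empty distance matrix", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- colnames(d)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-12) || any(d < 0) || any(d > 1) ||
      any(diag(d) != 0))
    stop("distance matrix must be symmetric, zero-diagonal, in [0,1]",
         call. = FALSE)
  if (n == 1L)
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), mergeDist = numeric(0),
                          labels = labs), class = "upgma"))
  ## active clusters: node code (hclust convention), leaf members, size,
  ## smallest leaf label (for tie-breaks)
  code <- -seq_len(n)
  size <- rep(1L, n)
  minLab <- labs
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  hgt <- numeric(n - 1L)
  active <- rep(TRUE, n)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    ## find minimal distance among active pairs, tie-break on labels
    best <- NULL; bestD <- Inf; bestKey <- NULL
    eps <- 1e-10   # averaged distances that differ only by float noise tie
    for (ii in seq_along(idx)[-length(idx)]) {
      for (jj in (ii + 1L):length(idx)) {
        i <- idx[ii]; j <- idx[jj]
        dij <- D[i, j]
        if (dij > bestD + eps) next
        lab2 <- sort(c(minLab[i], minLab[j]), method = "radix")
        if (dij < bestD - eps ||
            lab2[1L] < bestKey[1L] ||
            (lab2[1L] == bestKey[1L] && lab2[2L] < bestKey[2L])) {
          best <- c(i, j); bestD <- min(bestD, dij); bestKey <- lab2
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[s, ] <- sort(c(code[i], code[j]))  # hclust order: leaves first
    hgt[s] <- bestD
    ## Lance-Williams UPGMA update into slot i
    for (m in idx) {
      if (m == i || m == j) next
      D[i, m] <- D[m, i] <-
        (size[i] * D[i, m] + size[j] * D[j, m]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minLab[i] <- min(minLab[i], minLab[j])
    code[i] <- s
    active[j] <- FALSE
  }
  structure(list(merge = merge, height = hgt / 2, mergeDist = hgt,
                 labels = labs), class = "upgma")
}

#' Convert a UPGMA tree to a stats::hclust object
#'
#' Heights of the hclust object are full merge distances (twice the
#' ultrametric node heights), matching [stats::hclust()] convention.
#'
#' @param tree A tree from [buildUpgma()].
#' @return An object of class \code{"hclust"}.
#' @export
asHclust <- function(tree) {
  n <- length(tree$labels)
  ord <- if (n == 1L) 1L else {
    ## leaf order by recursive traversal of the merge matrix
    rec <- function(node) {
      if (node < 0L) return(-node)
      c(rec(tree$merge[node, 1L]), rec(tree$merge[node, 2L]))
    }
    rec(n - 1L)
  }
  structure(list(merge = tree$merge, height = tree$mergeDist,
                 order = ord, labels = tree$labels,
                 method = "average", call = match.call(),
                 dist.method = "graph-path"), class = "hclust")
}

#' Export a UPGMA tree as newick
#'
#' Branch lengths follow the ultrametric convention (leaf-to-node distance =
#' half the merge distance).
#'
#' @param tree A tree from [buildUpgma()].
#' @param file Output newick file path.
#' @return Invisibly, \code{file}.
#' @export
writeTreeNewick <- function(tree, file) {
  if (length(tree$labels) == 1L) {
    writeLines(sprintf("(%s:0);", tree$labels), file)
  } else {
    ape::write.tree(ape::as.phylo(asHclust(tree)), file = file)
  }
  invisible(file)
}

#' Cut a UPGMA tree into initial clusters at a fixed distance cutoff
#'
#' Clusters are the maximal subtrees whose root height is at most
#' \code{cutoff/2} (equivalently, whose merge distance is at most
#' \code{cutoff}); every leaf belongs to exactly one cluster.
#'
#' @param tree A tree from [buildUpgma()].
#' @param cutoff Distance cutoff in (0, 1).
#' @return List of clusters (lists with \code{id}, \code{members},
#'   \code{status}, \code{failReason}, \code{perAssembly}).
#' @export
cutTree <- function(tree, cutoff) {
  stopifnot(cutoff > 0, cutoff < 1)
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nodeLeaves <- vector("list", max(n - 1L, 0L))
  for (s in seq_len(max(n - 1L, 0L))) {
    kids <- tree$merge[s, ]
    leaves <- unlist(lapply(kids, function(kk)
      if (kk < 0L) -kk else nodeLeaves[[kk]]))
    nodeLeaves[[s]] <- leaves
    if (tree$mergeDist[s] <= cutoff) {
      r <- vapply(leaves, find, integer(1))
      parent[r] <- r[1L]
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(tree$labels, root)
  ## deterministic provisional ids: decreasing size, then smallest label
  firstLab <- vapply(groups, function(g) min(g), character(1))
  ord <- order(-lengths(groups), firstLab, method = "radix")
  groups <- groups[ord]
  lapply(seq_along(groups), function(i) newCluster(i, groups[[i]]))
}

## construct a cluster record
newCluster <- function(id, members, status = "pass", failReason = "none") {
  asm <- sub(":.*$", "", members)
  list(id = as.integer(id), members = sort(members, method = "radix"),
       status = status, failReason = failReason,
       perAssembly = table(asm))
}

## balance - lambda * tightness score for a set of member labels
clusterScore <- function(members, d, lambda) {
  asm <- sub(":.*$", "", members)
  balance <- mean(table(asm) == 1L)
  tight <- if (length(members) < 2L) 0 else {
    sub <- d[members, members, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  balance - lambda * tight
}

#' Refine initial clusters by testing subtree splits
#'
#' For every cluster in which some assembly contributes two or more contigs,
#' the split into the cluster's two child subtrees is accepted when it
#' strictly increases a score = balance - lambda * tightness, where balance is
#' the fraction of contributing assemblies with exactly one member and
#' tightness the mean intra-cluster distance. Child scores are combined as a
#' member-weighted mean. Splitting recurses until no further improvement.
#'
#' @param clusterList Clusters from [cutTree()].
#' @param tree The tree they were cut from.
#' @param d The distance matrix used to build the tree.
#' @param lambda Tightness weight (default 0.5).
#' @return Refined list of clusters.
#' @export
refineClusters <- function(clusterList, tree, d, lambda = 0.5) {
  n <- length(tree$labels)
  nodeLeaves <- vector("list", max(n - 1L, 0L))
  for (s in seq_len(max(n - 1L, 0L))) {
    kids <- tree$merge[s, ]
    nodeLeaves[[s]] <- unlist(lapply(kids, function(kk)
      if (kk < 0L) tree$labels[-kk] else nodeLeaves[[kk]]))
  }
  leavesOf <- function(node)
    if (node < 0L) tree$labels[-node] else nodeLeaves[[node]]
  ## node index of a member set (exact subtree match), or NA
  nodeOf <- function(members) {
    ms <- sort(members, method = "radix")
    for (s in rev(seq_len(max(n - 1L, 0L)))) {
      if (length(nodeLeaves[[s]]) == length(ms) &&
          all(sort(nodeLeaves[[s]], method = "radix") == ms))
        return(s)
    }
    NA_integer_
  }
  splitRec <- function(node) {
    members <- leavesOf(node)
    asm <- sub(":.*$", "", members)
    if (node < 0L || !any(table(asm) >= 2L)) return(list(members))
    kids <- tree$merge[node, ]
    mem1 <- leavesOf(kids[1L]); mem2 <- leavesOf(kids[2L])
    parentScore <- clusterScore(members, d, lambda)
    childScore <- (length(mem1) * clusterScore(mem1, d, lambda) +
                   length(mem2) * clusterScore(mem2, d, lambda)) /
      length(members)
    if (childScore > parentScore)
      c(splitRec(kids[1L]), splitRec(kids[2L]))
    else list(members)
  }
  out <- list()
  for (cl in clusterList) {
    if (length(cl$members) == 1L) { out[[length(out) + 1L]] <- cl$members; next }
    node <- nodeOf(cl$members)
    if (is.na(node)) { out[[length(out) + 1L]] <- cl$members; next }
    out <- c(out, splitRec(node))
  }
  firstLab <- vapply(out, function(g) min(g), character(1))
  ord <- order(-lengths(out), firstLab, method = "radix")
  out <- out[ord]
  lapply(seq_along(out), function(i) newCluster(i, out[[i]]))
}

#' Quality-control filter for refined clusters
#'
#' A cluster fails with reason \code{too_few_assemblies} when its
#' distinct-assembly count is below \code{ceiling(minAssemblyFraction *
#' nAssemblies)}, and with reason \code{contained} when at least
#' \code{containmentFraction} of its member-unitig bases (union over members)
#' also occur in some passing larger cluster. Failed clusters retain their
#' members so they can be rescued manually.
#'
#' @param clusterList Refined clusters.
#' @param nAssemblies Number of input assemblies.
#' @param graph The [UnitigGraph-class] the contigs belong to.
#' @param minAssemblyFraction,containmentFraction QC thresholds (defaults
#'   0.25 and 0.9).
#' @return Clusters with statuses, re-numbered by decreasing total member
#'   length (chromosome first).
#' @export
qcFilter <- function(clusterList, nAssemblies, graph,
                     minAssemblyFraction = 0.25, containmentFraction = 0.9) {
  labs <- pathNames(graph)
  pathLen <- vapply(graph@paths, function(p) as.numeric(p$length), numeric(1))
  names(pathLen) <- labs
  uLen <- Biostrings::width(graph@unitigs)
  unitigsOf <- function(members) {
    idx <- match(members, labs)
    sort(unique(unlist(lapply(graph@paths[idx], `[[`, "steps"))))
  }
  ## final ids: decreasing total member length
  tot <- vapply(clusterList, function(cl) sum(pathLen[cl$members]), numeric(1))
  firstLab <- vapply(clusterList, function(cl) min(cl$members), character(1))
  ord <- order(-tot, firstLab, method = "radix")
  clusterList <- clusterList[ord]
  minAsm <- ceiling(minAssemblyFraction * nAssemblies)
  out <- vector("list", length(clusterList))
  passUnitigs <- list()
  for (i in seq_along(clusterList)) {
    cl <- newCluster(i, clusterList[[i]]$members)
    nAsm <- length(cl$perAssembly)
    uu <- unitigsOf(cl$members)
    if (nAsm < minAsm) {
      cl$status <- "fail"; cl$failReason <- "too_few_assemblies"
    } else {
      bases <- sum(uLen[uu])
      for (pu in passUnitigs) {
        ov <- sum(uLen[intersect(uu, pu)])
        if (bases > 0 && ov / bases >= containmentFraction) {
          cl$status <- "fail"; cl$failReason <- "contained"
          break
        }
      }
    }
    if (cl$status == "pass")
      passUnitigs[[length(passUnitigs) + 1L]] <- uu
    out[[i]] <- cl
  }
  out
}

#' Cluster the contigs of a unitig graph into per-replicon groups
#'
#' Full clustering stage: pairwise graph-path distances, UPGMA tree, fixed
#' cutoff, balance/tightness refinement and QC filtering. A manual assignment
#' overrides the automatic clustering entirely.
#'
#' @param graph A [UnitigGraph-class].
#' @param cutoff Initial tree-cut distance (default 0.5; see the methods
#'   vignette for why path distances are far larger than per-base divergence).
#' @param lambda Tightness weight for refinement (default 0.5).
#' @param minAssemblyFraction,containmentFraction QC thresholds.
#' @param manual Optional manual assignment: a data.frame (or TSV file path)
#'   with columns \code{contig} ("assembly:contig" label) and \code{cluster}
#'   (integer id; 0 or NA excludes the contig).
#' @return A [ClusterSet-class].
#' @export
clusterContigs <- function(graph, cutoff = 0.5, lambda = 0.5,
                           minAssemblyFraction = 0.25,
                           containmentFraction = 0.9, manual = NULL) {
  stopifnot(methods::is(graph, "UnitigGraph"))
  d <- contigDistanceMatrix(graph)
  tree <- buildUpgma(d)
  nAsm <- length(unique(vapply(graph@paths, `[[`, "", "assembly")))
  if (is.null(manual)) {
    cls <- cutTree(tree, cutoff)
    cls <- refineClusters(cls, tree, d, lambda)
    cls <- qcFilter(cls, nAsm, graph, minAssemblyFraction,
                    containmentFraction)
  } else {
    if (is.character(manual))
      manual <- utils::read.delim(manual, stringsAsFactors = FALSE)
    stopifnot(all(c("contig", "cluster") %in% names(manual)))
    unknown <- setdiff(manual$contig, rownames(d))
    if (length(unknown))
      stopf("manual assignment names unknown contigs: %s", fmtIds(unknown))
    keep <- !is.na(manual$cluster) & manual$cluster > 0
    groups <- split(manual$contig[keep], manual$cluster[keep])
    cls <- lapply(seq_along(groups), function(i)
      newCluster(i, groups[[i]]))
    excluded <- c(manual$contig[!keep], setdiff(rownames(d), manual$contig))
    if (length(excluded))
      cls[[length(cls) + 1L]] <- newCluster(length(cls) + 1L, excluded,
                                            status = "fail",
                                            failReason = "user_excluded")
  }
  methods::new("ClusterSet", labels = rownames(d), distances = d,
               tree = unclass(tree), clusters = cls,
               parameters = list(cutoff = cutoff, lambda = lambda,
                                 minAssemblyFraction = minAssemblyFraction,
                                 containmentFraction = containmentFraction,
                                 nAssemblies = nAsm,
                                 manual = !is.null(manual)))
}
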