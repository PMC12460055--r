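## Long-read subsampling: partition a read set into minimally overlapping
## subsets of a target depth, for generating independent input assemblies.

#' Partition a long-read set into minimally overlapping subsets
#'
#' Reads are shuffled by a seeded permutation. Each subset takes consecutive
#' reads from the shuffled list, starting at evenly spaced base offsets
#' (subset i starts at offset \code{round(i * totalBases / count)}, wrapping)
#' and accumulating until the target \code{B = max(minDepth * genomeSize,
#' totalBases / count)} bases are reached. Evenly spaced start offsets keep
#' the maximum pairwise overlap of the contiguous windows minimal; when total
#' depth is at least \code{count * B} the subsets are disjoint.
#'
#' @param reads FASTQ records (data.frame from [readFastq()]) or a FASTQ file
#'   path.
#' @param genomeSize Genome size in bases (required; not estimated).
#' @param count Number of subsets (default 4, which avoids excessive overlap
#'   between subsets while keeping them diverse).
#' @param minDepth Minimum fold-coverage per subset (default 25).
#' @param seed Integer seed for the shuffling permutation (default 0).
#' @param outDir Optional directory: subsets are written as
#'   \code{sample_01.fastq.gz} ... together with \code{metrics/subsample.yaml}.
#' @return List with \code{subsets} (list of FASTQ data.frames) and
#'   \code{metrics} (a \code{"stepMetrics"} record: per-subset read/base
#'   counts and depths, pairwise overlap fractions, parameters).
#' @export
subsampleReads <- function(reads, genomeSize, count = 4L, minDepth = 25,
                           seed = 0L, outDir = NULL) {
  if (is.character(reads)) reads <- readFastq(reads)
  count <- as.integer(count)
  stopifnot(count >= 1L, genomeSize > 0, minDepth > 0)
  if (!nrow(reads)) stop("empty FASTQ", call. = FALSE)
  lens <- nchar(reads$seq)
  total <- sum(as.numeric(lens))
  if (total < minDepth * genomeSize)
    stopf(paste("insufficient read depth: %.1fx < %gx minimum;",
                "lower minDepth or use fewer subsets"),
          total / genomeSize, minDepth)
  B <- max(minDepth * genomeSize, total / count)

  perm <- withSeed(seed, sample.int(nrow(reads)))
  lens <- lens[perm]
  cum <- cumsum(as.numeric(lens))        # cum[i]: bases up to read i
  n <- length(perm)
  subsets <- vector("list", count)
  idxSets <- vector("list", count)
  for (i in seq_len(count)) {
    off <- round((i - 1L) * total / count)
    ## first read starting at or after the base offset (cum[start-1] >= off)
    startIdx <- if (off <= 0) 1L else sum(cum < off) + 2L
    if (startIdx > n) startIdx <- 1L
    got <- 0; j <- startIdx; idx <- integer(0)
    while (got < B && length(idx) < n) {
      if (length(idx) && j == startIdx) break      # full pass
      ## wrapping for less than one read's shortfall would only create
      ## overlap; the subset is then within one read of the target
      if (j < startIdx && B - got < lens[j]) break
      idx <- c(idx, j)
      got <- got + lens[j]
      j <- if (j == n) 1L else j + 1L
    }
    idxSets[[i]] <- idx
    subsets[[i]] <- reads[perm[idx], , drop = FALSE]
    rownames(subsets[[i]]) <- NULL
  }
  subBases <- vapply(idxSets, function(ix) sum(as.numeric(lens[ix])),
                     numeric(1))
  overlap <- matrix(0, count, count)
  for (i in seq_len(count)) {
    for (j in seq_len(count)) {
      if (i == j) next
      shared <- sum(as.numeric(lens[intersect(idxSets[[i]], idxSets[[j]])]))
      overlap[i, j] <- shared / subBases[i]
    }
  }
  m <- stepMetrics("subsample",
    parameters = list(count = count, genome_size = genomeSize,
                      min_depth = minDepth, seed = seed),
    values = list(total_reads = n, total_bases = total,
                  input_depth = total / genomeSize,
                  target_bases = B,
                  subset_bases = as.list(stats::setNames(
                    subBases, sprintf("sample_%02d", seq_len(count)))),
                  subset_depth = as.list(stats::setNames(
                    subBases / genomeSize,
                    sprintf("sample_%02d", seq_len(count)))),
                  max_pairwise_overlap = max(overlap)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(count))
      writeFastq(subsets[[i]],
                 file.path(outDir, sprintf("sample_%02d.fastq.gz", i)))
    writeMetrics(m, file.path(outDir, "metrics", "subsample.yaml"))
  }
  list(subsets = subsets, metrics = m)
}
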