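## Synthetic fixtures: random genomes, perturbed pseudo-assemblies and
## simulated long reads. Everything is fully determined by its seed, and
## every perturbation is logged to a truth record so downstream assertions
## (trim recovery, consensus majority correctness, cluster membership) can
## be checked exactly.

#' Generate a random genome
#'
#' Bases are i.i.d. at the requested GC content (no repeat structure by
#' default). Optionally an exact repeat can be implanted at two loci of the
#' first replicon, to exercise repeat handling.
#'
#' @param replicons data.frame with columns \code{name}, \code{length},
#'   \code{topology} ("circular"/"linear"); defaults to a 50 kb circular
#'   chromosome plus a 5 kb circular plasmid.
#' @param gc GC fraction in (0, 1), default 0.5.
#' @param seed Integer seed.
#' @param repeatLength If positive, an exact repeat of this length is copied
#'   between two loci of the first replicon (at 1/4 and 3/4 of its length).
#' @return List with \code{seqs} (named character vector) and \code{truth}
#'   (replicon table plus parameters).
#' @export
makeGenome <- function(replicons = data.frame(
                         name = c("chromosome", "plasmid"),
                         length = c(50000L, 5000L),
                         topology = c("circular", "circular"),
                         stringsAsFactors = FALSE),
                       gc = 0.5, seed = 1L, repeatLength = 0L) {
  stopifnot(gc > 0, gc < 1, !anyDuplicated(replicons$name),
            all(replicons$length >= 1000L))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withSeed(seed, {
    out <- vapply(replicons$length, function(n)
      paste(sample(names(probs), n, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    names(out) <- replicons$name
    out
  })
  if (repeatLength > 0L) {
    s <- seqs[[1L]]; n <- nchar(s)
    stopifnot(repeatLength < n / 4)
    src <- floor(n / 4); dst <- floor(3 * n / 4)
    rep <- substr(s, src + 1L, src + repeatLength)
    substr(s, dst + 1L, dst + repeatLength) <- rep
    seqs[[1L]] <- s
  }
  list(seqs = seqs,
       truth = list(replicons = replicons, gc = gc, seed = seed,
                    repeatLength = repeatLength))
}

#' Perturb a genome into a pseudo-assembly
#'
#' Emulates the failure modes of real long-read assemblers: random rotation
#' of circular replicons, scattered point errors, dropped or duplicated
#' replicons, spurious circular-overlap or hairpin-overhang sequence at
#' contig ends, and fragmentation. Every applied change is listed in the
#' returned truth diff.
#'
#' @param genome Result of [makeGenome()] (or a named character vector plus a
#'   \code{topology} argument).
#' @param rotation "random", "none", or a named integer vector of fixed
#'   rotations (circular replicons only).
#' @param substitutionRate,insertionRate,deletionRate Per-base error
#'   probabilities, each in [0, 0.05].
#' @param dropReplicons,duplicateReplicons Replicon names to omit, or to emit
#'   as head-to-tail doubled contigs.
#' @param circularOverlapBases Bases of the contig start to repeat at its end
#'   (circular replicons).
#' @param hairpinOverhangBases Bases of reverse-complement overhang to
#'   prepend (linear replicons only; requesting it on a circular replicon is
#'   an error).
#' @param fragments If > 1, each contig is split into this many pieces.
#' @param seed Integer seed.
#' @param topology Named character vector of topologies when \code{genome} is
#'   a bare vector.
#' @return List with \code{seqs} (the pseudo-assembly contigs) and
#'   \code{truth} (per-replicon list of applied changes: rotation and 0-based
#'   positions of each substitution/insertion/deletion).
#' @export
perturbAssembly <- function(genome, rotation = "random",
                            substitutionRate = 0, insertionRate = 0,
                            deletionRate = 0,
                            dropReplicons = character(0),
                            duplicateReplicons = character(0),
                            circularOverlapBases = 0L,
                            hairpinOverhangBases = 0L,
                            fragments = 1L, seed = 1L, topology = NULL) {
  if (is.list(genome) && !is.null(genome$seqs)) {
    seqs <- genome$seqs
    topo <- stats::setNames(genome$truth$replicons$topology,
                            genome$truth$replicons$name)
  } else {
    seqs <- genome
    topo <- if (is.null(topology))
      stats::setNames(rep("circular", length(seqs)), names(seqs))
    else topology
  }
  rates <- c(substitutionRate, insertionRate, deletionRate)
  stopifnot(all(rates >= 0), all(rates <= 0.05))
  if (hairpinOverhangBases > 0L &&
      any(topo[setdiff(names(seqs), dropReplicons)] == "circular"))
    stop("hairpin overhang requested on a circular replicon", call. = FALSE)
  seqs <- seqs[setdiff(names(seqs), dropReplicons)]
  truth <- list(dropped = dropReplicons, duplicated = duplicateReplicons,
                seed = seed, replicons = list())
  out <- character(0)
  withSeed(seed, {
    for (nm in names(seqs)) {
      s <- seqs[[nm]]
      n <- nchar(s)
      rec <- list(rotation = 0L, substitutions = integer(0),
                  insertions = integer(0), deletions = integer(0))
      if (topo[[nm]] == "circular") {
        r <- if (identical(rotation, "random")) sample.int(n, 1L) - 1L
        else if (identical(rotation, "none")) 0L
        else as.integer(rotation[[nm]])
        s <- rotateSeq(s, r)
        rec$rotation <- r
      }
      ## point errors on the rotated coordinate system
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      nSub <- stats::rbinom(1L, n, substitutionRate)
      nIns <- stats::rbinom(1L, n, insertionRate)
      nDel <- stats::rbinom(1L, n, deletionRate)
      pos <- sample.int(n, min(n, nSub + nIns + nDel))
      subPos <- sort(utils::head(pos, nSub))
      insPos <- sort(pos[seq_len(nIns) + nSub])
      delPos <- sort(pos[seq_len(nDel) + nSub + nIns])
      for (p in subPos)
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      ## insertions add a random base after position p; deletions drop base p
      for (j in seq_along(insPos))
        ch[insPos[j]] <- paste0(ch[insPos[j]],
                                sample(c("A", "C", "G", "T"), 1L))
      if (length(delPos)) ch[delPos] <- ""
      s <- paste(ch, collapse = "")
      rec$substitutions <- subPos - 1L
      rec$insertions <- insPos - 1L
      rec$deletions <- delPos - 1L
      if (nm %in% duplicateReplicons) {
        s <- paste0(s, s)
        rec$fullDuplication <- TRUE
      } else if (circularOverlapBases > 0L && topo[[nm]] == "circular") {
        s <- paste0(s, substr(s, 1L, circularOverlapBases))
        rec$circularOverlap <- as.integer(circularOverlapBases)
      } else if (hairpinOverhangBases > 0L && topo[[nm]] == "linear") {
        s <- paste0(revcompChar(substr(s, 1L, hairpinOverhangBases)), s)
        rec$hairpinOverhang <- as.integer(hairpinOverhangBases)
      }
      if (fragments > 1L) {
        bp <- sort(sample.int(nchar(s) - 1L, fragments - 1L))
        starts <- c(1L, bp + 1L); endsF <- c(bp, nchar(s))
        for (fi in seq_along(starts))
          out[[paste0(nm, "_f", fi)]] <- substr(s, starts[fi], endsF[fi])
        rec$fragments <- as.integer(fragments)
      } else {
        out[[nm]] <- s
      }
      truth$replicons[[nm]] <- rec
    }
  })
  list(seqs = out, truth = truth)
}

#' Simulate long reads from a genome
#'
#' Read start positions are uniform (wrapping across the origin of circular
#' replicons); lengths are gamma-distributed around \code{meanLen}; a uniform
#' 1 percent base-substitution error rate is applied. Read names encode the
#' true origin as \code{<replicon>_<start0>_<len>}. Total bases come out
#' within 2 percent of \code{depth * genomeSize}.
#'
#' @param genome Result of [makeGenome()] or a named character vector (with
#'   optional \code{topology} as in [perturbAssembly()]).
#' @param depth Target fold-coverage (> 0).
#' @param meanLen Mean read length in bases (default 8000).
#' @param errorRate Per-base substitution rate (default 0.01).
#' @param seed Integer seed.
#' @return FASTQ records data.frame (columns name/seq/qual) as for
#'   [writeFastq()].
#' @export
simulateReads <- function(genome, depth, meanLen = 8000, errorRate = 0.01,
                          seed = 1L, topology = NULL) {
  if (is.list(genome) && !is.null(genome$seqs)) {
    seqs <- genome$seqs
    topo <- stats::setNames(genome$truth$replicons$topology,
                            genome$truth$replicons$name)
  } else {
    seqs <- genome
    topo <- if (is.null(topology))
      stats::setNames(rep("circular", length(seqs)), names(seqs))
    else topology
  }
  stopifnot(depth > 0)
  gsize <- sum(nchar(seqs))
  target <- depth * gsize
  lens <- nchar(seqs)
  withSeed(seed, {
    name <- character(0); seqOut <- character(0)
    got <- 0
    i <- 0L
    while (got < target) {
      i <- i + 1L
      repl <- sample(names(seqs), 1L, prob = lens / sum(lens))
      n <- lens[[repl]]
      L <- max(100L, min(if (topo[[repl]] == "circular") n else n,
                         round(stats::rgamma(1L, shape = 4,
                                             scale = meanLen / 4))))
      start0 <- sample.int(n, 1L) - 1L
      if (topo[[repl]] == "circular") {
        s <- substr(rotateSeq(seqs[[repl]], start0), 1L, L)
      } else {
        if (start0 + L > n) start0 <- n - L
        s <- substr(seqs[[repl]], start0 + 1L, start0 + L)
      }
      if (got + nchar(s) > target * 1.02) {
        ## trim the last read so the total lands on target
        s <- substr(s, 1L, max(100L, round(target - got)))
      }
      if (errorRate > 0) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        nErr <- stats::rbinom(1L, length(ch), errorRate)
        if (nErr) {
          p <- sample.int(length(ch), nErr)
          for (q in p) ch[q] <- sample(setdiff(c("A", "C", "G", "T"),
                                               ch[q]), 1L)
          s <- paste(ch, collapse = "")
        }
      }
      name <- c(name, sprintf("%s_%d_%d read=%d", repl, start0, nchar(s), i))
      seqOut <- c(seqOut, s)
      got <- got + nchar(s)
    }
    data.frame(name = name, seq = seqOut,
               qual = strrep("I", nchar(seqOut)), stringsAsFactors = FALSE)
  })
}
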