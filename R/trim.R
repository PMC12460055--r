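## Overlap trimming of clustered contigs.
##
## Assemblers frequently leave spurious sequence at contig ends: circular
## overlaps (the start of a circular contig repeated at its end), hairpin
## overlaps (a linear contig extended past a terminal hairpin onto the
## reverse strand) and whole-plasmid tandem duplications. Each detector uses
## exact shared words as seeds and verifies candidates by ungapped
## end-anchored comparison with a mismatch tolerance, so scattered
## sequencing errors in one copy are tolerated.

#' Default trimming parameters
#'
#' @param minOverlap Minimum overlap length considered real (bases).
#' @param maxOverlapFraction Longest overlap considered, as a fraction of
#'   contig length.
#' @param mismatchRate Maximum mismatch rate between the two copies under
#'   ungapped comparison.
#' @param lengthTolerance Post-trim lengths deviating from the cluster median
#'   by more than this fraction are discarded.
#' @param seedWord Exact-word length used to seed overlap search.
#' @return Named list of parameters.
#' @export
trimParams <- function(minOverlap = 100L, maxOverlapFraction = 0.5,
                       mismatchRate = 0.01, lengthTolerance = 0.1,
                       seedWord = 21L) {
  list(minOverlap = as.integer(minOverlap),
       maxOverlapFraction = maxOverlapFraction,
       mismatchRate = mismatchRate,
       lengthTolerance = lengthTolerance,
       seedWord = as.integer(seedWord))
}

## one-row trim report
trimReport <- function(contig, detected, trimmedBases, preLength) {
  data.frame(contig = contig, detected = detected,
             trimmedBases = as.integer(trimmedBases),
             preLength = as.integer(preLength),
             postLength = as.integer(preLength - trimmedBases),
             kept = TRUE, discardReason = "none",
             stringsAsFactors = FALSE)
}

## candidate overlap lengths from exact shared words between two regions.
## aWords/bWords are word vectors; L(i, j) maps a match (word i in the first
## region, word j in the second) to a candidate overlap length.
seedCandidates <- function(aWords, bWords, Lfun) {
  m <- match(bWords, aWords)
  hit <- which(!is.na(m))
  if (!length(hit)) return(integer(0))
  L <- Lfun(m[hit], hit)
  sort(unique(L[is.finite(L)]), decreasing = TRUE)
}

## ungapped mismatch check: TRUE when regions match within rate
regionMatches <- function(seq, s1, e1, s2, e2, rate) {
  a <- substr(seq, s1, e1)
  b <- substr(seq, s2, e2)
  hammingDist(a, b) <= rate * nchar(a)
}

#' Trim a circular overlap (start of contig repeated at its end)
#'
#' Finds the longest suffix of the contig (at least \code{minOverlap}, at
#' most \code{maxOverlapFraction} of the length) matching a prefix of the
#' contig within the mismatch tolerance, and removes the suffix copy.
#'
#' @param seq Contig sequence (character scalar).
#' @param params Parameters from [trimParams()].
#' @param contig Contig name used in the report.
#' @return List with \code{seq} (trimmed sequence) and \code{report} (one-row
#'   data.frame; \code{detected} is "circular" or "none").
#' @export
trimCircularOverlap <- function(seq, params = trimParams(), contig = "contig") {
  n <- nchar(seq)
  w <- params$seedWord
  maxov <- floor(params$maxOverlapFraction * n)
  if (maxov < params$minOverlap || n < 2L * w)
    return(list(seq = seq, report = trimReport(contig, "none", 0L, n)))
  prefWords <- substring(seq, seq_len(maxov - w + 1L),
                         seq_len(maxov - w + 1L) + w - 1L)
  sufStart <- (n - maxov + 1L):(n - w + 1L)
  sufWords <- substring(seq, sufStart, sufStart + w - 1L)
  ## overlap L: suffix position j (absolute) aligns with prefix position i
  ## via i = j - (n - L)  =>  L = n - j + i
  cand <- seedCandidates(prefWords, sufWords,
                         function(i, j) n - sufStart[j] + i)
  cand <- cand[cand >= params$minOverlap & cand <= maxov]
  for (L in cand) {
    if (regionMatches(seq, 1L, L, n - L + 1L, n, params$mismatchRate)) {
      return(list(seq = substr(seq, 1L, n - L),
                  report = trimReport(contig, "circular", L, n)))
    }
  }
  list(seq = seq, report = trimReport(contig, "none", 0L, n))
}

#' Trim a hairpin overlap at either contig end
#'
#' Detects a prefix (resp. suffix) that is the reverse complement of the
#' immediately following (resp. preceding) region, i.e. an assembler read-through
#' past a terminal hairpin onto the opposite strand, and removes the
#' overhanging copy.
#'
#' @inheritParams trimCircularOverlap
#' @return List with \code{seq} and \code{report} (\code{detected} is
#'   "hairpin_start", "hairpin_end" or "none").
#' @export
trimHairpinOverlap <- function(seq, params = trimParams(), contig = "contig") {
  n <- nchar(seq)
  w <- params$seedWord
  maxov <- min(floor(params$maxOverlapFraction * n), n %/% 2L)
  if (maxov < params$minOverlap || n < 2L * w)
    return(list(seq = seq, report = trimReport(contig, "none", 0L, n)))
  R <- revcompChar(seq)   # R[p] pairs with seq[n - p + 1]

  ## hairpin at start: seq[1..L] == rc(seq[L+1..2L]) == R[n-2L+1..n-L];
  ## a word at seq position i matching a word at R position p gives
  ## i - 1 = p - (n - 2L + 1)  =>  L = (n + i - p) / 2
  prefWords <- substring(seq, seq_len(maxov - w + 1L),
                         seq_len(maxov - w + 1L) + w - 1L)
  rStart <- (n - 2L * maxov + 1L):(n - w + 1L)
  rStart <- rStart[rStart >= 1L]
  rWords <- substring(R, rStart, rStart + w - 1L)
  cand <- seedCandidates(prefWords, rWords, function(i, j) {
    L2 <- n + i - rStart[j]
    ifelse(L2 %% 2L == 0L, L2 %/% 2L, NA_integer_)
  })
  cand <- cand[cand >= params$minOverlap & cand <= maxov]
  for (L in cand) {
    a <- substr(seq, 1L, L)
    b <- substr(R, n - 2L * L + 1L, n - L)
    if (hammingDist(a, b) <= params$mismatchRate * L) {
      return(list(seq = substr(seq, L + 1L, n),
                  report = trimReport(contig, "hairpin_start", L, n)))
    }
  }

  ## hairpin at end: seq[n-L+1..n] == rc(seq[n-2L+1..n-L]) == R[L+1..2L];
  ## word at seq position j matching word at R position p gives
  ## j - (n - L + 1) = p - (L + 1)  =>  L = (n + p - j) / 2
  sufStart <- (n - maxov + 1L):(n - w + 1L)
  sufWords <- substring(seq, sufStart, sufStart + w - 1L)
  r2Start <- seq_len(min(2L * maxov, n) - w + 1L)
  r2Words <- substring(R, r2Start, r2Start + w - 1L)
  cand <- seedCandidates(sufWords, r2Words, function(i, j) {
    L2 <- n + r2Start[j] - sufStart[i]
    ifelse(L2 %% 2L == 0L, L2 %/% 2L, NA_integer_)
  })
  cand <- cand[cand >= params$minOverlap & cand <= maxov]
  for (L in cand) {
    a <- substr(seq, n - L + 1L, n)
    b <- substr(R, L + 1L, 2L * L)
    if (hammingDist(a, b) <= params$mismatchRate * L) {
      return(list(seq = substr(seq, 1L, n - L),
                  report = trimReport(contig, "hairpin_end", L, n)))
    }
  }
  list(seq = seq, report = trimReport(contig, "none", 0L, n))
}

#' Collapse a whole-sequence tandem duplication
#'
#' Small plasmids are sometimes assembled as two tandem copies in a single
#' contig. When the two halves of the contig match within the mismatch
#' tolerance (any rotation of the plasmid produces matching halves), one copy
#' is returned. Applied before circular-overlap trimming.
#'
#' @inheritParams trimCircularOverlap
#' @return List with \code{seq} and \code{report} (\code{detected} is
#'   "full_duplication" or "none").
#' @export
collapseFullDuplication <- function(seq, params = trimParams(),
                                    contig = "contig") {
  n <- nchar(seq)
  if (n %% 2L == 0L && n >= 2L * params$minOverlap) {
    h <- n %/% 2L
    if (regionMatches(seq, 1L, h, h + 1L, n, params$mismatchRate))
      return(list(seq = substr(seq, 1L, h),
                  report = trimReport(contig, "full_duplication", h, n)))
  }
  list(seq = seq, report = trimReport(contig, "none", 0L, n))
}

#' Discard post-trim length outliers from a cluster
#'
#' A contig is kept iff its length is within \code{lengthTolerance} times the
#' cluster median of the median post-trim length. The contig closest to the
#' median is always kept.
#'
#' @param lengths Named integer vector of post-trim contig lengths.
#' @param params Parameters from [trimParams()].
#' @return Logical vector (named like \code{lengths}): kept or not.
#' @export
filterByLength <- function(lengths, params = trimParams()) {
  stopifnot(length(lengths) >= 1L)
  med <- stats::median(lengths)
  keep <- abs(lengths - med) <= params$lengthTolerance * med
  if (!any(keep)) keep[which.min(abs(lengths - med))] <- TRUE
  keep
}

#' Trim all contigs of a cluster and discard length outliers
#'
#' Applies, in order, tandem-duplication collapse, hairpin trimming and
#' circular-overlap trimming to each contig, then filters post-trim lengths
#' against the cluster median.
#'
#' @param seqs Named character vector of cluster member sequences.
#' @param params Parameters from [trimParams()].
#' @return List with \code{seqs} (trimmed, kept contigs only) and
#'   \code{report} (data.frame, one row per input contig: detections,
#'   trimmed bases, pre/post lengths, kept flag, discard reason).
#' @export
trimCluster <- function(seqs, params = trimParams()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  out <- character(length(seqs)); names(out) <- names(seqs)
  rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    pre <- nchar(seqs[[i]])
    s <- toupper(seqs[[i]])
    detected <- character(0)
    trimmed <- 0L
    for (fn in list(collapseFullDuplication, trimHairpinOverlap,
                    trimCircularOverlap)) {
      res <- fn(s, params, contig = nm)
      if (res$report$detected != "none") {
        detected <- c(detected, res$report$detected)
        trimmed <- trimmed + res$report$trimmedBases
        s <- res$seq
      }
    }
    out[[i]] <- s
    rows[[i]] <- data.frame(
      contig = nm,
      detected = if (length(detected)) paste(detected, collapse = ",") else "none",
      trimmedBases = trimmed, preLength = pre,
      postLength = pre - trimmed, kept = TRUE, discardReason = "none",
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  keep <- filterByLength(stats::setNames(report$postLength, report$contig),
                         params)
  report$kept <- unname(keep)
  report$discardReason[!keep] <- "length_outlier"
  list(seqs = out[keep], report = report)
}

#' Word-match coordinates for a dot plot of two sequences
#'
#' Lists all positions at which a \code{word}-length substring of \code{a}
#' equals a substring of \code{b} on the forward strand, or its reverse
#' complement on the reverse strand. Coordinates are 0-based.
#'
#' @param a,b Sequences to compare (character scalars).
#' @param word Word length (>= 8, default 32).
#' @return data.frame with columns \code{xa}, \code{xb} (0-based start
#'   positions in \code{a} and \code{b}) and \code{strand} ("+"/"-").
#' @export
dotplotCoords <- function(a, b, word = 32L) {
  word <- as.integer(word)
  stopifnot(word >= 8L)
  a <- toupper(a); b <- toupper(b)
  matchWords <- function(wa, wb) {
    ia <- split(seq_along(wa), wa)
    ib <- split(seq_along(wb), wb)
    common <- intersect(names(ia), names(ib))
    if (!length(common))
      return(data.frame(xa = integer(0), xb = integer(0)))
    do.call(rbind, lapply(common, function(wd) {
      expand.grid(xa = ia[[wd]], xb = ib[[wd]], KEEP.OUT.ATTRS = FALSE)
    }))
  }
  wordsOf <- function(s) {
    n <- nchar(s)
    if (n < word) return(character(0))
    substring(s, seq_len(n - word + 1L), seq_len(n - word + 1L) + word - 1L)
  }
  wa <- wordsOf(a); wb <- wordsOf(b)
  fwd <- matchWords(wa, wb)
  rb <- revcompChar(b)
  nb <- nchar(b)
  rev <- matchWords(wa, wordsOf(rb))
  if (nrow(rev)) rev$xb <- nb - rev$xb - word + 2L  # map back to b coords
  out <- rbind(
    if (nrow(fwd)) data.frame(xa = fwd$xa - 1L, xb = fwd$xb - 1L,
                              strand = "+", stringsAsFactors = FALSE),
    if (nrow(rev)) data.frame(xa = rev$xa - 1L, xb = rev$xb - 1L,
                              strand = "-", stringsAsFactors = FALSE))
  if (is.null(out))
    out <- data.frame(xa = integer(0), xb = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$xa, out$xb, out$strand, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write dot-plot coordinates as TSV, optionally with a PNG raster
#'
#' @param coords data.frame from [dotplotCoords()].
#' @param tsv Output TSV path.
#' @param png Optional PNG path; when given, a raster dot plot is drawn
#'   (forward matches in black, reverse in red).
#' @return Invisibly, \code{tsv}.
#' @export
writeDotplot <- function(coords, tsv, png = NULL) {
  utils::write.table(coords, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    plot(coords$xa, coords$xb, pch = ".", cex = 2,
         col = ifelse(coords$strand == "+", "black", "red"),
         xlab = "sequence A (bp)", ylab = "sequence B (bp)")
  }
  invisible(tsv)
}
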