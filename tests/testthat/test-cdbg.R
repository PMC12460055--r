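## Compacted De Bruijn graph construction and lossless reconstruction.

test_that("a single non-repetitive contig becomes one unitig and one path", {
  s <- "ACGTTGCAAGCTTGG"
  g <- buildUnitigGraph(list(a = c(c1 = s)), k = 11)
  expect_s4_class(g, "UnitigGraph")
  expect_length(unitigSeqs(g), 1)
  expect_equal(unname(Biostrings::width(unitigSeqs(g))), 15)
  expect_equal(unitigDepth(g), 1L)
  expect_length(contigPaths(g), 1)
  expect_length(contigPaths(g)[[1]]$steps, 1)
  expect_identical(reconstructContig(g, 1), s)
})

test_that("identical contigs from two assemblies collapse to one unitig of depth 2", {
  s <- "ACGTTGCAAGCTTGG"
  g <- buildUnitigGraph(list(a = c(c1 = s), b = c(c1 = s)), k = 11)
  expect_length(unitigSeqs(g), 1)
  expect_equal(unitigDepth(g), 2L)
  expect_length(contigPaths(g), 2)
  expect_identical(reconstructContig(g, 2), s)
})

test_that("a single substitution produces the expected SNP bubble", {
  ## expected structure computed with the brute-force oracle: shared prefix
  ## and suffix plus one 2k-1 variant unitig per allele
  set.seed(7)
  s1 <- randSeq(61)
  s2 <- mutateStr(s1, 31)
  ora <- oracleCdbg(c(s1, s2), k = 11)
  expect_equal(ora$lengths, c(21, 21, 30, 30))

  g <- buildUnitigGraph(list(a = c(c1 = s1), b = c(c1 = s2)), k = 11)
  expect_equal(sort(unname(Biostrings::width(unitigSeqs(g)))), ora$lengths)
  canon <- vapply(as.character(unitigSeqs(g)),
                  function(x) min(x, rcStr(x)), character(1),
                  USE.NAMES = FALSE)
  expect_setequal(canon, ora$seqs)
  ## both paths reconstruct
  expect_identical(reconstructContig(g, 1), s1)
  expect_identical(reconstructContig(g, 2), s2)
})

test_that("graph structure matches the brute-force oracle on random inputs", {
  set.seed(11)
  for (rep in 1:25) {
    nc <- sample(1:3, 1)
    seqs <- vapply(seq_len(nc), function(i) randSeq(sample(20:200, 1)),
                   character(1))
    ## occasionally include a mutated copy to force bubbles
    if (rep %% 3 == 0) seqs <- c(seqs, mutateStr(seqs[1],
                                                 sample(nchar(seqs[1]), 1)))
    seqs <- seqs[nchar(seqs) >= 11]
    if (!length(seqs)) next
    g <- buildUnitigGraph(list(a = stats::setNames(seqs,
                                                   paste0("c", seq_along(seqs)))),
                          k = 11)
    ora <- oracleCdbg(seqs, k = 11)
    expect_equal(sort(unname(Biostrings::width(unitigSeqs(g)))), ora$lengths)
    canon <- vapply(as.character(unitigSeqs(g)),
                    function(x) min(x, rcStr(x)), character(1),
                    USE.NAMES = FALSE)
    expect_setequal(canon, ora$seqs)
  }
})

test_that("decompression is byte-exact for random multi-contig inputs and ks", {
  set.seed(21)
  for (rep in 1:30) {
    asms <- list()
    for (a in 1:2) {
      nc <- sample(1:3, 1)
      asms[[paste0("asm", a)]] <- stats::setNames(
        vapply(seq_len(nc), function(i) randSeq(sample(120:400, 1)),
               character(1)), paste0("c", seq_len(nc)))
    }
    for (k in c(11, 31)) {
      g <- buildUnitigGraph(asms, k = k)
      dec <- decompressContigs(g)
      expect_identical(dec[names(asms)], lapply(asms, unlist))
    }
  }
})

test_that("canonical k-mers are conserved between input and unitigs", {
  set.seed(31)
  kmersCanon <- function(s, k) {
    km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    unique(pmin(km, rcStr(km)))
  }
  seqs <- c(randSeq(150), randSeq(90))
  g <- buildUnitigGraph(list(a = stats::setNames(seqs, c("c1", "c2"))), k = 15)
  inKmers <- sort(unique(unlist(lapply(seqs, kmersCanon, k = 15))))
  outKmers <- sort(unname(unlist(lapply(as.character(unitigSeqs(g)),
                                        kmersCanon, k = 15))))
  ## each k-mer stored exactly once across unitigs
  expect_identical(outKmers, inKmers)
})

test_that("compaction is maximal: no mergeable adjacent unitig pair remains", {
  set.seed(41)
  for (rep in 1:10) {
    s <- randSeq(300)
    seqs <- c(s, mutateStr(s, 150))
    g <- buildUnitigGraph(list(a = stats::setNames(seqs, c("c1", "c2"))),
                          k = 21)
    lk <- unitigLinks(g)
    if (!nrow(lk)) next
    outCnt <- stats::aggregate(list(n = seq_len(nrow(lk))),
                               by = lk[c("from", "fromOrient")], FUN = length)
    degOut <- function(u, o) {
      r <- outCnt$n[outCnt$from == u & outCnt$fromOrient == o]
      if (length(r)) r else 0L
    }
    flip <- function(o) ifelse(o == "+", "-", "+")
    for (i in seq_len(nrow(lk))) {
      a <- lk$from[i]; oa <- lk$fromOrient[i]
      b <- lk$to[i]; ob <- lk$toOrient[i]
      if (a == b) next
      ## mergeable iff a's end has a single outgoing link and b's start a
      ## single incoming link
      expect_false(degOut(a, oa) == 1 && degOut(b, flip(ob)) == 1,
                   label = sprintf("link %d%s->%d%s is mergeable", a, oa, b, ob))
    }
  }
})

test_that("a minus-strand single-unitig path reconstructs the reverse complement", {
  s <- "ACGTTGCAAGCTTGGACGATCGA"
  g <- buildUnitigGraph(list(a = c(c1 = s)), k = 11)
  p <- contigPaths(g)[[1]]
  stored <- as.character(unitigSeqs(g)[[1]])
  p$strand <- if (p$strand == "+") "-" else "+"
  expect_identical(reconstructContig(g, p),
                   rcStr(if (p$strand == "-") stored else rcStr(stored)))
})

test_that("periodic sequences wrap onto themselves but stay lossless", {
  ## period-4 repeat: its k-mers recur, so the graph is a small cycle, and
  ## the path walks it with offsets
  s <- "ACGTACGTACGTACG"
  g <- buildUnitigGraph(list(a = c(c1 = s)), k = 11)
  expect_identical(reconstructContig(g, 1), s)
  expect_lt(sum(Biostrings::width(unitigSeqs(g))), nchar(s))
})

test_that("input validation errors are informative", {
  expect_error(buildUnitigGraph(list(), k = 11), "no sequences")
  expect_error(buildUnitigGraph(list(a = c(c1 = "ACGT")), k = 11),
               "k too large")
  expect_error(buildUnitigGraph(list(a = c(c1 = randSeq(50))), k = 12),
               "odd")
  expect_error(reconstructContig(buildUnitigGraph(list(a = c(c1 = randSeq(50))),
                                                  k = 11),
                                 list(steps = 99L, strand = "+",
                                      startOffset = 0L, endOffset = 0L)),
               "corrupt path")
})

test_that("contigs with ambiguous bases are split and logged", {
  set.seed(51)
  left <- randSeq(50); right <- randSeq(60)
  g <- buildUnitigGraph(list(a = c(c1 = paste0(left, "N", right, "NNRY",
                                               "ACGT"))), k = 11)
  dec <- decompressContigs(g)$a
  expect_identical(unname(dec), c(left, right))  # short tail dropped
  expect_length(graphMetadata(g)$splits, 1)
  expect_equal(graphMetadata(g)$splits[[1]]$dropped, 1L)
})

test_that("unitig ids are deterministic regardless of input order", {
  set.seed(61)
  s1 <- randSeq(200); s2 <- mutateStr(randSeq(200), 100)
  g1 <- buildUnitigGraph(list(a = c(c1 = s1), b = c(c1 = s2)), k = 21)
  g2 <- buildUnitigGraph(list(b = c(c1 = s2), a = c(c1 = s1)), k = 21)
  expect_identical(as.character(unitigSeqs(g1)), as.character(unitigSeqs(g2)))
  expect_identical(unitigLinks(g1), unitigLinks(g2))
})
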