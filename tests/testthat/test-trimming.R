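## Overlap trimming, length filtering and dot-plot coordinates.

test_that("circular overlaps are detected and removed exactly", {
  set.seed(101)
  S <- randSeq(10000)
  for (L in c(100, 500, 2000)) {
    res <- trimCircularOverlap(paste0(S, substr(S, 1, L)))
    expect_identical(res$seq, S)
    expect_equal(res$report$detected, "circular")
    expect_equal(res$report$trimmedBases, L)
    expect_equal(res$report$postLength,
                 res$report$preLength - res$report$trimmedBases)
  }
})

test_that("circular overlap trimming tolerates scattered copy errors", {
  set.seed(103)
  S <- randSeq(10000)
  copy <- substr(S, 1, 500)
  copy <- mutateStr(mutateStr(copy, 120), 380)   # 2/500 = 0.004 <= 0.01
  res <- trimCircularOverlap(paste0(S, copy))
  expect_identical(res$seq, S)
  expect_equal(res$report$trimmedBases, 500L)
})

test_that("sequences without self-overlap pass through unchanged", {
  set.seed(107)
  S <- randSeq(5000)
  expect_equal(trimCircularOverlap(S)$report$detected, "none")
  expect_identical(trimCircularOverlap(S)$seq, S)
  expect_equal(trimHairpinOverlap(S)$report$detected, "none")
  expect_equal(collapseFullDuplication(S)$report$detected, "none")
})

test_that("hairpin overlaps at either end are trimmed", {
  set.seed(109)
  S <- randSeq(8000)
  startRes <- trimHairpinOverlap(paste0(rcStr(substr(S, 1, 300)), S))
  expect_identical(startRes$seq, S)
  expect_equal(startRes$report$detected, "hairpin_start")
  expect_equal(startRes$report$trimmedBases, 300L)

  endRes <- trimHairpinOverlap(paste0(S, rcStr(substr(S, 7701, 8000))))
  expect_identical(endRes$seq, S)
  expect_equal(endRes$report$detected, "hairpin_end")
  expect_equal(endRes$report$trimmedBases, 300L)
})

test_that("whole-plasmid tandem duplications collapse to one copy", {
  set.seed(113)
  P <- randSeq(3000)
  res <- collapseFullDuplication(paste0(P, P))
  expect_identical(res$seq, P)
  expect_equal(res$report$detected, "full_duplication")
  ## any rotation of the doubled plasmid still has matching halves
  PR <- rotStr(P, 1234)
  res2 <- collapseFullDuplication(paste0(PR, PR))
  expect_identical(res2$seq, PR)
  expect_equal(nchar(res2$seq), 3000L)
})

test_that("all trim operations are idempotent and conserve bases", {
  set.seed(127)
  S <- randSeq(6000)
  fixtures <- list(
    circ = paste0(S, substr(S, 1, 400)),
    hair = paste0(rcStr(substr(S, 1, 200)), S),
    dup = paste0(S, S))
  ops <- list(trimCircularOverlap, trimHairpinOverlap, collapseFullDuplication)
  for (f in fixtures) {
    for (op in ops) {
      r1 <- op(f)
      expect_equal(r1$report$postLength + r1$report$trimmedBases,
                   r1$report$preLength)
      r2 <- op(r1$seq)
      expect_identical(r2$seq, r1$seq)
      expect_equal(r2$report$detected, "none")
    }
  }
})

test_that("length outliers are discarded against the cluster median", {
  lens <- c(a = 5000, b = 5010, c = 4995, d = 2500)
  keep <- filterByLength(lens, trimParams(lengthTolerance = 0.1))
  expect_identical(unname(keep), c(TRUE, TRUE, TRUE, FALSE))
  ## all equal lengths: everything kept
  expect_true(all(filterByLength(c(x = 100, y = 100, z = 100))))
  ## a single contig is always kept
  expect_true(filterByLength(c(only = 123)))
  ## even when nothing is within tolerance, the closest to median survives
  keep2 <- filterByLength(c(a = 1000, b = 3000),
                          trimParams(lengthTolerance = 0.01))
  expect_equal(sum(keep2), 1)
})

test_that("trimCluster applies collapse, hairpin and circular in order", {
  set.seed(131)
  P <- randSeq(3000)
  S <- randSeq(3000)
  seqs <- c(good = S,
            dup = paste0(P, P),
            circ = paste0(S, substr(S, 1, 300)))
  out <- trimCluster(seqs)
  expect_equal(out$report$detected[out$report$contig == "dup"],
               "full_duplication")
  expect_equal(out$report$detected[out$report$contig == "circ"], "circular")
  expect_identical(unname(out$seqs[["circ"]]), S)
  expect_identical(unname(out$seqs[["dup"]]), P)
  ## the 3000 bp sequences dominate the median; all kept
  expect_true(all(out$report$kept))
})

test_that("dot-plot coordinates mark diagonals and repeats", {
  set.seed(137)
  A <- randSeq(300)
  co <- dotplotCoords(A, A, word = 32)
  fwd <- co[co$strand == "+", ]
  ## the full forward diagonal
  expect_true(all((0:(300 - 32)) %in% fwd$xa[fwd$xa == fwd$xb]))
  co2 <- dotplotCoords(A, rcStr(A), word = 32)
  rev <- co2[co2$strand == "-", ]
  expect_equal(nrow(rev), 300 - 32 + 1)
  ## anti-diagonal: xa + xb constant
  expect_true(all(rev$xa + rev$xb == 300 - 32))
  ## self-comparison of S + prefix(S, 100): off-diagonal forward segment
  S <- randSeq(400)
  SP <- paste0(S, substr(S, 1, 100))
  co3 <- dotplotCoords(SP, SP, word = 32)
  off <- co3[co3$strand == "+" & co3$xa - co3$xb == 400, ]
  expect_equal(nrow(off), 100 - 32 + 1)
})

test_that("dot-plot TSV export round-trips", {
  set.seed(139)
  co <- dotplotCoords(randSeq(100), randSeq(100), word = 8)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDotplot(co, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(co))
})
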