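## Internal low-level helpers shared across modules.

#' Reverse-complement character vectors of DNA
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors (uppercase ACGT).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @keywords internal
#' @noRd
revcompChar <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## complement of single bases (no reversal)
complementBase <- function(x) chartr("ACGT", "TGCA", x)

## all k-mers of one string, as a character vector (1-based start positions)
kmersOf <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), k:n)
}

## reverse complements of all k-mers of s, aligned with kmersOf(s, k):
## rc of the k-mer starting at i is the k-mer of revcomp(s) starting at n-k+2-i
kmersRcOf <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  rs <- revcompChar(s)
  idx <- (n - k + 1L):1L
  substring(rs, idx, idx + k - 1L)
}

## rotate a (circular) sequence so it begins at 1-based position r+1
rotateSeq <- function(s, r) {
  n <- nchar(s)
  r <- ((r %% n) + n) %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1L, n), substr(s, 1L, r))
}

## evaluate expr with a temporarily-seeded RNG, restoring global state after
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## hamming distance between equal-length strings (raw byte comparison)
hammingDist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## number of contig-path records that traverse each unitig is computed by
## tabulate(); this helper formats unitig ids for messages
fmtIds <- function(ids, max = 10L) {
  if (length(ids) > max) paste0(paste(ids[seq_len(max)], collapse = ", "), ", ...")
  else paste(ids, collapse = ", ")
}

## deterministic C-locale string order
strOrder <- function(...) order(..., method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
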