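## Test helpers: random-sequence generation and independent brute-force
## oracles (naive cDBG construction, naive average-linkage clustering).
## The oracles share no code with the package implementation.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

rotStr <- function(s, r) {
  n <- nchar(s); r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

rcStr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

mutateStr <- function(s, pos, base = NULL) {
  old <- substr(s, pos, pos)
  if (is.null(base)) base <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(s, pos, pos) <- base
  s
}

## ---- brute-force compacted De Bruijn graph -------------------------------
## Naive fixpoint algorithm on strings: every canonical k-mer starts as its
## own unitig; adjacent unitigs are merged pairwise while exactly one
## observed edge connects them in either direction. Returns sorted unitig
## lengths and the set of unitig sequences (canonicalized).
oracleCdbg <- function(seqs, k) {
  seqs <- toupper(unname(unlist(seqs)))
  ## observed oriented k-mer adjacencies as string pairs "kmer orient"
  edgeSet <- new.env(hash = TRUE)
  nodes <- new.env(hash = TRUE)
  orientKey <- function(km) {
    rc <- rcStr(km)
    if (km <= rc) c(km, "+") else c(rc, "-")
  }
  addEdge <- function(a, b) {
    assign(paste(a[1], a[2], b[1], b[2]), TRUE, envir = edgeSet)
    ## reverse-complement twin
    flip <- function(o) if (o == "+") "-" else "+"
    assign(paste(b[1], flip(b[2]), a[1], flip(a[2])), TRUE, envir = edgeSet)
  }
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    prev <- NULL
    for (i in 1:(n - k + 1)) {
      km <- substr(s, i, i + k - 1)
      ok <- orientKey(km)
      assign(ok[1], TRUE, envir = nodes)
      if (!is.null(prev)) addEdge(prev, ok)
      prev <- ok
    }
  }
  kmers <- ls(nodes)
  edges <- ls(edgeSet)
  ## out-neighbour sets per oriented node
  parts <- strsplit(edges, " ", fixed = TRUE)
  outs <- list()
  for (p in parts) {
    key <- paste(p[1], p[2])
    outs[[key]] <- unique(c(outs[[key]], paste(p[3], p[4])))
  }
  outdeg <- function(key) length(outs[[key]])
  ## unitigs: oriented chains; walk from every node not mid-chain
  flip <- function(o) if (o == "+") "-" else "+"
  twinKey <- function(key) {
    p <- strsplit(key, " ", fixed = TRUE)[[1]]
    paste(p[1], flip(p[2]))
  }
  canMerge <- function(a, b) {
    pa <- strsplit(a, " ")[[1]]; pb <- strsplit(b, " ")[[1]]
    outdeg(a) == 1 && outs[[a]] == b && outdeg(twinKey(b)) == 1 &&
      pa[1] != pb[1]
  }
  hasMergeIn <- function(b) {
    tb <- twinKey(b)
    if (outdeg(tb) != 1) return(FALSE)
    a <- twinKey(outs[[tb]][1])
    canMerge(a, b)
  }
  spell <- function(keys) {
    out <- NULL
    for (keyI in keys) {
      p <- strsplit(keyI, " ")[[1]]
      km <- if (p[2] == "+") p[1] else rcStr(p[1])
      out <- if (is.null(out)) km else paste0(out, substr(km, k, k))
    }
    out
  }
  visited <- new.env(hash = TRUE)
  lens <- integer(0); useqs <- character(0)
  for (start in c(paste(kmers, "+"), paste(kmers, "-"))) {
    km0 <- strsplit(start, " ")[[1]][1]
    if (!is.null(visited[[km0]])) next
    if (hasMergeIn(start)) next
    chain <- start
    visited[[km0]] <- TRUE
    cur <- start
    repeat {
      if (outdeg(cur) != 1) break
      nxt <- outs[[cur]][1]
      if (!canMerge(cur, nxt)) break
      kmN <- strsplit(nxt, " ")[[1]][1]
      if (!is.null(visited[[kmN]])) break
      chain <- c(chain, nxt)
      visited[[kmN]] <- TRUE
      cur <- nxt
    }
    s <- spell(chain)
    lens <- c(lens, nchar(s))
    useqs <- c(useqs, min(s, rcStr(s)))
  }
  ## pure cycles: remaining unvisited k-mers
  for (km0 in kmers) {
    if (!is.null(visited[[km0]])) next
    start <- paste(km0, "+")
    chain <- start
    visited[[km0]] <- TRUE
    cur <- start
    repeat {
      if (outdeg(cur) != 1) break
      nxt <- outs[[cur]][1]
      if (nxt == start || !canMerge(cur, nxt)) break
      kmN <- strsplit(nxt, " ")[[1]][1]
      if (!is.null(visited[[kmN]])) break
      chain <- c(chain, nxt)
      visited[[kmN]] <- TRUE
      cur <- nxt
    }
    s <- spell(chain)
    lens <- c(lens, nchar(s))
    useqs <- c(useqs, min(s, rcStr(s)))
  }
  list(lengths = sort(lens), seqs = sort(useqs))
}

## ---- brute-force UPGMA ----------------------------------------------------
## Naive average-linkage: recompute every between-cluster average from the
## original matrix at each step; ties broken by the pair whose smallest leaf
## label sorts first (then the pair's other smallest label). Returns merges
## as member-label sets plus merge distances.
oracleUpgma <- function(d) {
  labs <- rownames(d)
  groups <- as.list(labs)
  merges <- list()
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- NULL; bestD <- Inf; bestKey <- NULL
    for (i in seq_along(groups)[-length(groups)]) {
      for (j in (i + 1):length(groups)) {
        tot <- 0
        for (a in groups[[i]]) for (b in groups[[j]]) tot <- tot + d[a, b]
        avg <- tot / (length(groups[[i]]) * length(groups[[j]]))
        key <- sort(c(min(groups[[i]]), min(groups[[j]])))
        better <- avg < bestD - 1e-12 ||
          (abs(avg - bestD) <= 1e-12 &&
           (key[1] < bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2])))
        if (better) { best <- c(i, j); bestD <- avg; bestKey <- key }
      }
    }
    i <- best[1]; j <- best[2]
    merged <- sort(c(groups[[i]], groups[[j]]))
    merges[[length(merges) + 1]] <- list(
      a = sort(groups[[i]]), b = sort(groups[[j]]), members = merged)
    heights <- c(heights, bestD)
    groups[[i]] <- merged
    groups[[j]] <- NULL
  }
  list(merges = merges, heights = heights)
}

## member-label sets of each internal node of a buildUpgma() tree
upgmaMemberSets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  leaf <- function(kk) if (kk < 0) tree$labels[-kk] else sets[[kk]]
  out <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    a <- leaf(tree$merge[s, 1]); b <- leaf(tree$merge[s, 2])
    sets[[s]] <- sort(c(a, b))
    out[[s]] <- list(a = sort(a), b = sort(b), members = sets[[s]])
  }
  out
}

## random symmetric distance matrix, optionally with tied entries
randDistMatrix <- function(n, ties = FALSE) {
  vals <- if (ties) sample(seq(0.1, 0.9, by = 0.1), n * (n - 1) / 2,
                           replace = TRUE)
  else stats::runif(n * (n - 1) / 2)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}
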