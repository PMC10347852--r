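## Independent pure-R oracles used against the package implementation.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateSeq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (j in hit) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
  paste(v, collapse = "")
}

rcR <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

canonR <- function(kmer) {
  r <- rcR(kmer)
  if (r < kmer) r else kmer
}

## all k-mers of a string, R-side (independent of the package's kmerizer)
kmersR <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

## Brute-force recursive DFS enumeration of traversal paths START -> STOP
## over a canonical solid k-mer set, with the same contract as the package
## traversal: STOP is absorbing, a canonical k-mer may be used at most
## `maxVisits` times per path, paths are capped at `maxLen` bases.
dfsEnumerate <- function(solidCanonical, start, stop, k,
                         maxLen = 100000L, maxVisits = 2L) {
  solid <- new.env(parent = emptyenv())
  for (s in solidCanonical) assign(s, TRUE, solid)
  canonCache <- new.env(parent = emptyenv())
  canonM <- function(kmer) {
    v <- canonCache[[kmer]]
    if (is.null(v)) {
      v <- canonR(kmer)
      canonCache[[kmer]] <- v
    }
    v
  }
  inGraph <- function(kmer) exists(canonM(kmer), solid)
  if (!inGraph(start) || !inGraph(stop)) return(character(0))
  if (start == stop) return(start)
  results <- character(0)
  ## explicit-stack DFS (paths can be long; no recursion)
  stack <- list(list(seq = start, visits = setNames(list(1L), canonR(start))))
  while (length(stack) > 0L) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    suffix <- substr(st$seq, nchar(st$seq) - k + 2L, nchar(st$seq))
    for (b in c("A", "C", "G", "T")) {
      kmer <- paste0(suffix, b)
      if (!inGraph(kmer)) next
      if (kmer == stop) {
        results[[length(results) + 1L]] <- paste0(st$seq, b)
        next
      }
      cn <- canonM(kmer)
      v <- st$visits[[cn]]
      if (is.null(v)) v <- 0L
      if (v >= maxVisits || nchar(st$seq) + 1L > maxLen) next
      visits2 <- st$visits
      visits2[[cn]] <- v + 1L
      stack[[length(stack) + 1L]] <- list(seq = paste0(st$seq, b),
                                          visits = visits2)
    }
  }
  sort(unique(results))
}

## random traversal test case: a base sequence, SNP-bubble variants, an
## optional tandem duplication, plus unrelated noise reads
randomGraphCase <- function(maxBubbles = 3) {
  k <- sample(c(11L, 13L, 15L, 17L, 21L), 1)
  L <- sample(150:500, 1)
  base <- randomSeq(L)
  if (runif(1) < 0.3) {   # tandem repeat: cycle in the graph
    u <- sample(seq(k + 5, 60), 1)
    p <- sample(seq(40, L - 80), 1)
    unit <- substr(base, p, p + u - 1)
    base <- paste0(substr(base, 1, p + u - 1), unit,
                   substr(base, p + u, L))
  }
  reads <- base
  for (b in seq_len(sample(0:maxBubbles, 1))) {
    v <- base
    for (m in seq_len(sample(1:2, 1))) {
      pos <- sample(seq(k + 2, nchar(base) - k - 2), 1)
      substr(v, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(v, pos, pos)), 1)
    }
    reads <- c(reads, v)
  }
  noise <- replicate(sample(0:4, 1), randomSeq(sample(k:40, 1)))
  list(k = k, reads = c(reads, noise),
       start = substr(base, 1, k),
       stop = substr(base, nchar(base) - k + 1, nchar(base)))
}
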