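test_that("graph counts canonical k-mers (hand-enumerated oracle)", {
  g <- buildGraph("ACGTACGT", k = 4, a = 1)
  ## 5 k-mer occurrences; ACGT and TACG share canonical forms with their
  ## reverse complements: {ACGT: 2, CGTA: 2, GTAC: 1}
  expect_identical(sum(g@counts), 5L)
  expect_identical(setNames(g@counts, g@kmers),
                   c(ACGT = 2L, CGTA = 2L, GTAC = 1L))
  expect_true(all(hasKmer(g, c("ACGT", "TACG", "GTAC"))))
  ## strand symmetry of membership
  expect_true(hasKmer(g, rcR("ACGT")))

  ## a = 2 with no repeated canonical k-mer: nothing solid
  g2 <- buildGraph("ACGGTTCA", k = 4, a = 2)
  expect_length(solidKmers(g2), 0)

  ## k-mers containing N are skipped
  g3 <- buildGraph("ACGTNACGT", k = 4, a = 1)
  expect_identical(sum(g3@counts), 2L)

  expect_error(buildGraph(c("ACG", "TTT"), k = 5), "shorter than k")
  expect_error(buildGraph(character(0), k = 5), "no reads")
})

test_that("traversal spells a linear path exactly", {
  s <- "ACGTACGTTTAGGCCATGAC"
  g <- buildGraph(s, k = 7, a = 1)
  cands <- traverseGraph(g, substr(s, 1, 7), substr(s, 14, 20),
                         assemblyParams(k = 7, a = 1))
  expect_length(cands, 1)
  expect_identical(cands[[1]]@sequence, s)
  ## agreement with the brute-force enumerator
  oracle <- dfsEnumerate(vapply(kmersR(s, 7), canonR, ""),
                         substr(s, 1, 7), substr(s, 14, 20), 7)
  expect_identical(sort(vapply(cands, function(x) x@sequence, "")), oracle)
})

test_that("start == stop degenerates to a single k-length candidate", {
  g <- buildGraph("ACGTACGTTT", k = 5, a = 1)
  cands <- traverseGraph(g, "ACGTA", "ACGTA", assemblyParams(k = 5, a = 1))
  expect_length(cands, 1)
  expect_identical(cands[[1]]@sequence, "ACGTA")
})

test_that("a SNP bubble yields exactly two candidates", {
  set.seed(8)
  base <- randomSeq(120)
  alt <- base
  substr(alt, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(base, 60, 60))[1]
  k <- 15
  g <- buildGraph(c(base, alt), k = k, a = 1)
  start <- substr(base, 1, k); stop <- substr(base, 106, 120)
  cands <- traverseGraph(g, start, stop, assemblyParams(k = k, a = 1))
  expect_length(cands, 2)
  seqs <- vapply(cands, function(x) x@sequence, "")
  expect_setequal(seqs, c(base, alt))
  d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
              seqs[1], seqs[2])
  expect_identical(as.integer(d), 1L)
  oracle <- dfsEnumerate(vapply(unique(c(kmersR(base, k), kmersR(alt, k))),
                                canonR, ""), start, stop, k)
  expect_identical(sort(seqs), oracle)
})

test_that("traversal equals brute-force DFS enumeration on random graphs", {
  set.seed(9)
  for (i in 1:40) {
    cs <- randomGraphCase()
    g <- buildGraph(cs$reads, k = cs$k, a = 1)
    cands <- traverseGraph(g, cs$start, cs$stop,
                           assemblyParams(k = cs$k, a = 1,
                                          maxPathLength = 5000L,
                                          maxActiveBranches = 100000L))
    expect_false(attr(cands, "limitReached"))
    got <- sort(vapply(cands, function(x) x@sequence, ""))
    oracle <- dfsEnumerate(vapply(kmersR(paste(cs$reads, collapse = "N"),
                                         cs$k), canonR, ""),
                           cs$start, cs$stop, cs$k, maxLen = 5000L)
    expect_identical(got, oracle)
    ## soundness: every candidate spells only solid k-mers and is anchored
    for (s in got) {
      expect_true(all(hasKmer(g, kmersR(s, cs$k))))
      expect_identical(substr(s, 1, cs$k), cs$start)
      expect_identical(substr(s, nchar(s) - cs$k + 1, nchar(s)), cs$stop)
    }
  }
})

test_that("assembling the reverse-complemented problem gives RC candidates", {
  set.seed(10)
  for (i in 1:10) {
    cs <- randomGraphCase()
    g <- buildGraph(cs$reads, k = cs$k, a = 1)
    p <- assemblyParams(k = cs$k, a = 1, maxPathLength = 5000L,
                        maxActiveBranches = 100000L)
    fwd <- sort(vapply(traverseGraph(g, cs$start, cs$stop, p),
                       function(x) x@sequence, ""))
    bwd <- sort(vapply(traverseGraph(g, rcR(cs$stop), rcR(cs$start), p),
                       function(x) x@sequence, ""))
    expect_identical(sort(vapply(bwd, rcR, "", USE.NAMES = FALSE)), fwd)
  }
})

test_that("raising the solidity threshold only removes k-mers from paths", {
  set.seed(11)
  for (i in 1:50) {
    reads <- replicate(sample(3:8, 1), mutateSeq(randomSeq(150), 0.01))
    reads <- c(reads, reads[sample(length(reads), 2, replace = TRUE)])
    k <- 13
    g1 <- buildGraph(reads, k = k, a = 1)
    a <- sample(1:3, 1)
    lo <- solidKmers(withAbundance(g1, a))
    hi <- solidKmers(withAbundance(g1, a + 1))
    expect_true(all(hi %in% lo))
    start <- substr(reads[1], 1, k)
    stop <- substr(reads[1], 138, 150)
    ch <- traverseGraph(withAbundance(g1, a + 1), start, stop,
                        assemblyParams(k = k, a = a + 1, maxPathLength = 2000L))
    gl <- withAbundance(g1, a)
    for (cand in ch)
      expect_true(all(hasKmer(gl, kmersR(cand@sequence, k))))
  }
})

test_that("anchor k-mers come from the majority of spanning reads", {
  set.seed(12)
  refSeq <- randomSeq(3000)
  k <- 21; ext <- 50
  tgt <- targetLocus("t", region("ref", 0, 1000), region("ref", 1200, 3000))
  ## START anchor interval: [1000 - ext, 1000 - ext + k)
  trueStart <- substr(refSeq, 951, 971)
  reads <- substr(refSeq, 901, 1000)
  readsR <- substr(refSeq, 1201, 1300)
  bam <- fixtureBamFromReads(refSeq, c(rep(900, 5), rep(1200, 5)),
                             c(rep(reads, 5), rep(readsR, 5)))
  anc <- pickAnchorKmers(bam, tgt, k, ext)
  expect_true(anc$ok)
  expect_identical(anc$start, trueStart)
  expect_identical(anc$startSupport, 5L)
  ## STOP anchor: [1200 + ext - k, 1200 + ext)
  expect_identical(anc$stop, substr(refSeq, 1230, 1250))

  ## a SNP carried by 3 of 4 spanning reads wins the vote
  snpRead <- reads
  substr(snpRead, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                     substr(reads, 60, 60))[1]
  bam2 <- fixtureBamFromReads(refSeq, c(rep(900, 4), rep(1200, 3)),
                              c(snpRead, snpRead, snpRead, reads,
                                rep(readsR, 3)))
  anc2 <- pickAnchorKmers(bam2, tgt, k, ext)
  ## the SNP sits at reference offset 959, position 10 of the START k-mer
  expect_identical(substr(anc2$start, 10, 10), substr(snpRead, 60, 60))
  expect_identical(anc2$startSupport, 3L)

  ## no spanning read: anchoring failure, reported per side
  bam3 <- fixtureBamFromReads(refSeq, 100, substr(refSeq, 101, 200))
  anc3 <- pickAnchorKmers(bam3, tgt, k, ext)
  expect_false(anc3$ok)
  expect_true("left" %in% anc3$failedSide || "right" %in% anc3$failedSide)
})

test_that("representative subset keeps only mutually divergent candidates", {
  set.seed(13)
  mk <- function(s) new("AssemblyCandidate", sequence = s, k = 21L, a = 1L,
                        pathLength = nchar(s), limitReached = FALSE)
  s <- randomSeq(1000)
  expect_length(representativeSubset(list(mk(s), mk(s))), 1)

  s2 <- s; substr(s2, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                           substr(s, 500, 500))[1]
  expect_length(representativeSubset(list(mk(s), mk(s2))), 1)

  rnd <- replicate(5, mk(randomSeq(500)))
  kept <- representativeSubset(rnd)
  expect_length(kept, 5)
  ## verify divergence with the aligner itself
  for (i in 1:4) for (j in (i + 1):5)
    expect_lte(linklocal:::.globalIdentity(kept[[i]]@sequence,
                                           kept[[j]]@sequence), 0.9)
})

test_that("one-shot assembly recovers a simulated 1 kb target", {
  fx <- fixtureSim()
  w <- flankWindows(fx$pt$target, 10000)
  sel <- selectBarcodes(collectFlankBarcodes(fx$sim$bamPath, w), 2)
  sub <- subsampleReads(sel, fx$idx)
  asm <- assembleTarget(sub, fx$pt$target,
                        assemblyParams(k = 61, a = 2, gapEstimate = 1000),
                        fx$sim$bamPath, ext = 500)
  expect_identical(asm$status, "ok")
  expect_length(asm$candidates, 1)
  inner <- trimExtensions(asm$candidates[[1]]@sequence, 500)
  al <- semiGlobalAlign(inner, fx$pt$truth)
  expect_gte(al$identity, 0.99)
  expect_gte(al$coverage, 0.99)

  ## zero reads: structured no-assembly
  none <- assembleTarget(sub[0, ], fx$pt$target,
                         assemblyParams(k = 61, a = 2), fx$sim$bamPath)
  expect_identical(none$status, "no_reads")
})

test_that("two divergent haplotype alleles give two representative candidates", {
  set.seed(14)
  ## perfect tiling reads from two alleles sharing flanks
  flankL <- randomSeq(300); flankR <- randomSeq(300)
  alleleA <- paste0(flankL, randomSeq(400), flankR)
  alleleB <- paste0(flankL, randomSeq(150), flankR)
  tile <- function(s) {
    st <- unique(c(seq(1, nchar(s) - 99, by = 7), nchar(s) - 99))
    substring(s, st, st + 99)
  }
  reads <- c(tile(alleleA), tile(alleleB))
  k <- 31
  g <- buildGraph(reads, k = k, a = 1)
  cands <- traverseGraph(g, substr(alleleA, 1, k),
                         substr(flankR, 300 - k + 1, 300),
                         assemblyParams(k = k, a = 1, maxPathLength = 5000L))
  reps <- representativeSubset(cands)
  expect_length(reps, 2)
  expect_setequal(vapply(reps, function(x) x@sequence, ""),
                  c(alleleA, alleleB))
})
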