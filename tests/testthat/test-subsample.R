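test_that("flank windows abut the gap and truncate at flank boundaries", {
  t <- targetLocus("t", region("chr1", 0, 10000), region("chr1", 12000, 30000))
  w <- flankWindows(t, 5000)
  expect_identical(linklocal:::regionStart0(w$left), 5000L)
  expect_identical(linklocal:::regionEnd0(w$left), 10000L)
  expect_identical(linklocal:::regionStart0(w$right), 12000L)
  expect_identical(linklocal:::regionEnd0(w$right), 17000L)

  ## truncation at the flank extent
  t2 <- targetLocus("t2", region("chr1", 0, 2000), region("chr1", 3000, 4000))
  w2 <- flankWindows(t2, 5000)
  expect_identical(linklocal:::regionStart0(w2$left), 0L)
  expect_identical(linklocal:::regionEnd0(w2$left), 2000L)
  expect_identical(linklocal:::regionEnd0(w2$right), 4000L)
  expect_error(flankWindows(t2, 0), "positive")

  ## reversed flank: the window sits at the end of the segment that abuts
  ## the gap
  t3 <- targetLocus("t3", region("chr1", 0, 10000),
                    region("chr1", 12000, 30000, "-"))
  w3 <- flankWindows(t3, 5000)
  expect_identical(linklocal:::regionStart0(w3$right), 25000L)
  expect_identical(linklocal:::regionEnd0(w3$right), 30000L)
})

test_that("flank barcode counts equal a whole-file scan oracle", {
  fx <- fixtureSim()
  w <- flankWindows(fx$pt$target, 10000)
  tab <- collectFlankBarcodes(fx$sim$bamPath, w)

  ## oracle: scan every alignment in the BAM and count overlaps manually
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "qwidth"),
                               tag = "BX")
  all <- Rsamtools::scanBam(fx$sim$bamPath, param = p)[[1]]
  keep <- bitwAnd(all$flag, 4L) == 0L & bitwAnd(all$flag, 256L) == 0L &
          bitwAnd(all$flag, 2048L) == 0L & bitwAnd(all$flag, 1024L) == 0L
  ivs <- lapply(w, function(x) c(GenomicRanges::start(x),
                                 GenomicRanges::end(x)))
  s <- all$pos; e <- all$pos + all$qwidth - 1L
  inWin <- keep & ((s <= ivs$left[2] & e >= ivs$left[1]) |
                   (s <= ivs$right[2] & e >= ivs$right[1]))
  oracle <- table(all$tag$BX[inWin])
  expect_identical(length(tab), length(oracle))
  expect_identical(as.integer(tab[names(oracle)]), as.integer(oracle))

  ## empty windows give an empty table
  far <- list(left = region("ref", 0, 50), right = region("ref", 50, 100))
  emptyTab <- collectFlankBarcodes(fx$sim$bamPath, list(far$left))
  expect_true(length(emptyTab) == 0 || sum(emptyTab) < 5)

  ## window on a sequence missing from the BAM header errors
  expect_error(
    collectFlankBarcodes(fx$sim$bamPath, list(region("nope", 0, 100))),
    "absent from BAM header")
})

test_that("barcode selection applies the occurrence threshold", {
  tab <- setNames(c(4L, 1L), c("X", "Y"))
  expect_identical(as.character(selectBarcodes(tab, 2)), "X")
  expect_identical(as.character(selectBarcodes(tab, 1)), c("X", "Y"))
  expect_error(selectBarcodes(tab, 0), ">= 1")
})

test_that("selection is monotone in the occurrence threshold", {
  set.seed(6)
  for (i in 1:60) {
    n <- sample(1:60, 1)
    tab <- setNames(sample(1:10, n, replace = TRUE),
                    paste0("b", sample(1e6, n)))
    occ <- sample(1:5, 1)
    s1 <- selectBarcodes(tab, occ)
    s2 <- selectBarcodes(tab, occ + sample(1:3, 1))
    expect_true(all(s2 %in% s1))
  }
})

test_that("recruitment composes fetch over the selected barcodes", {
  fx <- fixtureSim()
  w <- flankWindows(fx$pt$target, 10000)
  sel <- selectBarcodes(collectFlankBarcodes(fx$sim$bamPath, w), 2)
  sub <- subsampleReads(sel, fx$idx)
  expect_true(all(sub$barcode %in% sel))
  expect_identical(sub, fetchReadsByBarcodes(fx$idx, sel))
  ## both mates of a pair are always recruited together
  byPair <- table(sub("/[12]$", "", sub$id))
  expect_true(all(byPair == 2))
  ## empty selection warns and recruits nothing
  expect_warning(z <- subsampleReads(character(0), fx$idx), "empty")
  expect_identical(nrow(z), 0L)
})

test_that("most reads of molecules spanning a flank window are recruited", {
  fx <- fixtureSim()
  w <- flankWindows(fx$pt$target, 10000)
  sel <- selectBarcodes(collectFlankBarcodes(fx$sim$bamPath, w), 2)
  sub <- subsampleReads(sel, fx$idx)
  mol <- fx$sim$molecules
  ## molecules fully spanning the left window
  s0 <- linklocal:::regionStart0(w$left); e0 <- linklocal:::regionEnd0(w$left)
  spanning <- mol$molecule[mol$refStart <= s0 & mol$refEnd >= e0]
  rd <- fx$sim$reads
  fromSpanning <- rd$read[rd$molecule %in% spanning]
  recruited <- unique(sub("/[12]$", "", sub$id))
  expect_gte(mean(fromSpanning %in% recruited), 0.95)

  ## selected barcode count is within +/-50% of window-spanning molecules
  overl <- mol$molecule[mol$refStart <= e0 & mol$refEnd >= s0]
  e0r <- linklocal:::regionEnd0(w$right); s0r <- linklocal:::regionStart0(w$right)
  overr <- mol$molecule[mol$refStart <= e0r & mol$refEnd >= s0r]
  nSpan <- length(union(overl, overr))
  expect_gt(length(sel), 0.5 * nSpan)
  expect_lt(length(sel), 1.5 * nSpan)
})

test_that("subsampling enriches for molecules near the target", {
  ## the enrichment bound needs the molecule reach to be small relative to
  ## the genome, so this property is demonstrated on a 2 Mb reference
  set.seed(77)
  ref <- Biostrings::DNAStringSet(setNames(randomSeq(2000000), "ref"))
  pt <- plantTarget(ref, "locus", size = 1000, at = 1000000)
  sim <- simulateLinkedReads(reference = ref, coverage = 8, seed = 78,
                             outDir = file.path(tempdir(), "enrich"))
  idx <- buildBarcodeIndex(sim$fastqPath)
  w <- flankWindows(pt$target, 10000)
  sel <- selectBarcodes(collectFlankBarcodes(sim$bamPath, w), 2)
  sub <- subsampleReads(sel, idx)

  mol <- sim$molecules
  gapS <- 1000000; gapE <- 1001000
  near <- mol$molecule[mol$refStart <= gapE + 50000 &
                       mol$refEnd >= gapS - 50000]
  rd <- sim$reads
  nearRead <- setNames(rd$molecule %in% near, rd$read)
  recruitedPairs <- unique(sub("/[12]$", "", sub$id))
  fracRecruited <- mean(nearRead[recruitedPairs])
  fracGenome <- mean(nearRead)
  expect_gte(fracRecruited / fracGenome, 10)
  expect_lt(nrow(sub), 0.15 * nrow(idx@reads))

  ## determinism: identical inputs give identical subsamples
  sel2 <- selectBarcodes(collectFlankBarcodes(sim$bamPath, w), 2)
  expect_identical(as.character(sel2), as.character(sel))
  expect_identical(subsampleReads(sel2, idx), sub)

  ## scaffold ends far apart share (almost) no barcodes; a region shares
  ## all its selected barcodes with itself
  rA <- region("ref", 0, 20000)
  rB <- region("ref", 1980000, 2000000)
  expect_lte(countSharedBarcodes(sim$bamPath, rA, rB, 2), 1)
  tabA <- collectFlankBarcodes(sim$bamPath, list(rA))
  expect_identical(countSharedBarcodes(sim$bamPath, rA, rA, 2),
                   sum(tabA >= 2))
  ## nearby regions (within molecule reach) do share barcodes
  rC <- region("ref", 20000, 40000)
  expect_gt(countSharedBarcodes(sim$bamPath, rA, rC, 2), 0)
})

test_that("strict per-side mode only keeps barcodes seen on both flanks", {
  fx <- fixtureSim()
  w <- flankWindows(fx$pt$target, 10000)
  tabs <- collectFlankBarcodes(fx$sim$bamPath, w, perSide = TRUE)
  strict <- selectBarcodes(tabs$union, 2, strictTables = tabs)
  loose <- selectBarcodes(tabs$union, 2)
  expect_true(all(strict %in% loose))
  expect_true(all(strict %in% names(tabs$left)))
  expect_true(all(strict %in% names(tabs$right)))
})
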