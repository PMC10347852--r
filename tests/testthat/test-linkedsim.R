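test_that("identical seeds reproduce the dataset byte for byte", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  s1 <- simulateLinkedReads(refLength = 50000, coverage = 10, seed = 33,
                            outDir = d1)
  s2 <- simulateLinkedReads(refLength = 50000, coverage = 10, seed = 33,
                            outDir = d2)
  expect_identical(readLines(s1$fastqPath), readLines(s2$fastqPath))
  expect_identical(readLines(s1$refPath), readLines(s2$refPath))
  expect_identical(s1$molecules, s2$molecules)
  expect_identical(s1$reads, s2$reads)
})

test_that("realized coverage and error rate match the configuration", {
  fx <- fixtureSim()
  totalBases <- nrow(fx$sim$reads) * 2 * 100
  expect_lt(abs(totalBases - 100000 * 40) / (100000 * 40), 0.05)

  ## observed mismatch rate of mapped reads vs the reference within +/-20%
  refSeq <- as.character(fx$ref[[1]])
  rd <- fx$sim$reads[1:2000, ]
  idx <- fx$idx
  recs <- idx@reads[match(paste0(rd$read, "/1"), idx@reads$id), ]
  mm <- mapply(function(s, seq) {
    truth <- substr(refSeq, s + 1, s + 100)
    sum(strsplit(seq, "")[[1]] != strsplit(truth, "")[[1]])
  }, rd$start1, recs$seq)
  rate <- sum(mm) / (2000 * 100)
  expect_gt(rate, 0.005 * 0.8)
  expect_lt(rate, 0.005 * 1.2)
})

test_that("molecule lengths follow the truncated lognormal model", {
  fx <- fixtureSim()
  len <- fx$sim$molecules$hapEnd - fx$sim$molecules$hapStart
  ## molecules capped by the 100 kb reference here; check the raw bounds
  expect_true(all(len >= 5000))
  expect_true(all(len <= 150000))
})

test_that("reads sharing a molecule share a barcode (and conversely)", {
  fx <- fixtureSim()
  rd <- fx$sim$reads
  byMol <- tapply(rd$barcode, rd$molecule, function(x) length(unique(x)))
  expect_true(all(byMol == 1))
  ## one molecule per barcode: barcode determines the molecule
  byBc <- tapply(rd$molecule, rd$barcode, function(x) length(unique(x)))
  expect_true(all(byBc == 1))

  ## with molecule sharing, barcodes span several molecules
  s <- simulateLinkedReads(refLength = 50000, coverage = 10,
                           molPerBarcode = 3, seed = 44,
                           outDir = file.path(tempdir(), "collide"))
  byBc3 <- tapply(s$reads$molecule, s$reads$barcode,
                  function(x) length(unique(x)))
  expect_gt(max(byBc3), 1)
})

test_that("the truth BAM round-trips window queries against truth intervals", {
  fx <- fixtureSim()
  rd <- fx$sim$reads
  set.seed(19)
  for (i in 1:50) {
    s0 <- sample(0:99000, 1); e0 <- s0 + sample(200:2000, 1)
    p <- Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges("ref", IRanges::IRanges(s0 + 1, e0)),
      what = c("qname", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
    res <- Rsamtools::scanBam(fx$sim$bamPath, param = p)[[1]]
    got <- sort(unique(paste0(res$qname, "/",
                              ifelse(bitwAnd(res$flag, 128L) > 0, 2, 1))))
    exp1 <- rd$read[rd$start1 < e0 & rd$start1 + 100 > s0]
    exp2 <- rd$read[rd$start2 < e0 & rd$start2 + 100 > s0]
    oracle <- sort(c(paste0(exp1, "/1"), paste0(exp2, "/2")))
    expect_identical(got, oracle)
  }
})

test_that("error-free reads match the reference at their placement", {
  s <- simulateLinkedReads(refLength = 30000, coverage = 8, errorRate = 0,
                           seed = 55, outDir = file.path(tempdir(), "ef"))
  refSeq <- as.character(s$reference[[1]])
  p <- Rsamtools::ScanBamParam(what = c("pos", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(s$bamPath, param = p)[[1]]
  take <- sample(length(res$pos), 200)
  for (i in take)
    expect_identical(as.character(res$seq[i]),
                     substr(refSeq, res$pos[i], res$pos[i] + 99))
})

test_that("planted variants shape haplotypes, targets and truth", {
  set.seed(22)
  ref <- Biostrings::DNAStringSet(setNames(randomSeq(100000), "ref"))
  refSeq <- as.character(ref[[1]])

  ## random locus: truth is the reference substring
  pl <- plantTarget(ref, "locus", size = 1000, margin = 30000)
  expect_identical(nchar(pl$truth), 1000L)
  expect_identical(pl$truth, substr(refSeq, pl$at + 1, pl$at + 1000))
  expect_identical(gapEstimate(pl$target), 1000L)

  ## homozygous deletion: donor is shorter, truth is the 2*pad junction
  pd <- plantTarget(ref, "deletion", size = 2000, pad = 50, margin = 30000)
  expect_identical(nchar(pd$haplotypes[[1]]), 98000L)
  expect_identical(nchar(pd$truth), 100L)
  expect_identical(pd$truth,
                   paste0(substr(refSeq, pd$at - 49, pd$at),
                          substr(refSeq, pd$at + 2001, pd$at + 2050)))
  expect_identical(gapEstimate(pd$target), 100L)

  ## heterozygous insertion: two haplotypes, alt truth first, unknown length
  pi <- plantTarget(ref, "insertion", size = 500, zygosity = "het",
                    margin = 30000)
  expect_length(pi$haplotypes, 2)
  expect_identical(nchar(pi$haplotypes[[1]]), 100500L)
  expect_identical(pi$haplotypes[[2]], refSeq)
  expect_identical(nchar(pi$truth), c(600L, 100L))
  expect_true(is.na(gapEstimate(pi$target)))
})

test_that("reads from inside a planted insertion are unmapped with barcode", {
  set.seed(23)
  ref <- Biostrings::DNAStringSet(setNames(randomSeq(80000), "ref"))
  pt <- plantTarget(ref, "insertion", size = 3000, zygosity = "hom",
                    margin = 31000)
  s <- simulateLinkedReads(reference = ref, haplotypes = pt$haplotypes,
                           blocks = pt$blocks, coverage = 15, seed = 66,
                           outDir = file.path(tempdir(), "insun"))
  rd <- s$reads
  inside <- rd$start1 >= pt$at & rd$start1 + 100 <= pt$at + 3000
  expect_gt(sum(inside), 10)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag"), tag = "BX",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  un <- Rsamtools::scanBam(s$bamPath, param = p)[[1]]
  unIds <- un$qname[bitwAnd(un$flag, 64L) > 0]
  expect_true(all(rd$read[inside] %in% unIds))
  expect_true(all(nchar(un$tag$BX) == 16))
  ## but those reads are still present, barcoded, in the FASTQ
  idx <- buildBarcodeIndex(s$fastqPath)
  got <- fetchReadsByBarcodes(idx, rd$barcode[inside][1])
  expect_gt(nrow(got), 0)
})
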