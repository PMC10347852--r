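## Benchmark drivers mirroring the evaluation protocol: targets whose true
## sequence is known are planted in a simulated genome, assembled without
## using the truth, and classified successful / erroneous / no_assembly by
## >90% identity and coverage against the truth.

#' Benchmark assembly of randomly selected loci
#'
#' Simulates one linked-read dataset, plants `n` random targets per size
#' (the target is a sequence already present in the reference, so the truth
#' is known but unused by the assembler), runs the subsampling + iterative
#' assembly pipeline on each, and classifies the results. Also reports, per
#' target, the barcode-subsampling statistics: the recruited fraction of
#' the read set, and the enrichment of the recruited reads in molecules
#' near the target (fraction of recruited reads whose molecule overlaps the
#' target +/- `nearBp`, over the same fraction genome-wide).
#'
#' @param sizes integer vector: one entry per target, its size in bp.
#' @param refLength,coverage,errorRate simulation scale (defaults: 500 kb
#'   at 40x, 0.5\% errors, 50 kb molecules).
#' @param seed simulation and target-placement seed.
#' @param flankSize,minOcc,ext,kLadder,aLadder pipeline parameters.
#' @param nearBp window around the target used for the enrichment metric.
#' @param outDir scratch directory.
#' @param verbose log per-target progress.
#' @return list with `perTarget` (data.frame), `bySize` (list of
#'   [benchmarkSummary()] per distinct size), and `nReads`.
#' @export
benchmarkRandomLoci <- function(sizes = c(rep(1000L, 20), rep(5000L, 10)),
                                refLength = 500000L, coverage = 40,
                                errorRate = 0.005, seed = 1,
                                flankSize = 10000L, minOcc = 2L, ext = 500L,
                                kLadder = c(61L, 51L, 41L, 31L, 21L),
                                aLadder = c(3L, 2L), nearBp = 50000L,
                                outDir = tempfile("bench"),
                                verbose = FALSE) {
  set.seed(seed)
  ref <- Biostrings::DNAStringSet(setNames(.randomDNA(refLength), "ref"))
  sim <- simulateLinkedReads(reference = ref, coverage = coverage,
                             errorRate = errorRate, seed = seed + 1L,
                             outDir = outDir)
  idx <- buildBarcodeIndex(sim$fastqPath)
  ladder <- parameterLadder(kLadder, aLadder)
  set.seed(seed + 2L)
  rd <- sim$reads
  mol <- sim$molecules
  rows <- list()
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    pt <- plantTarget(ref, "locus", size = sz, margin = flankSize + 20000L,
                      label = sprintf("locus%02d_%d", i, sz))
    w <- flankWindows(pt$target, flankSize)
    sel <- selectBarcodes(collectFlankBarcodes(sim$bamPath, w), minOcc)
    sub <- subsampleReads(sel, idx)
    res <- iterativeAssemble(pt$target, sub, sim$bamPath, ref,
                             ladder = ladder, ext = ext)
    cls <- benchmarkClassify(res, pt$truth)

    near <- mol$molecule[mol$refStart <= pt$at + sz + nearBp &
                         mol$refEnd >= pt$at - nearBp]
    nearRead <- setNames(rd$molecule %in% near, rd$read)
    recruited <- unique(sub("/[12]$", "", sub$id))
    fracNearRecruited <- mean(nearRead[recruited])
    fracNearGenome <- mean(nearRead)
    rows[[i]] <- data.frame(
      label = targetLabel(pt$target), size = sz, at = pt$at,
      status = resultStatus(res), k = res@k, a = res@a,
      class = cls$label, identity = cls$identity, coverage = cls$coverage,
      nBarcodes = length(sel), nReads = nrow(sub),
      recruitedFrac = nrow(sub) / nrow(idx@reads),
      enrichment = fracNearRecruited / fracNearGenome,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("[%s] %s (%s)", targetLabel(pt$target),
                      resultStatus(res), cls$label))
  }
  perTarget <- do.call(rbind, rows)
  bySize <- lapply(split(perTarget$class, perTarget$size), benchmarkSummary)
  list(perTarget = perTarget, bySize = bySize, nReads = nrow(idx@reads))
}

#' Benchmark deletion-breakpoint assembly
#'
#' Simulates homozygous deletions: for each, the donor genome lacks a
#' segment, the target is the deleted segment padded by `pad` bp on each
#' side, and the expected assembly is the `2*pad` bp novel junction.
#'
#' @param n number of deletions.
#' @param sizeRange deletion length range in bp.
#' @param refLength,coverage per-deletion simulation scale.
#' @param pad padding (default 50, for an expected 100 bp breakpoint).
#' @param seed base seed.
#' @param flankSize,minOcc,ext pipeline parameters.
#' @param outDir scratch directory.
#' @return data.frame with one row per deletion: size, status, assembled
#'   breakpoint length, and classification against the known junction.
#' @export
benchmarkDeletions <- function(n = 10L, sizeRange = c(1000L, 5000L),
                               refLength = 120000L, coverage = 40,
                               pad = 50L, seed = 1, flankSize = 10000L,
                               minOcc = 2L, ext = 500L,
                               outDir = tempfile("delbench")) {
  rows <- list()
  for (i in seq_len(n)) {
    set.seed(seed + i)
    sz <- sample(seq(sizeRange[1], sizeRange[2]), 1)
    ref <- Biostrings::DNAStringSet(setNames(.randomDNA(refLength), "ref"))
    pt <- plantTarget(ref, "deletion", size = sz, pad = pad,
                      zygosity = "hom", margin = flankSize + 22000L)
    sim <- simulateLinkedReads(reference = ref, haplotypes = pt$haplotypes,
                               blocks = pt$blocks, coverage = coverage,
                               seed = seed + 100L + i,
                               outDir = file.path(outDir, i))
    idx <- buildBarcodeIndex(sim$fastqPath)
    w <- flankWindows(pt$target, flankSize)
    sel <- selectBarcodes(collectFlankBarcodes(sim$bamPath, w), minOcc)
    sub <- subsampleReads(sel, idx)
    res <- iterativeAssemble(pt$target, sub, sim$bamPath, ref, ext = ext)
    cls <- benchmarkClassify(res, pt$truth)
    rows[[i]] <- data.frame(
      size = sz, status = resultStatus(res),
      breakpointLength = if (resultStatus(res) == "assembled")
        nchar(resultSequence(res)[1]) else NA_integer_,
      class = cls$label, identity = cls$identity,
      stringsAsFactors = FALSE)
    unlink(file.path(outDir, i), recursive = TRUE)
  }
  do.call(rbind, rows)
}
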