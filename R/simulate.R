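## Synthetic linked-read generator. Long molecules (truncated-lognormal
## lengths) are placed uniformly on the donor haplotype(s), each molecule
## gets a barcode, and paired short reads are drawn from each molecule at a
## fixed per-molecule depth with iid substitution errors. The BAM is written
## from the truth placements; reads whose molecule interval does not map
## collinearly onto the reference (inside insertions, across deletion
## junctions) are emitted unmapped with their barcode preserved.

.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.randomBarcodes <- function(n, len = 16L) {
  repeat {
    bc <- vapply(seq_len(n), function(i) .randomDNA(len), character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

## identity coordinate map for an unmodified haplotype
.identityBlocks <- function(len) {
  data.frame(hapStart = 0, refStart = 0, length = len)
}

## map a 0-based hap interval [s, s+l) to reference coordinates, or NA when
## it is not contained in a single collinear block
.mapToRef <- function(blocks, s, l) {
  hit <- blocks$hapStart <= s & s + l <= blocks$hapStart + blocks$length
  if (!any(hit)) return(NA_real_)
  b <- blocks[which(hit)[1], ]
  b$refStart + (s - b$hapStart)
}

#' Simulate a linked-read dataset with ground truth
#'
#' Emulates the linked-read data model: long DNA molecules (lognormal
#' lengths truncated to \[molMin, molMax\]) carry a molecular barcode;
#' paired short reads are sampled from each molecule at depth
#' `molCoverage` and tagged with the molecule's barcode. Defaults mirror a
#' typical whole-genome linked-read run: 40x genome coverage, 100 bp reads,
#' 50 kb mean molecules, 0.5\% substitution errors, one molecule per
#' barcode.
#'
#' @param reference reference sequence: a named
#'   [Biostrings::DNAStringSet], a FASTA path, or NULL to generate a random
#'   sequence of `refLength` bp named `refName`.
#' @param refLength,refName used when `reference` is NULL.
#' @param haplotypes character vector of donor haplotype sequences (default
#'   the reference itself); reads are drawn from these.
#' @param blocks list (one per haplotype) of collinear coordinate maps to
#'   the reference, as returned by [plantTarget()]; default identity.
#' @param coverage total read depth over the reference.
#' @param readLength read length in bp.
#' @param molMean,molSdLog,molMin,molMax molecule length distribution:
#'   lognormal with mean `molMean`, log-sd `molSdLog`, truncated.
#' @param molCoverage per-molecule read depth (fraction of each molecule
#'   covered by its own reads; ~0.2 is typical of linked-read libraries).
#' @param molPerBarcode molecules sharing one barcode (>1 models barcode
#'   collisions).
#' @param insertMean,insertSd fragment (insert) size distribution.
#' @param errorRate per-base substitution error rate.
#' @param dialect barcode encoding in the FASTQ (see [buildBarcodeIndex()]).
#' @param seed random seed; identical seeds give byte-identical outputs.
#' @param outDir output directory (created); FASTA/FASTQ/BAM/TSVs written
#'   there.
#' @return list with paths (`refPath`, `fastqPath`, `bamPath`), the
#'   reference as a DNAStringSet, and truth tables `molecules` (molecule,
#'   barcode, haplotype, 0-based hap and reference intervals) and `reads`
#'   (read id, molecule, 0-based hap start of each mate).
#' @export
simulateLinkedReads <- function(reference = NULL, refLength = 100000L,
                                refName = "ref",
                                haplotypes = NULL, blocks = NULL,
                                coverage = 40, readLength = 100L,
                                molMean = 50000, molSdLog = 0.35,
                                molMin = 5000, molMax = 150000,
                                molCoverage = 0.2, molPerBarcode = 1L,
                                insertMean = 350, insertSd = 35,
                                errorRate = 0.005,
                                dialect = c("bx", "suffix"),
                                seed = NULL, outDir = tempfile("sim")) {
  dialect <- match.arg(dialect)
  if (!is.null(seed)) set.seed(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(reference)) {
    refSeq <- .randomDNA(refLength)
    reference <- Biostrings::DNAStringSet(setNames(refSeq, refName))
  } else {
    reference <- .asDNAStringSet(reference)
    refSeq <- as.character(reference[[1]])
    refName <- names(reference)[1]
    refLength <- nchar(refSeq)
  }
  if (is.null(haplotypes)) haplotypes <- setNames(refSeq, "hap1")
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("hap", seq_along(haplotypes))
  if (is.null(blocks))
    blocks <- lapply(haplotypes, function(h) .identityBlocks(nchar(h)))

  refPath <- file.path(outDir, "ref.fa")
  Biostrings::writeXStringSet(reference, refPath)

  ## molecules: draw until the expected read yield reaches the target
  targetBases <- refLength * coverage
  molBasesNeeded <- targetBases / molCoverage
  mlen <- integer(0)
  while (sum(mlen) < molBasesNeeded) {
    draw <- rlnorm(256, meanlog = log(molMean) - molSdLog^2 / 2,
                   sdlog = molSdLog)
    mlen <- c(mlen, as.integer(pmin(pmax(draw, molMin), molMax)))
  }
  mlen <- mlen[cumsum(as.numeric(mlen)) <= molBasesNeeded + molMax]
  nMol <- length(mlen)
  hap <- sample(rep_len(seq_along(haplotypes), nMol))
  hapLen <- nchar(haplotypes)
  mlen <- pmin(mlen, hapLen[hap])
  mstart <- floor(runif(nMol) * (hapLen[hap] - mlen + 1))

  nBc <- ceiling(nMol / molPerBarcode)
  bcPool <- .randomBarcodes(nBc)
  molBarcode <- bcPool[((sample(nMol) - 1L) %% nBc) + 1L]

  molecules <- data.frame(
    molecule = sprintf("m%06d", seq_len(nMol)),
    barcode = molBarcode,
    haplotype = names(haplotypes)[hap],
    hapStart = mstart, hapEnd = mstart + mlen,
    stringsAsFactors = FALSE)
  molecules$refStart <- vapply(seq_len(nMol), function(i)
    .mapToRef(blocks[[hap[i]]], mstart[i], 0), numeric(1))
  molecules$refEnd <- vapply(seq_len(nMol), function(i)
    .mapToRef(blocks[[hap[i]]], mstart[i] + mlen[i], 0), numeric(1))

  ## reads: per molecule, Poisson number of pairs at depth molCoverage
  nPairs <- rpois(nMol, mlen * molCoverage / (2 * readLength))
  molOf <- rep.int(seq_len(nMol), nPairs)
  nP <- length(molOf)
  insert <- as.integer(round(rnorm(nP, insertMean, insertSd)))
  insert <- pmax(insert, 2L * readLength)
  insert <- pmin(insert, mlen[molOf])
  fragStart <- floor(runif(nP) * (mlen[molOf] - insert + 1))
  s1 <- mstart[molOf] + fragStart                      # hap coords, 0-based
  s2 <- mstart[molOf] + fragStart + insert - readLength

  hseq <- haplotypes
  r1 <- substring(hseq[hap[molOf]], s1 + 1, s1 + readLength)
  r2 <- substring(hseq[hap[molOf]], s2 + 1, s2 + readLength)
  if (errorRate > 0) {
    r1 <- as.character(.mutate_seqs_cpp(r1, errorRate))
    r2 <- as.character(.mutate_seqs_cpp(r2, errorRate))
  }

  pairIdx <- sequence(nPairs)
  readId <- sprintf("%s_%04d", molecules$molecule[molOf], pairIdx)
  barcode <- molBarcode[molOf]

  reads <- data.frame(read = readId, molecule = molecules$molecule[molOf],
                      barcode = barcode, haplotype = names(haplotypes)[hap[molOf]],
                      start1 = s1, start2 = s2, stringsAsFactors = FALSE)

  ## FASTQ (mate 2 is the reverse strand of the fragment)
  r2fq <- as.character(.revcomp_cpp(r2))
  qual <- strrep("I", readLength)
  fastqPath <- file.path(outDir, "reads.fq")
  if (dialect == "bx") {
    h1 <- paste0("@", readId, "/1 BX:Z:", barcode)
    h2 <- paste0("@", readId, "/2 BX:Z:", barcode)
  } else {
    h1 <- paste0("@", readId, "#", barcode, "/1")
    h2 <- paste0("@", readId, "#", barcode, "/2")
  }
  writeLines(as.vector(rbind(h1, r1, "+", qual, h2, r2fq, "+", qual)),
             fastqPath)

  bamPath <- writeTruthBam(
    data.frame(read = readId, barcode = barcode,
               hap = hap[molOf], start1 = s1, start2 = s2,
               seq1 = r1, seq2 = r2, stringsAsFactors = FALSE),
    blocks, refName, refLength, readLength,
    file.path(outDir, "aln"))

  write.table(molecules, file.path(outDir, "molecules.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(reads, file.path(outDir, "reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  list(refPath = refPath, fastqPath = fastqPath, bamPath = bamPath,
       reference = reference, molecules = molecules, reads = reads,
       outDir = outDir)
}

#' Write a BAM of truth placements
#'
#' Each mate is placed at its true reference position (haplotype
#' coordinates mapped through the collinear blocks); mates that do not map
#' collinearly are emitted unmapped, keeping their barcode. Mate 1 is
#' forward, mate 2 reverse; substitution-only errors keep CIGARs as full
#' matches. The BAM is coordinate-sorted and indexed.
#'
#' @param pairs data.frame with columns `read`, `barcode`, `hap` (haplotype
#'   index), `start1`, `start2` (0-based hap coords), `seq1`, `seq2`. Both
#'   sequences are given in reference (genomic) orientation; the reverse
#'   flag on mate 2 records its strand, as SAM requires.
#' @param blocks per-haplotype collinear maps (see [simulateLinkedReads()]).
#' @param refName,refLength reference sequence name and length.
#' @param readLength read length.
#' @param dest output path without extension.
#' @return path of the sorted, indexed BAM.
#' @export
writeTruthBam <- function(pairs, blocks, refName, refLength, readLength,
                          dest) {
  n <- nrow(pairs)
  p1 <- vapply(seq_len(n), function(i)
    .mapToRef(blocks[[pairs$hap[i]]], pairs$start1[i], readLength), numeric(1))
  p2 <- vapply(seq_len(n), function(i)
    .mapToRef(blocks[[pairs$hap[i]]], pairs$start2[i], readLength), numeric(1))
  m1 <- !is.na(p1); m2 <- !is.na(p2)
  qual <- strrep("I", readLength)
  cig <- paste0(readLength, "M")
  bx <- paste0("BX:Z:", pairs$barcode)

  flag1 <- 1L + 64L + ifelse(m1, 0L, 4L) + ifelse(m2, 32L, 8L)
  flag2 <- 1L + 128L + ifelse(m2, 16L, 4L) + ifelse(m1, 0L, 8L)
  proper <- m1 & m2
  flag1 <- flag1 + ifelse(proper, 2L, 0L)
  flag2 <- flag2 + ifelse(proper, 2L, 0L)
  ## unmapped mate placed at its mate's coordinate for sortability
  pos1 <- ifelse(m1, p1 + 1, ifelse(m2, p2 + 1, 0))
  pos2 <- ifelse(m2, p2 + 1, ifelse(m1, p1 + 1, 0))
  rn1 <- ifelse(m1 | m2, refName, "*")
  tlen <- ifelse(proper, p2 + readLength - p1, 0)

  line <- function(id, flag, rname, pos, mapq, cigar, rnext, pnext, tl,
                   seq, tag)
    paste(id, flag, rname, format(pos, scientific = FALSE, trim = TRUE),
          mapq, cigar, rnext, format(pnext, scientific = FALSE, trim = TRUE),
          format(tl, scientific = FALSE, trim = TRUE), seq, qual, tag,
          sep = "\t")

  l1 <- line(pairs$read, flag1, rn1, pos1, ifelse(m1, 60L, 0L),
             ifelse(m1, cig, "*"), ifelse(m2 | m1, "=", "*"), pos2,
             tlen, pairs$seq1, bx)
  l2 <- line(pairs$read, flag2, rn1, pos2, ifelse(m2, 60L, 0L),
             ifelse(m2, cig, "*"), ifelse(m1 | m2, "=", "*"), pos1,
             -tlen, pairs$seq2, bx)

  samPath <- paste0(dest, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", refName, "\tLN:", refLength),
               l1, l2), samPath)
  tmpBam <- Rsamtools::asBam(samPath, paste0(dest, ".unsorted"),
                             overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(tmpBam, dest)
  Rsamtools::indexBam(bam)
  unlink(c(samPath, tmpBam))
  bam
}

#' Plant a target in a reference for benchmarking
#'
#' Prepares donor haplotype(s), the target definition, and the truth
#' sequence for one of three benchmark modes: `"locus"` (the target is a
#' sequence already present in the reference at a randomly chosen locus),
#' `"deletion"` (the donor lacks a segment; the target is the deleted
#' segment padded by `pad` bp, and the truth the `2*pad` bp breakpoint
#' junction), `"insertion"` (the donor carries an extra sequence at a site;
#' the target is the site padded by `pad` bp and the truth the padded
#' insertion; the expected assembled length is unknown a priori).
#'
#' @param reference named [Biostrings::DNAStringSet] (single sequence) or
#'   character.
#' @param type benchmark mode.
#' @param size target (or deleted segment / inserted sequence) length.
#' @param at 0-based position; chosen uniformly at random when NULL.
#' @param sequence insertion sequence (random of length `size` when NULL).
#' @param pad padding in bp for SV modes.
#' @param zygosity `"hom"` (all molecules from the donor) or `"het"` (donor
#'   and reference haplotypes in equal proportion).
#' @param margin minimum distance of the target from the reference ends
#'   (leaves room for flank windows and extensions).
#' @param label target label.
#' @param refName reference sequence name used in the target's regions.
#' @return list with `haplotypes`, `blocks` (for [simulateLinkedReads()]),
#'   `target` ([TargetLocus-class]), `truth` (character; for heterozygous
#'   insertions, alt allele first then reference allele), and `at`.
#' @export
plantTarget <- function(reference, type = c("locus", "deletion", "insertion"),
                        size = 1000L, at = NULL, sequence = NULL, pad = 50L,
                        zygosity = c("hom", "het"), margin = 30000L,
                        label = NULL, refName = "ref") {
  type <- match.arg(type)
  zygosity <- match.arg(zygosity)
  if (methods::is(reference, "DNAStringSet")) {
    refSeq <- as.character(reference[[1]])
  } else refSeq <- as.character(reference)
  refLen <- nchar(refSeq)
  size <- as.integer(size)
  if (type == "insertion" && is.null(sequence)) sequence <- .randomDNA(size)
  if (type == "insertion") size <- nchar(sequence)
  span <- if (type == "insertion") 0L else size
  if (refLen - 2L * margin - span <= 0L)
    stop("reference too short for margin ", margin, " and size ", span)
  if (is.null(at)) at <- margin + floor(runif(1) * (refLen - 2 * margin - span))
  at <- as.integer(at)
  sub <- function(s, e) substr(refSeq, s + 1L, e)   # 0-based half-open

  if (type == "locus") {
    if (is.null(label)) label <- sprintf("locus_%d_%d", at, size)
    target <- targetLocus(label,
      region(refName, 0, at), region(refName, at + size, refLen),
      gapEstimate = size)
    return(list(haplotypes = setNames(refSeq, "hap1"),
                blocks = list(.identityBlocks(refLen)),
                target = target, truth = sub(at, at + size), at = at))
  }

  if (type == "deletion") {
    donor <- paste0(sub(0, at), sub(at + size, refLen))
    blocksDonor <- data.frame(hapStart = c(0, at),
                              refStart = c(0, at + size),
                              length = c(at, refLen - size - at))
    if (is.null(label)) label <- sprintf("del_%d_%d", at, size)
    target <- targetLocus(label,
      region(refName, 0, at - pad), region(refName, at + size + pad, refLen),
      gapEstimate = 2L * pad)
    truth <- paste0(sub(at - pad, at), sub(at + size, at + size + pad))
    haps <- if (zygosity == "hom") setNames(donor, "hap1")
            else setNames(c(donor, refSeq), c("hap1", "hap2"))
    blocks <- if (zygosity == "hom") list(blocksDonor)
              else list(blocksDonor, .identityBlocks(refLen))
    return(list(haplotypes = haps, blocks = blocks, target = target,
                truth = truth, at = at))
  }

  ## insertion
  ins <- toupper(sequence)
  donor <- paste0(sub(0, at), ins, sub(at, refLen))
  blocksDonor <- data.frame(hapStart = c(0, at + size),
                            refStart = c(0, at),
                            length = c(at, refLen - at))
  if (is.null(label)) label <- sprintf("ins_%d_%d", at, size)
  target <- targetLocus(label,
    region(refName, 0, at - pad), region(refName, at + pad, refLen),
    gapEstimate = NA_integer_)
  truthAlt <- paste0(sub(at - pad, at), ins, sub(at, at + pad))
  truthRef <- sub(at - pad, at + pad)
  haps <- if (zygosity == "hom") setNames(donor, "hap1")
          else setNames(c(donor, refSeq), c("hap1", "hap2"))
  blocks <- if (zygosity == "hom") list(blocksDonor)
            else list(blocksDonor, .identityBlocks(refLen))
  truth <- if (zygosity == "hom") truthAlt else c(truthAlt, truthRef)
  list(haplotypes = haps, blocks = blocks, target = target, truth = truth,
       at = at)
}
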