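## Session-cached simulation fixtures shared across test files. Each is
## built once on first use. Sizes are scaled for fast unit testing; the
## acceptance tests build their own full-scale simulations.

.fixtureCache <- new.env(parent = emptyenv())

## haploid 100 kb reference at 40x with one plantable 1 kb locus
fixtureSim <- function() {
  if (!exists("sim", .fixtureCache)) {
    set.seed(20240101)
    ref <- Biostrings::DNAStringSet(setNames(randomSeq(100000), "ref"))
    pt <- plantTarget(ref, "locus", size = 1000, at = 52000, margin = 25000)
    sim <- simulateLinkedReads(reference = ref, coverage = 40, seed = 7,
                               outDir = file.path(tempdir(), "fixsim"))
    idx <- buildBarcodeIndex(sim$fastqPath)
    assign("sim", list(ref = ref, pt = pt, sim = sim, idx = idx),
           .fixtureCache)
  }
  get("sim", .fixtureCache)
}

## tiny 6-read FASTQ with barcodes {X: 4 reads, Y: 2 reads}
fixtureTinyFastq <- function(dialect = "bx") {
  path <- tempfile(fileext = ".fq")
  rec <- function(id, bc, seq) {
    hdr <- if (dialect == "bx") paste0("@", id, " BX:Z:", bc)
           else paste0("@", sub("(/[12])$", paste0("#", bc, "\\1"), id))
    c(hdr, seq, "+", strrep("I", nchar(seq)))
  }
  writeLines(c(
    rec("p1/1", "X", "ACGTACGTAC"), rec("p1/2", "X", "TTGCATGCAA"),
    rec("p2/1", "Y", "GGGGCCCCAA"), rec("p2/2", "Y", "AACCGGTTAA"),
    rec("p3/1", "X", "ACACACACAC"), rec("p3/2", "X", "GTGTGTGTGT")),
    path)
  path
}

## small BAM with hand-placed reads for anchor-picking tests: reads are
## supplied as (start, seq) on a given reference string; each record
## contributes exactly one mapped read (its mate is left unmapped)
fixtureBamFromReads <- function(refSeq, starts, seqs, refName = "ref") {
  rl <- nchar(seqs[1])
  pairs <- data.frame(
    read = sprintf("r%03d", seq_along(starts)), barcode = "AAAA",
    hap = 1L, start1 = starts, start2 = -1000L,
    seq1 = seqs, seq2 = seqs, stringsAsFactors = FALSE)
  writeTruthBam(pairs, list(data.frame(hapStart = 0, refStart = 0,
                                       length = nchar(refSeq))),
                refName, nchar(refSeq), rl,
                tempfile("anchorbam"))
}
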