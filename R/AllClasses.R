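#' @importClassesFrom GenomicRanges GRanges
NULL

## Central value classes. Coordinates handed to constructors are 0-based
## half-open (the GFA/BED convention); they are stored as native 1-based
## GRanges and converted back only at format boundaries (see region()).

#' TargetLocus: a gap between two oriented flanks on a reference
#'
#' A target locus is the unknown sequence between two known flanking
#' sequences. Each flank is an oriented region of the reference the reads
#' were mapped to; the left flank is oriented so its 3' end abuts the gap,
#' the right flank so its 5' end abuts the gap.
#'
#' @slot label unique identifier of the target within a run.
#' @slot leftFlank,rightFlank length-1 [GenomicRanges::GRanges] with strand.
#' @slot gapEstimate estimated length in bp of the sequence to assemble, or
#'   `NA_integer_` when unknown (e.g. inter-scaffold gaps, insertions).
#' @exportClass TargetLocus
setClass("TargetLocus",
  representation(label = "character", leftFlank = "GRanges",
                 rightFlank = "GRanges", gapEstimate = "integer"))

setValidity("TargetLocus", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "label must be a single non-empty string")
  if (length(object@leftFlank) != 1L || length(object@rightFlank) != 1L)
    msg <- c(msg, "flanks must be length-1 GRanges")
  st <- c(as.character(GenomicRanges::strand(object@leftFlank)),
          as.character(GenomicRanges::strand(object@rightFlank)))
  if (any(!st %in% c("+", "-")))
    msg <- c(msg, "flank strand must be '+' or '-'")
  if (length(object@gapEstimate) != 1L)
    msg <- c(msg, "gapEstimate must be length 1")
  if (!is.na(object@gapEstimate) && object@gapEstimate < 0L)
    msg <- c(msg, "gapEstimate must be >= 0 or NA")
  if (length(msg)) msg else TRUE
})

#' BarcodeIndex: barcode-keyed index over a linked-read FASTQ file
#'
#' Maps each barcode to the record positions of its reads in the backing
#' file, so that all reads of a set of barcodes can be extracted in bulk.
#' Parsed read records are cached in memory; [saveBarcodeIndex()] persists
#' the barcode table so re-runs skip re-indexing.
#'
#' @slot fastq path of the backing read file.
#' @slot reads data.frame with columns `id`, `mate`, `seq`, `qual`,
#'   `barcode` (NA for un-barcoded reads), one row per record in file order.
#' @slot index named list, barcode -> integer vector of row numbers.
#' @exportClass BarcodeIndex
setClass("BarcodeIndex",
  representation(fastq = "character", reads = "data.frame", index = "list"))

setValidity("BarcodeIndex", function(object) {
  msg <- character()
  need <- c("id", "mate", "seq", "qual", "barcode")
  if (!all(need %in% names(object@reads)))
    msg <- c(msg, paste("reads must have columns", paste(need, collapse = ", ")))
  if (length(object@index)) {
    if (is.null(names(object@index)) || any(!nzchar(names(object@index))))
      msg <- c(msg, "index must be named by barcode")
  }
  if (length(msg)) msg else TRUE
})

#' DeBruijnGraph: canonical solid k-mer set with abundances
#'
#' Stores counts of all canonical k-mers of a read set; only k-mers with
#' abundance at least `minAbundance` are *solid*, i.e. part of the graph
#' that is traversed. Membership is strand-symmetric: a k-mer and its
#' reverse complement are the same node.
#'
#' @slot k k-mer size (odd).
#' @slot minAbundance solidity threshold `a`.
#' @slot kmers canonical k-mer strings (lexicographically sorted).
#' @slot counts abundance of each k-mer.
#' @exportClass DeBruijnGraph
setClass("DeBruijnGraph",
  representation(k = "integer", minAbundance = "integer",
                 kmers = "character", counts = "integer"))

setValidity("DeBruijnGraph", function(object) {
  msg <- character()
  if (object@k < 2L)
    msg <- c(msg, "k must be >= 2")
  if (object@minAbundance < 1L)
    msg <- c(msg, "minAbundance must be >= 1")
  if (length(object@kmers) != length(object@counts))
    msg <- c(msg, "kmers and counts lengths differ")
  if (length(msg)) msg else TRUE
})

#' AssemblyParams: de Bruijn graph assembly parameters
#'
#' @slot k k-mer size (odd, typically 21-61).
#' @slot a solid k-mer abundance threshold (>= 1).
#' @slot maxPathLength cap in bp on an assembled sequence.
#' @slot maxActiveBranches cap on the number of partial paths kept on the
#'   breadth-first frontier.
#' @slot maxNodesExplored global exploration budget (accepted extensions).
#' @exportClass AssemblyParams
setClass("AssemblyParams",
  representation(k = "integer", a = "integer", maxPathLength = "integer",
                 maxActiveBranches = "integer", maxNodesExplored = "numeric"))

setValidity("AssemblyParams", function(object) {
  msg <- character()
  if (object@k %% 2L == 0L) msg <- c(msg, "k must be odd")
  if (object@a < 1L) msg <- c(msg, "a must be >= 1")
  if (object@maxPathLength <= 0L || object@maxActiveBranches <= 0L ||
      object@maxNodesExplored <= 0)
    msg <- c(msg, "exploration caps must be positive")
  if (length(msg)) msg else TRUE
})

#' AssemblyCandidate: one traversal path with its parameters
#'
#' @slot sequence assembled sequence from the START k-mer through the STOP
#'   k-mer inclusive (extensions still attached).
#' @slot k,a parameters the candidate was assembled with.
#' @slot pathLength length of `sequence` in bp.
#' @slot limitReached whether exploration limits were hit during traversal.
#' @exportClass AssemblyCandidate
setClass("AssemblyCandidate",
  representation(sequence = "character", k = "integer", a = "integer",
                 pathLength = "integer", limitReached = "logical"))

#' QualityVerdict: extension-alignment quality gate result
#'
#' Pass requires, on each side, identity > minIdentity over coverage >
#' minCoverage of the extension reference.
#'
#' @slot leftIdentity,rightIdentity identity fraction of each extension.
#' @slot leftCoverage,rightCoverage fraction of each extension reference
#'   covered by the alignment.
#' @slot pass logical gate outcome.
#' @slot reason short failure reason ("" on pass).
#' @exportClass QualityVerdict
setClass("QualityVerdict",
  representation(leftIdentity = "numeric", leftCoverage = "numeric",
                 rightIdentity = "numeric", rightCoverage = "numeric",
                 pass = "logical", reason = "character"))

#' AssemblyResult: final outcome for one target
#'
#' @slot label target label.
#' @slot status one of "assembled", "multiple_solutions", "no_assembly".
#' @slot sequence assembled target (extensions trimmed); empty unless
#'   status is "assembled", or "multiple_solutions" with report-multiple.
#' @slot k,a the ladder step that produced the result (NA if none).
#' @slot verdict [QualityVerdict] of the reported sequence (or first pass).
#' @slot details list with diagnostics (per-step log, read/barcode counts).
#' @exportClass AssemblyResult
setClass("AssemblyResult",
  representation(label = "character", status = "character",
                 sequence = "character", k = "integer", a = "integer",
                 verdict = "ANY", details = "list"))

## ---- show methods -------------------------------------------------------

setMethod("show", "TargetLocus", function(object) {
  fmt <- function(gr) sprintf("%s:%d-%d(%s)",
    as.character(GenomeInfoDb::seqnames(gr)),
    GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
    as.character(GenomicRanges::strand(gr)))
  cat("TargetLocus '", object@label, "'\n", sep = "")
  cat("  left flank : ", fmt(object@leftFlank), "\n", sep = "")
  cat("  right flank: ", fmt(object@rightFlank), "\n", sep = "")
  cat("  gap length : ",
      if (is.na(object@gapEstimate)) "unknown" else object@gapEstimate,
      "\n", sep = "")
})

setMethod("show", "BarcodeIndex", function(object) {
  cat("BarcodeIndex on '", object@fastq, "'\n", sep = "")
  cat("  ", nrow(object@reads), " reads, ", length(object@index),
      " barcodes\n", sep = "")
})

setMethod("show", "DeBruijnGraph", function(object) {
  solid <- sum(object@counts >= object@minAbundance)
  cat("DeBruijnGraph k=", object@k, " a=", object@minAbundance,
      ": ", solid, " solid / ", length(object@kmers),
      " distinct canonical k-mers\n", sep = "")
})

setMethod("show", "AssemblyResult", function(object) {
  cat("AssemblyResult '", object@label, "': ", object@status, sep = "")
  if (!is.na(object@k)) cat(" (k=", object@k, ", a=", object@a, ")", sep = "")
  if (length(object@sequence) && nzchar(object@sequence[1]))
    cat(", ", nchar(object@sequence[1]), " bp", sep = "")
  cat("\n")
})

## ---- accessors ----------------------------------------------------------

#' Accessors for linklocal classes
#'
#' @param x a linklocal object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases targetLabel leftFlank rightFlank gapEstimate kmerSize
#'   solidKmers resultStatus resultSequence
NULL

#' @rdname accessors
#' @export
targetLabel <- function(x) x@label

#' @rdname accessors
#' @export
leftFlank <- function(x) x@leftFlank

#' @rdname accessors
#' @export
rightFlank <- function(x) x@rightFlank

#' @rdname accessors
#' @export
gapEstimate <- function(x) x@gapEstimate

#' @rdname accessors
#' @export
kmerSize <- function(x) x@k

#' @rdname accessors
#' @export
solidKmers <- function(x) x@kmers[x@counts >= x@minAbundance]

#' @rdname accessors
#' @export
resultStatus <- function(x) x@status

#' @rdname accessors
#' @export
resultSequence <- function(x) x@sequence

#' Construct assembly parameters
#'
#' Defaults follow common solid-k-mer practice for 20-50x linked-read
#' subsamples. `maxPathLength` defaults to the gap length estimate plus the
#' two extensions plus 10 kb slack, or 50 kb when the estimate is unknown
#' (bounded by the reach of the long molecules).
#'
#' @param k k-mer size, odd.
#' @param a solid k-mer abundance threshold.
#' @param gapEstimate gap length estimate in bp used to derive
#'   `maxPathLength` (NA for unknown).
#' @param ext flank extension length in bp (see [scoreCandidate()]).
#' @param maxPathLength,maxActiveBranches,maxNodesExplored explicit caps.
#' @return an [AssemblyParams-class] object.
#' @export
assemblyParams <- function(k = 61L, a = 3L, gapEstimate = NA_integer_,
                           ext = 500L,
                           maxPathLength = NULL,
                           maxActiveBranches = 100L,
                           maxNodesExplored = 1e7) {
  if (is.null(maxPathLength)) {
    maxPathLength <- if (is.na(gapEstimate)) 50000L
                     else as.integer(gapEstimate + 2L * ext + 10000L)
  }
  new("AssemblyParams", k = as.integer(k), a = as.integer(a),
      maxPathLength = as.integer(maxPathLength),
      maxActiveBranches = as.integer(maxActiveBranches),
      maxNodesExplored = as.numeric(maxNodesExplored))
}
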