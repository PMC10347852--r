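## Barcode-based read subsampling: the core of the method. Barcodes observed
## in the two windows flanking the target are collected from the BAM, kept if
## seen at least `minOcc` times, and the whole read file is then searched for
## the reads (both mates) carrying those barcodes.

#' Flanking windows of a target
#'
#' The window of length at most `flankSize` immediately adjacent to the gap
#' on each flank, truncated at the flank's extent (never empty).
#'
#' @param target a [TargetLocus-class].
#' @param flankSize window size in bp (the `-flank` parameter).
#' @return list with elements `left` and `right`, each a length-1 GRanges.
#' @export
flankWindows <- function(target, flankSize) {
  flankSize <- as.integer(flankSize)
  if (flankSize <= 0L) stop("flankSize must be positive")
  one <- function(flank, side) {
    inner <- flankInnerCoord(flank, side)
    if (inner$into < 0L) {
      s0 <- max(regionStart0(flank), inner$coord - flankSize)
      e0 <- inner$coord
    } else {
      s0 <- inner$coord
      e0 <- min(regionEnd0(flank), inner$coord + flankSize)
    }
    region(regionSeq(flank), s0, e0, regionStrand(flank))
  }
  list(left = one(target@leftFlank, "left"),
       right = one(target@rightFlank, "right"))
}

## alignment filters used everywhere a barcode is counted: primary mapped
## records only, no duplicates, MAPQ >= 1
.countingFlags <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = FALSE)
}

## fetch (qname, mate, barcode) of counting-eligible alignments overlapping
## a window (>= 1 bp)
.windowAlignments <- function(bam, window) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  sq <- regionSeq(window)
  if (!sq %in% names(hdr))
    stop("sequence '", sq, "' absent from BAM header")
  gr <- GenomicRanges::GRanges(sq,
          IRanges::IRanges(GenomicRanges::start(window),
                           GenomicRanges::end(window)))
  p <- Rsamtools::ScanBamParam(which = gr, what = c("qname", "flag"),
                               tag = "BX", flag = .countingFlags(),
                               mapqFilter = 1L)
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  bx <- res$tag$BX
  if (is.null(bx)) bx <- rep(NA_character_, length(res$qname))
  data.frame(qname = res$qname,
             mate = ifelse(bitwAnd(res$flag, 128L) > 0L, 2L, 1L),
             barcode = bx, stringsAsFactors = FALSE)
}

#' Count barcode occurrences in flanking windows
#'
#' Counts read alignments per barcode over the union of both windows. A read
#' overlapping a window by at least 1 bp counts once; secondary,
#' supplementary, duplicate and MAPQ-0 alignments are excluded.
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param windows list of two windows as returned by [flankWindows()].
#' @param perSide if TRUE, additionally return per-window tables (used by
#'   the strict per-side selection mode).
#' @return named integer vector (barcode -> count), sorted by barcode; with
#'   `perSide`, a list with elements `union`, `left`, `right`.
#' @export
collectFlankBarcodes <- function(bam, windows, perSide = FALSE) {
  aln <- lapply(windows, function(w) .windowAlignments(bam, w))
  tab <- function(df) {
    df <- df[!is.na(df$barcode), , drop = FALSE]
    df <- df[!duplicated(paste0(df$qname, "/", df$mate)), , drop = FALSE]
    if (nrow(df) == 0L) return(setNames(integer(0), character(0)))
    t <- table(df$barcode)
    setNames(as.integer(t), names(t))
  }
  all <- do.call(rbind, aln)
  u <- tab(all)
  if (length(u) > 1L) u <- u[order(names(u))]
  if (!perSide) return(u)
  list(union = u, left = tab(aln[[1]]), right = tab(aln[[2]]))
}

#' Select barcodes by minimum occurrence
#'
#' @param table occurrence table from [collectFlankBarcodes()].
#' @param minOcc minimum number of observations in the flanking windows for
#'   a barcode to be retained (the `-occ` parameter).
#' @param strictTables optional `perSide` list from [collectFlankBarcodes()];
#'   when given, a barcode is additionally required to be observed at least
#'   once in each window (strict mode for inter-scaffold gaps).
#' @return sorted character vector of selected barcodes, with the occurrence
#'   table attached as attribute `"table"`.
#' @export
selectBarcodes <- function(table, minOcc = 2L, strictTables = NULL) {
  if (minOcc < 1L) stop("minOcc must be >= 1")
  sel <- names(table)[table >= minOcc]
  if (!is.null(strictTables))
    sel <- intersect(sel, intersect(names(strictTables$left),
                                    names(strictTables$right)))
  sel <- sort(sel)
  attr(sel, "table") <- table
  sel
}

#' Recruit the reads of the selected barcodes
#'
#' Fetches, genome-wide, every read (both mates, mapped or not) whose
#' barcode was selected. Recruiting reads far from the target is the point:
#' reads of molecules spanning the gap carry the gap sequence even though
#' they map nowhere near it (or nowhere at all).
#'
#' @param barcodes selected barcodes (from [selectBarcodes()]).
#' @param index a [BarcodeIndex-class] over the full read file.
#' @return data.frame of read records in file order (see
#'   [fetchReadsByBarcodes()]).
#' @export
subsampleReads <- function(barcodes, index) {
  if (length(barcodes) == 0L) {
    warning("empty barcode selection: no reads recruited")
    return(index@reads[0L, , drop = FALSE])
  }
  fetchReadsByBarcodes(index, barcodes)
}

#' Count barcodes shared between two regions
#'
#' The number of barcodes selected (same occurrence rule) in both regions;
#' used e.g. to order scaffolds by linked-read support before inter-scaffold
#' gap-filling.
#'
#' @param bam indexed BAM path.
#' @param regionA,regionB regions (see [region()]).
#' @param minOcc minimum per-region occurrence count.
#' @return integer.
#' @export
countSharedBarcodes <- function(bam, regionA, regionB, minOcc = 2L) {
  sel <- function(r) {
    t <- collectFlankBarcodes(bam, list(r))
    names(t)[t >= minOcc]
  }
  length(intersect(sel(regionA), sel(regionB)))
}
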