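## Coordinate conventions: every user-facing coordinate in this file is
## 0-based half-open (GFA/BED style). GRanges (1-based closed) is the internal
## container; conversion happens only here and in the BAM/GFA readers.

#' Build an oriented region from 0-based half-open coordinates
#'
#' @param seqid reference sequence name.
#' @param start 0-based inclusive start.
#' @param end exclusive end.
#' @param strand "+" or "-".
#' @return a length-1 [GenomicRanges::GRanges].
#' @export
region <- function(seqid, start, end, strand = "+") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(end <= start))
    stop("invalid region: need 0 <= start < end (got ", start, "-", end, ")")
  GenomicRanges::GRanges(seqid,
    IRanges::IRanges(start = start + 1, end = end), strand = strand)
}

## 0-based half-open view of a GRanges
regionStart0 <- function(gr) GenomicRanges::start(gr) - 1L
regionEnd0 <- function(gr) GenomicRanges::end(gr)
regionSeq <- function(gr) as.character(GenomeInfoDb::seqnames(gr))
regionStrand <- function(gr) as.character(GenomicRanges::strand(gr))

#' Construct a target locus
#'
#' @param label unique target identifier.
#' @param leftFlank,rightFlank oriented flank regions (see [region()]). The
#'   left flank is oriented so its 3' end abuts the gap, the right flank so
#'   its 5' end abuts the gap.
#' @param gapEstimate estimated gap length in bp, NA when unknown.
#' @return a [TargetLocus-class].
#' @export
targetLocus <- function(label, leftFlank, rightFlank,
                        gapEstimate = NA_integer_) {
  new("TargetLocus", label = as.character(label), leftFlank = leftFlank,
      rightFlank = rightFlank,
      gapEstimate = as.integer(round(gapEstimate)))
}

## The reference coordinate at which a flank meets the gap, and the direction
## (+1/-1 on the reference) pointing from the gap into the flank.
## side = "left" or "right" of the gap, in gap orientation.
flankInnerCoord <- function(flank, side) {
  st <- regionStrand(flank)
  if (side == "left") {
    if (st == "+") list(coord = regionEnd0(flank), into = -1L)
    else list(coord = regionStart0(flank), into = +1L)
  } else {
    if (st == "+") list(coord = regionStart0(flank), into = +1L)
    else list(coord = regionEnd0(flank), into = -1L)
  }
}

## Extract, in gap orientation, the `len` bp of flank sequence abutting the
## gap, optionally offset further into the flank by `offset` bp.
## Returns a character scalar. `ref` is a named DNAStringSet.
flankSequence <- function(ref, flank, side, len, offset = 0L) {
  inner <- flankInnerCoord(flank, side)
  sq <- regionSeq(flank)
  if (!sq %in% names(ref)) stop("sequence '", sq, "' absent from reference")
  if (inner$into < 0L) {        # flank lies left of the gap on the reference
    e0 <- inner$coord - offset
    s0 <- e0 - len
  } else {
    s0 <- inner$coord + offset
    e0 <- s0 + len
  }
  if (s0 < 0 || e0 > Biostrings::width(ref[sq]))
    stop("flank window ", sq, ":", s0, "-", e0, " outside reference")
  s <- as.character(Biostrings::subseq(ref[[sq]], start = s0 + 1, end = e0))
  ## orient into the gap: left flank read towards the gap, right flank away
  rc <- if (side == "left") inner$into == +1L else inner$into == -1L
  if (rc) s <- as.character(.revcomp_cpp(s)) else s
  s
}

## Reference interval (0-based half-open) of the anchor k-mer on one side,
## given extension ext: the START k-mer is the first k bases of the left
## extension, the STOP k-mer the last k bases of the right extension.
anchorInterval <- function(flank, side, k, ext) {
  inner <- flankInnerCoord(flank, side)
  if (side == "left") {
    if (inner$into < 0L) c(inner$coord - ext, inner$coord - ext + k)
    else c(inner$coord + ext - k, inner$coord + ext)
  } else {
    if (inner$into > 0L) c(inner$coord + ext - k, inner$coord + ext)
    else c(inner$coord - ext, inner$coord - ext + k)
  }
}

## Does the anchor k-mer need reverse-complementing to point into the gap
## (left side) / along the gap direction (right side)?
anchorNeedsRC <- function(flank, side) {
  inner <- flankInnerCoord(flank, side)
  if (side == "left") inner$into == +1L else inner$into == -1L
}
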