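## GFA 2.0 I/O. Targets are G (gap) lines between two oriented S (segment)
## lines. A segment is resolved on the reference either as a whole sequence
## (its name matches a FASTA name) or as a coordinate window written
## "seq:start-end" in 0-based half-open coordinates. Unknown gap lengths are
## written as dist 0 with a GE:Z:unknown tag (GFA2 requires an integer dist).

.coordPattern <- "^(.+):([0-9]+)-([0-9]+)$"

## resolve a segment name to a region (strand filled in later)
.resolveSegment <- function(sid, ref) {
  m <- regmatches(sid, regexec(.coordPattern, sid))[[1]]
  if (length(m) == 4L && m[2] %in% names(ref)) {
    region(m[2], as.numeric(m[3]), as.numeric(m[4]))
  } else if (sid %in% names(ref)) {
    region(sid, 0, Biostrings::width(ref[sid]))
  } else {
    stop("segment '", sid, "' is neither a reference sequence name nor a ",
         "resolvable coordinate window (seq:start-end)")
  }
}

.parseOrientedSid <- function(field, lineno) {
  n <- nchar(field)
  sign <- substr(field, n, n)
  if (!sign %in% c("+", "-"))
    stop("malformed G line ", lineno, ": segment reference '", field,
         "' lacks +/- orientation")
  list(sid = substr(field, 1L, n - 1L), strand = sign)
}

#' Read target loci from a GFA 2.0 file
#'
#' Every G line becomes one [TargetLocus-class]: the two referenced segments
#' are resolved on the reference and oriented per the G line so that both
#' flanks point into the gap.
#'
#' @param gfaPath path to a GFA 2.0 file with S and G lines.
#' @param reference a named [Biostrings::DNAStringSet] (or FASTA path).
#' @return list of [TargetLocus-class] objects.
#' @export
readGfaTargets <- function(gfaPath, reference) {
  ref <- .asDNAStringSet(reference)
  lines <- readLines(gfaPath)
  targets <- list()
  gi <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "G\t") && !startsWith(ln, "G ")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L)
      stop("malformed G line ", i, ": expected at least 5 fields, got ",
           length(f), " in: ", ln)
    gi <- gi + 1L
    o1 <- .parseOrientedSid(f[3], i)
    o2 <- .parseOrientedSid(f[4], i)
    dist <- suppressWarnings(as.integer(f[5]))
    if (is.na(dist) && f[5] != "*")
      stop("malformed G line ", i, ": dist field '", f[5], "' is not an integer")
    tags <- if (length(f) > 6L) f[-(1:6)] else character()
    if (f[5] == "*" || any(tags == "GE:Z:unknown") ||
        (length(f) >= 6L && f[6] == "GE:Z:unknown"))
      dist <- NA_integer_
    lf <- .resolveSegment(o1$sid, ref)
    rf <- .resolveSegment(o2$sid, ref)
    GenomicRanges::strand(lf) <- o1$strand
    GenomicRanges::strand(rf) <- o2$strand
    label <- if (f[2] == "*") sprintf("gap%d_%s_%s", gi, o1$sid, o2$sid) else f[2]
    targets[[length(targets) + 1L]] <-
      targetLocus(label, lf, rf, gapEstimate = dist)
  }
  targets
}

.segmentName <- function(flank, ref) {
  sq <- regionSeq(flank)
  if (regionStart0(flank) == 0L && regionEnd0(flank) == Biostrings::width(ref[sq]))
    sq
  else sprintf("%s:%d-%d", sq, regionStart0(flank), regionEnd0(flank))
}

#' Write target loci as a GFA 2.0 file
#'
#' Inverse of [readGfaTargets()]: emits one S line per distinct flank
#' segment (sequence omitted, length recorded) and one G line per target.
#'
#' @param targets list of [TargetLocus-class].
#' @param path output file.
#' @param reference named [Biostrings::DNAStringSet] (or FASTA path) used to
#'   name and size the segments.
#' @return `path`, invisibly.
#' @export
writeGfaTargets <- function(targets, path, reference) {
  ref <- .asDNAStringSet(reference)
  segs <- character(); slines <- character(); glines <- character()
  for (t in targets) {
    n1 <- .segmentName(t@leftFlank, ref)
    n2 <- .segmentName(t@rightFlank, ref)
    for (nm in c(n1, n2)) {
      if (!nm %in% segs) {
        segs <- c(segs, nm)
        w <- if (grepl(.coordPattern, nm) && !nm %in% names(ref)) {
          m <- regmatches(nm, regexec(.coordPattern, nm))[[1]]
          as.integer(m[4]) - as.integer(m[3])
        } else as.integer(Biostrings::width(ref[nm]))
        slines <- c(slines, sprintf("S\t%s\t%d\t*", nm, w))
      }
    }
    dist <- gapEstimate(t)
    glines <- c(glines, sprintf("G\t%s\t%s%s\t%s%s\t%d\t*%s",
      targetLabel(t), n1, regionStrand(t@leftFlank),
      n2, regionStrand(t@rightFlank),
      if (is.na(dist)) 0L else dist,
      if (is.na(dist)) "\tGE:Z:unknown" else ""))
  }
  writeLines(c("H\tVN:Z:2.0", slines, glines), path)
  invisible(path)
}

#' Convert a coordinate pair to a one-gap GFA
#'
#' Utility for BED-style input: two flank regions become two S lines and one
#' G line whose gap length is the distance between them (unknown when the
#' regions sit on different sequences).
#'
#' @param left,right flank regions (see [region()]), left preceding right.
#' @param reference named [Biostrings::DNAStringSet] (or FASTA path).
#' @param label target label (default derived from the coordinates).
#' @return GFA text as a character vector of lines.
#' @export
bedPairToGfa <- function(left, right, reference, label = NULL) {
  ref <- .asDNAStringSet(reference)
  for (gr in list(left, right)) {
    sq <- regionSeq(gr)
    if (!sq %in% names(ref)) stop("sequence '", sq, "' absent from reference")
    if (regionEnd0(gr) > Biostrings::width(ref[sq]))
      stop("region ", sq, ":", regionStart0(gr), "-", regionEnd0(gr),
           " extends past the end of the reference sequence")
  }
  sameSeq <- regionSeq(left) == regionSeq(right)
  if (sameSeq) {
    if (regionStart0(right) < regionEnd0(left))
      stop("right region must start at or after the end of the left region")
    dist <- regionStart0(right) - regionEnd0(left)
  } else dist <- NA_integer_
  GenomicRanges::strand(left) <- "+"
  GenomicRanges::strand(right) <- "+"
  if (is.null(label))
    label <- sprintf("%s_%d_gap", regionSeq(left), regionEnd0(left))
  t <- targetLocus(label, left, right, gapEstimate = dist)
  path <- tempfile(fileext = ".gfa")
  on.exit(unlink(path))
  writeGfaTargets(list(t), path, ref)
  readLines(path)
}

## accept a DNAStringSet or a FASTA path; names truncated at first whitespace
.asDNAStringSet <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    ref <- reference
  } else {
    ref <- Biostrings::readDNAStringSet(reference)
  }
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}
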