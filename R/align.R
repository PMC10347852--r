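## Single alignment engine of the package: free-end-gap (overlap) pairwise
## alignment, scored match +1 / mismatch -1 / gap open 2 / gap extend 1.
## Identity is matches over alignment columns; coverage is the fraction of
## the reference spanned by the aligned region.

.subMat <- NULL

.getSubMat <- function() {
  if (is.null(.subMat)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace(".subMat", m)
  }
  .subMat
}

## whole-sequence identity between two candidates: matches over all columns
## of a global alignment. End gaps count, so two alleles sharing their flank
## extensions but differing in between are correctly scored as divergent.
.globalIdentity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = .getSubMat(),
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  if (length(p) == 0L) return(0)
  sum(p == s & p != "-") / length(p)
}

#' Semi-global pairwise alignment with identity and coverage
#'
#' Aligns `query` against `reference` with free end gaps on both sequences
#' and reports identity (matches / alignment columns, end gaps excluded),
#' coverage (reference positions spanned by the alignment / reference
#' length) and the aligned reference interval.
#'
#' @param query,reference DNA strings.
#' @return list with `identity`, `coverage`, `interval` (0-based half-open
#'   on the reference), and `score`.
#' @export
semiGlobalAlign <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference))
    return(list(identity = 0, coverage = 0, interval = c(0L, 0L),
                score = -Inf))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = "overlap", substitutionMatrix = .getSubMat(),
    gapOpening = 2, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncols <- length(p)
  if (ncols == 0L)
    return(list(identity = 0, coverage = 0, interval = c(0L, 0L),
                score = Biostrings::score(aln)))
  matches <- sum(p == s & p != "-")
  sl <- IRanges::start(Biostrings::subject(aln))
  el <- IRanges::end(Biostrings::subject(aln))
  list(identity = matches / ncols,
       coverage = (el - sl + 1) / nchar(reference),
       interval = c(sl - 1L, el),
       score = Biostrings::score(aln))
}
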