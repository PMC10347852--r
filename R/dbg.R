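## Local assembly: solid k-mer graph over the read subsample, anchor k-mers
## recovered from reads aligned at the (extended) target boundaries, bounded
## breadth-first path enumeration between them, and reduction to
## representative sequences mutually below 90% identity.

#' Build a de Bruijn graph from reads
#'
#' Counts canonical k-mers (a k-mer and its reverse complement are one node;
#' k-mers containing non-ACGT characters are skipped). Counts for all k-mers
#' are retained so the solidity threshold can be varied without recounting;
#' only k-mers with abundance >= `a` are solid.
#'
#' @param reads character vector of read sequences, or a read data.frame
#'   with a `seq` column.
#' @param k k-mer size (odd).
#' @param a solidity threshold.
#' @return a [DeBruijnGraph-class].
#' @export
buildGraph <- function(reads, k, a = 1L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) == 0L) stop("no reads to build the graph from")
  if (max(nchar(reads)) < k)
    stop("all reads are shorter than k = ", k)
  res <- .count_kmers_cpp(toupper(reads), as.integer(k))
  new("DeBruijnGraph", k = as.integer(k), minAbundance = as.integer(a),
      kmers = res$kmer, counts = res$count)
}

#' Solidity-threshold view of a graph
#'
#' Returns the same graph with a different solidity threshold `a` (counts
#' are reused, nothing is recounted).
#'
#' @param graph a [DeBruijnGraph-class].
#' @param a new threshold.
#' @return a [DeBruijnGraph-class].
#' @export
withAbundance <- function(graph, a) {
  graph@minAbundance <- as.integer(a)
  graph
}

#' Is a k-mer solid in the graph?
#'
#' Strand-symmetric membership query.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param kmer character vector of k-mers.
#' @return logical vector.
#' @export
hasKmer <- function(graph, kmer) {
  canon <- as.character(.canonical_cpp(toupper(kmer)))
  i <- match(canon, graph@kmers)
  !is.na(i) & graph@counts[i] >= graph@minAbundance
}

## extract the read bases aligned to reference window [s0, e0) (0-based
## half-open), or NA if the alignment does not cover it collinearly within a
## single match block (indel-bearing reads are not used for anchoring)
.readBasesAtRef <- function(pos, cigar, seq, s0, e0) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("[0-9]+", "", ops)
  refCur <- pos          # 1-based
  qryCur <- 1L
  for (j in seq_along(op)) {
    if (op[j] %in% c("M", "=", "X")) {
      refEnd <- refCur + len[j] - 1L
      if (refCur <= s0 + 1L && refEnd >= e0) {
        qs <- qryCur + (s0 + 1L - refCur)
        return(substr(seq, qs, qs + (e0 - s0) - 1L))
      }
      refCur <- refEnd + 1L
      qryCur <- qryCur + len[j]
    } else if (op[j] %in% c("I", "S")) {
      qryCur <- qryCur + len[j]
    } else if (op[j] %in% c("D", "N")) {
      refCur <- refCur + len[j]
    }
  }
  NA_character_
}

#' Choose the START and STOP anchor k-mers from aligned reads
#'
#' Anchors are taken from the reads rather than the reference, so they
#' reflect the sequenced individual and are guaranteed to be observable in
#' the read set. For each side, reads aligned across the k bp abutting the
#' (extended) gap are inspected and the most frequent k-mer wins; count ties
#' break lexicographically. Anchors are reverse-complemented as needed so
#' the START k-mer points into the gap.
#'
#' @param bam indexed BAM path.
#' @param target a [TargetLocus-class].
#' @param k k-mer size.
#' @param ext anchor offset into the flanks in bp (the extension; must be
#'   >= k); the assembled sequence then overlaps `ext` bp of each flank.
#' @return list with `start`, `stop` (k-mer strings or NA on anchoring
#'   failure), `startSupport`, `stopSupport` (read counts), `ok`, and
#'   `failedSide`.
#' @export
pickAnchorKmers <- function(bam, target, k, ext = 500L) {
  k <- as.integer(k); ext <- as.integer(ext)
  if (ext < k) stop("ext (", ext, ") must be at least k (", k, ")")
  one <- function(flank, side) {
    iv <- anchorInterval(flank, side, k, ext)
    gr <- GenomicRanges::GRanges(regionSeq(flank),
            IRanges::IRanges(iv[1] + 1L, iv[2]))
    p <- Rsamtools::ScanBamParam(which = gr,
           what = c("pos", "cigar", "seq"),
           flag = .countingFlags(), mapqFilter = 1L)
    res <- Rsamtools::scanBam(bam, param = p)[[1]]
    if (length(res$pos) == 0L) return(NULL)
    seqs <- as.character(res$seq)
    kmers <- mapply(.readBasesAtRef, res$pos, res$cigar, seqs,
                    MoreArgs = list(s0 = iv[1], e0 = iv[2]))
    kmers <- kmers[!is.na(kmers) & !grepl("[^ACGT]", kmers)]
    if (length(kmers) == 0L) return(NULL)
    if (anchorNeedsRC(flank, side))
      kmers <- as.character(.revcomp_cpp(kmers))
    t <- table(kmers)
    best <- sort(names(t)[t == max(t)])[1]
    list(kmer = best, support = as.integer(t[best]))
  }
  l <- one(target@leftFlank, "left")
  r <- one(target@rightFlank, "right")
  list(start = if (is.null(l)) NA_character_ else l$kmer,
       stop = if (is.null(r)) NA_character_ else r$kmer,
       startSupport = if (is.null(l)) 0L else l$support,
       stopSupport = if (is.null(r)) 0L else r$support,
       ok = !is.null(l) && !is.null(r),
       failedSide = c(if (is.null(l)) "left", if (is.null(r)) "right"))
}

#' Enumerate assembly paths between anchor k-mers
#'
#' Breadth-first frontier expansion over the solid k-mers from START until
#' STOP (absorbing) or the exploration limits: per-step frontier cap,
#' global extension budget, and maximum path length. A path may use a node
#' (canonical k-mer) at most twice, which admits one extra copy of a tandem
#' repeat while guaranteeing termination.
#'
#' @param graph a [DeBruijnGraph-class].
#' @param start,stop anchor k-mers, oriented along the gap.
#' @param params an [AssemblyParams-class].
#' @return list of [AssemblyCandidate-class], ordered by (length,
#'   lexicographic); attribute `"limitReached"` flags a truncated search and
#'   attribute `"anchorsInGraph"` whether both anchors were solid.
#' @export
traverseGraph <- function(graph, start, stop, params = assemblyParams()) {
  stopifnot(params@k == graph@k)
  res <- .traverse_cpp(solidKmers(graph), start, stop, graph@k,
                       params@maxPathLength, params@maxActiveBranches,
                       params@maxNodesExplored)
  out <- lapply(res$sequences, function(s)
    new("AssemblyCandidate", sequence = s, k = graph@k,
        a = graph@minAbundance, pathLength = nchar(s),
        limitReached = res$limit_reached))
  attr(out, "limitReached") <- res$limit_reached
  attr(out, "anchorsInGraph") <- res$anchors_in_graph
  out
}

#' Reduce candidates to mutually divergent representatives
#'
#' Greedy clustering in input order: a candidate is kept iff its identity
#' (matches over all columns of a global alignment, end gaps included) to
#' every already-kept candidate is at most `maxIdentity`. End gaps must
#' count here: candidates share their flank extensions, and a free-end-gap
#' identity would score two divergent alleles as near-identical from the
#' shared extensions alone. The output is pairwise divergent by
#' construction.
#'
#' @param candidates list of [AssemblyCandidate-class].
#' @param maxIdentity identity above which two candidates are considered
#'   the same solution (default 0.90: sequences must differ by more than
#'   10\% to be reported as distinct).
#' @return sub-list of `candidates`.
#' @export
representativeSubset <- function(candidates, maxIdentity = 0.90) {
  kept <- list()
  for (cand in candidates) {
    dup <- FALSE
    for (kc in kept) {
      if (.globalIdentity(cand@sequence, kc@sequence) > maxIdentity) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cand
  }
  kept
}

#' One-shot local assembly of a target at fixed parameters
#'
#' Composition of [buildGraph()], [pickAnchorKmers()], [traverseGraph()] and
#' [representativeSubset()]. Anchors are placed `ext` bp inside the flanks,
#' so assembled sequences overlap both flanks by `ext` bp (used by the
#' quality gate).
#'
#' @param subsample read data.frame from [subsampleReads()].
#' @param target a [TargetLocus-class].
#' @param params an [AssemblyParams-class].
#' @param bam indexed BAM path (anchor k-mer recovery).
#' @param ext flank extension in bp.
#' @param graph optional pre-built [DeBruijnGraph-class] at `params@k`
#'   (counts are reused; `params@a` is applied).
#' @return list with `candidates` (possibly empty), `status` (`"ok"`,
#'   `"anchoring_failed"`, `"no_path"`, `"no_reads"`), and `flags`.
#' @export
assembleTarget <- function(subsample, target, params, bam, ext = 500L,
                           graph = NULL) {
  n <- if (is.data.frame(subsample)) nrow(subsample) else length(subsample)
  if (n == 0L)
    return(list(candidates = list(), status = "no_reads", flags = character()))
  if (is.null(graph)) graph <- buildGraph(subsample, params@k, params@a)
  else graph <- withAbundance(graph, params@a)
  anchors <- pickAnchorKmers(bam, target, params@k, ext)
  if (!anchors$ok)
    return(list(candidates = list(), status = "anchoring_failed",
                flags = anchors$failedSide))
  cands <- traverseGraph(graph, anchors$start, anchors$stop, params)
  flags <- character()
  if (isTRUE(attr(cands, "limitReached"))) flags <- c(flags, "limit_reached")
  if (!isTRUE(attr(cands, "anchorsInGraph"))) flags <- c(flags, "anchor_not_solid")
  if (length(cands) == 0L)
    return(list(candidates = list(), status = "no_path", flags = flags))
  list(candidates = representativeSubset(cands), status = "ok", flags = flags)
}
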