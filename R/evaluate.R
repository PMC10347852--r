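## Quality gate and iterative descent. An assembled sequence carries ext bp
## of each flank; those extensions are realigned to the reference and the
## sequence is accepted only with > minIdentity identity over > minCoverage
## of each extension reference (default 90/90, per side). On failure the
## assembly is retried with lower de Bruijn graph parameters.

#' Default (k, a) parameter ladder
#'
#' k descends 61, 51, 41, 31, 21; within each k the solidity threshold
#' descends 3, 2. The first rungs favour specificity (large k, strict
#' solidity); later rungs trade it for sensitivity when coverage over the
#' target is thin.
#'
#' @param kLadder decreasing k values.
#' @param aLadder decreasing a values tried within each k.
#' @return data.frame with columns `k` and `a`, one row per rung.
#' @export
parameterLadder <- function(kLadder = c(61L, 51L, 41L, 31L, 21L),
                            aLadder = c(3L, 2L)) {
  if (length(kLadder) == 0L || length(aLadder) == 0L)
    stop("ladder must be nonempty")
  if (is.unsorted(rev(kLadder), strictly = TRUE) ||
      is.unsorted(rev(aLadder), strictly = TRUE))
    stop("ladder values must be strictly decreasing")
  data.frame(k = rep(as.integer(kLadder), each = length(aLadder)),
             a = rep(as.integer(aLadder), times = length(kLadder)))
}

#' Score an assembly candidate against its flank extensions
#'
#' The first `ext` bp of the candidate are aligned to the left flank
#' extension reference and the last `ext` bp to the right one. Pass
#' requires, on each side, identity > `minIdentity` over coverage >
#' `minCoverage` (defaults 0.90/0.90).
#'
#' @param candidate an [AssemblyCandidate-class] (or a DNA string).
#' @param target a [TargetLocus-class].
#' @param reference named [Biostrings::DNAStringSet].
#' @param ext extension length the candidate was assembled with.
#' @param minIdentity,minCoverage per-side acceptance thresholds.
#' @return a [QualityVerdict-class].
#' @export
scoreCandidate <- function(candidate, target, reference, ext = 500L,
                           minIdentity = 0.90, minCoverage = 0.90) {
  seqc <- if (methods::is(candidate, "AssemblyCandidate"))
    candidate@sequence else as.character(candidate)
  k <- if (methods::is(candidate, "AssemblyCandidate")) candidate@k else 0L
  ref <- .asDNAStringSet(reference)
  n <- nchar(seqc)
  if (n < 2L * ext + k)
    return(new("QualityVerdict", leftIdentity = 0, leftCoverage = 0,
               rightIdentity = 0, rightCoverage = 0, pass = FALSE,
               reason = sprintf("candidate too short (%d < 2*%d+%d)",
                                n, ext, k)))
  leftRef <- flankSequence(ref, target@leftFlank, "left", ext)
  rightRef <- flankSequence(ref, target@rightFlank, "right", ext)
  la <- semiGlobalAlign(substr(seqc, 1L, ext), leftRef)
  ra <- semiGlobalAlign(substr(seqc, n - ext + 1L, n), rightRef)
  pass <- la$identity > minIdentity && la$coverage > minCoverage &&
          ra$identity > minIdentity && ra$coverage > minCoverage
  new("QualityVerdict",
      leftIdentity = la$identity, leftCoverage = la$coverage,
      rightIdentity = ra$identity, rightCoverage = ra$coverage,
      pass = pass,
      reason = if (pass) "" else "extension alignment below threshold")
}

#' Trim flank extensions off an assembled sequence
#'
#' @param sequence assembled sequence including extensions.
#' @param ext extension length.
#' @return the assembled target alone (may be empty for zero-length gaps).
#' @export
trimExtensions <- function(sequence, ext = 500L) {
  n <- nchar(sequence)
  if (n <= 2L * ext) return("")
  substr(sequence, ext + 1L, n - ext)
}

#' Iterative local assembly over a parameter ladder
#'
#' Walks the (k, a) ladder in order, assembling and scoring at each rung,
#' and stops at the first rung with at least one passing candidate. Exactly
#' one passing candidate is reported as the assembled target (extensions
#' trimmed); several mutually divergent passing candidates yield status
#' `"multiple_solutions"` and, by default, no sequence (it is not possible
#' to pick the right one); an exhausted ladder yields `"no_assembly"`.
#'
#' @param target a [TargetLocus-class].
#' @param subsample read data.frame from [subsampleReads()].
#' @param bam indexed BAM path.
#' @param reference named [Biostrings::DNAStringSet].
#' @param ladder data.frame from [parameterLadder()].
#' @param ext flank extension in bp.
#' @param minIdentity,minCoverage quality-gate thresholds.
#' @param reportMultiple if TRUE, all passing sequences are returned when
#'   multiple divergent solutions exist.
#' @param maxActiveBranches,maxNodesExplored traversal caps.
#' @return an [AssemblyResult-class].
#' @export
iterativeAssemble <- function(target, subsample, bam, reference,
                              ladder = parameterLadder(), ext = 500L,
                              minIdentity = 0.90, minCoverage = 0.90,
                              reportMultiple = FALSE,
                              maxActiveBranches = 100L,
                              maxNodesExplored = 1e7) {
  ref <- .asDNAStringSet(reference)
  log <- list()
  n <- nrow(subsample)
  graph <- NULL; graphK <- NA_integer_
  if (n > 0L) maxRead <- max(nchar(subsample$seq))
  for (i in seq_len(nrow(ladder))) {
    k <- ladder$k[i]; a <- ladder$a[i]
    if (n == 0L || maxRead < k) {
      log[[i]] <- list(k = k, a = a, status = "no_reads", nPass = 0L)
      next
    }
    if (is.na(graphK) || graphK != k) {
      graph <- buildGraph(subsample, k, 1L)
      graphK <- k
    }
    params <- assemblyParams(k = k, a = a, gapEstimate = gapEstimate(target),
                             ext = ext, maxActiveBranches = maxActiveBranches,
                             maxNodesExplored = maxNodesExplored)
    asm <- assembleTarget(subsample, target, params, bam, ext = ext,
                          graph = graph)
    verdicts <- lapply(asm$candidates, scoreCandidate, target = target,
                       reference = ref, ext = ext,
                       minIdentity = minIdentity, minCoverage = minCoverage)
    pass <- vapply(verdicts, function(v) v@pass, logical(1))
    log[[i]] <- list(k = k, a = a, status = asm$status,
                     nCandidates = length(asm$candidates),
                     nPass = sum(pass), flags = asm$flags)
    if (any(pass)) {
      pc <- asm$candidates[pass]
      pv <- verdicts[pass]
      if (length(pc) == 1L) {
        return(new("AssemblyResult", label = targetLabel(target),
                   status = "assembled",
                   sequence = trimExtensions(pc[[1]]@sequence, ext),
                   k = k, a = a, verdict = pv[[1]],
                   details = list(log = log, nReads = n,
                                  untrimmed = pc[[1]]@sequence)))
      }
      seqs <- if (reportMultiple)
        vapply(pc, function(x) trimExtensions(x@sequence, ext), character(1))
      else character(0)
      return(new("AssemblyResult", label = targetLabel(target),
                 status = "multiple_solutions", sequence = seqs,
                 k = k, a = a, verdict = pv[[1]],
                 details = list(log = log, nReads = n, nSolutions = length(pc))))
    }
  }
  new("AssemblyResult", label = targetLabel(target), status = "no_assembly",
      sequence = character(0), k = NA_integer_, a = NA_integer_,
      verdict = NULL, details = list(log = log, nReads = n))
}

#' Classify an assembly result against a known truth sequence
#'
#' Benchmark mode: the assembled sequence is aligned to the known truth;
#' identity > 0.90 and coverage > 0.90 of the truth is `"successful"`, any
#' other returned sequence is `"erroneous"`, and no returned sequence
#' (including the multiple-solutions case, where no sequence is reported by
#' default) is `"no_assembly"`.
#'
#' @param result an [AssemblyResult-class] (or a DNA string).
#' @param truth the true target sequence.
#' @param minIdentity,minCoverage classification thresholds.
#' @return list with `label` ("successful", "erroneous", "no_assembly"),
#'   `identity` and `coverage`.
#' @export
benchmarkClassify <- function(result, truth, minIdentity = 0.90,
                              minCoverage = 0.90) {
  seqc <- if (methods::is(result, "AssemblyResult")) {
    if (resultStatus(result) == "assembled") resultSequence(result)[1]
    else NA_character_
  } else as.character(result)
  if (is.na(seqc) || !nzchar(seqc))
    return(list(label = "no_assembly", identity = NA_real_,
                coverage = NA_real_))
  al <- semiGlobalAlign(seqc, truth)
  ## coverage of the assembly by the truth matters too: a sequence much
  ## longer than the truth is not a faithful reconstruction
  qcov <- (al$interval[2] - al$interval[1]) > 0 &&
          nchar(truth) / nchar(seqc) > minCoverage
  ok <- al$identity > minIdentity && al$coverage > minCoverage && qcov
  list(label = if (ok) "successful" else "erroneous",
       identity = al$identity, coverage = al$coverage)
}

#' Aggregate benchmark labels into success rate and accuracy
#'
#' Success rate is successful assemblies over all targets; accuracy is
#' successful over returned assemblies (successful + erroneous).
#'
#' @param labels character vector of labels from [benchmarkClassify()].
#' @return list with `successRate`, `accuracy`, and the three counts.
#' @export
benchmarkSummary <- function(labels) {
  s <- sum(labels == "successful")
  e <- sum(labels == "erroneous")
  n <- sum(labels == "no_assembly")
  list(successRate = s / length(labels),
       accuracy = if (s + e > 0) s / (s + e) else NA_real_,
       successful = s, erroneous = e, noAssembly = n)
}
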