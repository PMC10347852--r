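## Batch orchestration: every G line of the input GFA is processed
## independently (subsample -> iterative assembly -> quality gate); per-target
## failures are recorded in the report and never abort the batch. Outputs are
## an assembled-targets FASTA and a GFA complementing the input: solved gaps
## become new S lines joined to their flanks by edges with k-1 overlap,
## unsolved gaps keep their G lines.

#' Run the full local assembly pipeline
#'
#' @param gfa path to the GFA 2.0 file of targets.
#' @param bam coordinate-sorted, indexed BAM of the linked reads mapped to
#'   `reference`.
#' @param reads linked-read FASTQ (optionally gzipped) with barcodes.
#' @param reference reference FASTA path or named
#'   [Biostrings::DNAStringSet].
#' @param outDir output directory.
#' @param flankSize flanking window size in bp for barcode collection.
#' @param minOcc minimum barcode occurrence count for selection.
#' @param strict require each selected barcode to be observed on both
#'   flanks (for inter-scaffold gaps).
#' @param ext flank extension in bp included in the assembly.
#' @param kLadder,aLadder parameter descent (see [parameterLadder()]).
#' @param minIdentity,minCoverage quality-gate thresholds.
#' @param reportMultiple report all sequences when multiple divergent
#'   solutions pass.
#' @param threads targets processed in parallel (fork-based; the barcode
#'   index is read-only). Outputs are identical for any thread count.
#' @param resume skip barcode indexing and per-target subsampling when
#'   their output files already exist in `outDir`.
#' @param dialect,sidecar barcode encoding of `reads` (see
#'   [buildBarcodeIndex()]).
#' @param verbose log per-target progress.
#' @return list with `report` (one row per target: status, (k, a) used,
#'   barcode/read counts, identities, lengths, timing) and `results` (list
#'   of [AssemblyResult-class]); written files `assembled.fa`,
#'   `assembly.gfa`, `report.tsv` under `outDir`.
#' @export
runPipeline <- function(gfa, bam, reads, reference, outDir,
                        flankSize = 10000L, minOcc = 2L, strict = FALSE,
                        ext = 500L,
                        kLadder = c(61L, 51L, 41L, 31L, 21L),
                        aLadder = c(3L, 2L),
                        minIdentity = 0.90, minCoverage = 0.90,
                        reportMultiple = FALSE, threads = 1L,
                        resume = FALSE, dialect = c("bx", "suffix"),
                        sidecar = NULL, verbose = TRUE) {
  dialect <- match.arg(dialect)
  dir.create(file.path(outDir, "work"), recursive = TRUE,
             showWarnings = FALSE)
  ref <- .asDNAStringSet(reference)
  targets <- readGfaTargets(gfa, ref)
  if (length(targets) == 0L) stop("no G lines in ", gfa)
  ladder <- parameterLadder(kLadder, aLadder)

  idxPath <- file.path(outDir, "barcodes.idx")
  if (resume && file.exists(idxPath)) {
    index <- loadBarcodeIndex(reads, idxPath, dialect, sidecar)
  } else {
    index <- buildBarcodeIndex(reads, dialect, sidecar)
    saveBarcodeIndex(index, idxPath)
  }

  worker <- function(target) {
    t0 <- proc.time()[["elapsed"]]
    label <- targetLabel(target)
    subFq <- file.path(outDir, "work", paste0(label, ".subsample.fq"))
    bcTsv <- file.path(outDir, "work", paste0(label, ".barcodes.tsv"))
    tryCatch({
      if (resume && file.exists(subFq) && file.exists(bcTsv)) {
        sub <- .parseFastq(subFq, "bx")
        nBc <- nrow(read.table(bcTsv, sep = "\t", header = TRUE))
      } else {
        w <- flankWindows(target, flankSize)
        tabs <- collectFlankBarcodes(bam, w, perSide = strict)
        tab <- if (strict) tabs$union else tabs
        sel <- selectBarcodes(tab, minOcc,
                              strictTables = if (strict) tabs else NULL)
        write.table(data.frame(barcode = names(tab),
                               occurrences = as.integer(tab)),
                    bcTsv, sep = "\t", quote = FALSE, row.names = FALSE)
        sub <- suppressWarnings(subsampleReads(sel, index))
        .writeFastq(sub, subFq)
        nBc <- length(sel)
      }
      res <- iterativeAssemble(target, sub, bam, ref, ladder = ladder,
                               ext = ext, minIdentity = minIdentity,
                               minCoverage = minCoverage,
                               reportMultiple = reportMultiple)
      if (verbose)
        message(sprintf("[%s] %s%s (%d barcodes, %d reads, %.1fs)",
                        label, resultStatus(res),
                        if (!is.na(res@k)) sprintf(" at k=%d a=%d", res@k, res@a)
                        else "", nBc, nrow(sub),
                        proc.time()[["elapsed"]] - t0))
      list(result = res, nBarcodes = nBc, nReads = nrow(sub),
           seconds = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      list(result = new("AssemblyResult", label = label, status = "error",
                        sequence = character(0), k = NA_integer_,
                        a = NA_integer_, verdict = NULL,
                        details = list(error = conditionMessage(e))),
           nBarcodes = NA_integer_, nReads = NA_integer_,
           seconds = proc.time()[["elapsed"]] - t0)
    })
  }

  out <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(targets, worker, mc.cores = threads,
                       mc.preschedule = FALSE)
  } else lapply(targets, worker)

  results <- lapply(out, `[[`, "result")
  report <- do.call(rbind, lapply(seq_along(out), function(i) {
    r <- results[[i]]
    v <- r@verdict
    data.frame(label = r@label, status = r@status, k = r@k, a = r@a,
               nBarcodes = out[[i]]$nBarcodes, nReads = out[[i]]$nReads,
               length = if (r@status == "assembled") nchar(r@sequence[1])
                        else NA_integer_,
               leftIdentity = if (!is.null(v)) v@leftIdentity else NA_real_,
               rightIdentity = if (!is.null(v)) v@rightIdentity else NA_real_,
               seconds = round(out[[i]]$seconds, 2),
               stringsAsFactors = FALSE)
  }))

  ## FASTA of assembled targets
  fa <- character(0)
  for (r in results) {
    if (r@status == "assembled") {
      fa <- c(fa, sprintf(">%s k=%d a=%d length=%d", r@label, r@k, r@a,
                          nchar(r@sequence[1])), r@sequence[1])
    } else if (r@status == "multiple_solutions" && length(r@sequence) > 0L) {
      for (j in seq_along(r@sequence))
        fa <- c(fa, sprintf(">%s.%d k=%d a=%d length=%d multiple_solutions",
                            r@label, j, r@k, r@a, nchar(r@sequence[j])),
                r@sequence[j])
    }
  }
  writeLines(fa, file.path(outDir, "assembled.fa"))
  writeAssemblyGfa(targets, results, ref, file.path(outDir, "assembly.gfa"),
                   ext = ext)
  write.table(report, file.path(outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(report = report, results = results)
}

#' Write the output assembly GFA
#'
#' Complements the input target GFA: for each solved target a new segment
#' `<label>.assembled` (the assembled target plus k-1 bp of each flank) is
#' added with two edges declaring the k-1 overlap with the flank segments;
#' unsolved targets keep their G lines.
#'
#' @param targets list of [TargetLocus-class].
#' @param results matching list of [AssemblyResult-class].
#' @param reference named [Biostrings::DNAStringSet].
#' @param path output path.
#' @param ext extension length used during assembly.
#' @return `path`, invisibly.
#' @export
writeAssemblyGfa <- function(targets, results, reference, path, ext = 500L) {
  ref <- .asDNAStringSet(reference)
  segs <- character(); slines <- character(); other <- character()
  addSeg <- function(nm) {
    if (nm %in% segs) return()
    segs <<- c(segs, nm)
    m <- regmatches(nm, regexec(.coordPattern, nm))[[1]]
    w <- if (length(m) == 4L && !nm %in% names(ref))
      as.integer(m[4]) - as.integer(m[3])
    else as.integer(Biostrings::width(ref[nm]))
    slines <<- c(slines, sprintf("S\t%s\t%d\t*", nm, w))
  }
  for (i in seq_along(targets)) {
    t <- targets[[i]]; r <- results[[i]]
    n1 <- .segmentName(t@leftFlank, ref); addSeg(n1)
    n2 <- .segmentName(t@rightFlank, ref); addSeg(n2)
    o1 <- regionStrand(t@leftFlank); o2 <- regionStrand(t@rightFlank)
    if (r@status == "assembled") {
      k <- r@k
      untrimmed <- r@details$untrimmed
      s <- substr(untrimmed, ext - k + 2L, nchar(untrimmed) - ext + k - 1L)
      nm <- paste0(r@label, ".assembled")
      l1 <- .segLen(t@leftFlank, ref)
      other <- c(other,
        sprintf("S\t%s\t%d\t%s", nm, nchar(s), s),
        sprintf("E\t*\t%s%s\t%s+\t%d\t%d$\t0\t%d\t*",
                n1, o1, nm, l1 - (k - 1L), l1, k - 1L),
        sprintf("E\t*\t%s+\t%s%s\t%d\t%d$\t0\t%d\t*",
                nm, n2, o2, nchar(s) - (k - 1L), nchar(s), k - 1L))
    } else {
      dist <- gapEstimate(t)
      other <- c(other, sprintf("G\t%s\t%s%s\t%s%s\t%d\t*%s",
        r@label, n1, o1, n2, o2, if (is.na(dist)) 0L else dist,
        if (is.na(dist)) "\tGE:Z:unknown" else ""))
    }
  }
  writeLines(c("H\tVN:Z:2.0", slines, other), path)
  invisible(path)
}

.segLen <- function(flank, ref) {
  regionEnd0(flank) - regionStart0(flank)
}

#' Derive assembly targets from a structural-variant VCF
#'
#' Deletion mode: each DEL record becomes a target spanning the deleted
#' segment expanded by `pad` bp on each side; the expected assembly is the
#' `2*pad` bp breakpoint junction. Insertion mode: each INS record becomes
#' a target around the insertion site (`pad` bp each side) with unknown
#' expected length.
#'
#' @param vcf VCF path (SV records with SVTYPE and, for deletions, END or
#'   SVLEN).
#' @param reference reference FASTA path or named
#'   [Biostrings::DNAStringSet].
#' @param mode `"deletion"` or `"insertion"`.
#' @param pad padding in bp (default 50).
#' @param out optional path: write the targets as GFA.
#' @return list of [TargetLocus-class] (invisibly also written to `out`).
#' @export
svTargetsFromVcf <- function(vcf, reference, mode = c("deletion", "insertion"),
                             pad = 50L, out = NULL) {
  mode <- match.arg(mode)
  ref <- .asDNAStringSet(reference)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  svtype <- vcfR::extract.info(v, "SVTYPE")
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  svlen <- suppressWarnings(as.integer(vcfR::extract.info(v, "SVLEN")))
  pos <- as.integer(fix$POS)
  want <- if (mode == "deletion") "DEL" else "INS"
  targets <- list()
  for (i in which(svtype == want)) {
    chrom <- fix$CHROM[i]
    if (!chrom %in% names(ref)) {
      warning("record ", i, ": sequence '", chrom, "' absent from reference")
      next
    }
    clen <- Biostrings::width(ref[chrom])
    if (mode == "deletion") {
      s0 <- pos[i]                    # VCF POS = base before the event
      e0 <- if (!is.na(end[i])) end[i]
            else if (!is.na(svlen[i])) s0 + abs(svlen[i])
            else NA_integer_
      if (is.na(e0)) {
        warning("DEL record ", i, " lacks END/SVLEN; skipped")
        next
      }
      gs <- s0 - pad; ge <- e0 + pad
      est <- 2L * pad
      label <- sprintf("%s_del_%d_%d", chrom, s0, e0 - s0)
    } else {
      p0 <- pos[i]
      gs <- p0 - pad; ge <- p0 + pad
      est <- NA_integer_
      label <- sprintf("%s_ins_%d", chrom, p0)
    }
    if (gs <= 0L || ge >= clen) {
      warning("record ", i, ": padded target outside reference; skipped")
      next
    }
    targets[[length(targets) + 1L]] <- targetLocus(label,
      region(chrom, 0, gs), region(chrom, ge, clen), gapEstimate = est)
  }
  if (!is.null(out)) writeGfaTargets(targets, out, ref)
  targets
}
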