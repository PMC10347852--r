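## Linked-read FASTQ handling. Two barcode dialects are understood:
##   "bx"     - a SAM-style "BX:Z:<barcode>" tag in the FASTQ header comment
##              (the common 10x / longranger convention), and
##   "suffix" - a trailing "#<barcode>" on the read identifier (stLFR style).
## A two-column sidecar file (read id, barcode) can override either.

.parseFastq <- function(path, dialect = c("bx", "suffix"), sidecar = NULL) {
  dialect <- match.arg(dialect)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0L)
    return(data.frame(id = character(), mate = integer(), seq = character(),
                      qual = character(), barcode = character(),
                      stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ: ", path)
  hdr <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  sp <- regexpr(" ", hdr, fixed = TRUE)
  id <- ifelse(sp > 0L, substr(hdr, 1L, sp - 1L), hdr)
  comment <- ifelse(sp > 0L, substr(hdr, sp + 1L, nchar(hdr)), "")
  mate <- rep(1L, length(id))
  hasMate <- grepl("/[12]$", id)
  mate[hasMate] <- as.integer(sub("^.*/", "", id[hasMate]))
  barcode <- rep(NA_character_, length(id))
  if (dialect == "bx") {
    m <- regmatches(comment, regexpr("BX:Z:\\S+", comment))
    hit <- grepl("BX:Z:\\S+", comment)
    barcode[hit] <- sub("^BX:Z:", "", m)
  } else {
    core <- sub("/[12]$", "", id)
    hit <- grepl("#\\S+$", core)
    barcode[hit] <- sub("^.*#", "", core[hit])
    barcode[barcode %in% ""] <- NA_character_
  }
  if (!is.null(sidecar)) {
    sc <- read.table(sidecar, header = FALSE, sep = "\t",
                     col.names = c("id", "barcode"),
                     colClasses = "character")
    barcode <- sc$barcode[match(sub("/[12]$", "", id), sc$id)]
  }
  data.frame(id = id, mate = mate, seq = toupper(seqs), qual = qual,
             barcode = barcode, stringsAsFactors = FALSE)
}

#' Build a barcode index over a linked-read FASTQ file
#'
#' Scans the read file once and records, for every barcode, the positions of
#' its reads, so that the reads of any barcode set can be fetched in bulk
#' (both mates of a pair share a barcode and are both indexed).
#'
#' @param fastq path to the read file (optionally gzipped).
#' @param dialect barcode encoding: `"bx"` for a `BX:Z:` header-comment tag,
#'   `"suffix"` for a trailing `#barcode` on the read id.
#' @param sidecar optional two-column (read id, barcode) TSV overriding the
#'   in-header encoding.
#' @return a [BarcodeIndex-class].
#' @export
buildBarcodeIndex <- function(fastq, dialect = c("bx", "suffix"),
                              sidecar = NULL) {
  reads <- .parseFastq(fastq, dialect, sidecar)
  keep <- !is.na(reads$barcode)
  if (nrow(reads) > 0L && !any(keep))
    warning("no barcoded read found in ", fastq, "; index is empty")
  idx <- split(which(keep), reads$barcode[keep])
  idx <- idx[order(names(idx))]
  new("BarcodeIndex", fastq = fastq, reads = reads, index = idx)
}

#' Persist / reload a barcode index
#'
#' The index is stored as a barcode-sorted two-column TSV (barcode,
#' comma-separated record ordinals). Reloading re-reads the backing FASTQ
#' records but skips barcode re-indexing.
#'
#' @param index a [BarcodeIndex-class].
#' @param path index file path.
#' @return `path` ([saveBarcodeIndex()]); a [BarcodeIndex-class]
#'   ([loadBarcodeIndex()]).
#' @rdname barcodeIndexIO
#' @export
saveBarcodeIndex <- function(index, path) {
  df <- data.frame(barcode = names(index@index),
                   records = vapply(index@index, paste,
                                    character(1), collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @param fastq path of the backing FASTQ the index was built on.
#' @param dialect,sidecar as in [buildBarcodeIndex()].
#' @rdname barcodeIndexIO
#' @export
loadBarcodeIndex <- function(fastq, path, dialect = c("bx", "suffix"),
                             sidecar = NULL) {
  reads <- .parseFastq(fastq, dialect, sidecar)
  tab <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("barcode", "records"),
                    colClasses = "character")
  idx <- lapply(strsplit(tab$records, ",", fixed = TRUE), as.integer)
  names(idx) <- tab$barcode
  new("BarcodeIndex", fastq = fastq, reads = reads, index = idx)
}

#' Fetch all reads carrying any of a set of barcodes
#'
#' @param index a [BarcodeIndex-class].
#' @param barcodes character vector of barcodes; barcodes absent from the
#'   index contribute zero reads.
#' @return data.frame of read records (columns `id`, `mate`, `seq`, `qual`,
#'   `barcode`) in file order.
#' @export
fetchReadsByBarcodes <- function(index, barcodes) {
  hit <- intersect(names(index@index), barcodes)
  rows <- sort(unlist(index@index[hit], use.names = FALSE))
  index@reads[rows, , drop = FALSE]
}

## write read records back out as FASTQ (BX dialect), deterministically
.writeFastq <- function(reads, path) {
  if (nrow(reads) == 0L) { writeLines(character(), path); return(invisible(path)) }
  bx <- ifelse(is.na(reads$barcode), "", paste0(" BX:Z:", reads$barcode))
  out <- as.vector(rbind(paste0("@", reads$id, bx), reads$seq, "+", reads$qual))
  writeLines(out, path)
  invisible(path)
}
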