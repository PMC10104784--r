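#' MethReads: per-read CpG methylation profiles
#'
#' Container for read-level methylation data: a table of binary calls
#' (one row per read, chromosome and CpG position) plus the aligned span
#' of every read. Positions are 0-based reference coordinates of the
#' CpG's C on the plus strand; spans are held as a [GenomicRanges::GRanges]
#' (1-based, closed) named by read id.
#'
#' A read may carry at most one call per position; reads whose input
#' contained conflicting duplicate calls are listed in `flaggedReads()`
#' (the ambiguous positions are dropped by [assembleReads()]).
#'
#' @slot calls `data.frame` with columns `read_id`, `chrom`, `pos`
#'   (0-based integer), `state` (0/1).
#' @slot spans `GRanges`, one range per (read, chromosome), names = read id.
#' @slot flagged character vector of read ids with dropped ambiguous calls.
#'
#' @seealso [assembleReads()], [readMethCalls()]
#' @export
setClass("MethReads", slots = c(
  calls   = "data.frame",
  spans   = "GRanges",
  flagged = "character"
))

setValidity("MethReads", function(object) {
  cl <- object@calls
  req <- c("read_id", "chrom", "pos", "state")
  if (!all(req %in% names(cl)))
    return(sprintf("calls must have columns %s", paste(req, collapse = ", ")))
  if (nrow(cl)) {
    if (any(cl$pos < 0)) return("call positions must be >= 0")
    if (!all(cl$state %in% c(0L, 1L))) return("state must be 0 or 1")
    if (anyDuplicated(paste(cl$read_id, cl$chrom, cl$pos)))
      return("at most one call per (read_id, chrom, pos)")
    if (!all(unique(cl$read_id) %in% names(object@spans)))
      return("every read in calls needs a span")
  }
  TRUE
})

#' Construct a MethReads object
#'
#' @param calls data.frame with columns `read_id`, `chrom`, `pos` (0-based),
#'   `state` (0/1).
#' @param spans optional `GRanges` of aligned read intervals named by read
#'   id; if `NULL`, spans are inferred as the interval from the first to
#'   one past the last called CpG dinucleotide of each read.
#' @param flagged character vector of read ids carrying dropped ambiguous
#'   calls.
#' @return A [MethReads-class] object.
#' @examples
#' calls <- data.frame(read_id = "r1", chrom = "chr1",
#'                     pos = c(10L, 25L), state = c(1L, 0L))
#' mr <- MethReads(calls)
#' nReads(mr)
#' @export
MethReads <- function(calls, spans = NULL, flagged = character()) {
  calls <- as.data.frame(calls)
  calls$pos <- as.integer(calls$pos)
  calls$state <- as.integer(calls$state)
  calls <- calls[order(calls$read_id, calls$chrom, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  if (is.null(spans)) {
    if (nrow(calls)) {
      dt <- data.table::as.data.table(calls)
      sp <- dt[, list(start0 = min(pos), end0 = max(pos) + 2L),
               by = c("read_id", "chrom")]
      spans <- .grFrom0(sp$chrom, sp$start0, sp$end0)
      names(spans) <- sp$read_id
    } else {
      spans <- GenomicRanges::GRanges()
    }
  }
  new("MethReads", calls = calls, spans = spans, flagged = flagged)
}

#' @describeIn MethReads-class the call table (`read_id`, `chrom`, `pos`,
#'   `state`).
#' @param x,object a `MethReads` object.
#' @export
readCalls <- function(x) x@calls

#' @describeIn MethReads-class aligned read spans as a named `GRanges`.
#' @export
readSpans <- function(x) x@spans

#' @describeIn MethReads-class number of distinct reads.
#' @export
nReads <- function(x) length(unique(x@calls$read_id))

#' @describeIn MethReads-class read ids that carried conflicting duplicate
#'   calls (ambiguous positions dropped).
#' @export
flaggedReads <- function(x) x@flagged

setMethod("show", "MethReads", function(object) {
  cat(sprintf("MethReads: %d reads, %d calls on %d chromosome(s)\n",
              nReads(object), nrow(object@calls),
              length(unique(object@calls$chrom))))
  if (length(object@flagged))
    cat(sprintf("  %d read(s) flagged for ambiguous duplicate calls\n",
                length(object@flagged)))
})

#' EpialleleSet: epiallele counts over 4-mers of consecutive CpGs
#'
#' Holds, for each 4-mer of consecutive CpGs, the counts of the 16
#' possible binary methylation configurations (epialleles) observed on
#' reads spanning the entire 4-mer. Configuration index for states
#' (b1, b2, b3, b4) is `8*b1 + 4*b2 + 2*b3 + b4`; column names are the
#' pattern strings `"0000" ... "1111"` in that order.
#'
#' @slot fourmers `data.frame` with columns `fourmer_id`, `chrom`,
#'   `pos1..pos4` (0-based CpG positions, strictly increasing).
#' @slot counts integer matrix, one row per 4-mer, 16 columns.
#'
#' @seealso [countEpialleles()], [methEntropy()]
#' @export
setClass("EpialleleSet", slots = c(
  fourmers = "data.frame",
  counts   = "matrix"
))

setValidity("EpialleleSet", function(object) {
  fm <- object@fourmers
  cnt <- object@counts
  if (!all(c("fourmer_id", "chrom", "pos1", "pos2", "pos3", "pos4") %in% names(fm)))
    return("fourmers must have columns fourmer_id, chrom, pos1..pos4")
  if (ncol(cnt) != 16L) return("counts must have 16 columns")
  if (nrow(cnt) != nrow(fm)) return("counts rows must match fourmers rows")
  if (nrow(cnt) && any(cnt < 0)) return("counts must be non-negative")
  if (nrow(fm) && !all(fm$pos1 < fm$pos2 & fm$pos2 < fm$pos3 & fm$pos3 < fm$pos4))
    return("4-mer positions must be strictly increasing")
  TRUE
})

#' The 16 epiallele configurations of a 4-mer
#'
#' @return Character vector of the 16 binary pattern strings `"0000"`
#'   through `"1111"`, ordered by configuration index
#'   `8*b1 + 4*b2 + 2*b3 + b4`.
#' @examples
#' epialleleConfigs()
#' @export
epialleleConfigs <- function() {
  vapply(0:15, function(i)
    paste(as.integer(intToBits(i))[4:1], collapse = ""), character(1))
}

# number of methylated CpGs in configuration i (0-based index)
.popcount4 <- c(0L, 1L, 1L, 2L, 1L, 2L, 2L, 3L,
                1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

#' Construct an EpialleleSet
#'
#' @param fourmers data.frame with columns `fourmer_id`, `chrom`,
#'   `pos1..pos4` (as produced by [enumerateFourmers()]).
#' @param counts integer matrix with one row per 4-mer and 16 columns in
#'   configuration-index order.
#' @return An [EpialleleSet-class] object.
#' @export
EpialleleSet <- function(fourmers, counts) {
  fourmers <- as.data.frame(fourmers)
  rownames(fourmers) <- NULL
  storage.mode(counts) <- "integer"
  colnames(counts) <- epialleleConfigs()
  rownames(counts) <- fourmers$fourmer_id
  new("EpialleleSet", fourmers = fourmers, counts = counts)
}

#' @describeIn EpialleleSet-class the 4-mer annotation table.
#' @param x,object an `EpialleleSet`.
#' @export
fourmers <- function(x) x@fourmers

#' @describeIn EpialleleSet-class the n x 16 epiallele count matrix.
#' @export
epialleleCounts <- function(x) x@counts

#' @describeIn EpialleleSet-class per-4-mer coverage (reads spanning the
#'   entire 4-mer), i.e. row sums of the count matrix.
#' @export
fourmerCoverage <- function(x) rowSums(x@counts)

setMethod("show", "EpialleleSet", function(object) {
  cov <- fourmerCoverage(object)
  cat(sprintf("EpialleleSet: %d 4-mers, coverage %s\n",
              nrow(object@counts),
              if (length(cov)) sprintf("median %.0f [%.0f-%.0f]",
                                       stats::median(cov), min(cov), max(cov))
              else "-"))
})
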