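#' Read a methylation-call table
#'
#' Parses the tab-separated read-level methylation call dialect: a
#' `#`-prefixed header line followed by columns `read_id`, `chrom`, `pos`,
#' `strand`, `state`, `likelihood`. The `likelihood` column (absolute
#' log-likelihood of the call, nanopore dialect) is optional or may hold
#' `"."`; rows without a likelihood (bisulfite dialect) bypass the filter.
#'
#' Calls with a likelihood below `min_abs_likelihood` are dropped ("at
#' least" is inclusive: a call at exactly the threshold is kept). Calls on
#' the minus strand are destranded to the plus-strand C coordinate
#' (`pos - 1`) so both strands of a CpG collapse to one position.
#'
#' @param path path to the TSV file.
#' @param min_abs_likelihood minimum absolute call likelihood retained
#'   (default 2.5).
#' @return data.frame of calls with columns `read_id`, `chrom`, `pos`
#'   (0-based plus-strand C coordinate), `state` (0/1) and `likelihood`
#'   (`NA` where absent). Feed to [assembleReads()].
#' @seealso [writeMethCalls()], [assembleReads()]
#' @export
readMethCalls <- function(path, min_abs_likelihood = 2.5) {
  .assertScalarNum(min_abs_likelihood, "min_abs_likelihood", 0)
  header <- readLines(path, n = 1L)
  if (!length(header) || !startsWith(header, "#"))
    stop("expected a '#'-prefixed header line in ", path)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  need <- c("read_id", "chrom", "pos", "strand", "state")
  if (!all(need %in% cols))
    stop("header must contain columns ", paste(need, collapse = ", "))
  body <- readLines(path)[-1L]
  dt <- if (length(body))
    data.table::fread(text = body, sep = "\t", header = FALSE,
                      col.names = cols, na.strings = ".",
                      colClasses = list(character = which(cols == "chrom")))
  else data.table::data.table()
  if (nrow(dt) == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), state = integer(),
                      likelihood = numeric()))
  }
  if (!"likelihood" %in% names(dt)) dt[, likelihood := NA_real_]
  bad_state <- which(!(dt$state %in% c(0, 1)))
  if (length(bad_state))
    stop(sprintf("invalid state %s at line %d of %s (must be 0 or 1)",
                 dt$state[bad_state[1]], bad_state[1] + 1L, path))
  bad_pos <- which(is.na(dt$pos) | dt$pos < 0 | dt$pos != floor(dt$pos))
  if (length(bad_pos))
    stop(sprintf("malformed position at line %d of %s", bad_pos[1] + 1L, path))
  bad_strand <- which(!(dt$strand %in% c("+", "-")))
  if (length(bad_strand))
    stop(sprintf("malformed strand at line %d of %s", bad_strand[1] + 1L, path))
  pos <- as.integer(dt$pos)
  pos[dt$strand == "-"] <- pos[dt$strand == "-"] - 1L
  keep <- is.na(dt$likelihood) | abs(dt$likelihood) >= min_abs_likelihood
  out <- data.frame(read_id = as.character(dt$read_id),
                    chrom = dt$chrom, pos = pos,
                    state = as.integer(dt$state),
                    likelihood = as.numeric(dt$likelihood))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a methylation-call table
#'
#' Inverse of [readMethCalls()]; emits the `#`-headed TSV dialect. Calls
#' are written on the plus strand.
#'
#' @param calls data.frame with columns `read_id`, `chrom`, `pos`,
#'   `state` and optionally `likelihood` (`NA` written as `"."`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeMethCalls <- function(calls, path) {
  lik <- if ("likelihood" %in% names(calls)) calls$likelihood else NA_real_
  dt <- data.table::data.table(
    read_id = calls$read_id, chrom = calls$chrom,
    pos = as.integer(calls$pos), strand = "+",
    state = as.integer(calls$state),
    likelihood = ifelse(is.na(lik), ".", format(lik, digits = 17L)))
  writeLines(paste0("#", paste(names(dt), collapse = "\t")), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Assemble per-read methylation profiles from a call stream
#'
#' Groups calls by read and chromosome into a [MethReads-class] object
#' with positions sorted ascending. If a read carries duplicate calls at
#' the same position with conflicting states, that position is dropped
#' from the read (ambiguity must not fabricate an epiallele) and the read
#' is flagged; consistent duplicates collapse silently.
#'
#' @param calls data.frame of calls as returned by [readMethCalls()].
#' @param spans optional `GRanges` of aligned read intervals (names =
#'   read id); inferred from the calls when `NULL`.
#' @return A [MethReads-class] object.
#' @export
assembleReads <- function(calls, spans = NULL) {
  dt <- data.table::as.data.table(calls)[, c("read_id", "chrom", "pos", "state")]
  dt[, pos := as.integer(pos)]
  dt[, state := as.integer(state)]
  grp <- dt[, list(n_states = data.table::uniqueN(state), .N),
            by = c("read_id", "chrom", "pos")]
  conflict <- grp[grp$n_states > 1L]
  flagged <- character()
  if (nrow(conflict)) {
    flagged <- unique(conflict$read_id)
    warning(sprintf(
      "%d position(s) with conflicting duplicate calls dropped from %d read(s)",
      nrow(conflict), length(flagged)))
    dt <- dt[!conflict, on = c("read_id", "chrom", "pos")]
  }
  dt <- unique(dt, by = c("read_id", "chrom", "pos"))
  MethReads(as.data.frame(dt), spans = spans, flagged = flagged)
}

#' Read / write per-CpG methylation rates
#'
#' The per-CpG rate dialect is bedGraph-like: tab-separated columns
#' `chrom`, `start`, `end` (0-based half-open, `end = start + 1`),
#' `rate`, `n_meth`, `n_total`. Records must satisfy
#' `0 <= n_meth <= n_total`, `n_total > 0`, and `rate = n_meth/n_total`
#' within `1e-6`; violations are errors. Writing then reading reproduces
#' every field exactly.
#'
#' @param path file path.
#' @return `readCpGRates()`: a `GRanges` of width-1 CpG positions with
#'   metadata columns `rate`, `n_meth`, `n_total`.
#' @seealso [aggregateMethylation()], [callHyperCgis()]
#' @export
readCpGRates <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "rate",
                                        "n_meth", "n_total"),
                          colClasses = list(character = 1L))
  if (nrow(dt)) {
    if (any(dt$n_total <= 0))
      stop("n_total must be > 0 (rate undefined at zero coverage)")
    if (any(dt$n_meth < 0 | dt$n_meth > dt$n_total))
      stop("n_meth must satisfy 0 <= n_meth <= n_total")
    if (any(abs(dt$rate - dt$n_meth / dt$n_total) > 1e-6))
      stop("rate inconsistent with n_meth/n_total (tolerance 1e-6)")
  }
  gr <- .grFrom0(dt$chrom, dt$start, dt$end,
                 rate = as.numeric(dt$rate),
                 n_meth = as.integer(dt$n_meth),
                 n_total = as.integer(dt$n_total))
  sort(gr)
}

#' @rdname readCpGRates
#' @param rates `GRanges` with metadata columns `rate`, `n_meth`,
#'   `n_total` (width-1 CpG positions).
#' @return `writeCpGRates()`: invisibly, `path`.
#' @export
writeCpGRates <- function(rates, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(rates)),
    start = GenomicRanges::start(rates) - 1L,
    end = GenomicRanges::end(rates),
    rate = format(rates$rate, digits = 17L),
    n_meth = rates$n_meth, n_total = rates$n_total)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read genomic features from a BED file
#'
#' Reads BED3+ (0-based half-open) into a `GRanges` sorted by
#' (chromosome, start). Feature ids come from the BED name column when
#' present, otherwise they are synthesized from the coordinates.
#'
#' @param path BED file path.
#' @param feature_class label stored in the `feature_class` metadata
#'   column (e.g. `"cgi"`, `"tile"`; default `"custom"`).
#' @return `GRanges` with metadata columns `id` and `feature_class`.
#' @export
readFeatureBed <- function(path, feature_class = "custom") {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1L))
    stop("BED intervals must satisfy start < end")
  ids <- if (!is.null(gr$name) && !all(is.na(gr$name))) as.character(gr$name)
         else sprintf("%s:%d-%d", GenomicRanges::seqnames(gr),
                      GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(id = ids,
                                               feature_class = feature_class)
  GenomicRanges::strand(gr) <- "*"
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  sort(gr)
}

#' Read / write a chromosome-sizes table
#'
#' UCSC `.chrom.sizes` dialect: two tab-separated columns, chromosome
#' name and length.
#'
#' @param path file path.
#' @return `readChromSizes()`: named integer vector of lengths.
#' @export
readChromSizes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1L))
  stats::setNames(as.integer(dt$length), dt$chrom)
}

#' @rdname readChromSizes
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @export
writeChromSizes <- function(chrom_sizes, path) {
  data.table::fwrite(
    data.table::data.table(chrom = names(chrom_sizes),
                           length = as.integer(chrom_sizes)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Tile chromosomes into fixed-width windows
#'
#' Emits windows of `width` bp advancing by `step` bp per chromosome
#' (defaults 1 kb / 1 kb, i.e. non-overlapping tiles that partition the
#' chromosome; the final partial tile is retained).
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param width tile width in bp (> 0).
#' @param step distance between tile starts in bp (> 0).
#' @return `GRanges` of tiles with metadata columns `id` and
#'   `feature_class = "tile"`, seqlengths set.
#' @export
makeTiles <- function(chrom_sizes, width = 1000L, step = 1000L) {
  .assertScalarNum(width, "width", 1)
  .assertScalarNum(step, "step", 1)
  parts <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq.int(0L, max(len - 1L, 0L), by = step)
    data.frame(chrom = ch, start0 = starts,
               end0 = pmin(starts + as.integer(width), len))
  })
  df <- do.call(rbind, parts)
  gr <- .grFrom0(df$chrom, df$start0, df$end0,
                 id = sprintf("%s:%d-%d", df$chrom, df$start0, df$end0),
                 feature_class = "tile")
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Derive CGI shores and shelves
#'
#' Shores are the 2 kb intervals flanking each CpG island on either side;
#' shelves are the 2 kb intervals flanking the shores. Derived intervals
#' are truncated at chromosome bounds (and at zero when no lengths are
#' known); overlaps between derived features of neighbouring CGIs are
#' kept as-is.
#'
#' @param cgis `GRanges` of CpG islands with an `id` metadata column.
#' @param chrom_sizes optional named integer vector of chromosome lengths
#'   used for right-truncation.
#' @param flank flank width in bp (default 2000).
#' @return `GRanges` with metadata columns `id`, `feature_class`
#'   (`"shore"`/`"shelf"`) and `parent` (the source CGI id). Zero-width
#'   intervals (fully truncated) are dropped.
#' @export
deriveShoresShelves <- function(cgis, chrom_sizes = NULL, flank = 2000L) {
  flank <- as.integer(flank)
  s0 <- GenomicRanges::start(cgis) - 1L   # 0-based starts
  e0 <- GenomicRanges::end(cgis)          # 0-based half-open ends
  ch <- as.character(GenomicRanges::seqnames(cgis))
  ids <- if (!is.null(cgis$id)) cgis$id else as.character(seq_along(cgis))
  lens <- if (is.null(chrom_sizes)) rep(Inf, length(cgis))
          else unname(chrom_sizes[ch])
  piece <- function(start0, end0, class, side) {
    start0 <- pmax(start0, 0)
    end0 <- pmin(end0, lens)
    keep <- end0 > start0
    if (!any(keep)) return(NULL)
    .grFrom0(ch[keep], start0[keep], as.integer(end0[keep]),
             id = sprintf("%s_%s_%s", ids[keep], class, side),
             feature_class = class, parent = ids[keep])
  }
  out <- list(piece(s0 - flank, s0, "shore", "left"),
              piece(e0, e0 + flank, "shore", "right"),
              piece(s0 - 2L * flank, s0 - flank, "shelf", "left"),
              piece(e0 + flank, e0 + 2L * flank, "shelf", "right"))
  gr <- do.call(c, out[!vapply(out, is.null, logical(1))])
  sort(gr)
}
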