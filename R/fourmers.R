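#' Enumerate 4-mers of consecutive CpGs
#'
#' Builds the windows of four consecutive CpGs over which epialleles and
#' entropy are computed. In `sliding` mode (default) one 4-mer starts at
#' every CpG with three successors; `disjoint` mode advances four CpGs at
#' a time. 4-mers never span chromosomes.
#'
#' The reference CpG set is whatever positions you supply — typically the
#' union of positions observed in the data, or CpG coordinates from an
#' annotation track.
#'
#' @param cpg_positions either a named list of sorted 0-based integer
#'   vectors (one per chromosome) or a data.frame with columns `chrom`,
#'   `pos`.
#' @param mode `"sliding"` (step one CpG) or `"disjoint"` (step four).
#' @return data.frame with columns `fourmer_id`, `chrom`,
#'   `pos1`..`pos4`.
#' @examples
#' enumerateFourmers(list(chr1 = c(0L, 10L, 20L, 30L, 40L)))
#' @export
enumerateFourmers <- function(cpg_positions, mode = c("sliding", "disjoint")) {
  mode <- match.arg(mode)
  if (is.data.frame(cpg_positions))
    cpg_positions <- split(cpg_positions$pos, cpg_positions$chrom)
  parts <- lapply(names(cpg_positions), function(ch) {
    p <- sort(unique(as.integer(cpg_positions[[ch]])))
    n <- length(p)
    if (n < 4L) return(NULL)
    starts <- if (mode == "sliding") seq_len(n - 3L)
              else seq.int(1L, n - 3L, by = 4L)
    data.frame(chrom = ch, pos1 = p[starts], pos2 = p[starts + 1L],
               pos3 = p[starts + 2L], pos4 = p[starts + 3L])
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(fourmer_id = character(), chrom = character(),
                      pos1 = integer(), pos2 = integer(),
                      pos3 = integer(), pos4 = integer()))
  }
  df <- do.call(rbind, parts)
  df <- data.frame(fourmer_id = sprintf("%s:%d-%d", df$chrom, df$pos1, df$pos4),
                   df)
  rownames(df) <- NULL
  df
}

#' Count epialleles per 4-mer
#'
#' A read contributes to a 4-mer's epiallele counts only if it carries a
#' valid call at all four positions; it then increments the count of the
#' configuration `8*b1 + 4*b2 + 2*b3 + b4` formed by its binary states.
#' Reads missing any of the four calls contribute nothing.
#'
#' @param reads a [MethReads-class] object.
#' @param fourmers data.frame from [enumerateFourmers()].
#' @return An [EpialleleSet-class] with one row per input 4-mer (zero
#'   counts where no read spans it).
#' @export
countEpialleles <- function(reads, fourmers) {
  fm <- as.data.frame(fourmers)
  n_fm <- nrow(fm)
  counts <- matrix(0L, nrow = n_fm, ncol = 16L)
  if (n_fm && nrow(readCalls(reads))) {
    long <- data.table::rbindlist(lapply(1:4, function(k)
      data.table::data.table(fourmer_idx = seq_len(n_fm), chrom = fm$chrom,
                             pos = fm[[paste0("pos", k)]],
                             bit = c(8L, 4L, 2L, 1L)[k])))
    calls <- data.table::as.data.table(readCalls(reads))
    hits <- long[calls, on = c("chrom", "pos"), nomatch = NULL,
                 allow.cartesian = TRUE]
    per_read <- hits[, list(n_calls = .N, config = sum(bit * state)),
                     by = c("fourmer_idx", "read_id")]
    per_read <- per_read[per_read$n_calls == 4L]
    if (nrow(per_read)) {
      tab <- per_read[, list(n = .N), by = c("fourmer_idx", "config")]
      counts[cbind(tab$fourmer_idx, tab$config + 1L)] <- as.integer(tab$n)
    }
  }
  EpialleleSet(fm, counts)
}

#' Normalized methylation entropy of epiallele counts
#'
#' Shannon entropy (base 2) of the epiallele frequency distribution,
#' normalized by 4 (the maximum, `log2(16)` bits, reached when all 16
#' configurations are equally frequent):
#' \deqn{H = -\frac{1}{4}\sum_{i: n_i>0} \frac{n_i}{N}\log_2\frac{n_i}{N}}
#' with \eqn{N} the coverage. `0*log(0)` is taken as 0. A single observed
#' epiallele gives 0; a uniform distribution over all 16 gives 1. Zero
#' coverage yields `NA`.
#'
#' @param x a length-16 count vector, an n x 16 count matrix, or an
#'   [EpialleleSet-class].
#' @return Numeric entropy in `[0, 1]` (vector for matrix/EpialleleSet
#'   input, named by 4-mer id).
#' @examples
#' methEntropy(c(10, rep(0, 15)))   # 0
#' methEntropy(rep(10, 16))         # 1
#' @export
setGeneric("methEntropy", function(x) standardGeneric("methEntropy"))

.entropyRow <- function(n) {
  N <- sum(n)
  if (N == 0) return(NA_real_)
  p <- n[n > 0] / N
  -sum(p * log2(p)) / 4
}

#' @rdname methEntropy
#' @export
setMethod("methEntropy", "numeric", function(x) {
  if (length(x) != 16L) stop("expected 16 epiallele counts")
  if (any(x < 0)) stop("counts must be non-negative")
  .entropyRow(x)
})

#' @rdname methEntropy
#' @export
setMethod("methEntropy", "matrix", function(x) {
  if (ncol(x) != 16L) stop("expected 16 columns of epiallele counts")
  apply(x, 1L, .entropyRow)
})

#' @rdname methEntropy
#' @export
setMethod("methEntropy", "EpialleleSet", function(x) {
  stats::setNames(apply(epialleleCounts(x), 1L, .entropyRow),
                  fourmers(x)$fourmer_id)
})

#' Mean methylation of a 4-mer from epiallele counts
#'
#' Fraction of methylated calls among the `4 * N` constituent calls of a
#' 4-mer: `sum(counts[i] * popcount(i)) / (4 * N)`. Zero coverage yields
#' `NA`.
#'
#' @inheritParams methEntropy
#' @return Numeric in `[0, 1]`.
#' @export
setGeneric("fourmerMethylation", function(x) standardGeneric("fourmerMethylation"))

.methRow <- function(n) {
  N <- sum(n)
  if (N == 0) return(NA_real_)
  sum(n * .popcount4) / (4 * N)
}

#' @rdname fourmerMethylation
#' @export
setMethod("fourmerMethylation", "numeric", function(x) {
  if (length(x) != 16L) stop("expected 16 epiallele counts")
  .methRow(x)
})

#' @rdname fourmerMethylation
#' @export
setMethod("fourmerMethylation", "matrix", function(x) apply(x, 1L, .methRow))

#' @rdname fourmerMethylation
#' @export
setMethod("fourmerMethylation", "EpialleleSet", function(x) {
  stats::setNames(apply(epialleleCounts(x), 1L, .methRow),
                  fourmers(x)$fourmer_id)
})

#' Per-4-mer entropy table under a coverage window
#'
#' Computes entropy and mean methylation for every 4-mer whose coverage
#' (reads spanning the entire 4-mer) lies within `[min_cov, max_cov]`
#' (both inclusive; defaults 10 and 150). 4-mers outside the window are
#' absent from the result, not zero.
#'
#' @param x an [EpialleleSet-class], or a [MethReads-class] (in which
#'   case `fourmers` must be given and counting is performed first).
#' @param fourmers data.frame from [enumerateFourmers()] (only when `x`
#'   is a `MethReads`).
#' @param min_cov,max_cov inclusive coverage bounds.
#' @return data.frame with columns `fourmer_id`, `chrom`, `pos1`..`pos4`,
#'   `coverage`, `entropy`, `mean_methylation`.
#' @export
entropyTable <- function(x, fourmers = NULL, min_cov = 10L, max_cov = 150L) {
  if (min_cov > max_cov) stop("min_cov must not exceed max_cov")
  if (is(x, "MethReads")) {
    if (is.null(fourmers)) stop("supply 'fourmers' when x is a MethReads")
    x <- countEpialleles(x, fourmers)
  }
  cov <- fourmerCoverage(x)
  keep <- cov >= min_cov & cov <= max_cov
  out <- cbind(fourmers(x)[keep, , drop = FALSE],
               coverage = as.integer(cov[keep]),
               entropy = unname(methEntropy(x)[keep]),
               mean_methylation = unname(fourmerMethylation(x)[keep]))
  rownames(out) <- NULL
  out
}
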