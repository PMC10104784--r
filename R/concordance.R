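#' Select long reads spanning complete CpG islands
#'
#' A read spans a CGI when its aligned interval fully contains the CGI
#' interval (a read stopping one base short does not span). Reads
#' spanning fewer than two complete CGIs are dropped, then CGIs with
#' fewer than `min_reads_per_cgi` spanning reads (default 10) are
#' discarded.
#'
#' @param reads a [MethReads-class] object (long reads).
#' @param cgis `GRanges` of (hyper) CGIs with an `id` metadata column.
#' @param min_reads_per_cgi minimum spanning reads per retained CGI.
#' @return data.frame with columns `cgi_id`, `read_id`, `chrom`: one row
#'   per retained (CGI, spanning read) combination.
#' @export
selectSpanningReads <- function(reads, cgis, min_reads_per_cgi = 10L) {
  spans <- readSpans(reads)
  ov <- .overlaps(cgis, spans, type = "within")
  map <- data.table::data.table(
    cgi_id = cgis$id[S4Vectors::queryHits(ov)],
    read_id = names(spans)[S4Vectors::subjectHits(ov)],
    chrom = as.character(GenomicRanges::seqnames(cgis))[S4Vectors::queryHits(ov)])
  # reads must span >= 2 complete CGIs
  per_read <- map[, list(n = data.table::uniqueN(cgi_id)), by = "read_id"]
  map <- map[map$read_id %in% per_read$read_id[per_read$n >= 2L]]
  # CGIs must keep >= min_reads_per_cgi spanning reads
  per_cgi <- map[, list(n = data.table::uniqueN(read_id)), by = "cgi_id"]
  map <- map[map$cgi_id %in% per_cgi$cgi_id[per_cgi$n >= min_reads_per_cgi]]
  as.data.frame(map)
}

#' Per-read mean methylation within features
#'
#' For each (feature, read) pair in `span_map`, the mean of the read's
#' binary calls at CpGs inside the feature; `NA` when the read has fewer
#' than `min_calls` calls inside (default 1).
#'
#' @param reads a [MethReads-class] object.
#' @param features `GRanges` with an `id` metadata column.
#' @param span_map data.frame (`cgi_id`, `read_id`) from
#'   [selectSpanningReads()]; when `NULL`, all (feature, spanning-read)
#'   pairs are used without the pair/coverage filters.
#' @param min_calls minimum called CpGs per read per feature.
#' @return data.frame with columns `cgi_id`, `read_id`, `n_calls`,
#'   `mean_meth`.
#' @export
perReadFeatureMeans <- function(reads, features, span_map = NULL,
                                min_calls = 1L) {
  if (is.null(span_map)) {
    spans <- readSpans(reads)
    ov <- .overlaps(features, spans, type = "within")
    span_map <- data.frame(
      cgi_id = features$id[S4Vectors::queryHits(ov)],
      read_id = names(spans)[S4Vectors::subjectHits(ov)])
  }
  calls <- data.table::as.data.table(readCalls(reads))
  pts <- .grFrom0(calls$chrom, calls$pos, calls$pos + 1L)
  ov <- .overlaps(pts, features)
  inside <- data.table::data.table(
    cgi_id = features$id[S4Vectors::subjectHits(ov)],
    read_id = calls$read_id[S4Vectors::queryHits(ov)],
    state = calls$state[S4Vectors::queryHits(ov)])
  keys <- data.table::as.data.table(span_map[, c("cgi_id", "read_id")])
  inside <- inside[keys, on = c("cgi_id", "read_id"), nomatch = NULL]
  agg <- inside[, list(n_calls = .N, mean_meth = mean(state)),
                by = c("cgi_id", "read_id")]
  out <- merge(keys, agg, by = c("cgi_id", "read_id"), all.x = TRUE)
  out[is.na(out$n_calls), c("n_calls") := 0L]
  out[out$n_calls < min_calls, c("mean_meth") := NA_real_]
  data.table::setorderv(out, c("cgi_id", "read_id"))
  as.data.frame(out)
}

#' Fraction of concordant reads for a phased CGI pair
#'
#' A read with per-read means `(x_r, y_r)` over the two CGIs is
#' concordant when it falls on the same side of both CGIs' population
#' medians:
#' \deqn{(x_r > \tilde x \wedge y_r > \tilde y) \vee
#'       (x_r \le \tilde x \wedge y_r \le \tilde y)}
#' Ties at the median count to the low side (the `<=` in the predicate).
#' The medians are those of the unphased per-CGI distributions — computed
#' from all reads spanning each CGI, not only the pair's shared reads —
#' and are passed in, not recomputed.
#'
#' @param x,y per-read mean methylation over CGI A and B (same reads,
#'   same order).
#' @param median_x,median_y population medians of the unphased per-read
#'   means of each CGI.
#' @return Fraction of concordant reads in `[0, 1]`.
#' @export
concordanceFraction <- function(x, y, median_x, median_y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) return(NA_real_)
  mean((x > median_x & y > median_y) | (x <= median_x & y <= median_y))
}

#' Shuffle null for the concordant-read fraction
#'
#' Permutes the second CGI's per-read means across reads uniformly at
#' random `n_shuffles` times (default 100), recomputes the concordance
#' fraction each time against the same medians, and returns the average
#' across shuffles.
#'
#' @inheritParams concordanceFraction
#' @param n_shuffles number of random permutations.
#' @param seed integer seed (`NULL` leaves the RNG stream untouched).
#' @return Mean concordance fraction under the shuffle null.
#' @export
shuffleNull <- function(x, y, median_x, median_y, n_shuffles = 100L,
                        seed = NULL) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) return(NA_real_)
  .withSeed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i)
      concordanceFraction(x, sample(y), median_x, median_y), numeric(1)))
  })
}

#' Concordance of phased CGI pairs on long reads
#'
#' Full pair analysis: retain reads spanning at least two complete hyper
#' CGIs and CGIs with at least `min_reads_per_cgi` spanning reads;
#' compute per-read mean methylation per CGI and each CGI's unphased
#' median; then for every same-chromosome CGI pair sharing at least
#' `min_pair_reads` reads (default 10), report the observed concordant
#' fraction, its shuffle-null mean, and their difference.
#'
#' @inheritParams selectSpanningReads
#' @param min_pair_reads minimum shared reads per reported pair.
#' @param min_calls minimum called CpGs per read per CGI.
#' @param n_shuffles shuffles for the null.
#' @param seed integer seed; per-pair substreams are derived from it.
#' @return data.frame with columns `cgi_a`, `cgi_b`, `chrom`,
#'   `distance_bp` (gap between the islands), `n_reads`, `concordance`,
#'   `null_mean`, `delta`.
#' @export
cgiPairConcordance <- function(reads, cgis, min_reads_per_cgi = 10L,
                               min_pair_reads = 10L, min_calls = 1L,
                               n_shuffles = 100L, seed = 1L) {
  empty <- data.frame(cgi_a = character(), cgi_b = character(),
                      chrom = character(), distance_bp = integer(),
                      n_reads = integer(), concordance = numeric(),
                      null_mean = numeric(), delta = numeric())
  span_map <- selectSpanningReads(reads, cgis, min_reads_per_cgi)
  if (!nrow(span_map)) return(empty)
  means <- perReadFeatureMeans(reads, cgis, span_map, min_calls = min_calls)
  means <- means[!is.na(means$mean_meth), , drop = FALSE]
  med <- vapply(split(means$mean_meth, means$cgi_id), stats::median,
                numeric(1))
  by_read <- split(means[, c("read_id", "mean_meth")], means$cgi_id)
  cgi_meta <- data.frame(id = cgis$id,
                         chrom = as.character(GenomicRanges::seqnames(cgis)),
                         start = GenomicRanges::start(cgis) - 1L,
                         end = GenomicRanges::end(cgis))
  cgi_meta <- cgi_meta[cgi_meta$id %in% names(by_read), , drop = FALSE]
  cgi_meta <- cgi_meta[order(cgi_meta$chrom, cgi_meta$start), , drop = FALSE]
  rows <- list()
  pair_idx <- 0L
  for (ch in unique(cgi_meta$chrom)) {
    sub <- cgi_meta[cgi_meta$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2L) next
    prs <- utils::combn(nrow(sub), 2L)
    for (k in seq_len(ncol(prs))) {
      a <- sub[prs[1L, k], ]; b <- sub[prs[2L, k], ]
      pair_idx <- pair_idx + 1L
      va <- by_read[[a$id]]; vb <- by_read[[b$id]]
      shared <- intersect(va$read_id, vb$read_id)
      if (length(shared) < min_pair_reads) next
      x <- va$mean_meth[match(shared, va$read_id)]
      y <- vb$mean_meth[match(shared, vb$read_id)]
      conc <- concordanceFraction(x, y, med[[a$id]], med[[b$id]])
      null <- shuffleNull(x, y, med[[a$id]], med[[b$id]],
                          n_shuffles = n_shuffles,
                          seed = .subSeed(seed, pair_idx))
      rows[[length(rows) + 1L]] <- data.frame(
        cgi_a = a$id, cgi_b = b$id, chrom = ch,
        distance_bp = max(0L, b$start - a$end),
        n_reads = length(shared), concordance = conc,
        null_mean = null, delta = conc - null)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
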