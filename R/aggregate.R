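#' Aggregate per-CpG methylation over features
#'
#' Unweighted arithmetic mean of per-CpG methylation rates across the
#' CpGs falling inside each feature. A feature's mean is reported only
#' when at least `min_cpgs` covered CpGs fall inside it (default 3);
#' otherwise `NA`.
#'
#' @param features `GRanges` with an `id` metadata column (CGIs, tiles,
#'   shores, ...).
#' @param rates `GRanges` of width-1 CpG positions with a `rate`
#'   metadata column (see [readCpGRates()]).
#' @param min_cpgs minimum covered CpGs per feature.
#' @return data.frame with columns `feature_id`, `n_cpgs`,
#'   `mean_methylation` (one row per input feature, in input order).
#' @export
aggregateMethylation <- function(features, rates, min_cpgs = 3L) {
  ov <- .overlaps(rates, features, type = "within")
  n <- length(features)
  n_cpgs <- tabulate(S4Vectors::subjectHits(ov), nbins = n)
  sums <- rep(0, n)
  if (length(ov)) {
    agg <- rowsum(rates$rate[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov))
    sums[as.integer(rownames(agg))] <- agg[, 1L]
  }
  means <- ifelse(n_cpgs >= min_cpgs, sums / pmax(n_cpgs, 1L), NA_real_)
  data.frame(feature_id = features$id, n_cpgs = n_cpgs,
             mean_methylation = means)
}

#' Aggregate per-4-mer entropy over features
#'
#' Unweighted arithmetic mean of 4-mer entropies across the 4-mers
#' assigned to each feature. By default a 4-mer is assigned to a feature
#' if any of its four CpG positions lies inside the feature interval
#' (`assign = "any"`); `assign = "all"` requires all four. Features with
#' no assigned 4-mer get `NA`.
#'
#' @param features `GRanges` with an `id` metadata column.
#' @param records entropy table from [entropyTable()].
#' @param assign 4-mer-to-feature assignment rule, `"any"` or `"all"`.
#' @return data.frame with columns `feature_id`, `n_fourmers`,
#'   `mean_entropy` (one row per feature, in input order).
#' @export
aggregateEntropy <- function(features, records, assign = c("any", "all")) {
  assign <- match.arg(assign)
  n <- length(features)
  out <- data.frame(feature_id = features$id, n_fourmers = 0L,
                    mean_entropy = NA_real_)
  if (!nrow(records)) return(out)
  long <- data.table::rbindlist(lapply(1:4, function(k)
    data.table::data.table(row = seq_len(nrow(records)),
                           chrom = records$chrom,
                           pos = records[[paste0("pos", k)]])))
  pts <- .grFrom0(long$chrom, long$pos, long$pos + 1L)
  ov <- .overlaps(pts, features)
  if (!length(ov)) return(out)
  hit <- data.table::data.table(row = long$row[S4Vectors::queryHits(ov)],
                                feat = S4Vectors::subjectHits(ov))
  hit <- hit[, list(n_in = .N), by = c("row", "feat")]
  if (assign == "all") hit <- hit[hit$n_in == 4L]
  if (!nrow(hit)) return(out)
  hit[, entropy := records$entropy[hit$row]]
  agg <- hit[, list(n_fourmers = .N, mean_entropy = mean(entropy)),
             by = "feat"]
  out$n_fourmers[agg$feat] <- agg$n_fourmers
  out$mean_entropy[agg$feat] <- agg$mean_entropy
  out
}

#' Mask features not covered across samples
#'
#' For comparative analyses, retains only features whose summary value is
#' non-missing in at least `min_fraction` of the samples. The default 1.0
#' keeps the all-sample intersection; 0.8 is the convention for long
#' time-courses with many samples.
#'
#' @param summaries a long data.frame with columns `feature_id`,
#'   `sample_id` and one value column named by `value_col`.
#' @param min_fraction minimum fraction of samples with a non-missing
#'   value, in `(0, 1]`.
#' @param value_col name of the value column (default
#'   `"mean_methylation"`).
#' @return The rows of `summaries` belonging to retained features.
#' @export
maskCommonFeatures <- function(summaries, min_fraction = 1.0,
                               value_col = "mean_methylation") {
  .assertScalarNum(min_fraction, "min_fraction", lower = 1e-9, upper = 1)
  n_samples <- length(unique(summaries$sample_id))
  dt <- data.table::as.data.table(summaries)
  cov <- dt[, list(frac = sum(!is.na(.SD[[1L]])) / n_samples),
            by = "feature_id", .SDcols = value_col]
  keep <- cov$feature_id[cov$frac >= min_fraction]
  out <- summaries[summaries$feature_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal-overlap classification of tiles against CGIs
#'
#' Labels each tile as CGI-overlapping if, for some CGI, the overlap
#' covers at least `min_fraction` of the tile or at least `min_fraction`
#' of the CGI (default 20%, the convention used to relate 1 kb tiles to
#' CGI features in density plots).
#'
#' @param tiles,cgis `GRanges`.
#' @param min_fraction reciprocal overlap fraction threshold.
#' @return Logical vector along `tiles`.
#' @export
tileCgiOverlap <- function(tiles, cgis, min_fraction = 0.2) {
  ov <- .overlaps(tiles, cgis)
  out <- logical(length(tiles))
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(tiles[q], cgis[s]))
  hit <- w / GenomicRanges::width(tiles)[q] >= min_fraction |
         w / GenomicRanges::width(cgis)[s] >= min_fraction
  out[unique(q[hit])] <- TRUE
  out
}
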