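#' Call hypermethylated CGIs from two-condition rate tracks
#'
#' Implements the differential definition of hyper CGIs between an
#' extra-embryonic (ExE-like) and an epiblast-like condition:
#'
#' * **hyper** if the CGI's mean methylation difference
#'   `mean(ExE) - mean(Epi)` exceeds `diff_threshold` (strictly) AND
#'   either more than `cpg_fraction` of the CpGs covered in both
#'   conditions have a per-CpG difference of at least `diff_threshold`,
#'   or the CGI overlaps an externally supplied hyper-direction DMR with
#'   `q < q_max`;
#' * **excluded** if the epiblast mean is at or above `epi_max`
#'   (already-methylated islands), regardless of other criteria;
#' * **not_hyper** otherwise.
#'
#' CGI means follow the feature-aggregation rule: a condition's mean
#' needs at least `min_cpgs` covered CpGs inside the CGI, otherwise the
#' CGI's status is `NA`. DMR calling itself is out of scope — the DMR
#' criterion consumes an interval track produced elsewhere (e.g. metilene
#' with `-m 10 -d 0.1 -c 2 -f 1 -M 80 -v 0.7`); without one, only the
#' CpG-fraction criterion applies.
#'
#' @param cgis `GRanges` of CGIs with an `id` metadata column.
#' @param epi_rates,exe_rates per-CpG rate `GRanges` (see
#'   [readCpGRates()]) for the epiblast-like and ExE-like condition.
#' @param dmrs optional `GRanges` of DMRs with metadata columns `q`
#'   (q-value) and `direction` (`"hyper"` = more methylated in ExE).
#' @param diff_threshold CGI-mean and per-CpG difference threshold
#'   (default 0.1; CGI mean strictly greater, per-CpG at least).
#' @param cpg_fraction fraction of both-covered CpGs that must pass the
#'   per-CpG difference (strictly greater; default 0.5).
#' @param epi_max epiblast-mean exclusion threshold (inclusive;
#'   default 0.2).
#' @param min_cpgs minimum covered CpGs per condition per CGI.
#' @param q_max maximum DMR q-value considered usable.
#' @return data.frame with one row per CGI: `cgi_id`, `status`
#'   (`"hyper"`, `"not_hyper"`, `"excluded"` or `NA`), `epi_mean`,
#'   `exe_mean`, `mean_diff`, `n_cpgs_epi`, `n_cpgs_exe`,
#'   `n_cpgs_shared`, `frac_cpgs_diff`, `dmr_overlap`.
#' @export
callHyperCgis <- function(cgis, epi_rates, exe_rates, dmrs = NULL,
                          diff_threshold = 0.1, cpg_fraction = 0.5,
                          epi_max = 0.2, min_cpgs = 3L, q_max = 0.05) {
  .assertScalarNum(diff_threshold, "diff_threshold", 0, 1)
  .assertScalarNum(cpg_fraction, "cpg_fraction", 0, 1)
  .assertScalarNum(epi_max, "epi_max", 0, 1)
  epi <- aggregateMethylation(cgis, epi_rates, min_cpgs = min_cpgs)
  exe <- aggregateMethylation(cgis, exe_rates, min_cpgs = min_cpgs)

  # per-CpG differences at positions covered in both conditions
  key <- function(gr) paste0(GenomicRanges::seqnames(gr), ":",
                             GenomicRanges::start(gr))
  shared_idx <- match(key(epi_rates), key(exe_rates))
  has <- !is.na(shared_idx)
  shared <- epi_rates[has]
  shared$diff <- exe_rates$rate[shared_idx[has]] - epi_rates$rate[has]
  ov <- .overlaps(shared, cgis, type = "within")
  n_shared <- tabulate(S4Vectors::subjectHits(ov), nbins = length(cgis))
  # `tol` absorbs float accumulation noise so values landing exactly on a
  # threshold are classified as the definitions state (inclusive vs strict)
  tol <- 1e-9
  n_pass <- tabulate(
    S4Vectors::subjectHits(ov)[shared$diff[S4Vectors::queryHits(ov)] >=
                               diff_threshold - tol],
    nbins = length(cgis))
  frac <- ifelse(n_shared > 0L, n_pass / n_shared, NA_real_)

  dmr_overlap <- rep(FALSE, length(cgis))
  if (!is.null(dmrs) && length(dmrs)) {
    usable <- dmrs[!is.na(dmrs$q) & dmrs$q < q_max &
                   dmrs$direction == "hyper"]
    if (length(usable))
      dmr_overlap <- GenomicRanges::countOverlaps(cgis, usable) > 0L
  }

  mean_diff <- exe$mean_methylation - epi$mean_methylation
  cpg_crit <- !is.na(frac) & frac > cpg_fraction + tol
  status <- ifelse(
    is.na(epi$mean_methylation) | is.na(exe$mean_methylation), NA_character_,
    ifelse(epi$mean_methylation >= epi_max - tol, "excluded",
           ifelse(mean_diff > diff_threshold + tol & (cpg_crit | dmr_overlap),
                  "hyper", "not_hyper")))
  n_missing <- sum(is.na(status))
  if (n_missing)
    message(n_missing, " CGI(s) with fewer than ", min_cpgs,
            " covered CpGs in a condition: status NA")
  data.frame(cgi_id = cgis$id, status = status,
             epi_mean = epi$mean_methylation,
             exe_mean = exe$mean_methylation, mean_diff = mean_diff,
             n_cpgs_epi = epi$n_cpgs, n_cpgs_exe = exe$n_cpgs,
             n_cpgs_shared = n_shared, frac_cpgs_diff = frac,
             dmr_overlap = dmr_overlap)
}

#' Call CGIs gaining methylation in Polycomb knockouts
#'
#' The knockout-gain definition of hyper CGIs: a CGI is included when its
#' mean methylation in any knockout exceeds the wild-type mean by at
#' least `gain_threshold` (inclusive; default 0.2). CGIs without a
#' wild-type mean are skipped.
#'
#' @param wt_means data.frame (`feature_id`, `mean_methylation`) from
#'   [aggregateMethylation()] for the wild type.
#' @param ko_means named list of such data.frames, one per knockout.
#' @param gain_threshold minimum methylation gain (inclusive).
#' @return data.frame with columns `cgi_id`, `max_gain`, `best_ko`,
#'   `called` (one row per CGI with a wild-type mean).
#' @export
callPrcHyperCgis <- function(wt_means, ko_means, gain_threshold = 0.2) {
  .assertScalarNum(gain_threshold, "gain_threshold", 0, 1)
  if (is.null(names(ko_means)))
    names(ko_means) <- paste0("ko", seq_along(ko_means))
  wt <- stats::setNames(wt_means$mean_methylation, wt_means$feature_id)
  skipped <- names(wt)[is.na(wt)]
  if (length(skipped))
    message(length(skipped), " CGI(s) without a wild-type mean skipped")
  wt <- wt[!is.na(wt)]
  gains <- vapply(ko_means, function(km) {
    m <- stats::setNames(km$mean_methylation, km$feature_id)
    unname(m[names(wt)]) - unname(wt)
  }, numeric(length(wt)))
  if (is.null(dim(gains))) gains <- matrix(gains, nrow = length(wt))
  colnames(gains) <- names(ko_means)
  max_gain <- apply(gains, 1L, max, na.rm = TRUE)
  max_gain[is.infinite(max_gain)] <- NA_real_
  best <- colnames(gains)[apply(gains, 1L, function(g)
    if (all(is.na(g))) NA_integer_ else which.max(g))]
  data.frame(cgi_id = names(wt), max_gain = max_gain, best_ko = best,
             called = !is.na(max_gain) & max_gain >= gain_threshold - 1e-9,
             row.names = NULL)
}

#' Average replicate per-CpG rate tracks
#'
#' Replicates are combined per CpG first: at every position covered by at
#' least one replicate, the unweighted mean of the covering replicates'
#' rates (downstream feature means are then taken over these averaged
#' rates).
#'
#' @param rate_list list of per-CpG rate `GRanges` (see
#'   [readCpGRates()]).
#' @return `GRanges` of width-1 positions with metadata columns `rate`
#'   (mean across covering replicates) and `n_reps`.
#' @export
averageReplicateRates <- function(rate_list) {
  dt <- data.table::rbindlist(lapply(rate_list, function(gr)
    data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                           pos = GenomicRanges::start(gr), rate = gr$rate)))
  agg <- dt[, list(rate = mean(rate), n_reps = .N), by = c("chrom", "pos")]
  data.table::setorderv(agg, c("chrom", "pos"))
  GenomicRanges::GRanges(agg$chrom, IRanges::IRanges(agg$pos, agg$pos),
                         rate = agg$rate, n_reps = agg$n_reps)
}
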