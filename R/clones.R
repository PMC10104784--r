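#' Pool epiallele counts across clones
#'
#' Elementwise sum of the epiallele count matrices of several clones
#' indexed on the same 4-mer universe. Pooling is commutative and
#' associative; 4-mers with zero pooled coverage are retained (their
#' entropy is `NA`).
#'
#' @param clones named list of [EpialleleSet-class] objects sharing
#'   identical `fourmer_id`s in identical order.
#' @return An [EpialleleSet-class] of pooled counts.
#' @export
poolEpialleles <- function(clones) {
  if (!length(clones)) stop("need at least one clone")
  ids <- fourmers(clones[[1L]])$fourmer_id
  for (cl in clones[-1L])
    if (!identical(fourmers(cl)$fourmer_id, ids))
      stop("all clones must share an identical 4-mer universe")
  pooled <- Reduce(`+`, lapply(clones, epialleleCounts))
  EpialleleSet(fourmers(clones[[1L]]), pooled)
}

#' In-silico bulk from single-cell-derived clones
#'
#' Reconstructs a pseudo-bulk from per-clone epiallele counts: for each
#' 4-mer, counts are pooled over all clones and repeatedly subsampled
#' (`n_rounds` times, default 100) at the average per-clone coverage.
#' Each round draws `c = round(mean(per-clone coverage))` epialleles from
#' the pooled proportions (multinomial, i.e. with replacement), computes
#' entropy and mean methylation, and the per-4-mer average across rounds
#' is reported as the bulk value. Rounding is half-to-even; 4-mers whose
#' average coverage rounds to 0 are skipped.
#'
#' The comparison of these bulk values against per-clone entropies
#' distinguishes statically inherited methylation (clones far below
#' bulk) from dynamically re-equilibrating methylation (clones match
#' bulk); see [cloneBulkContrast()].
#'
#' @param clones named list of [EpialleleSet-class] objects on a shared
#'   4-mer universe.
#' @param n_rounds number of subsampling rounds.
#' @param seed integer seed; per-4-mer random substreams are derived from
#'   it deterministically, so results do not depend on evaluation order.
#' @return data.frame with columns `fourmer_id`, `sampled_coverage`,
#'   `n_rounds`, `bulk_entropy`, `bulk_methylation`.
#' @export
insilicoBulk <- function(clones, n_rounds = 100L, seed = 1L) {
  .assertScalarNum(n_rounds, "n_rounds", 1)
  pooled <- poolEpialleles(clones)
  cnt <- epialleleCounts(pooled)
  covs <- vapply(clones, fourmerCoverage, numeric(nrow(cnt)))
  if (is.null(dim(covs))) covs <- matrix(covs, nrow = 1L)
  c_target <- as.integer(round(rowMeans(covs)))
  keep <- which(c_target >= 1L & rowSums(cnt) > 0L)
  res <- lapply(keep, function(i) {
    .withSeed(.subSeed(seed, i), {
      draws <- stats::rmultinom(n_rounds, size = c_target[i], prob = cnt[i, ])
      c(ent = mean(apply(draws, 2L, .entropyRow)),
        meth = mean(apply(draws, 2L, .methRow)))
    })
  })
  res <- do.call(rbind, c(res, list(matrix(numeric(), ncol = 2L))))
  data.frame(fourmer_id = fourmers(pooled)$fourmer_id[keep],
             sampled_coverage = c_target[keep],
             n_rounds = rep(as.integer(n_rounds), length(keep)),
             bulk_entropy = res[, 1L],
             bulk_methylation = res[, 2L])
}

#' Per-4-mer clone vs in-silico-bulk entropy contrast
#'
#' Emits, per 4-mer and clone, the clone's entropy next to the in-silico
#' bulk entropy, optionally restricted to 4-mers overlapping a feature
#' set (e.g. hyper CGIs). Clone entropies obey the standard coverage
#' window (10-150 reads by default). No verdict is computed; the contrast
#' table is the deliverable — its distribution shows whether clones
#' re-reach bulk entropy (dynamic turnover) or stay below it (static
#' inheritance).
#'
#' @param clones named list of [EpialleleSet-class] objects.
#' @param bulk data.frame from [insilicoBulk()]; computed on the fly
#'   (with `seed`) when `NULL`.
#' @param features optional `GRanges`; keep only 4-mers with at least one
#'   position inside a feature.
#' @param min_cov,max_cov inclusive clone coverage window.
#' @param n_rounds,seed passed to [insilicoBulk()] when `bulk` is `NULL`.
#' @return Long data.frame with columns `fourmer_id`, `clone_id`,
#'   `clone_coverage`, `clone_entropy`, `clone_methylation`,
#'   `bulk_entropy`, `bulk_methylation`.
#' @export
cloneBulkContrast <- function(clones, bulk = NULL, features = NULL,
                              min_cov = 10L, max_cov = 150L,
                              n_rounds = 100L, seed = 1L) {
  if (is.null(bulk)) bulk <- insilicoBulk(clones, n_rounds = n_rounds, seed = seed)
  if (is.null(names(clones))) names(clones) <- paste0("clone", seq_along(clones))
  per_clone <- data.table::rbindlist(lapply(names(clones), function(id) {
    tab <- entropyTable(clones[[id]], min_cov = min_cov, max_cov = max_cov)
    if (!nrow(tab)) return(NULL)
    data.table::data.table(fourmer_id = tab$fourmer_id, clone_id = id,
                           clone_coverage = tab$coverage,
                           clone_entropy = tab$entropy,
                           clone_methylation = tab$mean_methylation)
  }))
  out <- merge(per_clone,
               data.table::as.data.table(
                 bulk[, c("fourmer_id", "bulk_entropy", "bulk_methylation")]),
               by = "fourmer_id")
  if (!is.null(features) && nrow(out)) {
    fm <- fourmers(clones[[1L]])
    rec <- fm[fm$fourmer_id %in% out$fourmer_id, , drop = FALSE]
    long <- data.table::rbindlist(lapply(1:4, function(k)
      data.table::data.table(id = rec$fourmer_id, chrom = rec$chrom,
                             pos = rec[[paste0("pos", k)]])))
    pts <- .grFrom0(long$chrom, long$pos, long$pos + 1L)
    hit_ids <- unique(long$id[S4Vectors::queryHits(
      .overlaps(pts, features))])
    out <- out[out$fourmer_id %in% hit_ids]
  }
  data.table::setorderv(out, c("fourmer_id", "clone_id"))
  as.data.frame(out)
}
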