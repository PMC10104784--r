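#' Run an analysis stage end to end
#'
#' Programmatic entry point chaining the package's stages over files on
#' disk; a thin command-line wrapper around it ships in
#' `inst/scripts/epientropy-cli.R`. Every stage writes its outputs plus a
#' `<stage>_manifest.json` recording inputs, parameters, seed and package
#' version, so a run can be reproduced bit-for-bit from the manifest.
#' All randomness flows from the single `seed` entry in `params`;
#' per-stage substreams are namespaced internally.
#'
#' Stages and their `params`:
#' \describe{
#'   \item{simulate}{a [syntheticConfig()] (or its arguments); writes
#'     `calls.tsv`, `rates_epi.tsv`/`rates_exe.tsv`, `cgis.bed`,
#'     `chrom.sizes`, `truth.tsv`.}
#'   \item{entropy}{`calls` (TSV path), optional `min_abs_likelihood`
#'     (2.5), `mode` ("sliding"), `min_cov` (10), `max_cov` (150);
#'     writes `entropy.tsv`.}
#'   \item{aggregate}{`features` (BED), `rates` and/or `entropy` (TSV),
#'     `min_cpgs` (3); writes `feature_summary.tsv`.}
#'   \item{clones}{`calls` (named vector of per-clone TSVs), `n_rounds`
#'     (100), `min_cov`/`max_cov`; writes `clone_contrast.tsv`.}
#'   \item{concordance}{`calls` (TSV), `cgis` (BED), `min_reads_per_cgi`
#'     (10), `min_pair_reads` (10), `n_shuffles` (100); writes
#'     `cgi_pairs.tsv`.}
#'   \item{hypercgi}{`cgis` (BED), `epi_rates`, `exe_rates` (TSV),
#'     optional `dmrs`, thresholds (0.1 / 0.5 / 0.2); writes
#'     `hyper_cgis.tsv`.}
#' }
#'
#' @param stage one of `"simulate"`, `"entropy"`, `"aggregate"`,
#'   `"clones"`, `"concordance"`, `"hypercgi"`.
#' @param params named list of stage parameters (see Details); missing
#'   entries take the defaults above.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a character vector of the files written.
#' @export
runPipeline <- function(stage = c("simulate", "entropy", "aggregate",
                                  "clones", "concordance", "hypercgi"),
                        params = list(), out_dir = ".") {
  stage <- match.arg(stage)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  get_par <- function(name, default = NULL) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  need_file <- function(name) {
    p <- params[[name]]
    if (is.null(p)) stop("stage '", stage, "' requires parameter '", name, "'")
    missing <- p[!file.exists(p)]
    if (length(missing)) stop("input file not found: ", missing[1L])
    p
  }
  seed <- as.integer(get_par("seed", 1L))
  outputs <- character()
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    data.table::fwrite(df, path, sep = "\t")
    outputs <<- c(outputs, path)
    path
  }

  if (stage == "simulate") {
    cfg <- if (inherits(params, "SyntheticConfig")) params
           else do.call(syntheticConfig, params[names(params) %in%
                          names(formals(syntheticConfig))])
    genome <- simulateGenome(cfg)
    reads <- do.call(rbind, lapply(names(genome$cpg_pos), function(ch)
      readCalls(simulateReadsDisordered(
        genome$cpg_pos[[ch]], chrom = ch, m = cfg$m,
        coverage = cfg$coverage, read_span_cpgs = cfg$read_span_cpgs,
        seed = .subSeed(cfg$seed, match(ch, names(genome$cpg_pos))),
        read_prefix = paste0(ch, "_read")))))
    reads <- attachLikelihoods(reads, low_frac = cfg$lik_low_frac,
                               seed = .subSeed(cfg$seed, 999L))
    writeMethCalls(reads, file.path(out_dir, "calls.tsv"))
    outputs <- c(outputs, file.path(out_dir, "calls.tsv"))
    cond <- simulateConditionPair(seed = .subSeed(cfg$seed, 1000L))
    writeCpGRates(cond$epi_rates, file.path(out_dir, "rates_epi.tsv"))
    writeCpGRates(cond$exe_rates, file.path(out_dir, "rates_exe.tsv"))
    cgi_bed <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(genome$cgis)),
      start = GenomicRanges::start(genome$cgis) - 1L,
      end = GenomicRanges::end(genome$cgis),
      name = genome$cgis$id)
    path <- file.path(out_dir, "cgis.bed")
    data.table::fwrite(cgi_bed, path, sep = "\t", col.names = FALSE)
    writeChromSizes(genome$chrom_sizes, file.path(out_dir, "chrom.sizes"))
    emit(cond$truth, "truth.tsv")
    outputs <- c(outputs, path, file.path(out_dir, "chrom.sizes"),
                 file.path(out_dir, "rates_epi.tsv"),
                 file.path(out_dir, "rates_exe.tsv"))
  } else if (stage == "entropy") {
    min_cov <- get_par("min_cov", 10L)
    max_cov <- get_par("max_cov", 150L)
    if (min_cov > max_cov)
      stop("invalid configuration: min_cov (", min_cov,
           ") exceeds max_cov (", max_cov, ")")
    calls <- readMethCalls(need_file("calls"),
                           min_abs_likelihood = get_par("min_abs_likelihood", 2.5))
    reads <- assembleReads(calls)
    fm <- enumerateFourmers(
      lapply(split(calls$pos, calls$chrom), unique),
      mode = get_par("mode", "sliding"))
    emit(entropyTable(reads, fm, min_cov = min_cov, max_cov = max_cov),
         "entropy.tsv")
  } else if (stage == "aggregate") {
    features <- readFeatureBed(need_file("features"))
    min_cpgs <- get_par("min_cpgs", 3L)
    out <- data.frame(feature_id = features$id)
    if (!is.null(params$rates)) {
      rates <- readCpGRates(need_file("rates"))
      out <- cbind(out, aggregateMethylation(features, rates,
                                             min_cpgs = min_cpgs)[-1L])
    }
    if (!is.null(params$entropy)) {
      rec <- as.data.frame(data.table::fread(need_file("entropy")))
      out <- cbind(out, aggregateEntropy(features, rec)[-1L])
    }
    emit(out, "feature_summary.tsv")
  } else if (stage == "clones") {
    paths <- need_file("calls")
    if (is.null(names(paths)))
      names(paths) <- sub("\\.tsv$", "", basename(paths))
    clone_reads <- lapply(paths, function(p) assembleReads(readMethCalls(p)))
    all_pos <- lapply(split(
      do.call(rbind, lapply(clone_reads, readCalls))[, c("chrom", "pos")],
      do.call(rbind, lapply(clone_reads, readCalls))$chrom),
      function(d) unique(d$pos))
    fm <- enumerateFourmers(all_pos, mode = get_par("mode", "sliding"))
    sets <- lapply(clone_reads, countEpialleles, fourmers = fm)
    emit(cloneBulkContrast(sets, n_rounds = get_par("n_rounds", 100L),
                           min_cov = get_par("min_cov", 10L),
                           max_cov = get_par("max_cov", 150L), seed = seed),
         "clone_contrast.tsv")
  } else if (stage == "concordance") {
    reads <- assembleReads(readMethCalls(
      need_file("calls"),
      min_abs_likelihood = get_par("min_abs_likelihood", 2.5)))
    cgis <- readFeatureBed(need_file("cgis"), feature_class = "cgi")
    emit(cgiPairConcordance(reads, cgis,
                            min_reads_per_cgi = get_par("min_reads_per_cgi", 10L),
                            min_pair_reads = get_par("min_pair_reads", 10L),
                            n_shuffles = get_par("n_shuffles", 100L),
                            seed = seed),
         "cgi_pairs.tsv")
  } else if (stage == "hypercgi") {
    cgis <- readFeatureBed(need_file("cgis"), feature_class = "cgi")
    dmrs <- NULL
    if (!is.null(params$dmrs)) {
      d <- as.data.frame(data.table::fread(need_file("dmrs"),
                                           col.names = c("chrom", "start", "end",
                                                         "direction", "q")))
      dmrs <- .grFrom0(d$chrom, d$start, d$end, direction = d$direction,
                       q = d$q)
    }
    emit(callHyperCgis(cgis, readCpGRates(need_file("epi_rates")),
                       readCpGRates(need_file("exe_rates")), dmrs = dmrs,
                       diff_threshold = get_par("diff_threshold", 0.1),
                       cpg_fraction = get_par("cpg_fraction", 0.5),
                       epi_max = get_par("epi_max", 0.2),
                       min_cpgs = get_par("min_cpgs", 3L)),
         "hyper_cgis.tsv")
  }

  manifest <- list(stage = stage, seed = seed,
                   package = "epientropy",
                   version = as.character(utils::packageVersion("epientropy")),
                   params = params[!vapply(params, is.function, logical(1))],
                   outputs = basename(outputs))
  man_path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(c(outputs, man_path))
}
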