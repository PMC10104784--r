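#' Synthetic-data configuration
#'
#' Bundles the parameters of the synthetic methylome generator. The
#' defaults describe the regimes the analysis is designed to
#' distinguish: a disordered intermediate methylome (per-CpG, per-read
#' independent Bernoulli states at level `m = 0.5`), with bimodal
#' somatic-like levels available at `m = 0.03` (unmethylated) and
#' `m = 0.85` (methylated); eight clones; and long reads whose CpG-island
#' coordination is tuned by `rho` in `[0, 1]`.
#'
#' @param seed master integer seed; fully determines all output.
#' @param n_chroms,chrom_length genome layout.
#' @param mean_gap mean inter-CpG gap in bp outside CGIs.
#' @param cgi_density CGI density multiplier (CpG gaps inside CGIs have
#'   mean `mean_gap / cgi_density`).
#' @param n_cgis_per_chrom,cgi_length CGI layout.
#' @param m per-CpG methylation level of the disordered regime.
#' @param coverage target per-CpG read coverage.
#' @param read_span_cpgs CpGs covered per (short) read.
#' @param n_clones,clone_model,epsilon clone generator: `"dynamic"`
#'   (reads redrawn i.i.d., entropy re-equilibrates) or `"static"`
#'   (each clone inherits one fixed pattern, copied with per-call error
#'   `epsilon`).
#' @param rho,beta_shape1,beta_shape2 long-read coordination strength and
#'   the Beta law of the per-read latent methylation propensity.
#' @param lik_low_frac fraction of emitted nanopore-dialect calls given a
#'   likelihood below 2.5 (to exercise the call filter).
#' @return A `SyntheticConfig` list.
#' @seealso [simulateGenome()], [simulateClones()],
#'   [simulateLongReads()], [simulateConditionPair()]
#' @export
syntheticConfig <- function(seed = 1L, n_chroms = 2L, chrom_length = 200000L,
                            mean_gap = 100L, cgi_density = 10,
                            n_cgis_per_chrom = 10L, cgi_length = 1000L,
                            m = 0.5, coverage = 30L, read_span_cpgs = 30L,
                            n_clones = 8L,
                            clone_model = c("dynamic", "static"),
                            epsilon = 0.02, rho = 0,
                            beta_shape1 = 2, beta_shape2 = 2,
                            lik_low_frac = 0.05) {
  clone_model <- match.arg(clone_model)
  for (p in c("m", "epsilon", "rho", "lik_low_frac"))
    .assertScalarNum(get(p), p, 0, 1)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              mean_gap = mean_gap, cgi_density = cgi_density,
              n_cgis_per_chrom = as.integer(n_cgis_per_chrom),
              cgi_length = as.integer(cgi_length), m = m,
              coverage = as.integer(coverage),
              read_span_cpgs = as.integer(read_span_cpgs),
              n_clones = as.integer(n_clones), clone_model = clone_model,
              epsilon = epsilon, rho = rho,
              beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
              lik_low_frac = lik_low_frac)
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' @export
print.SyntheticConfig <- function(x, ...) {
  cat("SyntheticConfig:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

# CpG positions in [from, to) with geometric gaps of the given mean
.cpgWalk <- function(from, to, mean_gap) {
  len <- to - from
  n_exp <- ceiling(len / mean_gap * 1.6) + 10L
  gaps <- stats::rgeom(n_exp, 1 / mean_gap) + 2L
  pos <- from + cumsum(gaps) - gaps[1L] %/% 2L
  pos[pos >= from & pos < to]
}

#' Simulate a CpG landscape with CpG islands
#'
#' Draws CpG positions with geometric inter-CpG gaps (mean `mean_gap`),
#' densified by a factor `cgi_density` inside CpG islands, which are
#' placed with jitter at regular intervals along each chromosome.
#'
#' @param config a [syntheticConfig()] (its `seed` determines the
#'   output).
#' @return list with `cpg_pos` (named list of sorted 0-based positions
#'   per chromosome), `cgis` (`GRanges` with `id`,
#'   `feature_class = "cgi"`), and `chrom_sizes` (named integer vector).
#' @export
simulateGenome <- function(config = syntheticConfig()) {
  .withSeed(config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    len <- config$chrom_length
    n_cgi <- config$n_cgis_per_chrom
    cgi_len <- config$cgi_length
    cpg_pos <- list()
    cgi_rows <- list()
    for (ch in chroms) {
      pitch <- (len - n_cgi * cgi_len) / (n_cgi + 1)
      starts <- round(pitch * seq_len(n_cgi) + cgi_len * (seq_len(n_cgi) - 1L) +
                      stats::runif(n_cgi, -pitch / 4, pitch / 4))
      starts <- pmax(0L, pmin(as.integer(starts), len - cgi_len))
      bounds <- c(0L, as.vector(rbind(starts, starts + cgi_len)), len)
      pos <- integer()
      for (i in seq_len(length(bounds) - 1L)) {
        inside_cgi <- i %% 2L == 0L
        g <- if (inside_cgi) config$mean_gap / config$cgi_density
             else config$mean_gap
        pos <- c(pos, .cpgWalk(bounds[i], bounds[i + 1L], g))
      }
      cpg_pos[[ch]] <- sort(unique(pos))
      cgi_rows[[ch]] <- data.frame(chrom = ch, start0 = starts,
                                   end0 = starts + cgi_len)
    }
    df <- do.call(rbind, cgi_rows)
    cgis <- .grFrom0(df$chrom, df$start0, df$end0,
                     id = sprintf("cgi_%s_%d", df$chrom,
                                  as.integer(stats::ave(df$start0, df$chrom,
                                                        FUN = seq_along))),
                     feature_class = "cgi")
    list(cpg_pos = cpg_pos,
         cgis = cgis,
         chrom_sizes = stats::setNames(rep(len, length(chroms)), chroms))
  })
}

# build a MethReads from read windows over a CpG position vector
.readsFromStates <- function(cpg_pos, chrom, starts, L, state_fun,
                             read_prefix) {
  n_reads <- length(starts)
  ids <- sprintf("%s_%05d", read_prefix, seq_len(n_reads))
  idx <- lapply(starts, function(s) s:(s + L - 1L))
  states <- state_fun(idx)
  calls <- data.frame(
    read_id = rep(ids, each = L),
    chrom = chrom,
    pos = cpg_pos[unlist(idx)],
    state = unlist(states))
  first <- cpg_pos[starts]
  last <- cpg_pos[starts + L - 1L]
  spans <- .grFrom0(rep(chrom, n_reads), first, last + 2L)
  names(spans) <- ids
  MethReads(calls, spans = spans)
}

#' Simulate reads from a disordered methylome
#'
#' Each read covers a window of `read_span_cpgs` consecutive CpGs and its
#' call at every covered CpG is an independent Bernoulli(`m`) draw — the
#' stochastic-turnover model in which every molecule is an independent
#' sample of the per-CpG methylation level. At `m = 0.5` and high
#' coverage, 4-mer entropy approaches 1.
#'
#' @param cpg_pos sorted 0-based CpG positions of the region.
#' @param chrom chromosome name.
#' @param m per-CpG methylation probability.
#' @param coverage target per-CpG coverage (expected reads per CpG).
#' @param read_span_cpgs CpGs per read.
#' @param seed integer seed.
#' @param read_prefix prefix for generated read ids.
#' @return A [MethReads-class] object.
#' @export
simulateReadsDisordered <- function(cpg_pos, chrom = "chr1", m = 0.5,
                                    coverage = 30L, read_span_cpgs = 30L,
                                    seed = 1L, read_prefix = "read") {
  .assertScalarNum(m, "m", 0, 1)
  n <- length(cpg_pos)
  L <- min(read_span_cpgs, n)
  .withSeed(seed, {
    n_reads <- ceiling(coverage * n / L)
    starts <- sample.int(n - L + 1L, n_reads, replace = TRUE)
    .readsFromStates(cpg_pos, chrom, starts, L,
                     function(idx) lapply(idx, function(i)
                       stats::rbinom(length(i), 1L, m)),
                     read_prefix)
  })
}

#' Simulate single-cell-derived clones
#'
#' Two inheritance models for a clonal population grown from single
#' cells:
#'
#' * `"dynamic"`: methylation turns over continuously, so every clone's
#'   reads are fresh i.i.d. Bernoulli(`m`) draws — each clone re-reaches
#'   the bulk's entropy;
#' * `"static"`: each clone inherits one fixed binary pattern (drawn once
#'   per CpG with probability `m`) and its reads copy that pattern with
#'   per-call error `epsilon` — clone entropy stays near zero while the
#'   pool across clones remains diverse.
#'
#' @inheritParams simulateReadsDisordered
#' @param n_clones number of clones.
#' @param model `"dynamic"` or `"static"`.
#' @param epsilon per-call copy error of the static model.
#' @return list with `clones` (named list of [MethReads-class]) and
#'   `truth` (model, `m`, `epsilon`, and the inherited `patterns` matrix
#'   for the static model).
#' @export
simulateClones <- function(cpg_pos, chrom = "chr1", n_clones = 8L,
                           model = c("dynamic", "static"), m = 0.5,
                           epsilon = 0.02, coverage = 40L,
                           read_span_cpgs = 30L, seed = 1L) {
  model <- match.arg(model)
  .assertScalarNum(epsilon, "epsilon", 0, 1)
  n <- length(cpg_pos)
  L <- min(read_span_cpgs, n)
  patterns <- NULL
  if (model == "static")
    patterns <- .withSeed(.subSeed(seed, 0L), {
      matrix(stats::rbinom(n_clones * n, 1L, m), nrow = n_clones)
    })
  clones <- lapply(seq_len(n_clones), function(k) {
    if (model == "dynamic") {
      simulateReadsDisordered(cpg_pos, chrom, m = m, coverage = coverage,
                              read_span_cpgs = read_span_cpgs,
                              seed = .subSeed(seed, k),
                              read_prefix = sprintf("clone%02d", k))
    } else {
      .withSeed(.subSeed(seed, k), {
        n_reads <- ceiling(coverage * n / L)
        starts <- sample.int(n - L + 1L, n_reads, replace = TRUE)
        .readsFromStates(cpg_pos, chrom, starts, L, function(idx)
          lapply(idx, function(i) {
            pat <- patterns[k, i]
            flip <- stats::rbinom(length(i), 1L, epsilon)
            as.integer(ifelse(flip == 1L, 1L - pat, pat))
          }),
          sprintf("clone%02d", k))
      })
    }
  })
  names(clones) <- sprintf("clone%02d", seq_len(n_clones))
  list(clones = clones,
       truth = list(model = model, m = m,
                    epsilon = if (model == "static") epsilon else NA_real_,
                    patterns = patterns))
}

#' Simulate long reads spanning multiple CpG islands
#'
#' Long-read model with tunable read-level coordination: blocks of
#' `cgis_per_block` CGIs are laid out on separate chromosomes and every
#' read of a block spans all of its CGIs. Per read `r` a latent
#' methylation propensity `u_r ~ Beta(beta_shape1, beta_shape2)` is
#' drawn; within CGI `c` the read's calls are Bernoulli at
#' `rho * u_r + (1 - rho) * v_rc` with an independent per-(read, CGI)
#' Beta draw `v_rc`. `rho = 0` makes CGIs independent within a read;
#' `rho = 1` couples them fully. With `u_binary = TRUE` the latent
#' propensity is forced to 0 or 1 (probability `m`), giving perfectly
#' concordant reads at `rho = 1`.
#'
#' @param n_blocks number of multi-CGI blocks (one chromosome each).
#' @param cgis_per_block CGIs per block.
#' @param cpgs_per_cgi CpGs per CGI.
#' @param cpg_spacing intra-CGI CpG spacing in bp.
#' @param cgi_gap gap between neighbouring CGIs in bp.
#' @param n_reads_per_block reads per block (each spans all CGIs).
#' @param rho coordination strength in `[0, 1]`.
#' @param beta_shape1,beta_shape2 Beta shape parameters of the latent
#'   propensities.
#' @param u_binary force the read-level latent to `{0, 1}`.
#' @param m success probability of the binary latent.
#' @param seed integer seed.
#' @return list with `reads` ([MethReads-class]), `cgis` (`GRanges`) and
#'   `truth` (the generating parameters incl. `rho`).
#' @export
simulateLongReads <- function(n_blocks = 50L, cgis_per_block = 4L,
                              cpgs_per_cgi = 12L, cpg_spacing = 40L,
                              cgi_gap = 2000L, n_reads_per_block = 24L,
                              rho = 0, beta_shape1 = 2, beta_shape2 = 2,
                              u_binary = FALSE, m = 0.5, seed = 1L) {
  .assertScalarNum(rho, "rho", 0, 1)
  cgi_len <- cpgs_per_cgi * cpg_spacing
  .withSeed(seed, {
    all_calls <- vector("list", n_blocks)
    all_spans <- vector("list", n_blocks)
    all_cgis <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      ch <- sprintf("blk%03d", b)
      cgi_start <- 1000L + (seq_len(cgis_per_block) - 1L) * (cgi_len + cgi_gap)
      cpgs <- lapply(cgi_start, function(s)
        s + (seq_len(cpgs_per_cgi) - 1L) * cpg_spacing)
      block_end <- cgi_start[cgis_per_block] + cgi_len + 1000L
      ids <- sprintf("%s_read%04d", ch, seq_len(n_reads_per_block))
      u <- if (u_binary) stats::rbinom(n_reads_per_block, 1L, m)
           else stats::rbeta(n_reads_per_block, beta_shape1, beta_shape2)
      block_calls <- vector("list", cgis_per_block)
      for (cgi in seq_len(cgis_per_block)) {
        v <- stats::rbeta(n_reads_per_block, beta_shape1, beta_shape2)
        p <- rho * u + (1 - rho) * v
        states <- vapply(p, function(pr)
          stats::rbinom(cpgs_per_cgi, 1L, pr), integer(cpgs_per_cgi))
        block_calls[[cgi]] <- data.frame(
          read_id = rep(ids, each = cpgs_per_cgi),
          chrom = ch,
          pos = rep(cpgs[[cgi]], times = n_reads_per_block),
          state = as.integer(states))
      }
      all_calls[[b]] <- do.call(rbind, block_calls)
      all_spans[[b]] <- data.frame(chrom = ch, end0 = block_end,
                                   read_id = ids)
      all_cgis[[b]] <- data.frame(chrom = ch, start0 = cgi_start,
                                  id = sprintf("%s_cgi%d", ch,
                                               seq_len(cgis_per_block)))
    }
    spdf <- do.call(rbind, all_spans)
    spans <- .grFrom0(spdf$chrom, 0L, spdf$end0)
    names(spans) <- spdf$read_id
    cgidf <- do.call(rbind, all_cgis)
    # CGI interval ends just past its last CpG dinucleotide so that a read
    # whose aligned span covers all the island's CpGs spans the island
    cgis <- .grFrom0(cgidf$chrom, cgidf$start0,
                     cgidf$start0 + (cpgs_per_cgi - 1L) * cpg_spacing + 2L,
                     id = cgidf$id, feature_class = "cgi")
    reads <- MethReads(do.call(rbind, all_calls), spans = spans)
    list(reads = reads, cgis = cgis,
         truth = list(rho = rho, m = m, u_binary = u_binary,
                      beta_shape1 = beta_shape1, beta_shape2 = beta_shape2))
  })
}

#' Simulate a two-condition differential methylome
#'
#' Emits per-CpG rate tracks for an epiblast-like and an ExE-like
#' condition with a planted set of hyper CGIs (epiblast level below the
#' exclusion threshold, ExE level raised above it) and, optionally, a set
#' of islands already methylated in the epiblast (which the caller must
#' exclude). With `noise = TRUE` counts are binomial at the given
#' sequencing depth; with `noise = FALSE` rates equal the planted levels
#' exactly (counts scaled to a depth of 1000).
#'
#' @param n_cgis total CGIs (one chromosome).
#' @param n_hyper planted hyper CGIs.
#' @param n_excluded planted epiblast-methylated CGIs.
#' @param cpgs_per_cgi,cpg_spacing,cgi_gap geometry.
#' @param epi_level,exe_level levels of the planted hyper set.
#' @param background_level level of unaffected CGIs (both conditions).
#' @param excluded_epi_level,excluded_exe_level levels of the planted
#'   excluded set.
#' @param depth per-CpG sequencing depth for the binomial noise model.
#' @param noise draw binomial counts (`TRUE`) or emit exact rates.
#' @param seed integer seed.
#' @return list with `epi_rates`, `exe_rates` (rate `GRanges`), `cgis`
#'   (`GRanges`) and `truth` (data.frame: `cgi_id`, `class`,
#'   `epi_level`, `exe_level`, `hyper`, `excluded`).
#' @export
simulateConditionPair <- function(n_cgis = 40L, n_hyper = 10L,
                                  n_excluded = 0L, cpgs_per_cgi = 10L,
                                  cpg_spacing = 50L, cgi_gap = 5000L,
                                  epi_level = 0.05, exe_level = 0.5,
                                  background_level = 0.05,
                                  excluded_epi_level = 0.25,
                                  excluded_exe_level = 0.8,
                                  depth = 30L, noise = TRUE, seed = 1L) {
  stopifnot(n_hyper + n_excluded <= n_cgis)
  cgi_len <- cpgs_per_cgi * cpg_spacing
  cls <- rep("background", n_cgis)
  if (n_hyper) cls[seq_len(n_hyper)] <- "hyper"
  if (n_excluded) cls[n_hyper + seq_len(n_excluded)] <- "excluded"
  epi_lev <- c(hyper = epi_level, excluded = excluded_epi_level,
               background = background_level)[cls]
  exe_lev <- c(hyper = exe_level, excluded = excluded_exe_level,
               background = background_level)[cls]
  starts <- 1000L + (seq_len(n_cgis) - 1L) * (cgi_len + cgi_gap)
  cgis <- .grFrom0(rep("chr1", n_cgis), starts, starts + cgi_len,
                   id = sprintf("cgi%03d", seq_len(n_cgis)),
                   feature_class = "cgi")
  pos <- unlist(lapply(starts, function(s)
    s + (seq_len(cpgs_per_cgi) - 1L) * cpg_spacing))
  lev_epi <- rep(epi_lev, each = cpgs_per_cgi)
  lev_exe <- rep(exe_lev, each = cpgs_per_cgi)
  track <- function(lev, sub) {
    if (noise) {
      n_meth <- .withSeed(.subSeed(seed, sub),
                          stats::rbinom(length(pos), depth, lev))
      n_total <- rep(as.integer(depth), length(pos))
    } else {
      n_total <- rep(1000L, length(pos))
      n_meth <- as.integer(round(lev * 1000))
    }
    .grFrom0(rep("chr1", length(pos)), pos, pos + 1L,
             rate = n_meth / n_total, n_meth = n_meth, n_total = n_total)
  }
  truth <- data.frame(cgi_id = cgis$id, class = cls,
                      epi_level = unname(epi_lev),
                      exe_level = unname(exe_lev),
                      hyper = cls == "hyper",
                      excluded = epi_lev >= 0.2)
  list(epi_rates = track(lev_epi, 1L), exe_rates = track(lev_exe, 2L),
       cgis = cgis, truth = truth)
}

#' Attach nanopore-dialect call likelihoods
#'
#' Draws an absolute call likelihood for every call so that a fraction
#' `low_frac` falls below the 2.5 retention threshold (uniform on
#' `[0, 2.5)`) and the rest above it (2.5 plus an exponential tail) —
#' used to exercise the likelihood filter on simulated data.
#'
#' @param calls data.frame of calls (`read_id`, `chrom`, `pos`,
#'   `state`).
#' @param low_frac fraction of calls below threshold.
#' @param seed integer seed.
#' @return `calls` with a `likelihood` column added.
#' @export
attachLikelihoods <- function(calls, low_frac = 0.05, seed = 1L) {
  .assertScalarNum(low_frac, "low_frac", 0, 1)
  n <- nrow(calls)
  .withSeed(seed, {
    low <- stats::runif(n) < low_frac
    calls$likelihood <- ifelse(low, stats::runif(n, 0, 2.5),
                               2.5 + stats::rexp(n, rate = 0.5))
  })
  calls
}
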