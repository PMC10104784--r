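# internal helpers shared across modules

# Derive a deterministic 32-bit sub-seed from a base seed and an index so
# per-unit random substreams (per 4-mer, per CGI pair) are reproducible
# regardless of evaluation order. Constants are from a standard LCG.
.subSeed <- function(seed, i) {
  s <- as.numeric(seed) %% 65521
  as.integer((s * 32749 + as.numeric(i) * 2654435 + 12345) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. `seed = NULL` leaves the RNG untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# findOverlaps without the seqinfo-merge warning emitted when query and
# subject share no sequence levels (a legitimate "no overlap" situation)
.overlaps <- function(query, subject, ...) {
  withCallingHandlers(
    GenomicRanges::findOverlaps(query, subject, ...),
    warning = function(w) {
      if (grepl("sequence levels in common", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# 0-based half-open interval -> GRanges (1-based closed)
.grFrom0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}
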