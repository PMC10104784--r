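# Small in-code fixtures shared across test files.

# write a methylation-call TSV (the '#'-headed dialect) and return its path
write_call_file <- function(df) {
  path <- tempfile("calls", fileext = ".tsv")
  if (!"strand" %in% names(df)) df$strand <- rep("+", nrow(df))
  if (!"likelihood" %in% names(df)) df$likelihood <- rep(".", nrow(df))
  df <- df[, c("read_id", "chrom", "pos", "strand", "state", "likelihood")]
  writeLines(paste0("#", paste(names(df), collapse = "\t")), path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = FALSE, row.names = FALSE)
  path
}

# MethReads in which each read realizes a given 4-CpG pattern string at
# positions `pos` (e.g. patterns = c("1010", "0101"))
reads_from_patterns <- function(patterns, pos = c(10L, 20L, 30L, 40L),
                                chrom = "chr1") {
  stopifnot(length(pos) == 4L)
  calls <- do.call(rbind, lapply(seq_along(patterns), function(i) {
    states <- as.integer(strsplit(patterns[i], "")[[1]])
    data.frame(read_id = sprintf("r%04d", i), chrom = chrom,
               pos = pos, state = states)
  }))
  MethReads(calls)
}

# epiallele count vector for a single 4-mer from pattern counts,
# e.g. pattern_counts(c("1111" = 10)) -> counts[16] = 10
pattern_counts <- function(x) {
  v <- integer(16)
  names(v) <- epialleleConfigs()
  v[names(x)] <- as.integer(x)
  v
}

# GRanges feature from 0-based half-open coordinates
feat <- function(chrom, start0, end0, id = sprintf("%s:%d-%d", chrom, start0, end0)) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), id = id)
}

# width-1 rate GRanges from 0-based positions and rates
rate_track <- function(pos, rate, chrom = "chr1", n_total = 100L) {
  n_meth <- as.integer(round(rate * n_total))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L),
                         rate = rate, n_meth = n_meth,
                         n_total = rep(as.integer(n_total), length(pos)))
}

# independent brute-force Shannon entropy over 16 categories, in bits/4
oracle_entropy <- function(counts) {
  total <- 0
  N <- sum(counts)
  if (N == 0) return(NA_real_)
  for (k in seq_along(counts)) {
    if (counts[k] > 0) {
      p <- counts[k] / N
      total <- total - p * (log(p) / log(2))
    }
  }
  total / 4
}

# all permutations of 1..n (n <= 7), as a list of integer vectors
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}
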