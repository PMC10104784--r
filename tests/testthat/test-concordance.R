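# a long-read fixture: two CGIs on one chromosome, n reads spanning both
two_cgi_reads <- function(states_a, states_b, cgi_a = c(100L, 300L),
                          cgi_b = c(1000L, 1200L), span_end = 2000L) {
  n <- nrow(states_a)
  ids <- sprintf("r%03d", seq_len(n))
  pos_a <- seq(cgi_a[1] + 10L, cgi_a[2] - 10L, length.out = ncol(states_a))
  pos_b <- seq(cgi_b[1] + 10L, cgi_b[2] - 10L, length.out = ncol(states_b))
  calls <- rbind(
    data.frame(read_id = rep(ids, each = ncol(states_a)), chrom = "chr1",
               pos = as.integer(rep(pos_a, n)),
               state = as.integer(t(states_a))),
    data.frame(read_id = rep(ids, each = ncol(states_b)), chrom = "chr1",
               pos = as.integer(rep(pos_b, n)),
               state = as.integer(t(states_b))))
  spans <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, span_end))
  spans <- rep(spans, n); names(spans) <- ids
  list(reads = MethReads(calls, spans = spans),
       cgis = c(feat("chr1", cgi_a[1], cgi_a[2], id = "A"),
                feat("chr1", cgi_b[1], cgi_b[2], id = "B")))
}

test_that("spanning requires full containment and ten reads per CGI", {
  cgi <- feat("chr1", 100L, 200L, id = "A")
  cgi2 <- feat("chr1", 300L, 400L, id = "B")
  mk_span <- function(id, s0, e0) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1L, e0))
    names(g) <- id
    g
  }
  calls <- data.frame(read_id = rep(sprintf("r%02d", 1:11), each = 2),
                      chrom = "chr1", pos = rep(c(150L, 350L), 11),
                      state = 1L)
  spans <- do.call(c, lapply(1:11, function(i) mk_span(sprintf("r%02d", i),
                                                       0L, 500L)))
  # read r11 stops one base short of CGI B's end -> spans only A
  spans[11] <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 399))
  mr <- MethReads(calls, spans = spans)
  map <- selectSpanningReads(mr, c(cgi, cgi2), min_reads_per_cgi = 10)
  expect_false("r11" %in% map$read_id)           # not a complete span of B
  expect_setequal(unique(map$cgi_id), c("A", "B"))
  expect_equal(sum(map$cgi_id == "B"), 10L)
  # with only 9 complete double-spanners, both CGIs fall below 10 reads
  mr9 <- MethReads(calls[calls$read_id %in% sprintf("r%02d", 1:9), ],
                   spans = spans[1:9])
  expect_equal(nrow(selectSpanningReads(mr9, c(cgi, cgi2))), 0L)
  # a read spanning only one CGI never enters
  one <- MethReads(data.frame(read_id = "solo", chrom = "chr1",
                              pos = 150L, state = 1L),
                   spans = mk_span("solo", 90L, 250L))
  expect_equal(nrow(selectSpanningReads(one, c(cgi, cgi2),
                                        min_reads_per_cgi = 1)), 0L)
})

test_that("per-read CGI means average the read's calls inside the island", {
  fx <- two_cgi_reads(matrix(c(1, 1, 0, 0), nrow = 1),
                      matrix(c(1, 1, 1, 1), nrow = 1))
  m <- perReadFeatureMeans(fx$reads, fx$cgis)
  expect_equal(m$mean_meth[m$cgi_id == "A"], 0.5)
  expect_equal(m$mean_meth[m$cgi_id == "B"], 1.0)
  # no calls inside -> missing
  empty_b <- fx
  calls <- readCalls(fx$reads)
  calls <- calls[calls$pos < 500L, ]
  mr <- MethReads(calls, spans = readSpans(fx$reads))
  m2 <- perReadFeatureMeans(mr, fx$cgis)
  expect_true(is.na(m2$mean_meth[m2$cgi_id == "B"]))
  expect_equal(m2$n_calls[m2$cgi_id == "B"], 0L)
})

test_that("concordance is 1 for identical pairing and 0 for reversed ranks", {
  x <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(concordanceFraction(x, x, median(x), median(x)), 1.0)
  expect_equal(concordanceFraction(x, rev(x), median(x), median(x)), 0.0)
  # ties at the median count to the low side
  expect_equal(concordanceFraction(c(0.5, 0.5), c(0.4, 0.6), 0.5, 0.5), 0.5)
  # invariant under jointly permuting read order
  set.seed(3)
  y <- runif(6)
  x6 <- runif(6)
  p <- sample(6)
  expect_equal(concordanceFraction(x6, y, median(x6), median(y)),
               concordanceFraction(x6[p], y[p], median(x6), median(y)))
})

test_that("mean concordance over all pairings matches the analytic expectation", {
  # brute force over every permutation of y for n <= 6
  set.seed(17)
  for (n in 3:6) {
    x <- runif(n); y <- runif(n)
    mx <- median(x); my <- median(y)
    perms <- all_perms(n)
    brute <- mean(vapply(perms, function(p)
      concordanceFraction(x, y[p], mx, my), numeric(1)))
    n_hx <- sum(x > mx); n_lx <- n - n_hx
    n_hy <- sum(y > my); n_ly <- n - n_hy
    analytic <- (n_hx * n_hy + n_lx * n_ly) / n^2
    expect_lt(abs(brute - analytic), 1e-12)
    # the sampled shuffle null converges to the same expectation
    null <- shuffleNull(x, y, mx, my, n_shuffles = 4000, seed = n)
    expect_lt(abs(null - analytic), 0.02)
  }
  # n = 4, identical pairing: observed 1.0, exhaustive mean 0.5
  x4 <- c(0.1, 0.2, 0.8, 0.9)
  expect_equal(concordanceFraction(x4, x4, median(x4), median(x4)), 1.0)
  brute4 <- mean(vapply(all_perms(4), function(p)
    concordanceFraction(x4, x4[p], median(x4), median(x4)), numeric(1)))
  expect_equal(brute4, 0.5)
})

test_that("shuffle null handles degenerate values and is seed-deterministic", {
  # all y identical and <= median: every shuffle equals the observed value
  x <- c(0.1, 0.2, 0.8, 0.9)
  y <- rep(0.3, 4)
  obs <- concordanceFraction(x, y, median(x), 0.3)
  expect_equal(shuffleNull(x, y, median(x), 0.3, seed = 5), obs)
  set.seed(71)
  y2 <- runif(10); x2 <- runif(10)
  expect_identical(shuffleNull(x2, y2, median(x2), median(y2), seed = 9),
                   shuffleNull(x2, y2, median(x2), median(y2), seed = 9))
})

test_that("pair analysis reports only pairs with >= 10 shared reads", {
  set.seed(12)
  n <- 12
  fx <- two_cgi_reads(matrix(rbinom(n * 6, 1, 0.5), nrow = n),
                      matrix(rbinom(n * 6, 1, 0.5), nrow = n))
  tab <- cgiPairConcordance(fx$reads, fx$cgis, seed = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_reads, 12L)
  expect_equal(tab$cgi_a, "A")
  expect_equal(tab$distance_bp, 700L)
  expect_true(tab$concordance >= 0 && tab$concordance <= 1)
  expect_equal(tab$delta, tab$concordance - tab$null_mean)
  # 9 reads -> no pair reported
  fx9 <- two_cgi_reads(matrix(rbinom(9 * 6, 1, 0.5), nrow = 9),
                       matrix(rbinom(9 * 6, 1, 0.5), nrow = 9))
  expect_equal(nrow(cgiPairConcordance(fx9$reads, fx9$cgis, seed = 2)), 0L)
  # determinism of the whole pair table
  expect_identical(cgiPairConcordance(fx$reads, fx$cgis, seed = 2), tab)
})

test_that("independent CGIs show no coordination; coupled CGIs show it", {
  sim0 <- simulateLongReads(n_blocks = 20, cgis_per_block = 4, rho = 0,
                            seed = 31)
  tab0 <- cgiPairConcordance(sim0$reads, sim0$cgis, seed = 32)
  expect_gte(nrow(tab0), 100)
  expect_lt(abs(mean(tab0$delta)), 0.02)
  sim1 <- simulateLongReads(n_blocks = 20, cgis_per_block = 4, rho = 1,
                            seed = 31)
  tab1 <- cgiPairConcordance(sim1$reads, sim1$cgis, seed = 32)
  expect_gte(mean(tab1$concordance > tab1$null_mean), 0.95)
  # fully binary latent: every read all-methylated or all-unmethylated
  simb <- simulateLongReads(n_blocks = 5, rho = 1, u_binary = TRUE,
                            seed = 33)
  tabb <- cgiPairConcordance(simb$reads, simb$cgis, seed = 34)
  expect_true(all(tabb$concordance == 1.0))
})
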