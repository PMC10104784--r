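# build an EpialleleSet for one 4-mer from pattern counts
one_fm_set <- function(...) {
  fm <- enumerateFourmers(list(chr1 = c(10L, 20L, 30L, 40L)))
  EpialleleSet(fm, matrix(pattern_counts(c(...)), nrow = 1))
}

test_that("pooling epialleles is elementwise, commutative and associative", {
  a <- one_fm_set("0000" = 10L)
  b <- one_fm_set("1111" = 10L)
  c3 <- one_fm_set("1010" = 3L, "0101" = 4L)
  pooled <- poolEpialleles(list(a, b))
  expect_equal(unname(epialleleCounts(pooled)[1, "0000"]), 10L)
  expect_equal(unname(epialleleCounts(pooled)[1, "1111"]), 10L)
  expect_equal(sum(epialleleCounts(pooled)), 20L)
  expect_equal(epialleleCounts(poolEpialleles(list(a, b, c3))),
               epialleleCounts(poolEpialleles(list(c3, b, a))))
  expect_equal(
    epialleleCounts(poolEpialleles(list(poolEpialleles(list(a, b)), c3))),
    epialleleCounts(poolEpialleles(list(a, poolEpialleles(list(b, c3))))))
  # single clone -> identity
  expect_equal(epialleleCounts(poolEpialleles(list(c3))), epialleleCounts(c3))
  # mismatched universes refuse to pool
  fm2 <- enumerateFourmers(list(chr1 = c(100L, 200L, 300L, 400L)))
  d <- EpialleleSet(fm2, matrix(pattern_counts(c("0000" = 1L)), nrow = 1))
  expect_error(poolEpialleles(list(a, d)), "universe")
})

test_that("in-silico bulk of homogeneous clones has zero entropy every round", {
  clones <- list(one_fm_set("0000" = 50L), one_fm_set("0000" = 30L))
  bulk <- insilicoBulk(clones, seed = 1)
  expect_equal(bulk$bulk_entropy, 0)
  expect_equal(bulk$bulk_methylation, 0)
  expect_equal(bulk$sampled_coverage, 40L)  # mean(50, 30)
})

test_that("opposite homogeneous clones mix to entropy 1/4 and methylation 1/2", {
  clones <- list(A = one_fm_set("1111" = 100L), B = one_fm_set("0000" = 100L))
  bulk <- insilicoBulk(clones, n_rounds = 100, seed = 7)
  # two equally frequent epialleles: H = 0.25 up to multinomial plug-in bias
  expect_lt(abs(bulk$bulk_entropy - 0.25), 0.02)
  expect_lt(abs(bulk$bulk_methylation - 0.5), 0.02)
  expect_equal(bulk$sampled_coverage, 100L)
})

test_that("bulk resampling is deterministic given the seed", {
  clones <- list(one_fm_set("1010" = 20L, "1111" = 15L),
                 one_fm_set("0101" = 40L))
  expect_identical(insilicoBulk(clones, seed = 42),
                   insilicoBulk(clones, seed = 42))
  expect_false(identical(insilicoBulk(clones, seed = 42)$bulk_entropy,
                         insilicoBulk(clones, seed = 43)$bulk_entropy))
})

test_that("average coverage rounds half-to-even and zero-coverage 4-mers are skipped", {
  clones <- list(one_fm_set("0000" = 1L), one_fm_set("0000" = 2L))
  expect_equal(insilicoBulk(clones, seed = 1)$sampled_coverage, 2L)  # 1.5 -> 2
  clones25 <- list(one_fm_set("0000" = 2L), one_fm_set("0000" = 3L))
  expect_equal(insilicoBulk(clones25, seed = 1)$sampled_coverage, 2L)  # 2.5 -> 2
  empty <- list(one_fm_set(), one_fm_set())
  expect_equal(nrow(insilicoBulk(empty, seed = 1)), 0L)
})

test_that("bulk converges to the exact expectation of plug-in entropy (2 epialleles, c <= 4)", {
  # exhaustive oracle: with c draws from proportions (p, 1-p) over two
  # epialleles, E[H_plugin] = sum_k C(c,k) p^k (1-p)^(c-k) H(k, c-k)
  exact_expectation <- function(p, c) {
    h <- function(k) methEntropy(pattern_counts(c("0000" = k, "1111" = c - k)))
    sum(vapply(0:c, function(k) dbinom(k, c, p) * h(k), numeric(1)))
  }
  # clone pairs engineered so the average coverage is exactly c and the
  # pooled proportions are p over two epialleles
  cases <- list(
    list(c = 2L, p = 0.5,  a = c("0000" = 1L, "1111" = 2L),
                           b = c("0000" = 1L)),
    list(c = 3L, p = 0.5,  a = c("0000" = 2L, "1111" = 2L),
                           b = c("0000" = 1L, "1111" = 1L)),
    list(c = 4L, p = 0.25, a = c("0000" = 1L, "1111" = 5L),
                           b = c("0000" = 1L, "1111" = 1L)),
    list(c = 4L, p = 0.5,  a = c("0000" = 3L, "1111" = 3L),
                           b = c("0000" = 1L, "1111" = 1L)))
  for (cs in cases) {
    clones <- list(do.call(one_fm_set, as.list(cs$a)),
                   do.call(one_fm_set, as.list(cs$b)))
    pooled <- epialleleCounts(poolEpialleles(clones))[1, ]
    expect_equal(unname(pooled["0000"] / sum(pooled)), cs$p)
    bulk <- insilicoBulk(clones, n_rounds = 4000, seed = 11)
    expect_equal(bulk$sampled_coverage, cs$c)
    expect_lt(abs(bulk$bulk_entropy - exact_expectation(cs$p, cs$c)), 0.01)
  }
})

test_that("a single clone's bulk reproduces its own entropy up to resampling bias", {
  set.seed(21)
  cnts <- pattern_counts(c("0000" = 40L, "1000" = 30L, "1111" = 30L))
  clone <- one_fm_set("0000" = 40L, "1000" = 30L, "1111" = 30L)
  bulk <- insilicoBulk(list(clone), n_rounds = 400, seed = 3)
  expect_lt(abs(bulk$bulk_entropy - methEntropy(cnts)), 0.02)
  expect_lt(abs(bulk$bulk_methylation - fourmerMethylation(cnts)), 0.02)
})

test_that("the clone-bulk contrast separates dynamic from static inheritance", {
  pos <- as.integer(seq(0, by = 30, length.out = 150))
  fm <- enumerateFourmers(list(chr1 = pos))

  dyn <- simulateClones(pos, n_clones = 8, model = "dynamic", m = 0.5,
                        coverage = 40, seed = 501)
  dyn_sets <- lapply(dyn$clones, countEpialleles, fourmers = fm)
  dyn_ctr <- cloneBulkContrast(dyn_sets, seed = 502)
  expect_lte(abs(median(dyn_ctr$clone_entropy) -
                 median(dyn_ctr$bulk_entropy)), 0.05)

  sta <- simulateClones(pos, n_clones = 8, model = "static", m = 0.5,
                        epsilon = 0.02, coverage = 40, seed = 503)
  sta_sets <- lapply(sta$clones, countEpialleles, fourmers = fm)
  sta_ctr <- cloneBulkContrast(sta_sets, seed = 504)
  expect_lte(median(sta_ctr$clone_entropy), 0.2)
  expect_gte(median(sta_ctr$bulk_entropy), 0.6)
})

test_that("contrast restricts to 4-mers overlapping a feature set when given", {
  pos <- as.integer(seq(0, by = 30, length.out = 60))
  fm <- enumerateFourmers(list(chr1 = pos))
  cl <- simulateClones(pos, n_clones = 3, model = "dynamic", coverage = 30,
                       seed = 9)
  sets <- lapply(cl$clones, countEpialleles, fourmers = fm)
  cgi <- feat("chr1", 0L, 300L, id = "c")
  full <- cloneBulkContrast(sets, seed = 10)
  sub <- cloneBulkContrast(sets, features = cgi, seed = 10)
  expect_lt(nrow(sub), nrow(full))
  expect_true(all(sub$fourmer_id %in% full$fourmer_id))
  # every retained 4-mer has a position inside the feature
  kept <- fm[fm$fourmer_id %in% sub$fourmer_id, ]
  expect_true(all(kept$pos1 < 300L))
})
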