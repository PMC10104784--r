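# ten-CpG CGI at [1000, 1500) with evenly spaced CpGs
ten_cpg_cgi <- function(id = "cgi1") {
  list(cgi = feat("chr1", 1000L, 1500L, id = id),
       pos = as.integer(seq(1010L, 1460L, by = 50L)))
}

test_that("the differential definition calls, rejects and excludes as stated", {
  fx <- ten_cpg_cgi()
  # Epi 0.05, ExE 0.50, all 10 CpGs diff >= 0.1 -> hyper
  res <- callHyperCgis(fx$cgi, rate_track(fx$pos, rep(0.05, 10)),
                       rate_track(fx$pos, rep(0.50, 10)))
  expect_equal(res$status, "hyper")
  expect_equal(res$frac_cpgs_diff, 1.0)
  # Epi 0.25 -> excluded regardless of a large difference
  res2 <- callHyperCgis(fx$cgi, rate_track(fx$pos, rep(0.25, 10)),
                        rate_track(fx$pos, rep(0.80, 10)))
  expect_equal(res2$status, "excluded")
  # diff 0.07 -> not hyper ("more than 0.1" is strict)
  res3 <- callHyperCgis(fx$cgi, rate_track(fx$pos, rep(0.05, 10)),
                        rate_track(fx$pos, rep(0.12, 10)))
  expect_equal(res3$status, "not_hyper")
})

test_that("boundary thresholds behave literally", {
  fx <- ten_cpg_cgi()
  # mean diff exactly 0.1 -> not called (strict >)
  exact <- callHyperCgis(fx$cgi, rate_track(fx$pos, rep(0.10, 10)),
                         rate_track(fx$pos, rep(0.20, 10)))
  expect_equal(exact$status, "not_hyper")
  # epiblast mean exactly 0.2 -> excluded (inclusive >=)
  at_max <- callHyperCgis(fx$cgi, rate_track(fx$pos, rep(0.20, 10)),
                          rate_track(fx$pos, rep(0.90, 10)))
  expect_equal(at_max$status, "excluded")
  # exactly half the CpGs passing is not "more than half"
  half <- callHyperCgis(fx$cgi,
                        rate_track(fx$pos, rep(0.00, 10)),
                        rate_track(fx$pos, rep(c(0.5, 0.05), each = 5)))
  expect_equal(half$frac_cpgs_diff, 0.5)
  expect_equal(half$status, "not_hyper")
  # per-CpG diff exactly 0.1 counts ("minimum difference of 0.1")
  per_cpg <- callHyperCgis(fx$cgi,
                           rate_track(fx$pos, rep(0.00, 10)),
                           rate_track(fx$pos, c(rep(0.1, 6), rep(0.5, 4))))
  expect_equal(per_cpg$frac_cpgs_diff, 1.0)
  expect_equal(per_cpg$status, "hyper")
})

test_that("a hyper-direction DMR can rescue but never remove calls", {
  fx <- ten_cpg_cgi()
  epi <- rate_track(fx$pos, rep(0.05, 10))
  # mean diff passes but only 3 of 10 CpGs do: needs the DMR
  exe <- rate_track(fx$pos, c(rep(0.55, 3), rep(0.12, 7)))
  base <- callHyperCgis(fx$cgi, epi, exe)
  expect_equal(base$status, "not_hyper")
  dmr_ok <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1100),
                                   q = 0.01, direction = "hyper")
  with_dmr <- callHyperCgis(fx$cgi, epi, exe, dmrs = dmr_ok)
  expect_equal(with_dmr$status, "hyper")
  expect_true(with_dmr$dmr_overlap)
  # q >= 0.05 or wrong direction does not rescue
  dmr_q <- dmr_ok; dmr_q$q <- 0.2
  expect_equal(callHyperCgis(fx$cgi, epi, exe, dmrs = dmr_q)$status,
               "not_hyper")
  dmr_dir <- dmr_ok; dmr_dir$direction <- "hypo"
  expect_equal(callHyperCgis(fx$cgi, epi, exe, dmrs = dmr_dir)$status,
               "not_hyper")
  # superset property on a random methylome: calls without DMR track are a
  # subset of calls with one
  sp <- simulateConditionPair(n_cgis = 30, n_hyper = 8, depth = 50, seed = 88)
  no_dmr <- callHyperCgis(sp$cgis, sp$epi_rates, sp$exe_rates)
  wide_dmr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10^9),
                                     q = 0.001, direction = "hyper")
  with_all <- callHyperCgis(sp$cgis, sp$epi_rates, sp$exe_rates,
                            dmrs = wide_dmr)
  expect_true(all(no_dmr$cgi_id[no_dmr$status == "hyper"] %in%
                  with_all$cgi_id[with_all$status == "hyper"]))
})

test_that("calling is monotone in its thresholds", {
  sp <- simulateConditionPair(n_cgis = 40, n_hyper = 15, n_excluded = 5,
                              depth = 30, seed = 41)
  n_hyper_at <- function(d) sum(callHyperCgis(sp$cgis, sp$epi_rates,
                                              sp$exe_rates,
                                              diff_threshold = d)$status ==
                                "hyper", na.rm = TRUE)
  ds <- c(0.05, 0.1, 0.2, 0.3)
  expect_true(all(diff(vapply(ds, n_hyper_at, numeric(1))) <= 0))
  n_excl_at <- function(e) sum(callHyperCgis(sp$cgis, sp$epi_rates,
                                             sp$exe_rates,
                                             epi_max = e)$status ==
                               "excluded", na.rm = TRUE)
  es <- c(0.3, 0.2, 0.1)
  expect_true(all(diff(vapply(es, n_excl_at, numeric(1))) >= 0))
})

test_that("insufficiently covered CGIs get NA status with a message", {
  fx <- ten_cpg_cgi()
  expect_message(
    res <- callHyperCgis(fx$cgi, rate_track(fx$pos[1:2], rep(0.05, 2)),
                         rate_track(fx$pos, rep(0.5, 10))),
    "fewer than 3")
  expect_true(is.na(res$status))
})

test_that("planted differential methylomes are recovered perfectly without noise", {
  sp <- simulateConditionPair(n_cgis = 40, n_hyper = 12, n_excluded = 6,
                              noise = FALSE, seed = 55)
  res <- callHyperCgis(sp$cgis, sp$epi_rates, sp$exe_rates)
  called <- res$cgi_id[res$status == "hyper"]
  truth <- sp$truth$cgi_id[sp$truth$hyper]
  expect_setequal(called, truth)   # precision = recall = 1
  expect_setequal(res$cgi_id[res$status == "excluded"],
                  sp$truth$cgi_id[sp$truth$excluded])
})

test_that("PRC knockout gains use an inclusive 0.2 threshold", {
  wt <- data.frame(feature_id = c("a", "b", "c", "d"),
                   mean_methylation = c(0.3, 0.3, 0.3, NA))
  kos <- list(
    eed = data.frame(feature_id = c("a", "b", "c", "d"),
                     mean_methylation = c(0.5, 0.45, 0.2, 0.9)),
    rnf2 = data.frame(feature_id = c("a", "b", "c", "d"),
                      mean_methylation = c(0.35, 0.40, 0.55, 0.9)))
  expect_message(res <- callPrcHyperCgis(wt, kos), "skipped")
  expect_equal(res$cgi_id, c("a", "b", "c"))        # d has no WT mean
  expect_equal(res$called, c(TRUE, FALSE, TRUE))    # a: gain exactly 0.2
  expect_equal(res$best_ko, c("eed", "eed", "rnf2"))
  expect_equal(res$max_gain, c(0.2, 0.15, 0.25))
})

test_that("replicate rate tracks average per CpG before aggregation", {
  r1 <- rate_track(c(10L, 20L, 30L), c(0.2, 0.4, 0.6))
  r2 <- rate_track(c(10L, 20L, 40L), c(0.4, 0.6, 1.0))
  avg <- averageReplicateRates(list(r1, r2))
  expect_equal(length(avg), 4L)
  expect_equal(avg$rate, c(0.3, 0.5, 0.6, 1.0))
  expect_equal(avg$n_reps, c(2L, 2L, 1L, 1L))
})
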