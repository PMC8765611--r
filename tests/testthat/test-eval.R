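fake_regions <- function(start, end, chrom = "chr1") {
  structure(data.frame(chrom = rep(chrom, length(start)), start = start,
                       end = end),
            class = c("candidate_regions", "data.frame"))
}

test_that("FDR and power arithmetic", {
  set.seed(2)
  # 100 regions, 60 of which contain a site
  start <- seq(0, by = 1e4, length.out = 100)
  r <- fake_regions(start, start + 5e3)
  sites <- data.frame(chrom = "chr1", pos = start[1:60] + 100)
  ev <- scan_fdr(r, sites)
  expect_equal(ev$n_regions, 100L)
  expect_equal(ev$n_true_positive, 60L)
  expect_equal(ev$fdr, 0.40)
  # FDR + per-region true-positive rate = 1 exactly
  expect_equal(ev$fdr + ev$n_true_positive / ev$n_regions, 1)
  # every region covered -> FDR 0
  sites_all <- data.frame(chrom = "chr1", pos = start + 100)
  expect_equal(scan_fdr(r, sites_all)$fdr, 0)
  # power is per site
  s2 <- data.frame(chrom = "chr1", pos = c(start[1:73] + 100,
                                           start[74:100] + 6e3))
  expect_equal(scan_power(r, s2)$power, 0.73)
  # no regions: power 0, FDR undefined (classed condition)
  expect_equal(scan_power(fake_regions(numeric(0), numeric(0)), s2)$power, 0)
  expect_error(scan_fdr(fake_regions(numeric(0), numeric(0)), s2),
               class = "ehhscan_undefined_fdr")
})

test_that("randomly placed regions give expected FDR of 1 - length fraction", {
  # one chromosome of length G with one uniformly placed true site; a fixed
  # region of length l is a true positive with probability l / G
  set.seed(3)
  G <- 1e6
  l <- 2e5
  r <- fake_regions(4e5, 4e5 + l)
  hits <- replicate(3000, {
    scan_fdr(r, data.frame(chrom = "chr1", pos = runif(1, 0, G)))$fdr == 0
  })
  expect_equal(mean(hits), l / G, tolerance = 0.1)
})

test_that("power threshold calibration hits the requested genome fraction", {
  # synthetic neutral genome: 20 chromosomes x 1 Mb of N(0,1) scores; finer
  # windows than the region caller so that ~1% coverage is reachable
  set.seed(6)
  tabs <- lapply(1:20, function(cc) {
    pos <- sort(sample(1:1e6, 1500))
    make_score_table(pos, std = rnorm(1500), chrom = paste0("chr", cc),
                     extent = c(0, 1e6))
  })
  tab <- bind_scores(tabs)
  wt <- window_scan(tab, width = 50000, offset = 10000)
  thr <- calibrate_power_threshold(wt, genome_fraction = 0.01,
                                   min_fraction = 0.5, min_markers = 30)
  expect_true(attr(thr, "coverage") >= 0.009 && attr(thr, "coverage") <= 0.011)
  # coverage at the returned threshold recomputes to the same value
  r <- call_regions(wt, thr, min_fraction = 0.5, min_markers = 30)
  expect_equal(sum(r$end - r$start) / 2e7, unname(attr(thr, "coverage")))
  # constant scores: coverage jumps from everything to nothing -> error
  tabc <- make_score_table(sort(sample(1:1e6, 2000)), std = rep(1, 2000),
                           extent = c(0, 1e6))
  expect_error(calibrate_power_threshold(window_scan(tabc, 100000, 20000),
                                         genome_fraction = 0.01,
                                         min_markers = 50),
               "not attainable")
  # fraction 1.0 is attainable there with the minimal threshold
  thr1 <- calibrate_power_threshold(window_scan(tabc, 100000, 20000),
                                    genome_fraction = 1, min_markers = 50)
  expect_equal(unname(attr(thr1, "coverage")), 1)
})
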