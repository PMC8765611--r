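# Brute-force check configuration: markers every 10 kb on [0, 990 kb],
# extremeness 3 on positions 300-500 kb inclusive (21 markers), 0.5
# elsewhere; windows 250 kb / offset 50 kb.
toy_windows <- function() {
  pos <- seq(0, 990000, by = 10000)
  make_score_table(pos, std = ifelse(pos >= 3e5 & pos <= 5e5, 3, 0.5),
                   extent = c(0, 1e6))
}

test_that("window membership is half-open and tiles the chromosome", {
  wt <- window_scan(toy_windows())
  expect_equal(attr(wt, "width"), 250000)
  # interior windows hold 25 markers at 10-kb spacing
  expect_true(all(wt$n_markers[wt$start <= 740000] == 25))
  # a marker exactly at start + width belongs to the next window only
  tab <- make_score_table(c(0, 250000), std = c(1, 1), extent = c(0, 5e5))
  w2 <- window_scan(tab)
  expect_equal(w2$n_markers[w2$start == 0], 1L)
  expect_equal(w2$n_markers[w2$start == 50000], 1L)  # holds only 250000
  # empty table -> empty window table
  w0 <- window_scan(make_score_table(numeric(0), numeric(0)))
  expect_equal(nrow(w0), 0L)
})

test_that("qualifying windows and merging match brute-force counting", {
  wt <- window_scan(toy_windows())
  r <- call_regions(wt, score_threshold = 2, min_fraction = 0.5,
                    min_markers = 5)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 200000)
  expect_equal(r$end, 600000)
  expect_equal(strsplit(r$window_starts, ",")[[1]],
               as.character(c(2e5, 2.5e5, 3e5, 3.5e5)))
  expect_equal(r$n_extreme, 21L)
  # all below threshold -> nothing
  expect_equal(nrow(call_regions(wt, 10, 0.5, 5)), 0L)
  # min_markers above every window count -> nothing regardless of scores
  expect_equal(nrow(call_regions(wt, 0.1, 0.5, 100)), 0L)
})

test_that("threshold calibration hits the requested region count", {
  wt <- window_scan(toy_windows())
  cal <- calibrate_regions(wt, 1, min_markers = 5)
  expect_equal(cal$achieved, 1L)
  expect_true(cal$threshold > 0.5 && cal$threshold <= 3)
  expect_equal(cal$regions$start, 200000)
  expect_equal(cal$regions$end, 600000)
  # a second cluster makes two regions reachable
  pos <- seq(0, 990000, by = 10000)
  tab2 <- make_score_table(pos, std = ifelse((pos >= 3e5 & pos <= 4.5e5) |
                                               (pos >= 7e5 & pos <= 8.5e5),
                                             3, 0.5), extent = c(0, 1e6))
  cal2 <- calibrate_regions(window_scan(tab2), 2, min_markers = 5)
  expect_equal(cal2$achieved, 2L)
  # unreachable targets are rejected with the achievable maximum
  expect_error(calibrate_regions(wt, 50, min_markers = 5), "at most")
})

test_that("raising the threshold never increases a window's extreme count", {
  set.seed(12)
  pos <- sort(sample(1:1e6, 400))
  tab <- make_score_table(pos, std = rnorm(400), extent = c(0, 1e6))
  wt <- window_scan(tab)
  thrs <- c(0, 0.5, 1, 1.5, 2, 3)
  ne <- vapply(thrs, function(t) ehhscan:::.window_extreme_counts(wt, t),
               integer(nrow(wt)))
  expect_true(all(apply(ne, 1, function(x) all(diff(x) <= 0))))
})

test_that("merged regions are disjoint and contain every qualifying window", {
  set.seed(13)
  pos <- sort(sample(1:3e6, 900))
  tab <- make_score_table(pos, std = rnorm(900, sd = 2), extent = c(0, 3e6))
  wt <- window_scan(tab)
  r <- call_regions(wt, 1, min_fraction = 0.3, min_markers = 10)
  if (nrow(r) > 1) {
    o <- order(r$start)
    expect_true(all(r$start[o][-1] > r$end[o][-nrow(r)]))
  }
  ne <- ehhscan:::.window_extreme_counts(wt, 1)
  qual <- wt[wt$n_markers > 10 & wt$n_scored > 0 &
               ne / pmax(wt$n_scored, 1) >= 0.3, ]
  if (nrow(qual) > 0) {
    inside <- vapply(seq_len(nrow(qual)), function(k)
      sum(r$start <= qual$start[k] & r$end >= qual$end[k]), integer(1))
    expect_true(all(inside == 1L))
  }
})

test_that("overlap counting: identity, disjoint sets, site mode", {
  a <- structure(data.frame(chrom = c("c1", "c1", "c2"),
                            start = c(0, 5e5, 0), end = c(1e5, 6e5, 1e5)),
                 class = c("candidate_regions", "data.frame"))
  expect_equal(region_overlap(a, a)$n_overlapping, 3L)
  b <- a
  b$start <- b$start + 2e6
  b$end <- b$end + 2e6
  expect_equal(region_overlap(a, b)$n_overlapping, 0L)
  sites <- data.frame(chrom = c("c1", "c2"), pos = c(50000, 99999))
  expect_equal(region_overlap(a, sites)$n_overlapping, 2L)
})
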