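test_that("uniHS is the log-ratio of the per-allele integrals", {
  h <- random_hapset(7, n_seq = 10, n_markers = 25)
  cfg <- scan_config("phased")
  tab <- unihs_scan(h, "phased", "polarized", cfg)
  ok <- which(!is.na(tab$score_un))
  expect_gt(length(ok), 0)
  for (s in utils::head(ok, 6)) {
    ia <- ihh(h, s, tab$allele_num[s], "phased", cfg)
    id <- ihh(h, s, tab$allele_den[s], "phased", cfg)
    expect_equal(tab$score_un[s], log(ia$value / id$value))
    # polarized: the numerator allele is the ancestral one (code 0 here)
    expect_equal(tab$allele_num[s], 0L)
  }
})

test_that("major/minor mode breaks frequency ties towards the lower code", {
  A <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L),
             c(0L, 0L, 0L, 1L))
  h <- haploset(A, c(0, 10, 20, 30))
  tab <- unihs_scan(h, "phased", "major_minor",
                    scan_config("phased", maf_min = 0))
  expect_equal(tab$allele_num[2], 0L)  # p = 0.5 for both alleles
  expect_equal(tab$allele_den[2], 1L)
})

test_that("markers with more than two alleles are flagged, not scored", {
  A <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 2L, 0L), c(0L, 1L, 0L, 1L))
  h <- haploset(A, c(0, 10, 20), ancestral = c(0L, 0L, 0L))
  tab <- unihs_scan(h, "phased", "polarized",
                    scan_config("phased", maf_min = 0))
  expect_true(tab$multiallelic[2])
  expect_true(is.na(tab$score_un[2]))
})

test_that("MAF and unphased focal-support filters flag markers", {
  g <- cached("score_hapset", {
    simulate_neutral(sim_params(N = 100, L = 2e5, n = 40,
                                mu = 200 / (4 * 100 * 2e5),
                                r = 200 / (4 * 100 * 2e5), seed = 31),
                     1)$haps[[1]]
  })
  tab <- unihs_scan(g, "phased", "polarized")
  low <- which(tab$maf < 0.05)
  expect_true(all(tab$below_maf[low]))
  expect_true(all(is.na(tab$score_un[low])))
  # unphased: each core allele needs >= 10 homozygous sequences
  tabu <- unihs_scan(g, "unphased", "polarized")
  expect_gt(sum(tabu$insufficient), 0)
  expect_true(all(is.na(tabu$score_un[tabu$insufficient])))
  # a single-individual sample cannot support the unphased estimator
  h1 <- haploset(g$alleles[1:50, 1:2, drop = FALSE], g$positions[1:50])
  t1 <- ies_scan(h1, "unphased")
  expect_true(all(t1$insufficient))
})

test_that("polarized mode rejects (or skips) markers without ancestry", {
  h <- random_hapset(13, n_seq = 8, n_markers = 20)
  h$ancestral[3:20] <- NA_integer_
  expect_error(unihs_scan(h, "phased", "polarized",
                          scan_config("phased", maf_min = 0)),
               "ancestral")
  tab <- unihs_scan(h, "phased", "polarized",
                    scan_config("phased", maf_min = 0),
                    on_unpolarized = "skip")
  expect_true(any(tab$unpolarized))
  expect_true(all(is.na(tab$score_un[tab$unpolarized])))
})

test_that("standardization: median centering with sd about the mean", {
  tab <- make_score_table(c(10, 20, 30), std = NA)
  tab$score_un <- c(0, 0, 10)
  tab[ehhscan:::.flag_cols] <- FALSE
  out <- standardize(tab, std_spec("unbinned", center = "median"))
  expect_equal(out$score_std, c(0, 0, 10 / sd(c(0, 0, 10))))
  expect_equal(out$score_std[3], 1.7321, tolerance = 1e-4)
  # already-standard values are unchanged under mean/sd
  tab$score_un <- c(-1, 0, 1)
  out2 <- standardize(tab, std_spec("unbinned", center = "mean"))
  expect_equal(out2$score_std, c(-1, 0, 1))
  # zero scale flags instead of emitting scores
  tab$score_un <- c(1, 1, 1)
  out3 <- standardize(tab, std_spec("unbinned"))
  expect_true(all(out3$zero_scale))
  expect_true(all(is.na(out3$score_std)))
})

test_that("frequency-binned standardization gives mean 0, sd 1 per bin", {
  set.seed(4)
  n <- 600
  tab <- make_score_table(sort(sample(1:1e6, n)), std = NA)
  tab$p_derived <- runif(n)
  tab$score_un <- rnorm(n, mean = 2 * tab$p_derived, sd = 1)
  tab[ehhscan:::.flag_cols] <- FALSE
  out <- standardize(tab, std_spec("freq_binned", bin_width = 0.1,
                                   min_bin_count = 20))
  expect_equal(mean(out$score_std), 0, tolerance = 0.2)
  expect_equal(sd(out$score_std), 1, tolerance = 0.2)
  # flagged markers are excluded from the moments and stay unscored
  tab$truncated[1:50] <- TRUE
  out2 <- standardize(tab, std_spec("unbinned"))
  expect_true(all(is.na(out2$score_std[1:50])))
  expect_equal(mean(out2$score_std[-(1:50)]), 0, tolerance = 1e-12)
})

test_that("cross-population statistics: identity, antisymmetry, unphased
          coincidence", {
  sp <- cached("split_small", {
    simulate_split(sim_params(N = 100, L = 2e5, n = 60,
                              mu = 300 / (4 * 100 * 2e5),
                              r = 300 / (4 * 100 * 2e5), seed = 77), 1)
  })
  t1 <- ies_scan(sp$pop1$haps[[1]], "phased")
  t2 <- ies_scan(sp$pop2$haps[[1]], "phased")
  # same population twice: all unstandardized scores are exactly 0
  self <- xpehh(t1, t1)
  expect_true(all(self$score_un[!is.na(self$score_un)] == 0))
  # swapping populations flips every unstandardized score's sign
  ab <- xpehh(t1, t2)
  ba <- xpehh(t2, t1)
  expect_equal(ab$score_un, -ba$score_un)
  # unphased estimator: iES = inES, so unXP-EHH = unRsb at every marker
  u1 <- ies_scan(sp$pop1$haps[[1]], "unphased")
  u2 <- ies_scan(sp$pop2$haps[[1]], "unphased")
  expect_equal(u1$ies[!u1$insufficient], u1$ines[!u1$insufficient])
  xpu <- xpehh(u1, u2)
  rsu <- rsb(u1, u2)
  expect_identical(xpu$score_un, rsu$score_un)
  # ... and the standardized scores differ only via mean-vs-median centering
  keep <- !is.na(xpu$score_std)
  sd_un <- sd(xpu$score_un[keep & !ehhscan:::.disqualified(xpu)])
  expect_equal(xpu$score_std[keep] - rsu$score_std[keep],
               rep((median(rsu$score_un[keep & !ehhscan:::.disqualified(rsu)]) -
                      mean(xpu$score_un[keep & !ehhscan:::.disqualified(xpu)])) /
                     sd_un, sum(keep)),
               tolerance = 1e-9)
  # disjoint marker sets are an error
  t2b <- t2
  t2b$pos <- t2b$pos + 1e7
  expect_error(xpehh(t1, t2b), "no marker")
})

test_that("monomorphic markers are scored by iES but not by uniHS", {
  A <- rbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  h <- haploset(A, c(0, 50, 100))
  te <- ies_scan(h, "phased")
  expect_false(is.na(te$ies[1]))
  tu <- unihs_scan(h, "phased", "major_minor",
                   scan_config("phased", maf_min = 0))
  expect_true(tu$undefined[1])
})
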