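# The toy configuration (positions 0..40, four sequences H1..H4, focal
# marker 3 at position 20) has hand-enumerated shared haplotypes:
# allele 0 carriers H1,H2,H3 with pairwise lengths 40, 30, 30.

test_that("identity classes over an interval match exhaustive comparison", {
  t4 <- hap_example("toy4")
  expect_equal(shared_partition(t4, 3, 4, restrict_allele = 0),
               list(c(1L, 2L, 3L)))
  expect_equal(shared_partition(t4, 3, 5, restrict_allele = 0),
               list(c(1L, 2L), 3L))
  # t = s without restriction: classes are the allele groups at s
  expect_equal(shared_partition(t4, 3, 3), list(c(1L, 2L, 3L), 4L))
  # missing data makes a sequence a singleton
  tm <- t4
  tm$alleles[4, 2] <- NA_integer_
  expect_equal(shared_partition(tm, 3, 4, restrict_allele = 0),
               list(c(1L, 3L), 2L))
})

test_that("phased EHH values follow the pair-fraction definition", {
  t4 <- hap_example("toy4")
  cv <- ehh_allele(t4, 3, 0, "phased")
  expect_equal(cv$value_at_s, 1)
  d <- as.data.frame(cv)
  expect_equal(d$value[d$pos == 30], 1)
  expect_equal(d$value[d$pos == 40], 1 / 3)
  expect_equal(d$value[d$pos == 10], 1 / 3)
  expect_equal(d$value[d$pos == 0], 1 / 3)
  # n_a < 2 is an undefined statistic, not an empty-data error
  expect_error(ehh_allele(t4, 3, 1, "phased"), "undefined statistic")
  # unphased: only individual 1 counts and H1 = H2 everywhere
  cu <- ehh_allele(t4, 3, 0, "unphased")
  expect_true(all(c(cu$left$value, cu$right$value) == 1))
})

test_that("EHHS equals focal homozygosity at s (phased) and 1 (unphased)", {
  t4 <- hap_example("toy4")
  es <- ehhs(t4, 3, "phased")
  expect_equal(es$value_at_s, 0.5)
  d <- as.data.frame(es)
  expect_equal(d$value[d$pos == 30], 0.5)
  expect_equal(d$value[d$pos == 40], 1 / 6)
  eu <- ehhs(t4, 3, "unphased")
  expect_true(all(c(eu$left$value, eu$right$value) == 1))
  # all-identical sample: phased EHHS is 1 everywhere
  hid <- haploset(matrix(0L, 4, 4), c(0, 10, 20, 30))
  eid <- ehhs(hid, 2, "phased")
  expect_true(all(c(eid$left$value, eid$right$value) == 1))
})

test_that("integration reproduces the hand-computed toy integrals", {
  t4 <- hap_example("toy4")
  i <- integrate_curve(ehh_allele(t4, 3, 0, "phased"),
                       cfg_mean_length("phased"))
  expect_equal(i$value, 100 / 3)
  expect_true(i$truncated)
  expect_equal(i$left$stop_reason, "chromosome-boundary")
  iu <- integrate_curve(ehh_allele(t4, 3, 0, "unphased"),
                        cfg_mean_length("unphased"))
  expect_equal(iu$value, 40)
  # flat curve over [0, L] with cutoff 0.05 integrates to L, truncated
  hid <- haploset(matrix(0L, 3, 4), c(0, 500, 1000))
  ifl <- integrate_curve(ehh_allele(hid, 2, 0, "phased"),
                         scan_config("phased", curve_mode = "stepwise"))
  expect_equal(ifl$value, 1000)
  expect_true(ifl$truncated)
  # inES: iES / EHHS at s (phased); equality for unphased
  r <- ines(t4, 3, "phased", cfg_mean_length("phased"))
  expect_equal(r$value, 50 / 3)
  expect_equal(r$ines, r$value / 0.5)
  ru <- ines(t4, 3, "unphased", cfg_mean_length("unphased"))
  expect_equal(ru$ines, ru$value)
})

test_that("linear integration interpolates the cutoff crossing", {
  # curve 1, 0.5, 0 at 0/10/20; cutoff 0.25 crosses at x = 15
  h <- haploset(rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 1L, 1L),
                      c(0L, 1L, 0L, 1L)), c(0, 10, 20))
  # EHH for allele 0 at s=1: at 10: pairs (1,2),(3,4) -> 2/6... use EHHS-free
  cv <- ehh_allele(h, 1, 0, "phased")
  expect_equal(cv$right$value, c(1, 1 / 3, 0))
  i <- integrate_curve(cv, scan_config("phased", ehh_cutoff = 0.25,
                                       curve_mode = "linear"))
  # right side: trapezoid 0->10 (1 + 1/3)/2*10 then crossing from 1/3 to 0.25
  d <- 10 * (1 / 3 - 0.25) / (1 / 3 - 0)
  expect_equal(i$right$area, (1 + 1 / 3) / 2 * 10 + (1 / 3 + 0.25) / 2 * d)
  expect_equal(i$right$stop_reason, "cutoff-crossed")
  expect_equal(i$right$stop_pos, 10 + d)
})

test_that("pairwise shared lengths (the oracle) match hand enumeration", {
  t4 <- hap_example("toy4")
  o <- pairwise_shared_lengths(t4, 3, 0)
  expect_equal(sort(o$length), c(30, 30, 40))
  expect_equal(attr(o, "mean_length"), 100 / 3)
  expect_error(pairwise_shared_lengths(t4, 3, 1), "undefined statistic")
  # identical duplicated sequences share the whole chromosome
  hid <- haploset(matrix(0L, 3, 4), c(0, 500, 1000))
  oid <- pairwise_shared_lengths(hid, 2, 0)
  expect_true(all(oid$length == 1000))
})

test_that("worked two-diploid example: unphased mean 35 bp, phased 30 bp", {
  f <- hap_example("two_diploids")
  iu <- integrate_curve(ehh_allele(f, 5, 0, "unphased"),
                        cfg_mean_length("unphased"))
  ip <- integrate_curve(ehh_allele(f, 5, 0, "phased"),
                        cfg_mean_length("phased"))
  expect_equal(iu$value, 35)
  expect_equal(ip$value, 30)
  expect_equal(attr(pairwise_shared_lengths(f, 5, 0), "mean_length"), 30)
})

test_that("stepwise iHH with cutoff 0 equals the pairwise oracle", {
  # the central correctness property, on random haplotype sets with missing
  # data and occasional third alleles
  for (seed in 1:40) {
    h <- random_hapset(seed, miss_prob = if (seed %% 3 == 0) 0.08 else 0,
                       tri_prob = if (seed %% 5 == 0) 0.05 else 0)
    for (s in unique(round(seq(1, n_markers(h), length.out = 5)))) {
      for (a in unique(h$alleles[s, ])) {
        if (is.na(a) || sum(h$alleles[s, ] == a, na.rm = TRUE) < 2) next
        i <- integrate_curve(ehh_allele(h, s, a, "phased"),
                             cfg_mean_length("phased"))
        o <- attr(pairwise_shared_lengths(h, s, a), "mean_length")
        expect_equal(i$value, o, tolerance = 1e-9)
      }
      # iES against the all-pairs mean
      if (sum(!is.na(h$alleles[s, ])) >= 2) {
        ie <- integrate_curve(ehhs(h, s, "phased"), cfg_mean_length("phased"))
        oe <- attr(pairwise_shared_lengths(h, s, a = NULL), "mean_length")
        expect_equal(ie$value, oe, tolerance = 1e-9)
      }
    }
  }
})

test_that("curves are monotone decreasing away from the focal marker", {
  for (seed in 41:55) {
    h <- random_hapset(seed, miss_prob = 0.05)
    s <- sample(n_markers(h), 1)
    a <- h$alleles[s, which(!is.na(h$alleles[s, ]))[1]]
    if (sum(h$alleles[s, ] == a, na.rm = TRUE) < 2) next
    cv <- ehh_allele(h, s, a, "phased")
    expect_true(all(diff(cv$left$value) <= 1e-12))
    expect_true(all(diff(cv$right$value) <= 1e-12))
    expect_true(all(cv$left$value >= 0 & cv$left$value <= 1))
    expect_equal(cv$value_at_s, 1)
  }
})

test_that("raising the cutoff never increases the integral", {
  for (seed in 56:65) {
    h <- random_hapset(seed)
    s <- ceiling(n_markers(h) / 2)
    a <- h$alleles[s, 1]
    if (sum(h$alleles[s, ] == a, na.rm = TRUE) < 2) next
    cv <- ehh_allele(h, s, a, "phased")
    vals <- vapply(c(0, 0.05, 0.2, 0.5), function(ct)
      integrate_curve(cv, scan_config("phased", ehh_cutoff = ct,
                                      min_support_stop = 0))$value,
      numeric(1))
    expect_true(all(diff(vals) <= 1e-9))
  }
})

test_that("unphased estimator equals phased within-individual comparison on
          fully homozygous individuals", {
  set.seed(99)
  base <- matrix(sample(0:1, 10 * 4, replace = TRUE), 10, 4)
  A <- base[, rep(1:4, each = 2)]  # each individual = duplicated sequence
  h <- haploset(A, positions = sort(sample(1:500, 10)))
  s <- 5
  a <- A[s, 1]
  if (sum(A[s, ] == a) >= 2) {
    cu <- ehh_allele(h, s, a, "unphased")
    # phased comparison restricted to within-individual pairs is identically 1
    # for duplicated sequences; so is the unphased curve
    expect_true(all(c(cu$left$value, cu$right$value) == 1))
  }
})

test_that("a gap larger than max_gap_bp truncates integration at the last
          marker", {
  A <- matrix(0L, 4, 4)
  h <- haploset(A, positions = c(0, 10, 20, 100020))
  i <- integrate_curve(ehh_allele(h, 2, 0, "phased"),
                       scan_config("phased", ehh_cutoff = 0,
                                   min_support_stop = 0,
                                   max_gap_bp = 1000,
                                   curve_mode = "stepwise"))
  expect_equal(i$right$stop_reason, "gap")
  expect_true(i$truncated)
  expect_equal(i$right$area, 10)  # [10, 20] only
})
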