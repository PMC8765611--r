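test_that("simulation is reproducible and chromosomes are independent", {
  p <- sim_params(N = 100, L = 1e5, n = 20, seed = 5,
                  mu = 100 / (4 * 100 * 1e5), r = 100 / (4 * 100 * 1e5))
  g1 <- simulate_neutral(p, 3)
  g2 <- simulate_neutral(p, 3)
  expect_identical(g1$haps[[2]]$alleles, g2$haps[[2]]$alleles)
  expect_false(identical(g1$haps[[1]]$alleles, g1$haps[[2]]$alleles))
  # outputs satisfy the container invariants
  for (h in g1$haps) {
    expect_true(all(diff(h$positions) > 0))
    expect_true(all(h$alleles %in% c(0L, 1L)))
    expect_true(h$phased)
    expect_true(all(!is.na(h$ancestral)))
  }
})

test_that("too-sparse parameter settings trigger a warning", {
  p <- sim_params(N = 50, L = 1e4, n = 4, seed = 1, mu = 1e-9, r = 1e-9)
  expect_warning(simulate_neutral(p, 1), "segregating sites")
})

test_that("without recombination every chromosome shares one genealogy", {
  # r = 0: the matrix must be compatible with a single tree, i.e. any two
  # derived-carrier sets are nested or disjoint (infinite sites, one tree)
  p <- sim_params(N = 100, L = 1e4, n = 12, seed = 8,
                  mu = 60 / (4 * 100 * 1e4), r = 0)
  g <- simulate_neutral(p, 2)
  for (h in g$haps) {
    sets <- apply(h$alleles == 1, 1, which, simplify = FALSE)
    violations <- 0L
    for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
      ov <- length(intersect(sets[[i]], sets[[j]]))
      if (!(ov == 0 || ov == length(sets[[i]]) || ov == length(sets[[j]])))
        violations <- violations + 1L
    }
    expect_equal(violations, 0L)
  }
})

test_that("segregating sites follow Watterson's expectation (small design)", {
  p <- sim_params(N = 100, L = 1e5, n = 20, seed = 21,
                  mu = 100 / (4 * 100 * 1e5), r = 100 / (4 * 100 * 1e5))
  g <- simulate_neutral(p, 60)
  S <- vapply(g$haps, n_markers, integer(1))
  expS <- 100 * sum(1 / seq_len(19))
  z <- (mean(S) - expS) / (sd(S) / sqrt(length(S)))
  expect_lt(abs(z), 3)
})

test_that("sweep trajectories respect the frequency condition and truth", {
  p <- sim_params(N = 100, L = 1e5, n = 40, seed = 33,
                  mu = 200 / (4 * 100 * 1e5), r = 200 / (4 * 100 * 1e5),
                  selection = list(target_freq = 0.6, position = 5e4))
  g <- simulate_sweep(p, 4)
  expect_true(all(abs(g$truth$pop_freq - 0.6) <= 0.02 + 1e-12))
  expect_true(all(g$truth$status == "ongoing"))
  # the reported sample frequency matches the matrix at the selected site
  for (i in seq_along(g$haps)) {
    h <- g$haps[[i]]
    k <- which(h$positions == g$truth$pos[i])
    if (length(k) == 1) {
      expect_equal(mean(h$alleles[k, ]), g$truth$sample_freq[i])
    }
  }
  # neutral conditioned trajectory (2Ns = 0) still terminates
  p0 <- sim_params(N = 20, L = 2e4, n = 10, seed = 9,
                   mu = 20 / (4 * 20 * 2e4), r = 20 / (4 * 20 * 2e4),
                   selection = list(ns2 = 0, target_freq = 0.5, tol = 0.1))
  g0 <- simulate_sweep(p0, 1, max_attempts = 5000)
  expect_true(abs(g0$truth$pop_freq - 0.5) <= 0.1 + 1e-12)
})

test_that("sweeps at intermediate frequency elevate EHH near the target", {
  # the sweep haplotype (tens of kb at these rates) must be much shorter
  # than the chromosome, so use the 1 Mb desk scale with a reduced sample
  g <- cached("sweep_small_genome", {
    simulate_sweep(sim_params(n = 80, seed = 44,
                              selection = list(target_freq = 0.7)), 6)
  })
  ihs <- lapply(g$haps, unihs_scan, estimator = "phased",
                allele_mode = "polarized")
  tab <- standardize(bind_scores(ihs), std_spec("freq_binned"))
  near <- abs(tab$pos - 5e5) < 50000
  expect_gt(mean(abs(tab$score_std[near]), na.rm = TRUE),
            mean(abs(tab$score_std[!near]), na.rm = TRUE))
})

test_that("the two-population split yields exchangeable populations", {
  sp <- cached("split_small", {
    simulate_split(sim_params(N = 100, L = 2e5, n = 60,
                              mu = 300 / (4 * 100 * 2e5),
                              r = 300 / (4 * 100 * 2e5), seed = 77), 1)
  })
  h1 <- sp$pop1$haps[[1]]
  h2 <- sp$pop2$haps[[1]]
  expect_true(all(diff(h1$positions) > 0))
  expect_equal(n_seq(h1), 60L)
  expect_equal(n_seq(h2), 60L)
  # shared ancestral polymorphism: many positions appear in both samples
  expect_gt(length(intersect(h1$positions, h2$positions)), 100)
})
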