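test_that("constructor enforces the container invariants", {
  expect_error(haploset(matrix(0L, 2, 2), c(10, 5)), "strictly increasing")
  expect_error(haploset(matrix(c(0L, -1L), 1, 2), 1), ">= 0")
  expect_error(haploset(matrix(0L, 2, 2), c(10, 20, 30)), "one position")
  h <- haploset(matrix(c(0L, 1L, NA, 1L), 2, 2), c(5, 9))
  expect_s3_class(h, "haploset")
  expect_equal(n_markers(h), 2L)
  expect_equal(n_seq(h), 2L)
  expect_equal(h$extent, c(5, 9))
})

test_that("an ancestral code absent from a marker does not polarize it", {
  A <- rbind(c(0L, 1L), c(0L, 0L))
  h <- haploset(A, c(1, 2), ancestral = c(0L, 1L))  # marker 2 has no allele 1
  expect_equal(is.na(h$ancestral), c(FALSE, TRUE))
})

test_that("focal statistics match hand counts on the toy configuration", {
  t4 <- hap_example("toy4")
  fs <- focal_stats(t4, 3)
  expect_equal(unname(fs$counts), c(3L, 1L))
  expect_equal(fs$n_s, 4L)
  expect_equal(fs$maf, 0.25)
  expect_equal(fs$I_ss, 1L)                    # only individual 1 homozygous
  expect_equal(unname(fs$I_ss_a), c(1L, 0L))
  expect_equal(fs$p_derived, 0.25)             # ancestral is 0
  # invariants: counts sum to n_s, homozygote count consistency
  expect_equal(sum(fs$counts), fs$n_s)
  expect_equal(fs$I_ss, sum(fs$I_ss_a))
  expect_true(all(2 * fs$I_ss_a <= fs$counts))
})

test_that("polarize matches labels, skips absent alleles, reports coverage", {
  A <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 0L))
  h <- haploset(A, c(10, 20, 30), ancestral = NULL,
                allele_labels = list(c("A", "G"), c("C", "T"), c("A")))
  h2 <- polarize(h, data.frame(position = c(10, 20),
                               allele = c("A", "G")))  # G absent at 20
  expect_equal(h2$ancestral, c(0L, NA_integer_, NA_integer_))
  expect_equal(attr(h2, "coverage"), 1 / 3)
  h3 <- polarize(h, data.frame(position = numeric(0), allele = character(0)))
  expect_equal(attr(h3, "coverage"), 0)
  # depolarize(polarize(.)) leaves the allele matrix untouched
  expect_identical(depolarize(h2)$alleles, h$alleles)
  expect_true(all(is.na(depolarize(h2)$ancestral)))
})

test_that("unphase preserves genotypes and is reproducible", {
  # a fully homozygous individual is invariant
  A <- rbind(c(1L, 1L), c(0L, 0L))
  h <- haploset(A, c(1, 2))
  hu <- unphase(h, seed = 1)
  expect_identical(hu$alleles, h$alleles)
  expect_false(hu$phased)

  # genotype (unordered pair) preserved at every marker, for every individual
  h <- random_hapset(101, n_seq = 8, n_markers = 30, miss_prob = 0.05)
  hu <- unphase(h, seed = 7)
  for (id in unique(h$ind)) {
    cols <- which(h$ind == id)
    g0 <- apply(h$alleles[, cols], 1, function(x) paste(sort(x, na.last = TRUE),
                                                        collapse = "/"))
    g1 <- apply(hu$alleles[, cols], 1, function(x) paste(sort(x, na.last = TRUE),
                                                         collapse = "/"))
    expect_identical(g0, g1)
  }
  # per-marker allele counts unchanged
  expect_equal(rowSums(hu$alleles == 1, na.rm = TRUE),
               rowSums(h$alleles == 1, na.rm = TRUE))
  # fixed seed reproducible
  expect_identical(unphase(h, seed = 7)$alleles, hu$alleles)

  # odd sequence counts are rejected
  h3 <- haploset(matrix(0L, 2, 3), c(1, 2), ind = c(1L, 1L, 2L))
  expect_error(unphase(h3, 1), "exactly 2 sequences")
})
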