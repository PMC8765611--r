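# Shared fixtures and small utilities for the test suite.

# configuration for "plain average shared length" computations: stepwise
# curve, no cutoff, no support stop
cfg_mean_length <- function(estimator) {
  scan_config(estimator, ehh_cutoff = 0, min_support_stop = 0,
              curve_mode = "stepwise")
}

# random small haploset; optionally with missing data and a third allele
random_hapset <- function(seed, n_seq = NULL, n_markers = NULL,
                          miss_prob = 0, tri_prob = 0) {
  set.seed(seed)
  if (is.null(n_seq)) n_seq <- 2 * sample(2:6, 1)        # <= 12, even
  if (is.null(n_markers)) n_markers <- sample(5:40, 1)   # <= 40
  pos <- sort(sample(1:(50 * n_markers), n_markers))
  A <- matrix(sample(0:1, n_markers * n_seq, replace = TRUE),
              n_markers, n_seq)
  if (tri_prob > 0) {
    k <- runif(n_markers * n_seq) < tri_prob
    A[k] <- 2L
  }
  if (miss_prob > 0) {
    k <- runif(n_markers * n_seq) < miss_prob
    A[k] <- NA_integer_
  }
  haploset(A, positions = pos, ancestral = rep(0L, n_markers))
}

# a synthetic standardized score table (for the region caller)
make_score_table <- function(pos, std, chrom = "chr1",
                             extent = NULL) {
  if (is.null(extent))
    extent <- if (length(pos)) c(min(pos), max(pos)) else c(0, 1)
  ext <- stats::setNames(list(extent), chrom)
  structure(data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                       score_std = std),
            extent = ext, class = c("score_table", "data.frame"))
}

# memoized simulated genomes shared between expensive tests
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}
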