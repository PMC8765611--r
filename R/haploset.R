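#' Haplotype set: a marker-by-sequence allele matrix with metadata
#'
#' The central data container of the package: integer allele codes for every
#' (marker, sequence) pair on one chromosome, together with physical marker
#' positions, the phase flag, per-marker polarization (which allele code is
#' ancestral, when known), textual allele labels, and the grouping of
#' sequences into diploid individuals.
#'
#' @param alleles integer matrix, markers in rows and sequences in columns;
#'   `NA` marks missing alleles; codes must be non-negative.
#' @param positions numeric vector of physical positions in bp, strictly
#'   increasing, one per marker.
#' @param chrom chromosome label.
#' @param phased logical; `TRUE` if the allele-to-chromosome assignment of
#'   heterozygous genotypes is known.
#' @param ancestral integer vector of ancestral allele codes per marker
#'   (`NA` where the ancestral state is unknown); a marker is polarized iff
#'   its entry is not `NA` and the code is present among its alleles.
#' @param allele_labels list of character vectors, one per marker; element
#'   `code + 1` is the textual label of that allele code (defaults to the
#'   codes themselves).
#' @param ind integer vector assigning each sequence to a diploid individual;
#'   defaults to consecutive pairs. Every individual must own exactly two
#'   sequences when any individual-based (unphased) operation is used.
#' @param extent numeric length-2 vector, the chromosome extent in bp used as
#'   the integration boundary; defaults to the marker range.
#'
#' @return An object of class `haploset`.
#' @examples
#' h <- haploset(matrix(c(0L, 0L, 0L, 1L), 2, 2), positions = c(100, 200))
#' h
#' @export
haploset <- function(alleles, positions, chrom = "chr1", phased = TRUE,
                     ancestral = NULL, allele_labels = NULL, ind = NULL,
                     extent = NULL) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  M <- nrow(alleles)
  n <- ncol(alleles)
  positions <- as.numeric(positions)
  if (length(positions) != M)
    stop("need one position per marker (", M, " markers, ",
         length(positions), " positions)")
  if (M > 1 && any(diff(positions) <= 0))
    stop("marker positions must be strictly increasing")
  if (any(alleles < 0, na.rm = TRUE))
    stop("allele codes must be >= 0 (use NA for missing)")
  if (is.null(ancestral)) ancestral <- rep(NA_integer_, M)
  ancestral <- as.integer(ancestral)
  if (length(ancestral) != M) stop("'ancestral' must have one entry per marker")
  if (is.null(ind)) {
    if (n %% 2 == 0) ind <- rep(seq_len(n %/% 2), each = 2)
    else ind <- seq_len(n)  # no diploid grouping possible
  }
  ind <- as.integer(ind)
  if (length(ind) != n) stop("'ind' must have one entry per sequence")
  if (is.null(allele_labels)) {
    allele_labels <- lapply(seq_len(M), function(s) {
      mx <- suppressWarnings(max(alleles[s, ], na.rm = TRUE))
      if (!is.finite(mx)) mx <- 0L
      as.character(0:mx)
    })
  }
  if (is.null(extent)) extent <- range(positions)
  extent <- as.numeric(extent)
  # ancestral code must actually occur at the marker to count as polarized
  for (s in which(!is.na(ancestral))) {
    if (!ancestral[s] %in% alleles[s, ]) ancestral[s] <- NA_integer_
  }
  structure(
    list(chrom = as.character(chrom)[1], positions = positions,
         alleles = alleles, phased = isTRUE(phased), ancestral = ancestral,
         allele_labels = allele_labels, ind = ind, extent = extent),
    class = "haploset")
}

#' @export
print.haploset <- function(x, ...) {
  cat("haploset:", x$chrom, "-", n_markers(x), "markers x", n_seq(x),
      "sequences (", length(unique(x$ind)), "individuals )\n")
  cat("  positions:", format(x$positions[1], big.mark = ","), "-",
      format(x$positions[n_markers(x)], big.mark = ","), "bp; extent [",
      format(x$extent[1], big.mark = ","), ",",
      format(x$extent[2], big.mark = ","), "]\n")
  cat("  phased:", x$phased, "; polarized markers:",
      sum(!is.na(x$ancestral)), "/", n_markers(x), "\n")
  invisible(x)
}

#' @export
summary.haploset <- function(object, ...) {
  print(object)
  miss <- mean(is.na(object$alleles))
  cat("  missing genotype fraction:", signif(miss, 3), "\n")
  invisible(object)
}

#' Number of markers / sequences in a haploset
#' @param h a [haploset].
#' @return integer count.
#' @export
n_markers <- function(h) nrow(h$alleles)

#' @rdname n_markers
#' @export
n_seq <- function(h) ncol(h$alleles)

# 0-based consecutive individual index for the C++ layer
.ind0 <- function(h) {
  f <- match(h$ind, unique(h$ind))
  list(idx = as.integer(f - 1L), n = length(unique(h$ind)))
}

.check_even_individuals <- function(h) {
  tab <- table(h$ind)
  if (any(tab != 2))
    stop("individual-based operations require exactly 2 sequences per ",
         "individual (offending: ", paste(names(tab)[tab != 2], collapse = ", "),
         ")")
  invisible(TRUE)
}

#' Per-marker focal statistics
#'
#' Allele counts, minor allele frequency, derived allele frequency (when the
#' marker is polarized) and homozygous-individual counts at one focal marker.
#'
#' @param h a [haploset].
#' @param s focal marker index (1-based).
#' @return A list with elements `marker`, `position`, `counts` (named by
#'   allele code), `n_s`, `maf`, `p_derived`, `I_ss` (homozygous individuals)
#'   and `I_ss_a` (homozygous individuals per allele).
#' @export
focal_stats <- function(h, s) {
  stopifnot(s >= 1, s <= n_markers(h))
  a <- h$alleles[s, ]
  counts <- table(factor(a, levels = sort(unique(a[!is.na(a)]))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  ns <- sum(counts)
  srt <- sort(counts, decreasing = TRUE)
  maf <- if (length(srt) >= 2) unname(srt[2]) / ns else 0
  p_derived <- NA_real_
  if (!is.na(h$ancestral[s]) && ns > 0) {
    anc <- as.character(h$ancestral[s])
    p_derived <- 1 - (if (anc %in% names(counts)) counts[[anc]] else 0) / ns
  }
  # homozygote counts
  I_ss_a <- integer(0)
  I_ss <- 0L
  tab <- table(h$ind)
  if (all(tab == 2)) {
    by_ind <- split(a, h$ind)
    hom <- vapply(by_ind, function(g) {
      !anyNA(g) && g[1] == g[2]
    }, logical(1))
    hom_allele <- vapply(by_ind, function(g) {
      if (!anyNA(g) && g[1] == g[2]) g[1] else NA_integer_
    }, integer(1))
    I_ss <- sum(hom)
    I_ss_a <- vapply(names(counts), function(cc)
      sum(hom_allele == as.integer(cc), na.rm = TRUE), integer(1))
  }
  list(marker = s, position = h$positions[s], counts = counts, n_s = ns,
       maf = maf, p_derived = unname(p_derived), I_ss = I_ss, I_ss_a = I_ss_a)
}

#' Assign ancestral alleles from an annotation table
#'
#' Flags markers as polarized where an ancestral allele label is supplied and
#' that label occurs among the marker's alleles. Markers whose stated
#' ancestral allele is absent stay unpolarized; partial coverage is the
#' expected case (outgroup alignments rarely cover every site).
#'
#' @param h a [haploset].
#' @param ancestral a data.frame with columns `position` and `allele`
#'   (textual allele label), or a named character vector
#'   (names = positions, values = labels).
#' @return The haploset with updated polarization; the fraction of markers
#'   polarized is attached as attribute `"coverage"`.
#' @export
polarize <- function(h, ancestral) {
  if (is.character(ancestral) && !is.null(names(ancestral))) {
    ancestral <- data.frame(position = as.numeric(names(ancestral)),
                            allele = unname(ancestral),
                            stringsAsFactors = FALSE)
  }
  anc <- rep(NA_integer_, n_markers(h))
  if (nrow(ancestral) > 0) {
    m <- match(h$positions, ancestral$position)
    for (s in which(!is.na(m))) {
      lab <- as.character(ancestral$allele[m[s]])
      code <- match(lab, h$allele_labels[[s]]) - 1L
      if (!is.na(code) && code %in% h$alleles[s, ]) anc[s] <- code
    }
  }
  h$ancestral <- anc
  attr(h, "coverage") <- mean(!is.na(anc))
  h
}

#' Drop all polarization flags
#' @param h a [haploset].
#' @return The haploset with every marker unpolarized; alleles unchanged.
#' @export
depolarize <- function(h) {
  h$ancestral <- rep(NA_integer_, n_markers(h))
  attr(h, "coverage") <- NULL
  h
}

#' Scramble phase within individuals
#'
#' Independently and uniformly permutes the two allele copies of every
#' individual at every marker and clears the phased flag. Genotypes (the
#' unordered allele pair of an individual at a marker) are invariant, so all
#' allele counts and genotype frequencies are preserved exactly.
#'
#' @param h a [haploset]; every individual must own exactly two sequences.
#' @param seed optional integer seed for reproducibility.
#' @return The unphased haploset.
#' @export
unphase <- function(h, seed = NULL) {
  .check_even_individuals(h)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  M <- n_markers(h)
  for (id in unique(h$ind)) {
    cols <- which(h$ind == id)
    swap <- stats::runif(M) < 0.5
    if (any(swap)) {
      tmp <- h$alleles[swap, cols[1]]
      h$alleles[swap, cols[1]] <- h$alleles[swap, cols[2]]
      h$alleles[swap, cols[2]] <- tmp
    }
  }
  h$phased <- FALSE
  h
}

#' Built-in worked examples
#'
#' `hap_example("two_diploids")` returns a small phased haploset of four
#' sequences from two diploid individuals with nine markers around a focal
#' marker at position 40 bp at which all four sequences carry the same
#' allele.  Its pairwise shared-haplotype lengths are 30 and 40 bp within the
#' two individuals and 30, 40, 30, 40, 20, 20 bp over all six sequence pairs,
#' so the unphased (within-individual) mean shared length is 35 bp and the
#' phased (all pairs) mean is 30 bp -- a compact illustration of how much the
#' two estimators can differ.  `hap_example("toy4")` is an even smaller
#' five-marker configuration used throughout the unit tests.
#'
#' @param which example name: `"two_diploids"` or `"toy4"`.
#' @return A [haploset].
#' @examples
#' h <- hap_example("two_diploids")
#' # mean within-individual shared length (35 bp): stepwise curve, no cutoff,
#' # no support stop
#' ihh(h, s = 5, allele = 0, estimator = "unphased",
#'     config = scan_config("unphased", ehh_cutoff = 0, min_support_stop = 0,
#'                          curve_mode = "stepwise"))
#' @export
hap_example <- function(which = c("two_diploids", "toy4")) {
  which <- match.arg(which)
  if (which == "two_diploids") {
    # rows = markers at 0,10,...,80; columns = H1, H2 (individual 1),
    # H3, H4 (individual 2); focal marker at position 40 (index 5)
    A <- rbind(
      c(0L, 0L, 0L, 0L),
      c(0L, 0L, 0L, 1L),
      c(0L, 0L, 1L, 0L),
      c(0L, 1L, 0L, 0L),
      c(0L, 0L, 0L, 0L),
      c(0L, 0L, 1L, 1L),
      c(0L, 1L, 0L, 1L),
      c(0L, 0L, 0L, 0L),
      c(0L, 0L, 0L, 0L))
    haploset(A, positions = seq(0, 80, by = 10), chrom = "toy",
             phased = TRUE, ancestral = rep(0L, 9))
  } else {
    A <- rbind(
      c(0L, 0L, 0L, 1L),
      c(0L, 0L, 1L, 1L),
      c(0L, 0L, 0L, 1L),
      c(0L, 0L, 0L, 1L),
      c(0L, 0L, 1L, 1L))
    haploset(A, positions = seq(0, 40, by = 10), chrom = "toy4",
             phased = TRUE, ancestral = rep(0L, 5))
  }
}
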