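#' Scan configuration
#'
#' Bundles the tunable parameters of EHH/EHHS computation and integration.
#' Defaults depend on the estimator: the unphased (homozygote-based)
#' estimator uses a raised integration cutoff of 0.10 (instead of 0.05),
#' requires at least 10 homozygous sequences (five individuals) per core
#' allele at the focal marker, and stops integration when fewer than four
#' sequences (two individuals) remain homozygous. These restrictions damp
#' the statistical noise caused by the few extremely long shared haplotypes
#' that arise even under neutrality when only within-individual comparisons
#' are available.
#'
#' @param estimator `"phased"` or `"unphased"`.
#' @param ehh_cutoff EHH/EHHS value at which integration stops.
#' @param min_support_stop integration stops when fewer sequences than this
#'   still participate in a shared haplotype (counted in sequences; two
#'   individuals = 4 for the unphased estimator).
#' @param min_focal_support minimum homozygous sequences per core allele at
#'   the focal marker (unphased estimator only).
#' @param maf_min minor allele frequency below which markers are not scored
#'   (iHS only).
#' @param max_gap_bp stop integration at the last marker before any
#'   inter-marker gap larger than this (default: no gap rule).
#' @param curve_mode `"linear"` (trapezoid integration with interpolated
#'   cutoff crossing) or `"stepwise"` (hold the nearer-to-focal value; under
#'   cutoff 0 this makes the integral equal the mean pairwise shared length).
#' @param boundary_policy `"flag"` keeps markers whose integration hit a
#'   chromosome boundary (flagged, excluded from standardization);
#'   `"discard"` drops them from the score table.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(estimator = c("phased", "unphased"),
                        ehh_cutoff = NULL, min_support_stop = NULL,
                        min_focal_support = 10L, maf_min = 0.05,
                        max_gap_bp = Inf,
                        curve_mode = c("linear", "stepwise"),
                        boundary_policy = c("flag", "discard")) {
  estimator <- match.arg(estimator)
  if (is.null(ehh_cutoff))
    ehh_cutoff <- if (estimator == "phased") 0.05 else 0.10
  if (is.null(min_support_stop))
    min_support_stop <- if (estimator == "phased") 2L else 4L
  structure(list(estimator = estimator, ehh_cutoff = ehh_cutoff,
                 min_support_stop = as.integer(min_support_stop),
                 min_focal_support = as.integer(min_focal_support),
                 maf_min = maf_min, max_gap_bp = max_gap_bp,
                 curve_mode = match.arg(curve_mode),
                 boundary_policy = match.arg(boundary_policy)),
            class = "scan_config")
}

.stop_reason_label <- function(code) {
  c("cutoff-crossed", "support-exhausted", "chromosome-boundary",
    "gap")[code + 1L]
}

#' Partition sequences into identity classes over a marker interval
#'
#' Two or more sequences identical at every marker between `s` and `t`
#' (inclusive) constitute a shared haplotype. Sequences with missing data in
#' the interval form singleton classes.
#'
#' @param h a [haploset].
#' @param s,t marker indices (1-based) delimiting the closed interval.
#' @param restrict_allele optional allele code; only sequences carrying it at
#'   `s` are partitioned.
#' @return A list of integer vectors of sequence indices, the identity
#'   classes (sizes are the `n_k`, the length is `K_{s,t}`).
#' @export
shared_partition <- function(h, s, t, restrict_allele = NULL) {
  rng <- sort(c(s, t))
  sel <- seq_len(n_seq(h))
  if (!is.null(restrict_allele)) {
    sel <- which(!is.na(h$alleles[s, ]) & h$alleles[s, ] == restrict_allele)
  }
  block <- h$alleles[rng[1]:rng[2], sel, drop = FALSE]
  keys <- apply(block, 2, paste, collapse = ",")
  has_na <- apply(block, 2, anyNA)
  keys[has_na] <- paste0("singleton_", which(has_na))  # missing => singleton
  unname(split(sel, factor(keys, levels = unique(keys))))
}

.new_curve <- function(h, s, allele, estimator, kind, raw) {
  structure(list(
    chrom = h$chrom, focal = s, focal_pos = h$positions[s],
    allele = allele, estimator = estimator, kind = kind,
    value_at_s = raw$value_at_s, focal_support = raw$focal_support,
    left = data.frame(pos = raw$left_pos, value = raw$left_val,
                      support = raw$left_supp),
    right = data.frame(pos = raw$right_pos, value = raw$right_val,
                       support = raw$right_supp),
    extent = h$extent), class = "ehh_curve")
}

.full_curve_cpp <- function(h, s, allele, estimator) {
  ii <- .ind0(h)
  if (estimator == "unphased") .check_even_individuals(h)
  cpp_ehh_curve(h$alleles, h$positions, s - 1L,
                if (is.null(allele)) -1L else as.integer(allele),
                estimator == "unphased", ii$idx, ii$n,
                -1, 0L, Inf)
}

#' EHH decay curve for one core allele
#'
#' Extended haplotype homozygosity around focal marker `s` for sequences
#' carrying allele `a`, computed independently on each side.  The phased
#' estimator is the classical shared-haplotype pair fraction; the unphased
#' estimator is the fraction of individuals homozygous (for `a` at `s`) over
#' the whole interval, which needs no phase information.
#'
#' @param h a [haploset].
#' @param s focal marker index (1-based).
#' @param a core allele code.
#' @param estimator `"phased"` or `"unphased"`.
#' @return An object of class `ehh_curve` covering all markers to both
#'   chromosome ends (integration stopping is applied later by
#'   [integrate_curve()]).
#' @export
ehh_allele <- function(h, s, a, estimator = c("phased", "unphased")) {
  estimator <- match.arg(estimator)
  raw <- .full_curve_cpp(h, s, as.integer(a), estimator)
  if (estimator == "phased") {
    na <- sum(h$alleles[s, ] == a, na.rm = TRUE)
    if (na < 2)
      stop("undefined statistic: allele ", a, " carried by fewer than 2 ",
           "sequences at marker ", s, call. = FALSE)
  } else {
    if (raw$focal_support < 2)
      stop("undefined statistic: no individual homozygous for allele ", a,
           " at marker ", s, call. = FALSE)
  }
  .new_curve(h, s, as.integer(a), estimator, "ehh", raw)
}

#' Site-specific EHH (EHHS) decay curve
#'
#' Like [ehh_allele()] but pooled over all sequences regardless of core
#' allele. For the phased estimator the value at the focal marker equals the
#' focal marker's homozygosity (not 1); the unphased estimator is normalized
#' to 1 at the focal marker by construction.
#'
#' @inheritParams ehh_allele
#' @return An `ehh_curve` with `allele = NA` and `kind = "ehhs"`.
#' @export
ehhs <- function(h, s, estimator = c("phased", "unphased")) {
  estimator <- match.arg(estimator)
  raw <- .full_curve_cpp(h, s, NULL, estimator)
  if (estimator == "phased") {
    if (sum(!is.na(h$alleles[s, ])) < 2)
      stop("undefined statistic: fewer than 2 sequences at marker ", s,
           call. = FALSE)
  } else if (raw$focal_support < 2) {
    stop("undefined statistic: no homozygous individual at marker ", s,
         call. = FALSE)
  }
  .new_curve(h, s, NA_integer_, estimator, "ehhs", raw)
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat(toupper(x$kind), "curve (", x$estimator, ") at", x$chrom, "marker",
      x$focal, "( pos", x$focal_pos, ")",
      if (!is.na(x$allele)) paste("allele", x$allele) else "pooled", "\n")
  cat("  value at focal marker:", signif(x$value_at_s, 4),
      "; support:", x$focal_support, "sequences\n")
  cat("  markers left/right:", nrow(x$left) - 1L, "/", nrow(x$right) - 1L, "\n")
  invisible(x)
}

#' @export
as.data.frame.ehh_curve <- function(x, ...) {
  lf <- x$left[nrow(x$left):1, , drop = FALSE]
  rbind(data.frame(side = rep("left", nrow(lf) - 1L),
                   lf[-nrow(lf), , drop = FALSE]),
        data.frame(side = "focal", x$right[1, , drop = FALSE]),
        data.frame(side = rep("right", nrow(x$right) - 1L),
                   x$right[-1, , drop = FALSE]))
}

#' @export
plot.ehh_curve <- function(x, ...) {
  d <- as.data.frame(x)
  plot(d$pos, d$value, type = "l", xlab = "position (bp)",
       ylab = toupper(x$kind), ylim = c(0, 1), ...)
  graphics::abline(v = x$focal_pos, lty = 3)
  invisible(x)
}

#' Integrate an EHH/EHHS curve
#'
#' Numeric integration per side from the focal marker outward. Integration
#' stops where the (interpolated) curve crosses `ehh_cutoff`, when the
#' supporting count drops below `min_support_stop`, at any inter-marker gap
#' larger than `max_gap_bp`, or at the chromosome end (which sets the
#' truncated flag). The area above zero and below the cutoff up to the
#' crossing point is included; integration simply stops there.
#'
#' @param curve an [ehh_allele()] / [ehhs()] curve.
#' @param config a [scan_config()]; its `curve_mode` selects linear
#'   (trapezoid, interpolated crossing) or stepwise-constant integration.
#' @param extent chromosome extent (length-2 numeric); defaults to the extent
#'   recorded in the curve.
#' @return A list of class `ehh_integral` with elements `value` (bp), `kind`,
#'   `left`/`right` side components (area, stop reason, stop position) and
#'   `truncated`.
#' @export
integrate_curve <- function(curve, config = scan_config(curve$estimator),
                            extent = curve$extent) {
  linear <- config$curve_mode == "linear"
  il <- cpp_integrate_side(curve$left$pos, curve$left$value,
                           curve$left$support, config$ehh_cutoff,
                           config$min_support_stop, linear, config$max_gap_bp,
                           extent[1])
  ir <- cpp_integrate_side(curve$right$pos, curve$right$value,
                           curve$right$support, config$ehh_cutoff,
                           config$min_support_stop, linear, config$max_gap_bp,
                           extent[2])
  kind <- if (curve$kind == "ehh") "iHH" else "iES"
  structure(list(
    value = il$area + ir$area, kind = kind,
    left = list(area = il$area, stop_reason = .stop_reason_label(il$reason),
                stop_pos = il$stop_pos),
    right = list(area = ir$area, stop_reason = .stop_reason_label(ir$reason),
                 stop_pos = ir$stop_pos),
    truncated = il$reason >= 2 || ir$reason >= 2,
    value_at_s = curve$value_at_s), class = "ehh_integral")
}

#' @export
print.ehh_integral <- function(x, ...) {
  cat(x$kind, "=", format(x$value, digits = 6), "bp",
      if (x$truncated) "(truncated at chromosome boundary)" else "", "\n")
  cat("  left:", format(x$left$area, digits = 6), "bp, stop:",
      x$left$stop_reason, "; right:", format(x$right$area, digits = 6),
      "bp, stop:", x$right$stop_reason, "\n")
  invisible(x)
}

#' Integrated EHH (iHH) for one core allele
#'
#' Convenience wrapper: [ehh_allele()] followed by [integrate_curve()].
#'
#' @inheritParams ehh_allele
#' @param allele core allele code.
#' @param config a [scan_config()].
#' @return An `ehh_integral` of kind `"iHH"`.
#' @export
ihh <- function(h, s, allele, estimator = c("phased", "unphased"),
                config = scan_config(estimator)) {
  estimator <- match.arg(estimator)
  integrate_curve(ehh_allele(h, s, allele, estimator), config)
}

#' Integrated EHHS (iES) and its normalized variant (inES)
#'
#' inES is iES divided by the focal marker's homozygosity (the EHHS value at
#' the focal marker). For the unphased estimator that value is 1 by
#' construction, so iES and inES coincide -- the reason the unphased versions
#' of the two cross-population statistics are essentially the same.
#'
#' @inheritParams ehh_allele
#' @param config a [scan_config()].
#' @return An `ehh_integral` of kind `"iES"` with an extra element `ines`.
#' @export
ines <- function(h, s, estimator = c("phased", "unphased"),
                 config = scan_config(estimator)) {
  estimator <- match.arg(estimator)
  r <- integrate_curve(ehhs(h, s, estimator), config)
  r$ines <- if (r$value_at_s > 0) r$value / r$value_at_s else NA_real_
  r
}

#' Pairwise shared-haplotype lengths (the integration oracle)
#'
#' For every unordered pair of phased sequences carrying core allele `a` at
#' marker `s`, scans outward to the first differing (or missing) marker on
#' each side; the shared length is the distance between the two boundary
#' positions (chromosome ends where no difference occurs). The mean of these
#' lengths equals the stepwise-integrated iHH with cutoff 0 -- the classical
#' equivalence used as an independent cross-check of the curve/integration
#' machinery. Implemented in plain R, independent of the scan code path.
#'
#' @inheritParams ehh_allele
#' @param a core allele code.
#' @return A data.frame of class `pairwise_shared` with columns `i`, `j`,
#'   `left`, `right`, `length`; the mean length is attached as attribute
#'   `"mean_length"`.
#' @export
pairwise_shared_lengths <- function(h, s, a = NULL) {
  carriers <- if (is.null(a)) which(!is.na(h$alleles[s, ]))
  else which(!is.na(h$alleles[s, ]) & h$alleles[s, ] == a)
  if (length(carriers) < 2)
    stop("undefined statistic: fewer than 2 carriers", call. = FALSE)
  M <- n_markers(h)
  pairs <- utils::combn(carriers, 2)
  res <- data.frame(i = pairs[1, ], j = pairs[2, ], left = NA_real_,
                    right = NA_real_, length = NA_real_)
  same_at <- function(i, j, t) {
    ai <- h$alleles[t, i]; aj <- h$alleles[t, j]
    !is.na(ai) && !is.na(aj) && ai == aj
  }
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (!same_at(i, j, s)) {  # differ at the focal marker itself
      res$left[p] <- res$right[p] <- h$positions[s]
      res$length[p] <- 0
      next
    }
    left <- h$extent[1]
    for (t in rev(seq_len(s - 1))) {
      if (!same_at(i, j, t)) { left <- h$positions[t]; break }
    }
    right <- h$extent[2]
    if (s < M) for (t in (s + 1):M) {
      if (!same_at(i, j, t)) { right <- h$positions[t]; break }
    }
    res$left[p] <- left; res$right[p] <- right
    res$length[p] <- right - left
  }
  structure(res, mean_length = mean(res$length), class = c("pairwise_shared",
                                                           "data.frame"))
}
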