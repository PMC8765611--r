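# FDR and statistical power of a scan against simulation truth.
#
# A called region is a true positive when its half-open interval contains a
# truly selected site; the FDR is the fraction of regions that do not.
# Power is per site: the fraction of true sites covered by at least one
# region. A region containing two sites counts once for the FDR; each
# covered site counts once for power.

#' False discovery rate of called regions
#'
#' @param regions a [call_regions()] result (columns `chrom`, `start`, `end`).
#' @param truth a data.frame of truly selected sites with columns `chrom` and
#'   `pos`.
#' @param genome_length optional total genome length in bp, used to report
#'   the fraction of the genome covered by the called regions.
#' @return A list of class `scan_eval` with `n_regions`, `n_true_positive`,
#'   `fdr`, `power`, `covered_length` and (if `genome_length` is given)
#'   `genome_fraction`.
#' @export
scan_fdr <- function(regions, truth, genome_length = NULL) {
  if (nrow(regions) == 0)
    stop(structure(class = c("ehhscan_undefined_fdr", "error", "condition"),
                   list(message = "no regions called: FDR undefined",
                        call = sys.call())))
  tp <- logical(nrow(regions))
  covered <- logical(nrow(truth))
  for (r in seq_len(nrow(regions))) {
    inside <- truth$chrom == regions$chrom[r] &
      truth$pos >= regions$start[r] & truth$pos < regions$end[r]
    tp[r] <- any(inside)
    covered <- covered | inside
  }
  res <- list(n_regions = nrow(regions), n_true_positive = sum(tp),
              fdr = 1 - sum(tp) / nrow(regions),
              n_sites = nrow(truth), n_sites_covered = sum(covered),
              power = mean(covered),
              covered_length = sum(regions$end - regions$start),
              threshold = attr(regions, "threshold"))
  if (!is.null(genome_length))
    res$genome_fraction <- res$covered_length / genome_length
  structure(res, class = "scan_eval")
}

#' Per-site detection power
#'
#' @inheritParams scan_fdr
#' @return A `scan_eval` list; `power` is the fraction of true sites inside
#'   at least one called region.
#' @export
scan_power <- function(regions, truth, genome_length = NULL) {
  if (nrow(regions) == 0) {
    return(structure(list(n_regions = 0L, n_true_positive = 0L, fdr = NA_real_,
                          n_sites = nrow(truth), n_sites_covered = 0L,
                          power = 0, covered_length = 0,
                          threshold = NA_real_), class = "scan_eval"))
  }
  scan_fdr(regions, truth, genome_length)
}

#' @export
print.scan_eval <- function(x, ...) {
  cat("scan evaluation:", x$n_regions, "regions,", x$n_true_positive,
      "true positives\n")
  cat("  FDR =", signif(x$fdr, 4), "; power =", signif(x$power, 4),
      "(", x$n_sites_covered, "/", x$n_sites, "sites )\n")
  if (!is.null(x$genome_fraction))
    cat("  called regions cover", signif(100 * x$genome_fraction, 3),
        "% of the genome\n")
  invisible(x)
}

#' Calibrate a score threshold on a neutral genome
#'
#' Finds the extremeness threshold at which the regions called on a neutrally
#' evolving genome cover a requested fraction of it (the classical "1% of the
#' neutral genome falsely designated as selected" convention used to compare
#' statistical power across statistics and sample sizes).
#'
#' @param wt a [window_scan()] table computed on the neutral genome.
#' @param genome_fraction target fraction of the genome covered by called
#'   regions.
#' @param rel_tol accepted relative deviation from `genome_fraction` (region
#'   merging makes exact coverage unattainable).
#' @inheritParams call_regions
#' @return The calibrated threshold, with the achieved coverage fraction as
#'   attribute `"coverage"`.
#' @export
calibrate_power_threshold <- function(wt, genome_fraction = 0.01,
                                      rel_tol = 0.10, min_fraction = 0.5,
                                      min_markers = 150) {
  ext <- attr(wt, "extent")
  genome_length <- sum(vapply(ext, function(e) e[2] - e[1], numeric(1)))
  thrs <- .threshold_grid(wt)
  if (length(thrs) == 0) stop("no scored markers to calibrate on")
  cov <- .region_counts(wt, thrs, min_fraction, min_markers)$coverage /
    genome_length
  dev <- abs(cov - genome_fraction) / genome_fraction
  pick <- max(which(dev == min(dev)))
  if (dev[pick] > rel_tol + 1e-9)
    stop("coverage of ", genome_fraction, " not attainable within ",
         100 * rel_tol, "% (attainable range ",
         signif(min(cov), 3), " - ", signif(max(cov), 3), ")", call. = FALSE)
  structure(thrs[pick], coverage = cov[pick])
}
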