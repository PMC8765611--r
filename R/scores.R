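# Score tables: per-marker statistics built on the EHH integrals.
#
# A score_table is a data.frame with one row per marker of the input
# haploset(s), quality-flag columns, the unstandardized score in `score_un`
# and the standardized score in `score_std` (NA until standardize() is
# applied, and NA for any flagged marker). Flagged markers stay in the table
# so that window marker counts can distinguish "no marker" from "marker
# without score".

.flag_cols <- c("below_maf", "insufficient", "multiallelic", "undefined",
                "unpolarized", "truncated", "zero_scale")

.decode_flags <- function(flag) {
  data.frame(below_maf = bitwAnd(flag, 1L) > 0L,
             insufficient = bitwAnd(flag, 2L) > 0L,
             multiallelic = bitwAnd(flag, 4L) > 0L,
             undefined = bitwAnd(flag, 8L) > 0L,
             unpolarized = FALSE,
             truncated = bitwAnd(flag, 16L) > 0L,
             zero_scale = FALSE)
}

.disqualified <- function(tab) {
  Reduce(`|`, lapply(.flag_cols, function(cc) tab[[cc]]))
}

.new_score_table <- function(df, statistic, estimator, extent) {
  structure(df, statistic = statistic, estimator = estimator,
            extent = extent, class = c("score_table", "data.frame"))
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table:", attr(x, "statistic"), "(", attr(x, "estimator"),
      "estimator ),", nrow(x), "markers,",
      sum(!is.na(x$score_std)), "standardized scores\n")
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Combine per-chromosome score tables
#'
#' Genome scans are computed per chromosome; standardization and region
#' calling are genome-wide. This binds tables row-wise and merges their
#' chromosome-extent metadata.
#'
#' @param tabs list of score tables from the same statistic/estimator.
#' @return A single score table.
#' @export
bind_scores <- function(tabs) {
  stopifnot(length(tabs) >= 1)
  ext <- do.call(c, unname(lapply(tabs, attr, "extent")))
  ext <- ext[!duplicated(names(ext))]
  .new_score_table(do.call(rbind, lapply(tabs, as.data.frame)),
                   statistic = attr(tabs[[1]], "statistic"),
                   estimator = attr(tabs[[1]], "estimator"), extent = ext)
}

#' Genome scan of unstandardized iHS (uniHS)
#'
#' Computes per-allele integrated EHH (iHH) at every biallelic marker passing
#' the MAF filter and forms the log-ratio uniHS.  In `"polarized"` mode the
#' ratio is ancestral over derived; in `"major_minor"` mode it is the most
#' frequent over the second most frequent allele (ties broken towards the
#' lower allele code), which requires no ancestry information.
#'
#' @param h a [haploset].
#' @param estimator `"phased"` or `"unphased"`; the unphased estimator
#'   additionally requires `min_focal_support` homozygous sequences per core
#'   allele at the focal marker.
#' @param allele_mode `"polarized"` or `"major_minor"`.
#' @param config a [scan_config()].
#' @param on_unpolarized in polarized mode, what to do with scoreable markers
#'   lacking a valid ancestral assignment: `"error"` (default) or `"skip"`
#'   (flag and leave unscored).
#' @return A score table with columns including `ihh_num`, `ihh_den` (bp),
#'   `score_un` (uniHS) and quality flags. Apply [standardize()] to obtain
#'   iHS.
#' @export
unihs_scan <- function(h, estimator = c("phased", "unphased"),
                       allele_mode = c("polarized", "major_minor"),
                       config = scan_config(estimator),
                       on_unpolarized = c("error", "skip")) {
  estimator <- match.arg(estimator)
  allele_mode <- match.arg(allele_mode)
  on_unpolarized <- match.arg(on_unpolarized)
  if (estimator == "unphased") .check_even_individuals(h)
  ii <- .ind0(h)
  raw <- cpp_scan(h$alleles, h$positions, ii$idx, ii$n,
                  estimator == "unphased", 0L, config$ehh_cutoff,
                  config$min_support_stop, config$min_focal_support,
                  config$maf_min, config$curve_mode == "linear",
                  config$max_gap_bp, h$extent[1], h$extent[2])
  fl <- .decode_flags(raw$flag)
  M <- n_markers(h)
  p_derived <- rep(NA_real_, M)
  ihh_num <- ihh_den <- rep(NA_real_, M)
  code_num <- code_den <- rep(NA_integer_, M)
  scoreable <- !(fl$below_maf | fl$insufficient | fl$multiallelic |
                   fl$undefined)

  if (allele_mode == "polarized") {
    anc <- h$ancestral
    valid <- !is.na(anc) & (anc == raw$code1 | anc == raw$code2)
    offenders <- which(scoreable & !valid)
    if (length(offenders) > 0) {
      if (on_unpolarized == "error")
        stop("polarized scoring requested but ", length(offenders),
             " scoreable marker(s) lack a valid ancestral allele ",
             "(positions ",
             paste(utils::head(h$positions[offenders], 10), collapse = ", "),
             if (length(offenders) > 10) ", ..." else "", ")", call. = FALSE)
      fl$unpolarized[offenders] <- TRUE
    }
    use <- scoreable & valid
    anc_is_1 <- use & anc == raw$code1
    ihh_num[anc_is_1] <- raw$ihh1[anc_is_1]
    ihh_den[anc_is_1] <- raw$ihh2[anc_is_1]
    code_num[anc_is_1] <- raw$code1[anc_is_1]
    code_den[anc_is_1] <- raw$code2[anc_is_1]
    anc_is_2 <- use & anc == raw$code2
    ihh_num[anc_is_2] <- raw$ihh2[anc_is_2]
    ihh_den[anc_is_2] <- raw$ihh1[anc_is_2]
    code_num[anc_is_2] <- raw$code2[anc_is_2]
    code_den[anc_is_2] <- raw$code1[anc_is_2]
    # derived allele frequency
    cnt_der <- ifelse(anc_is_1, raw$cnt2, ifelse(anc_is_2, raw$cnt1, NA))
    p_derived[use] <- (cnt_der / raw$n_s)[use]
  } else {
    ihh_num[scoreable] <- raw$ihh1[scoreable]  # major
    ihh_den[scoreable] <- raw$ihh2[scoreable]  # minor
    code_num[scoreable] <- raw$code1[scoreable]
    code_den[scoreable] <- raw$code2[scoreable]
  }
  score_un <- log(ihh_num / ihh_den)
  score_un[!is.finite(score_un)] <- NA_real_

  df <- cbind(
    data.frame(chrom = h$chrom, pos = h$positions, n_s = raw$n_s,
               maf = raw$maf, p_derived = p_derived,
               allele_num = code_num, allele_den = code_den,
               ihh_num = ihh_num, ihh_den = ihh_den,
               score_un = score_un, score_std = NA_real_), fl)
  if (config$boundary_policy == "discard") df <- df[!df$truncated, ]
  ext <- stats::setNames(list(h$extent), h$chrom)
  .new_score_table(df, statistic = paste0("ihs_", allele_mode),
                   estimator = estimator, extent = ext)
}

#' Genome scan of iES and inES
#'
#' Integrated site-specific EHH at every marker (monomorphic markers are
#' scored too: EHHS does not need two alleles, and no MAF filter applies).
#' This is the per-population half of XP-EHH and Rsb.
#'
#' @inheritParams unihs_scan
#' @return A score table with columns `ies`, `ines`, `ehhs_s` and flags.
#' @export
ies_scan <- function(h, estimator = c("phased", "unphased"),
                     config = scan_config(estimator)) {
  estimator <- match.arg(estimator)
  if (estimator == "unphased") .check_even_individuals(h)
  ii <- .ind0(h)
  raw <- cpp_scan(h$alleles, h$positions, ii$idx, ii$n,
                  estimator == "unphased", 1L, config$ehh_cutoff,
                  config$min_support_stop, config$min_focal_support,
                  0, config$curve_mode == "linear",
                  config$max_gap_bp, h$extent[1], h$extent[2])
  fl <- .decode_flags(raw$flag)
  df <- cbind(
    data.frame(chrom = h$chrom, pos = h$positions, n_s = raw$n_s,
               maf = raw$maf, ies = raw$ies, ines = raw$ines,
               ehhs_s = raw$ehhs_s), fl)
  if (config$boundary_policy == "discard") df <- df[!df$truncated, ]
  ext <- stats::setNames(list(h$extent), h$chrom)
  .new_score_table(df, statistic = "ies", estimator = estimator, extent = ext)
}

#' Standardization specification
#'
#' @param mode `"unbinned"` (one global group) or `"freq_binned"`
#'   (separate groups per derived-allele-frequency bin; requires polarized
#'   markers).
#' @param bin_width width of the frequency bins.
#' @param center `"mean"` or `"median"`.
#' @param min_bin_count bins with fewer scored markers are merged with their
#'   neighbors.
#' @param bin_edges optional explicit bin edges overriding `bin_width`.
#' @return A list of class `std_spec`.
#' @export
std_spec <- function(mode = c("unbinned", "freq_binned"), bin_width = 0.025,
                     center = c("mean", "median"), min_bin_count = 10L,
                     bin_edges = NULL) {
  structure(list(mode = match.arg(mode), bin_width = bin_width,
                 center = match.arg(center),
                 min_bin_count = as.integer(min_bin_count),
                 bin_edges = bin_edges), class = "std_spec")
}

# merge bins with too few members into their right neighbor (last bin
# backward); returns a group id per bin
.merge_bins <- function(counts, min_count) {
  nb <- length(counts)
  grp <- integer(nb)
  g <- 1L
  acc <- 0L
  for (b in seq_len(nb)) {
    grp[b] <- g
    acc <- acc + counts[b]
    if (acc >= min_count) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && g > 1L) grp[grp == g] <- g - 1L  # fold a small tail back
  grp
}

#' Standardize a score table
#'
#' Subtracts the center statistic and divides by the sample standard
#' deviation of the unstandardized scores, computed over non-flagged markers
#' only -- either globally or within derived-allele-frequency bins. The
#' standard deviation is always taken about the mean, even under median
#' centering (as the cross-population Rsb statistic prescribes).
#'
#' @param tab a score table with a `score_un` column.
#' @param spec a [std_spec()].
#' @return The score table with `score_std` filled in for unflagged markers.
#' @export
standardize <- function(tab, spec = std_spec()) {
  if (!"score_un" %in% names(tab)) stop("no unstandardized score to standardize")
  ok <- !is.na(tab$score_un) & !.disqualified(tab)
  if (sum(ok) < 2) stop("need at least 2 scored markers to standardize")
  grp <- rep(1L, nrow(tab))
  if (spec$mode == "freq_binned") {
    if (!"p_derived" %in% names(tab) || all(is.na(tab$p_derived[ok])))
      stop("freq_binned standardization requires polarized markers ",
           "(p_derived)")
    edges <- if (!is.null(spec$bin_edges)) spec$bin_edges
    else seq(0, 1, by = spec$bin_width)
    bin <- findInterval(tab$p_derived, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(bin[ok], nbins = length(edges) - 1L)
    bgrp <- .merge_bins(counts, spec$min_bin_count)
    grp <- bgrp[bin]
  }
  tab$score_std <- NA_real_
  tab$zero_scale <- FALSE
  groups <- rep(NA_integer_, nrow(tab))
  for (g in unique(grp[ok])) {
    sel <- ok & grp == g
    v <- tab$score_un[sel]
    ctr <- if (spec$center == "mean") mean(v) else stats::median(v)
    scl <- stats::sd(v)
    if (!is.finite(scl) || scl == 0) {
      tab$zero_scale[sel] <- TRUE
      next
    }
    tab$score_std[sel] <- (tab$score_un[sel] - ctr) / scl
    groups[sel] <- g
  }
  attr(tab, "std_spec") <- spec
  attr(tab, "std_groups") <- groups  # standardization group per marker
  tab
}

.join_pops <- function(tab1, tab2) {
  k1 <- paste(tab1$chrom, tab1$pos)
  k2 <- paste(tab2$chrom, tab2$pos)
  m <- match(k1, k2)
  keep <- which(!is.na(m))
  if (length(keep) == 0)
    stop("the two populations share no marker coordinates", call. = FALSE)
  list(i1 = keep, i2 = m[keep])
}

.xp_table <- function(tab1, tab2, column, statistic, spec) {
  if (attr(tab1, "estimator") != attr(tab2, "estimator"))
    stop("both populations must use the same estimator")
  j <- .join_pops(tab1, tab2)
  t1 <- as.data.frame(tab1)[j$i1, ]
  t2 <- as.data.frame(tab2)[j$i2, ]
  v1 <- t1[[column]]
  v2 <- t2[[column]]
  # as a difference of logs so that swapping populations flips the sign
  # bit-exactly
  score_un <- log(v1) - log(v2)
  undef <- t1$undefined | t2$undefined | !is.finite(score_un)
  score_un[!is.finite(score_un)] <- NA_real_
  df <- data.frame(
    chrom = t1$chrom, pos = t1$pos,
    n_s_pop1 = t1$n_s, n_s_pop2 = t2$n_s,
    int_pop1 = v1, int_pop2 = v2,
    score_un = score_un, score_std = NA_real_,
    below_maf = FALSE,
    insufficient = t1$insufficient | t2$insufficient,
    multiallelic = FALSE,
    undefined = undef,
    unpolarized = FALSE,
    truncated = t1$truncated | t2$truncated,
    zero_scale = FALSE)
  ext <- c(attr(tab1, "extent"), attr(tab2, "extent"))
  ext <- ext[!duplicated(names(ext))]
  out <- .new_score_table(df, statistic = statistic,
                          estimator = attr(tab1, "estimator"), extent = ext)
  standardize(out, spec)
}

#' Cross-population statistics XP-EHH and Rsb
#'
#' Log-ratios of the integrated site-specific EHH of two populations at
#' shared markers (inner join on chromosome and position): XP-EHH uses iES
#' and mean-centered standardization; Rsb uses inES and median-centered
#' standardization (both unbinned, with the standard deviation about the
#' mean). Positive scores indicate longer haplotype homozygosity in
#' population 1. With the unphased estimator iES = inES, so the two
#' statistics differ only through the centering constant.
#'
#' @param tab1,tab2 [ies_scan()] tables of the two populations.
#' @param spec a [std_spec()]; defaults to the statistic's convention.
#' @return A standardized score table.
#' @export
xpehh <- function(tab1, tab2, spec = std_spec(center = "mean")) {
  .xp_table(tab1, tab2, "ies", "xpehh", spec)
}

#' @rdname xpehh
#' @export
rsb <- function(tab1, tab2, spec = std_spec(center = "median")) {
  .xp_table(tab1, tab2, "ines", "rsb", spec)
}
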