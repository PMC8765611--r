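# Candidate-region delineation: overlapping sliding windows over a
# standardized score table, a cluster rule (at least half of the scored
# markers in a window beyond a threshold), merging of qualifying windows,
# and threshold calibration to a requested number of regions.

#' Sliding-window summary of a score table
#'
#' Tiles every chromosome extent with overlapping windows and records, per
#' window, the number of markers with attempted scores and the number
#' actually scored. Marker membership is by half-open interval
#' `[start, start + width)`.
#'
#' @param tab a standardized score table.
#' @param width window width in bp.
#' @param offset distance between consecutive window starts in bp.
#' @param extremeness how a standardized score is turned into an extremeness
#'   value: `"two_sided"` (absolute value), `"high"` (the score itself) or
#'   `"low"` (its negative).
#' @return A data.frame of class `window_table` with per-window marker
#'   counts; per-window score data are carried in attributes for use by
#'   [call_regions()] and [calibrate_regions()].
#' @export
window_scan <- function(tab, width = 250000, offset = 50000,
                        extremeness = c("two_sided", "high", "low")) {
  extremeness <- match.arg(extremeness)
  ext <- attr(tab, "extent")
  chroms <- unique(tab$chrom)
  if (is.null(ext)) {
    ext <- lapply(chroms, function(cc) range(tab$pos[tab$chrom == cc]))
    names(ext) <- chroms
  }
  e_all <- switch(extremeness, two_sided = abs(tab$score_std),
                  high = tab$score_std, low = -tab$score_std)
  rows <- list()
  marker_data <- list()
  for (cc in chroms) {
    sel <- which(tab$chrom == cc)
    pos <- tab$pos[sel]
    o <- order(pos)
    pos <- pos[o]
    e <- e_all[sel][o]
    scored <- !is.na(e)
    lo <- ext[[cc]][1]
    hi <- ext[[cc]][2]
    starts <- seq(lo, by = offset,
                  length.out = max(1L, ceiling((hi - lo) / offset)))
    # marker index ranges per window on the sorted positions
    i1 <- findInterval(starts, pos, left.open = TRUE) + 1L
    i2 <- findInterval(starts + width, pos, left.open = TRUE)
    nm <- pmax(0L, i2 - i1 + 1L)
    cum_scored <- c(0L, cumsum(scored))
    ns <- cum_scored[pmax(i2, 0L) + 1L] - cum_scored[pmin(i1, length(pos) + 1L)]
    ns[nm == 0] <- 0L
    rows[[cc]] <- data.frame(chrom = rep(cc, length(starts)), start = starts,
                             end = pmin(starts + width, hi), n_markers = nm,
                             n_scored = as.integer(ns))
    marker_data[[cc]] <- list(pos = pos, e = e,
                              pos_scored = pos[scored], e_scored = e[scored])
  }
  wt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_markers = integer(0), n_scored = integer(0))
  rownames(wt) <- NULL
  structure(wt, markers = marker_data, width = width, offset = offset,
            extremeness = extremeness, extent = ext,
            class = c("window_table", "data.frame"))
}

#' @export
print.window_table <- function(x, ...) {
  cat("window_table:", nrow(x), "windows of", attr(x, "width"), "bp (offset",
      attr(x, "offset"), ") over", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

# number of scored markers with extremeness >= thr, per window; membership
# is [start, start + width), matching the n_scored bookkeeping
.window_extreme_counts <- function(wt, thr) {
  md <- attr(wt, "markers")
  width <- attr(wt, "width")
  out <- integer(nrow(wt))
  for (cc in names(md)) {
    sel <- which(wt$chrom == cc)
    ps <- md[[cc]]$pos_scored
    es <- md[[cc]]$e_scored
    for (k in sel) {
      i1 <- findInterval(wt$start[k], ps, left.open = TRUE) + 1L
      i2 <- findInterval(wt$start[k] + width, ps, left.open = TRUE)
      if (i2 >= i1) out[k] <- sum(es[i1:i2] >= thr)
    }
  }
  out
}

# merge half-open intervals (overlapping or book-ended)
.merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1) for (i in 2:length(start)) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  list(start = out_s, end = out_e)
}

#' Call candidate regions from a window table
#'
#' A window qualifies when it holds more than `min_markers` markers and at
#' least a fraction `min_fraction` of its scored markers have extremeness at
#' or above `score_threshold`. Overlapping or book-ended qualifying windows
#' are merged into maximal regions.
#'
#' @param wt a [window_scan()] table.
#' @param score_threshold extremeness threshold.
#' @param min_fraction minimum fraction of scored markers beyond the
#'   threshold.
#' @param min_markers a qualifying window must contain more markers (scored
#'   or flagged) than this.
#' @return A data.frame of class `candidate_regions` with half-open intervals
#'   and per-region marker statistics.
#' @export
call_regions <- function(wt, score_threshold, min_fraction = 0.5,
                         min_markers = 150) {
  ne <- .window_extreme_counts(wt, score_threshold)
  qual <- wt$n_markers > min_markers & wt$n_scored > 0 &
    ne / pmax(wt$n_scored, 1L) >= min_fraction
  md <- attr(wt, "markers")
  out <- list()
  for (cc in unique(wt$chrom)) {
    sel <- which(wt$chrom == cc & qual)
    if (length(sel) == 0) next
    mg <- .merge_intervals(wt$start[sel], wt$end[sel])
    ps <- md[[cc]]$pos; pe <- md[[cc]]$e
    pss <- md[[cc]]$pos_scored; ess <- md[[cc]]$e_scored
    for (r in seq_along(mg$start)) {
      inside_all <- ps >= mg$start[r] & ps < mg$end[r]
      inside_sc <- pss >= mg$start[r] & pss < mg$end[r]
      wstarts <- wt$start[sel][wt$start[sel] >= mg$start[r] &
                                wt$start[sel] < mg$end[r]]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc, start = mg$start[r], end = mg$end[r],
        n_markers = sum(inside_all),
        n_extreme = sum(ess[inside_sc] >= score_threshold),
        max_score = if (any(inside_sc)) max(ess[inside_sc]) else NA_real_,
        n_windows = length(wstarts),
        window_starts = paste(wstarts, collapse = ","))
    }
  }
  regions <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_markers = integer(0), n_extreme = integer(0),
               max_score = numeric(0), n_windows = integer(0),
               window_starts = character(0))
  structure(regions, threshold = score_threshold,
            min_fraction = min_fraction, min_markers = min_markers,
            class = c("candidate_regions", "data.frame"))
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("candidate_regions:", nrow(x), "region(s) at threshold",
      signif(attr(x, "threshold"), 4), "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

# candidate threshold grid: actual extremeness values (quantile-thinned)
.threshold_grid <- function(wt, max_grid = 1500L) {
  md <- attr(wt, "markers")
  e <- sort(unique(unlist(lapply(md, function(m) m$e_scored))))
  if (length(e) > max_grid)
    e <- unique(stats::quantile(e, probs = seq(0, 1, length.out = max_grid),
                                type = 1, names = FALSE))
  e
}

# region counts for many thresholds at once
.region_counts <- function(wt, thrs, min_fraction, min_markers) {
  md <- attr(wt, "markers")
  width <- attr(wt, "width")
  W <- nrow(wt)
  # per-window counts of scored markers >= each threshold
  cnt <- matrix(0L, W, length(thrs))
  for (cc in names(md)) {
    sel <- which(wt$chrom == cc)
    ps <- md[[cc]]$pos_scored
    es <- md[[cc]]$e_scored
    for (k in sel) {
      i1 <- findInterval(wt$start[k], ps, left.open = TRUE) + 1L
      i2 <- findInterval(wt$start[k] + width, ps, left.open = TRUE)
      if (i2 >= i1) {
        v <- sort(es[i1:i2])
        cnt[k, ] <- length(v) - findInterval(thrs, v, left.open = TRUE)
      }
    }
  }
  size_ok <- wt$n_markers > min_markers & wt$n_scored > 0
  counts <- integer(length(thrs))
  covs <- numeric(length(thrs))
  chrom_f <- factor(wt$chrom, levels = unique(wt$chrom))
  for (t in seq_along(thrs)) {
    qual <- size_ok & cnt[, t] / pmax(wt$n_scored, 1L) >= min_fraction
    nreg <- 0L
    cov <- 0
    for (cc in levels(chrom_f)) {
      sel <- which(qual & wt$chrom == cc)
      if (length(sel) == 0) next
      mg <- .merge_intervals(wt$start[sel], wt$end[sel])
      nreg <- nreg + length(mg$start)
      cov <- cov + sum(mg$end - mg$start)
    }
    counts[t] <- nreg
    covs[t] <- cov
  }
  list(counts = counts, coverage = covs)
}

#' Calibrate the score threshold to a requested number of regions
#'
#' Searches the extremeness thresholds (keeping the cluster fraction fixed)
#' for the largest threshold whose region count matches `target_count`.
#' Because merging makes the count non-monotone in plateaus, an exact match
#' may not exist; then the threshold with the closest achieved count is
#' returned, preferring the higher threshold.
#'
#' @inheritParams call_regions
#' @param target_count requested number of candidate regions.
#' @return A list with `threshold`, `regions` (a [call_regions()] result) and
#'   `achieved` (the realized region count).
#' @export
calibrate_regions <- function(wt, target_count, min_fraction = 0.5,
                              min_markers = 150) {
  stopifnot(target_count >= 1)
  thrs <- .threshold_grid(wt)
  if (length(thrs) == 0) stop("no scored markers to calibrate on")
  rc <- .region_counts(wt, thrs, min_fraction, min_markers)$counts
  if (max(rc) < target_count)
    stop("target of ", target_count, " regions not achievable; at most ",
         max(rc), " region(s) can be called", call. = FALSE)
  exact <- which(rc == target_count)
  pick <- if (length(exact) > 0) max(exact)
  else {
    d <- abs(rc - target_count)
    max(which(d == min(d)))  # closest count, preferring higher threshold
  }
  thr <- thrs[pick]
  regions <- call_regions(wt, thr, min_fraction, min_markers)
  list(threshold = thr, regions = regions, achieved = nrow(regions))
}

#' Count overlaps between two region sets
#'
#' Counts how many regions in `a` overlap at least one region (half-open
#' interval intersection) or site (point-in-interval) in `b`. This is the
#' procedure used to compare candidate-region sets from different estimators
#' of the same statistic.
#'
#' @param a a `candidate_regions` data.frame (or any data.frame with `chrom`,
#'   `start`, `end`).
#' @param b a second region set, or a site table with columns `chrom` and
#'   `pos`.
#' @return A list with `n_a`, `n_overlapping` and `fraction`.
#' @export
region_overlap <- function(a, b) {
  hit <- logical(nrow(a))
  sites <- "pos" %in% names(b) && !"end" %in% names(b)
  for (r in seq_len(nrow(a))) {
    bb <- b[b$chrom == a$chrom[r], , drop = FALSE]
    if (nrow(bb) == 0) next
    hit[r] <- if (sites)
      any(bb$pos >= a$start[r] & bb$pos < a$end[r])
    else
      any(bb$start < a$end[r] & bb$end > a$start[r])
  }
  list(n_a = nrow(a), n_overlapping = sum(hit),
       fraction = if (nrow(a) > 0) mean(hit) else NA_real_)
}
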