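# Reproducible end-to-end scans: read input, score, standardize, window,
# call regions, and write score TSV / window TSV / region BED plus a JSON
# manifest carrying every parameter and the seed, so a run can be repeated
# bit-identically. These functions are the programmatic face of the
# command-line script in inst/cli/ehhscan.R.

.default_run_config <- function() {
  list(input = NULL, input2 = NULL, format = "hap", locus_length = NULL,
       estimator = "phased", allele_mode = "polarized",
       ancestral_file = NULL, on_unpolarized = "error",
       ehh_cutoff = NULL, min_support_stop = NULL, min_focal_support = 10,
       maf_min = 0.05, max_gap_bp = Inf, curve_mode = "linear",
       boundary_policy = "flag",
       bin_width = 0.025, min_bin_count = 10,
       window_width = 250000, window_offset = 50000,
       extremeness = "two_sided", min_markers = 150,
       score_threshold = NULL, target_regions = NULL,
       seed = 1L, out_dir = ".", prefix = "ehhscan")
}

.fill_config <- function(config) {
  utils::modifyList(.default_run_config(), config)
}

.read_input <- function(paths, format, locus_length) {
  if (format == "ms") {
    if (is.null(locus_length))
      stop("ms input needs 'locus_length'", call. = FALSE)
    haps <- do.call(c, lapply(paths, read_ms, locus_length_bp = locus_length))
    for (i in seq_along(haps)) haps[[i]]$chrom <- paste0("chr", i)
    return(haps)
  }
  reader <- switch(format, vcf = read_vcf, hap = read_hap_table,
                   stop("unknown input format: ", format))
  lapply(paths, reader)
}

.manifest_hash <- function(manifest) {
  # the hash identifies the computation: output location does not enter it
  manifest$hash <- NULL
  manifest$params$out_dir <- NULL
  manifest$params$prefix <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(manifest, path) {
  manifest$hash <- .manifest_hash(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$hash
}

.scan_outputs <- function(tab, wt, regions, threshold, config, subcommand) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(config$out_dir, config$prefix)
  manifest <- list(tool = "ehhscan",
                   version = as.character(utils::packageVersion("ehhscan")),
                   subcommand = subcommand,
                   params = config[!vapply(config, is.null, logical(1))],
                   threshold = threshold, n_regions = nrow(regions),
                   dropped = list(
                     below_maf = sum(tab$below_maf),
                     insufficient = sum(tab$insufficient),
                     multiallelic = sum(tab$multiallelic),
                     undefined = sum(tab$undefined),
                     unpolarized = sum(tab$unpolarized),
                     truncated = sum(tab$truncated)))
  hash <- .manifest_hash(manifest)
  cmt <- paste0("manifest_hash=", hash)
  files <- c(scores = paste0(pre, "_scores.tsv"),
             windows = paste0(pre, "_windows.tsv"),
             regions = paste0(pre, "_regions.bed"),
             manifest = paste0(pre, "_manifest.json"))
  write_score_table(tab, files["scores"], comment = cmt)
  wt_out <- as.data.frame(wt)
  wt_out$n_extreme <- .window_extreme_counts(wt, threshold)
  con <- file(files["windows"], "w")
  writeLines(paste0("# ", cmt), con)
  utils::write.table(wt_out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_regions_bed(regions, files["regions"], comment = cmt)
  .write_manifest(manifest, files["manifest"])
  invisible(list(files = files, scores = tab, windows = wt,
                 regions = regions, threshold = threshold))
}

.pick_threshold <- function(wt, config) {
  if (!is.null(config$target_regions)) {
    cal <- calibrate_regions(wt, config$target_regions,
                             min_markers = config$min_markers)
    list(threshold = cal$threshold, regions = cal$regions)
  } else {
    thr <- config$score_threshold
    if (is.null(thr)) {
      # default: 99th percentile of extremeness over scored markers
      md <- attr(wt, "markers")
      e <- unlist(lapply(md, function(m) m$e_scored))
      thr <- stats::quantile(e, 0.99, names = FALSE)
    }
    list(threshold = thr,
         regions = call_regions(wt, thr, min_markers = config$min_markers))
  }
}

#' Run a complete iHS scan
#'
#' Reads haplotypes, scores every chromosome, standardizes genome-wide
#' (frequency-binned for polarized scoring, unbinned for major/minor),
#' summarizes sliding windows, delineates candidate regions and writes the
#' score TSV, window TSV, region BED and a JSON run manifest.
#'
#' With the unphased estimator the region-caller marker minimum is halved
#' automatically, tracking the roughly halved number of markers for which an
#' unphased score can be obtained.
#'
#' @param config a named list; see `ehhscan:::.default_run_config()` for all
#'   fields. Minimally `input` (path(s)), `format` (`"hap"`, `"vcf"` or
#'   `"ms"`), `estimator` and `out_dir`.
#' @return Invisibly, a list with the output file paths and the score,
#'   window and region objects.
#' @export
scan_ihs <- function(config) {
  config <- .fill_config(config)
  set.seed(config$seed)
  haps <- .read_input(config$input, config$format, config$locus_length)
  if (config$estimator == "unphased" &&
      config$min_markers == .default_run_config()$min_markers)
    config$min_markers <- config$min_markers / 2
  if (!is.null(config$ancestral_file)) {
    anc <- utils::read.table(config$ancestral_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    haps <- lapply(haps, polarize, ancestral = anc)
  }
  if (config$allele_mode == "polarized" &&
      all(vapply(haps, function(h) all(is.na(h$ancestral)), logical(1))))
    stop("polarized mode requires ancestral-allele annotation ",
         "(none present and no 'ancestral_file' given)", call. = FALSE)
  cfg <- scan_config(config$estimator, ehh_cutoff = config$ehh_cutoff,
                     min_support_stop = config$min_support_stop,
                     min_focal_support = config$min_focal_support,
                     maf_min = config$maf_min, max_gap_bp = config$max_gap_bp,
                     curve_mode = config$curve_mode,
                     boundary_policy = config$boundary_policy)
  tabs <- lapply(haps, unihs_scan, estimator = config$estimator,
                 allele_mode = config$allele_mode, config = cfg,
                 on_unpolarized = config$on_unpolarized)
  tab <- bind_scores(tabs)
  spec <- if (config$allele_mode == "polarized")
    std_spec("freq_binned", bin_width = config$bin_width,
             min_bin_count = config$min_bin_count)
  else std_spec("unbinned")
  tab <- standardize(tab, spec)
  wt <- window_scan(tab, config$window_width, config$window_offset,
                    config$extremeness)
  sel <- .pick_threshold(wt, config)
  .scan_outputs(tab, wt, sel$regions, sel$threshold, config, "scan-ihs")
}

.scan_xp <- function(config, statistic) {
  config <- .fill_config(config)
  set.seed(config$seed)
  if (is.null(config$input2))
    stop("cross-population scans need 'input' and 'input2'", call. = FALSE)
  h1 <- .read_input(config$input, config$format, config$locus_length)
  h2 <- .read_input(config$input2, config$format, config$locus_length)
  cfg <- scan_config(config$estimator, ehh_cutoff = config$ehh_cutoff,
                     min_support_stop = config$min_support_stop,
                     min_focal_support = config$min_focal_support,
                     max_gap_bp = config$max_gap_bp,
                     curve_mode = config$curve_mode,
                     boundary_policy = config$boundary_policy)
  t1 <- bind_scores(lapply(h1, ies_scan, estimator = config$estimator,
                           config = cfg))
  t2 <- bind_scores(lapply(h2, ies_scan, estimator = config$estimator,
                           config = cfg))
  tab <- if (statistic == "xpehh") xpehh(t1, t2) else rsb(t1, t2)
  wt <- window_scan(tab, config$window_width, config$window_offset,
                    config$extremeness)
  sel <- .pick_threshold(wt, config)
  .scan_outputs(tab, wt, sel$regions, sel$threshold, config,
                paste0("scan-", statistic))
}

#' Run a complete XP-EHH or Rsb scan of two populations
#'
#' @inheritParams scan_ihs
#' @return As [scan_ihs()].
#' @export
scan_xpehh <- function(config) .scan_xp(config, "xpehh")

#' @rdname scan_xpehh
#' @export
scan_rsb <- function(config) .scan_xp(config, "rsb")

#' Simulate a genome and write it as ms format plus truth TSV
#'
#' @param config a named list with simulation fields: `mode` (`"neutral"`,
#'   `"sweep"` or `"split"`), `n_chromosomes`, `N`, `L`, `n`, `sweep_freq`
#'   or `fixed_since`, `seed`, `out_dir`, `prefix`.
#' @return Invisibly, the output file paths.
#' @export
run_simulate <- function(config) {
  defaults <- list(mode = "neutral", n_chromosomes = 20, N = 500, L = 1e6,
                   n = 200, sweep_freq = NULL, fixed_since = NULL,
                   split_time = 0.05, seed = 1L, out_dir = ".",
                   prefix = "sim")
  config <- utils::modifyList(defaults, config)
  sel <- NULL
  if (config$mode == "sweep") {
    sel <- list(target_freq = config$sweep_freq,
                fixed_since = config$fixed_since)
    sel <- sel[!vapply(sel, is.null, logical(1))]
    if (length(sel) == 0) sel <- list(target_freq = 0.7)
  }
  p <- sim_params(N = config$N, L = config$L, n = config$n, selection = sel,
                  seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(config$out_dir, config$prefix)
  files <- character(0)
  if (config$mode == "split") {
    pops <- simulate_split(p, config$n_chromosomes, config$split_time)
    for (pp in c("pop1", "pop2")) {
      write_ms(pops[[pp]], paste0(pre, "_", pp, ".ms"), L = config$L)
      files <- c(files, paste0(pre, "_", pp, ".ms"))
    }
    genome <- pops$pop1
  } else {
    genome <- if (config$mode == "sweep")
      simulate_sweep(p, config$n_chromosomes)
    else simulate_neutral(p, config$n_chromosomes)
    write_ms(genome, paste0(pre, ".ms"), L = config$L)
    files <- c(files, paste0(pre, ".ms"))
  }
  write_truth(genome, paste0(pre, "_truth.tsv"))
  files <- c(files, paste0(pre, "_truth.tsv"))
  manifest <- list(tool = "ehhscan",
                   version = as.character(utils::packageVersion("ehhscan")),
                   subcommand = "simulate",
                   params = config[!vapply(config, is.null, logical(1))])
  .write_manifest(manifest, paste0(pre, "_manifest.json"))
  invisible(c(files, paste0(pre, "_manifest.json")))
}

#' Evaluate called regions against simulation truth
#'
#' @param config a named list with `regions` (BED path), `truth` (truth TSV
#'   path), optional `genome_length`, `out_dir`, `prefix`.
#' @return Invisibly, the `scan_eval` result (also written as JSON). When no
#'   regions were called the FDR is undefined; a JSON with an explanatory
#'   message is written and a condition of class `ehhscan_undefined_fdr`
#'   is signalled.
#' @export
run_evaluate <- function(config) {
  defaults <- list(regions = NULL, truth = NULL, genome_length = NULL,
                   out_dir = ".", prefix = "eval")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$regions) || is.null(config$truth))
    stop("run_evaluate() needs 'regions' and 'truth' paths", call. = FALSE)
  regions <- read_bed_regions(config$regions)
  truth <- read_truth(config$truth)
  truth <- truth[!is.na(truth$pos), , drop = FALSE]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$out_dir, paste0(config$prefix, ".json"))
  res <- tryCatch(scan_fdr(regions, truth,
                           genome_length = config$genome_length),
                  ehhscan_undefined_fdr = function(e) e)
  if (inherits(res, "ehhscan_undefined_fdr")) {
    jsonlite::write_json(list(error = "undefined_fdr",
                              message = conditionMessage(res)),
                         out, auto_unbox = TRUE)
    stop(res)
  }
  jsonlite::write_json(unclass(res), out, auto_unbox = TRUE, digits = NA)
  invisible(res)
}
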