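# Readers and writers: VCF (GT field), ms-format simulator output, the plain
# haplotype table, score-table TSV, region BED and truth TSV.

#' Read haplotypes from a VCF file
#'
#' Uses the GT field only. Allele codes are the VCF allele indices (0 = REF);
#' a missing genotype puts the missing sentinel (`NA`) in both sequences. The
#' phased flag is set only when every genotype uses the phased separator
#' `"|"`. Each sample becomes one diploid individual contributing two
#' sequences.
#'
#' @param path VCF file (plain or gzipped).
#' @param samples optional character vector restricting the samples read.
#' @return A [haploset]. Multi-chromosome files are rejected; read one
#'   chromosome at a time.
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no variant records in ", path)
  chroms <- unique(fix[, "CHROM"])
  if (length(chroms) > 1)
    stop("VCF spans multiple chromosomes (", paste(chroms, collapse = ", "),
         "); read one chromosome at a time")
  pos <- as.numeric(fix[, "POS"])
  if (any(diff(pos) <= 0)) {
    bad <- which(diff(pos) <= 0)[1] + 1L
    stop("positions not strictly increasing at record ", bad, " (",
         fix[bad, "CHROM"], ":", fix[bad, "POS"], ")")
  }
  gt <- vcf@gt[, -1, drop = FALSE]
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing) > 0)
      stop("samples not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  # the GT field is the first colon-separated entry
  gt <- sub(":.*$", "", gt)
  M <- nrow(gt)
  nsam <- ncol(gt)
  alleles <- matrix(NA_integer_, M, 2 * nsam)
  phased <- TRUE
  for (j in seq_len(nsam)) {
    g <- gt[, j]
    miss <- is.na(g) | g == "."
    g[miss] <- ".|."  # fully missing genotype; does not decide the phase flag
    pieces <- strsplit(g, "[|/]")
    npl <- lengths(pieces)
    if (any(npl != 2))
      stop("mixed or non-diploid ploidy for sample ", colnames(gt)[j],
           " (record ", which(npl != 2)[1], ")")
    if (any(!grepl("|", g[!miss], fixed = TRUE))) phased <- FALSE
    a1 <- suppressWarnings(as.integer(vapply(pieces, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(pieces, `[`, "", 2L)))
    alleles[, 2 * j - 1L] <- a1
    alleles[, 2 * j] <- a2
  }
  labels <- lapply(seq_len(M), function(s) {
    alt <- fix[s, "ALT"]
    unname(c(fix[s, "REF"], if (!is.na(alt) && nzchar(alt))
      strsplit(alt, ",", fixed = TRUE)[[1]]))
  })
  h <- haploset(alleles, positions = pos, chrom = chroms, phased = phased,
                allele_labels = labels,
                ind = rep(seq_len(nsam), each = 2))
  attr(h, "samples") <- colnames(gt)
  h
}

#' Read ms-format simulator output
#'
#' Parses the standard ms layout (`//` replicate delimiter, `segsites:`,
#' `positions:` in `[0, 1]`, 0/1 haplotype rows). Fractional positions are
#' scaled to bp and rounded to distinct integers (duplicates are resolved by
#' a minimal right shift whose count is reported as attribute
#' `"n_shifted"`). Alleles are polarized with 0 = ancestral and the data are
#' phased.
#'
#' @param path ms output file.
#' @param locus_length_bp physical length represented by the `[0, 1]`
#'   interval.
#' @return A list of [haploset]s, one per replicate.
#' @export
read_ms <- function(path, locus_length_bp) {
  lines <- readLines(path)
  breaks <- which(trimws(lines) == "//")
  if (length(breaks) == 0) stop("no '//' replicate delimiter found in ", path)
  out <- vector("list", length(breaks))
  bounds <- c(breaks, length(lines) + 1L)
  for (r in seq_along(breaks)) {
    block <- lines[(bounds[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    seg_line <- grep("^segsites:", block, value = TRUE)
    S <- as.integer(sub("^segsites:\\s*", "", seg_line[1]))
    if (S == 0) {
      out[[r]] <- haploset(matrix(integer(0), 0, 0), numeric(0),
                           chrom = paste0("rep", r), phased = TRUE,
                           extent = c(1, locus_length_bp))
      next
    }
    pos_line <- grep("^positions:", block, value = TRUE)
    frac <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "",
                                           pos_line[1])), "\\s+")[[1]])
    hap_rows <- block[grepl("^[01]+$", trimws(block))]
    mat <- do.call(cbind, lapply(hap_rows, function(rr)
      as.integer(strsplit(trimws(rr), "")[[1]])))
    bp <- .positions_to_bp(frac * locus_length_bp)
    out[[r]] <- haploset(mat, positions = as.numeric(bp),
                         chrom = paste0("rep", r), phased = TRUE,
                         ancestral = rep(0L, S),
                         extent = c(1, locus_length_bp))
    attr(out[[r]], "n_shifted") <- attr(bp, "n_shifted")
  }
  out
}

#' Write a simulated genome in ms format (plus a truth table)
#'
#' @param genome a `sim_genome` (all chromosomes must share one length and
#'   be biallelic 0/1).
#' @param path output file.
#' @param L locus length in bp used to scale positions into `[0, 1]`;
#'   defaults to the first chromosome's extent.
#' @return `path`, invisibly.
#' @export
write_ms <- function(genome, path, L = NULL) {
  haps <- genome$haps
  if (is.null(L)) L <- haps[[1]]$extent[2]
  n <- n_seq(haps[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ehhscan-sim", n, length(haps)), "0 0 0"), con)
  for (h in haps) {
    if (any(h$alleles > 1, na.rm = TRUE))
      stop("ms format supports biallelic 0/1 data only")
    writeLines("", con)
    writeLines("//", con)
    writeLines(paste0("segsites: ", n_markers(h)), con)
    writeLines(paste0("positions: ",
                      paste(sprintf("%.10f", h$positions / L),
                            collapse = " ")), con)
    apply(h$alleles, 2, function(col)
      writeLines(paste(col, collapse = ""), con))
  }
  invisible(path)
}

#' Write / read the truth table of a simulated genome
#' @param genome a `sim_genome`.
#' @param path TSV path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_truth <- function(genome, path) {
  utils::write.table(genome$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read the plain haplotype table
#'
#' TSV with one row per marker: `chrom`, `pos`, the comma-joined textual
#' allele labels, the ancestral allele label (`.` if unpolarized), then one
#' column per sequence (missing alleles as `.`). The header row carries the
#' sequence-to-individual mapping (`I<k>` repeated per sequence) and a `##`
#' metadata line carries the phased flag and the chromosome extent, so a
#' round trip reproduces alleles, positions and flags exactly.
#'
#' @param h a [haploset].
#' @param path TSV path.
#' @return `path` (write) or a [haploset] (read).
#' @export
write_hap_table <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("## ehhscan_haplotypes phased=", h$phased,
                    " extent=", format(h$extent[1], scientific = FALSE), ",",
                    format(h$extent[2], scientific = FALSE)), con)
  writeLines(paste(c("chrom", "pos", "alleles", "anc",
                     paste0("I", h$ind)), collapse = "\t"), con)
  anc_lab <- rep(".", n_markers(h))
  for (s in which(!is.na(h$ancestral)))
    anc_lab[s] <- h$allele_labels[[s]][h$ancestral[s] + 1L]
  body <- vapply(seq_len(n_markers(h)), function(s) {
    a <- h$alleles[s, ]
    a <- ifelse(is.na(a), ".", as.character(a))
    paste(c(h$chrom, format(h$positions[s], scientific = FALSE),
            paste(h$allele_labels[[s]], collapse = ","), anc_lab[s], a),
          collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_hap_table
#' @export
read_hap_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  lines <- lines[!startsWith(lines, "##")]
  phased <- any(grepl("phased=TRUE", meta))
  extent <- NULL
  em <- regmatches(meta, regexpr("extent=[0-9.eE+-]+,[0-9.eE+-]+", meta))
  if (length(em) > 0)
    extent <- as.numeric(strsplit(sub("extent=", "", em[1]), ",")[[1]])
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  seq_cols <- header[-(1:4)]
  ind <- as.integer(sub("^I", "", seq_cols))
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  M <- length(rows)
  chrom <- rows[[1]][1]
  pos <- vapply(rows, function(rr) as.numeric(rr[2]), numeric(1))
  labels <- lapply(rows, function(rr) strsplit(rr[3], ",", fixed = TRUE)[[1]])
  anc_lab <- vapply(rows, `[`, "", 4L)
  alleles <- t(vapply(rows, function(rr) {
    a <- rr[-(1:4)]
    suppressWarnings(as.integer(ifelse(a == ".", NA, a)))
  }, integer(length(seq_cols))))
  ancestral <- rep(NA_integer_, M)
  for (s in seq_len(M)) {
    if (anc_lab[s] != ".")
      ancestral[s] <- match(anc_lab[s], labels[[s]]) - 1L
  }
  haploset(alleles, positions = pos, chrom = chrom, phased = phased,
           ancestral = ancestral, allele_labels = labels, ind = ind,
           extent = extent)
}

#' Write a score table as TSV
#'
#' @param tab a score table.
#' @param path TSV path.
#' @param comment optional `#` header comment lines (e.g. a manifest hash).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED (and read them back)
#'
#' Internal coordinates are 1-based; BED is 0-based half-open, so starts are
#' shifted down by one (clamped at zero). Extra columns carry the marker
#' counts and the maximum extremeness.
#'
#' @param regions a `candidate_regions` data.frame.
#' @param path BED path.
#' @param comment optional `#` header comment lines.
#' @return `path` (write) or a `candidate_regions` data.frame (read).
#' @export
write_regions_bed <- function(regions, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  if (nrow(regions) > 0) {
    bed <- data.frame(chrom = regions$chrom,
                      start = format(pmax(regions$start - 1, 0),
                                     scientific = FALSE, trim = TRUE),
                      end = format(pmax(regions$end - 1, 0),
                                   scientific = FALSE, trim = TRUE),
                      name = paste0("region_", seq_len(nrow(regions))),
                      score = regions$max_score,
                      n_markers = regions$n_markers,
                      n_extreme = regions$n_extreme)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0)),
                     class = c("candidate_regions", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)) + 1,
    end = as.numeric(vapply(parts, `[`, "", 3L)) + 1)
  if (lengths(parts)[1] >= 7) {
    df$max_score <- as.numeric(vapply(parts, `[`, "", 5L))
    df$n_markers <- as.integer(vapply(parts, `[`, "", 6L))
    df$n_extreme <- as.integer(vapply(parts, `[`, "", 7L))
  }
  structure(df, class = c("candidate_regions", "data.frame"))
}
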