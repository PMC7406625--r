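## Genotype containers, readers/writers, and the population-level QC rules:
## heterozygote recoding for BILs and the >20%-missingness line filter.
## Calls are coded A (donor homozygote), B (recurrent homozygote),
## H (heterozygote), "-" (missing); marker positions are 1-based bp.

VALID_CALLS <- c("A", "B", "H", "-")

#' Construct a SNP genotype matrix
#'
#' @param calls character matrix, lines x markers, entries in
#'   `{"A","B","H","-"}`; rownames are line ids.
#' @param markers data.frame with columns `chrom`, `pos`, `marker_id`,
#'   sorted by (chrom, pos) with strictly increasing positions within each
#'   chromosome.
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, markers) {
  stopifnot(is.matrix(calls), is.character(calls),
            ncol(calls) == nrow(markers),
            all(c("chrom", "pos", "marker_id") %in% names(markers)))
  bad <- which(!(calls %in% VALID_CALLS))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(calls))
    stop(sprintf("invalid genotype code '%s' at line %s, marker %s",
                 calls[bad[1]], rownames(calls)[i[1]] %||% i[1],
                 markers$marker_id[i[2]]))
  }
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("marker positions not strictly increasing on ", ch)
    }
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("line%04d", seq_len(nrow(calls)))
  }
  colnames(calls) <- markers$marker_id
  rownames(markers) <- NULL
  structure(list(calls = calls,
                 markers = markers[, c("chrom", "pos", "marker_id")]),
            class = "snp_matrix")
}

#' @exportS3Method base::print
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix:", nrow(x$calls), "lines x", ncol(x$calls), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s)\n")
  tb <- table(factor(x$calls, levels = VALID_CALLS))
  cat("  calls:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

normalize_gt <- function(gt) {
  # "0/1", "1|0", "." -> sorted allele pair or NA
  gt <- sub(":.*$", "", gt)
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) == 0 || any(p == ".") || any(is.na(p))) return(NA_character_)
    paste(sort(p), collapse = "/")
  }, character(1))
}

#' Read a genotype matrix
#'
#' Two dialects are supported. `format = "csv"`: first header row of
#' marker ids, second and third header rows of chromosome and bp position,
#' then one row per line with calls in `{A,B,H,-}` (written by
#' [write_genotypes()]). `format = "vcf"`: a VCF v4.x whose GT fields are
#' polarized against the two parental samples so that A is the donor-parent
#' homozygote and B the recurrent-parent homozygote; markers at which the
#' parents are not opposite homozygotes cannot be polarized and are dropped
#' with a logged count.
#'
#' @param path input file.
#' @param format `"csv"` or `"vcf"`.
#' @param donor_sample,recurrent_sample VCF sample names of the parents
#'   (required for `format = "vcf"`).
#' @return a [snp_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "vcf"),
                           donor_sample = NULL, recurrent_sample = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                           check.names = FALSE)
    if (nrow(raw) < 4) stop("genotype CSV must have 3 header rows and >=1 line")
    ids <- as.character(raw[1, -1])
    chrom <- as.character(raw[2, -1])
    pos <- as.numeric(raw[3, -1])
    markers <- data.frame(chrom = chrom, pos = pos, marker_id = ids,
                          stringsAsFactors = FALSE)
    calls <- as.matrix(raw[-(1:3), -1, drop = FALSE])
    rownames(calls) <- as.character(raw[-(1:3), 1])
    bad <- which(!(calls %in% VALID_CALLS))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(calls))
      stop(sprintf("unknown genotype code '%s' (line %s, marker %s) in %s",
                   calls[bad[1]], rownames(calls)[i[1]], ids[i[2]], path))
    }
    return(snp_matrix(calls, markers))
  }
  if (is.null(donor_sample) || is.null(recurrent_sample)) {
    stop("VCF input needs donor_sample and recurrent_sample for polarization")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  samples <- colnames(gt)
  if (!all(c(donor_sample, recurrent_sample) %in% samples)) {
    stop("parental samples not present in VCF")
  }
  markers <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.numeric(fix[, "POS"]),
                        marker_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                           paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                           fix[, "ID"]),
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    stop("VCF positions are not sorted by (chrom, pos)")
  }
  gtn <- apply(gt, 2, normalize_gt)
  don <- gtn[, donor_sample]
  rec <- gtn[, recurrent_sample]
  hom <- function(g) !is.na(g) & sub("/.*", "", g) == sub(".*/", "", g)
  polarizable <- hom(don) & hom(rec) & don != rec
  n_drop <- sum(!polarizable)
  if (n_drop > 0) {
    dq_log(sprintf("read_genotypes: dropped %d unpolarizable marker(s)", n_drop))
  }
  prog <- setdiff(samples, c(donor_sample, recurrent_sample))
  gtn <- gtn[polarizable, prog, drop = FALSE]
  don <- don[polarizable]; rec <- rec[polarizable]
  markers <- markers[polarizable, , drop = FALSE]
  calls <- matrix("-", length(prog), nrow(markers),
                  dimnames = list(prog, markers$marker_id))
  for (j in seq_len(nrow(markers))) {
    g <- gtn[j, ]
    calls[, j] <- ifelse(is.na(g), "-",
                  ifelse(g == don[j], "A",
                  ifelse(g == rec[j], "B", "H")))
  }
  snp_matrix(calls, markers)
}

#' Write a genotype matrix
#'
#' CSV dialect: three header rows (marker ids, chromosomes, positions),
#' then one row per line. VCF: GT-only records with the donor homozygote as
#' `1/1`, the recurrent homozygote as `0/0`, heterozygotes as `0/1` and
#' missing as `./.`; the two parents are appended as synthetic samples
#' (`donor_sample`, `recurrent_sample`) so the file round-trips through
#' [read_genotypes()].
#'
#' @param m a [snp_matrix()].
#' @param path output file.
#' @param format `"csv"` or `"vcf"`.
#' @param donor_sample,recurrent_sample sample names used for the appended
#'   parental columns in VCF output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(m, path, format = c("csv", "vcf"),
                            donor_sample = "NIP", recurrent_sample = "9311") {
  format <- match.arg(format)
  stopifnot(inherits(m, "snp_matrix"))
  if (format == "csv") {
    hdr <- rbind(c("line", m$markers$marker_id),
                 c("chrom", m$markers$chrom),
                 c("pos", format(m$markers$pos, scientific = FALSE, trim = TRUE)))
    body <- cbind(rownames(m$calls), m$calls)
    utils::write.table(rbind(hdr, body), path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c(A = "1/1", B = "0/0", H = "0/1", "-" = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dormqtl",
               sprintf("##contig=<ID=%s>", unique(m$markers$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(m$calls),
                     donor_sample, recurrent_sample), collapse = "\t"), con)
  for (j in seq_len(nrow(m$markers))) {
    writeLines(paste(c(m$markers$chrom[j],
                       format(m$markers$pos[j], scientific = FALSE),
                       m$markers$marker_id[j], "A", "G", ".", "PASS", ".",
                       "GT", gt_code[m$calls[, j]], "1/1", "0/0"),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Recode heterozygous calls as missing
#'
#' BIL populations are near-homozygous after repeated selfing, so residual
#' heterozygous calls are treated as missing before bin calling. The
#' number of recoded calls is attached as attribute `n_het_recoded`.
#'
#' @param m a [snp_matrix()].
#' @return the recoded `snp_matrix`.
#' @export
recode_het_to_missing <- function(m) {
  stopifnot(inherits(m, "snp_matrix"))
  n_het <- sum(m$calls == "H")
  m$calls[m$calls == "H"] <- "-"
  attr(m, "n_het_recoded") <- n_het
  m
}

#' Exclude lines with excessive missing data
#'
#' Lines whose missing-call fraction is strictly greater than `threshold`
#' (default 0.20) are removed; a line at exactly the threshold is kept.
#' The marker set is unchanged.
#'
#' @param m a [snp_matrix()].
#' @param threshold maximum tolerated missing fraction.
#' @return list with `geno` (the filtered `snp_matrix`) and `report`
#'   (a `qc_report`: per-line missing fractions, excluded line ids, and the
#'   heterozygote-recoding count if [recode_het_to_missing()] ran first).
#' @export
filter_lines_by_missingness <- function(m, threshold = 0.20) {
  stopifnot(inherits(m, "snp_matrix"), threshold >= 0, threshold <= 1)
  miss <- rowMeans(m$calls == "-")
  excluded <- rownames(m$calls)[miss > threshold]
  if (length(excluded) == nrow(m$calls)) {
    stop("all lines exceed the missingness threshold (", threshold, ")")
  }
  keep <- !(rownames(m$calls) %in% excluded)
  out <- m
  out$calls <- m$calls[keep, , drop = FALSE]
  report <- structure(list(per_line_missing = miss,
                           threshold = threshold,
                           excluded = excluded,
                           n_het_recoded = attr(m, "n_het_recoded") %||% 0L),
                      class = "qc_report")
  list(geno = out, report = report)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [filter_lines_by_missingness()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    list(threshold = report$threshold,
         n_excluded = length(report$excluded),
         excluded = report$excluded,
         n_het_recoded = report$n_het_recoded,
         per_line_missing = as.list(report$per_line_missing)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
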