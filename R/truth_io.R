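## Ground-truth export: per-line ancestry as BED, planted effects as JSON.

#' Write a truth set's ancestry mosaic as BED
#'
#' One 0-based half-open interval per (line, chromosome segment) with the
#' line id and ancestry call (`A` donor hom, `H` het, `B` recurrent hom)
#' in the name column.
#'
#' @param truth a `truth_set`.
#' @param path output file.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  a <- truth$ancestry
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dormqtl truth ancestry; 0-based half-open; name=line:ancestry",
             con)
  utils::write.table(
    data.frame(a$chrom, format(a$start, scientific = FALSE, trim = TRUE),
               format(a$end, scientific = FALSE, trim = TRUE),
               paste0(a$line, ":", a$geno)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a planted-effects manifest as JSON
#'
#' @param effects list of [qtl_effect()] / [epistatic_effect()] objects.
#' @param path output file.
#' @export
write_effects_json <- function(effects, path) {
  jsonlite::write_json(lapply(effects, unclass), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
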