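#' Build a genetic map for the simulator
#'
#' The map relates physical (bp) and genetic (cM) coordinates by a uniform
#' scaling (default 270 kb/cM, a rice-typical genome-wide average) and
#' places markers at evenly spaced positions along each chromosome.
#' Physical positions are 1-based bp; genetic positions are cM from the
#' chromosome start.
#'
#' @param n_chrom number of chromosomes.
#' @param length_cM genetic length per chromosome (recycled to `n_chrom`).
#' @param markers_per_chrom number of markers per chromosome (recycled).
#' @param kb_per_cM physical-to-genetic scaling, kilobases per centimorgan.
#' @return an object of class `genetic_map`: a list with `chromosomes`
#'   (chrom, length_bp, length_cM) and `markers`
#'   (chrom, pos, cM, marker_id), markers sorted by (chrom, pos).
#' @examples
#' gm <- genetic_map(2, length_cM = 100, markers_per_chrom = 30)
#' head(gm$markers)
#' @export
genetic_map <- function(n_chrom, length_cM, markers_per_chrom,
                        kb_per_cM = 270) {
  stopifnot(n_chrom >= 1, all(length_cM > 0), all(markers_per_chrom >= 2),
            kb_per_cM > 0)
  length_cM <- rep_len(length_cM, n_chrom)
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom), n_chrom)
  chroms <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_bp = round(length_cM * kb_per_cM * 1000),
    length_cM = length_cM,
    stringsAsFactors = FALSE
  )
  markers <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
    m <- markers_per_chrom[i]
    cm <- length_cM[i] * (seq_len(m) - 0.5) / m
    data.frame(
      chrom = chroms$chrom[i],
      pos = round(cm * kb_per_cM * 1000),
      cM = cm,
      marker_id = sprintf("%s_m%03d", chroms$chrom[i], seq_len(m)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(markers) <- NULL
  map <- list(chromosomes = chroms, markers = markers, kb_per_cM = kb_per_cM)
  class(map) <- "genetic_map"
  validate_genetic_map(map)
  map
}

validate_genetic_map <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  for (ch in map$chromosomes$chrom) {
    mk <- map$markers[map$markers$chrom == ch, ]
    if (nrow(mk) == 0) stop("chromosome without markers: ", ch)
    if (any(diff(mk$pos) <= 0)) {
      stop("marker bp positions not strictly increasing on ", ch)
    }
    if (any(mk$cM < 0) || any(diff(mk$cM) < 0)) {
      stop("marker cM positions must be non-negative and non-decreasing on ", ch)
    }
  }
  invisible(map)
}

#' @exportS3Method base::print
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers,", x$kb_per_cM, "kb/cM\n")
  invisible(x)
}
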