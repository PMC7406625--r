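## Recombination bin-map construction: sliding-window genotype smoothing,
## block collapse, breakpoint placement, and population-level bins.
##
## Window rule: each 15-SNP window (step 1) is called from its informative
## (A/B) calls; a donor fraction a/(a+b) >= 12/15 gives "A", <= 3/15 gives
## "B", anything else (or too few informative calls) is undetermined. The
## proportion form keeps the published 12:3 rule well defined when a window
## contains missing or heterozygous calls.
## Coordinates: marker positions are 1-based bp; all interval output
## (blocks, bins, BED) is 0-based half-open.

#' Configuration of the sliding-window bin caller
#'
#' Defaults mirror the published rule: 15-SNP windows, step 1, and the
#' 12:3 / 3:12 calling thresholds.
#'
#' @param window window size in SNPs.
#' @param step window step in SNPs.
#' @param a_threshold,b_threshold the a:b calling ratio, interpreted as
#'   donor-call fractions `a_threshold / window` (call A at or above) and
#'   `b_threshold / window` (call B at or below).
#' @param min_informative minimum number of informative (A/B) calls for a
#'   window to be called at all.
#' @param merge_tol breakpoint merge radius in bp used by
#'   [build_binmap()]; 0 keeps exact positions.
#' @return a `bin_call_config` list.
#' @export
bin_call_config <- function(window = 15L, step = 1L, a_threshold = 12L,
                            b_threshold = 3L, min_informative = 8L,
                            merge_tol = 0) {
  stopifnot(b_threshold > 0, b_threshold < a_threshold,
            a_threshold <= window, step >= 1, min_informative <= window,
            merge_tol >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 a_threshold = as.integer(a_threshold),
                 b_threshold = as.integer(b_threshold),
                 min_informative = as.integer(min_informative),
                 merge_tol = merge_tol),
            class = "bin_call_config")
}

#' Call sliding windows along one line and chromosome
#'
#' @param calls character vector of genotype calls (`A`,`B`,`H`,`-`) in
#'   marker order along one chromosome.
#' @param cfg a [bin_call_config()].
#' @return character vector of window calls in `{"A","B","U"}` (U =
#'   undetermined) with attributes `starts` (first marker index of each
#'   window) and `width`. If the chromosome has fewer markers than the
#'   window size, the whole chromosome is treated as a single window.
#' @export
call_windows <- function(calls, cfg = bin_call_config()) {
  n <- length(calls)
  if (n == 0L) stop("empty call sequence")
  if (n < cfg$window) {
    dq_log(sprintf("call_windows: %d markers < window of %d; using one window",
                   n, cfg$window))
    starts <- 1L
    width <- n
  } else {
    starts <- seq.int(1L, n - cfg$window + 1L, by = cfg$step)
    width <- cfg$window
  }
  ca <- cumsum(c(0L, calls == "A"))
  cb <- cumsum(c(0L, calls == "B"))
  a <- ca[starts + width] - ca[starts]
  b <- cb[starts + width] - cb[starts]
  inf <- a + b
  frac <- ifelse(inf > 0, a / inf, NA_real_)
  out <- rep("U", length(starts))
  hi <- cfg$a_threshold / cfg$window
  lo <- cfg$b_threshold / cfg$window
  ok <- inf >= min(cfg$min_informative, width)
  out[ok & !is.na(frac) & frac >= hi] <- "A"
  out[ok & !is.na(frac) & frac <= lo] <- "B"
  attr(out, "starts") <- starts
  attr(out, "width") <- width
  out
}

#' Collapse window calls into blocks and breakpoints
#'
#' Each marker receives the majority vote of the determined windows
#' covering it (ties undetermined); runs of equal determined calls become
#' blocks, undetermined runs are absorbed into their flanking determined
#' blocks, and a recombination breakpoint is placed at the bp midpoint
#' between the last marker of one block and the first marker of the next
#' block with a different genotype. Blocks tile `[0, chrom_length)`.
#'
#' @param window_calls output of [call_windows()] on the same markers.
#' @param marker_pos bp positions of the markers.
#' @param chrom_length chromosome length in bp (defaults to the last
#'   marker position).
#' @param cfg the [bin_call_config()] used for the window calls.
#' @return list with `blocks` (data.frame: genotype, start, end,
#'   first_marker, last_marker) and `breakpoints` (numeric bp positions).
#'   A line with no determined window yields one `undetermined` block and
#'   no breakpoints.
#' @export
collapse_blocks <- function(window_calls, marker_pos,
                            chrom_length = max(marker_pos),
                            cfg = bin_call_config()) {
  n <- length(marker_pos)
  starts <- attr(window_calls, "starts")
  width <- attr(window_calls, "width")
  if (is.null(starts) || is.null(width)) {
    stop("window_calls must come from call_windows()")
  }
  # majority vote of determined windows covering each marker (diff trick)
  covA <- numeric(n + 1L)
  covB <- numeric(n + 1L)
  for (w in seq_along(starts)) {
    if (window_calls[w] == "A") {
      covA[starts[w]] <- covA[starts[w]] + 1
      covA[starts[w] + width] <- covA[starts[w] + width] - 1
    } else if (window_calls[w] == "B") {
      covB[starts[w]] <- covB[starts[w]] + 1
      covB[starts[w] + width] <- covB[starts[w] + width] - 1
    }
  }
  cA <- cumsum(covA[seq_len(n)])
  cB <- cumsum(covB[seq_len(n)])
  marker_call <- rep("U", n)
  marker_call[cA > cB] <- "A"
  marker_call[cB > cA] <- "B"
  r <- rle(marker_call)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  det <- which(r$values != "U")
  if (length(det) == 0L) {
    dq_log("collapse_blocks: no determined window on this chromosome")
    blocks <- data.frame(genotype = "undetermined", start = 0,
                         end = chrom_length, first_marker = 1L,
                         last_marker = n, stringsAsFactors = FALSE)
    return(list(blocks = blocks, breakpoints = numeric(0)))
  }
  # merge consecutive determined runs sharing a genotype (absorbing the
  # undetermined runs between them)
  geno <- character(0)
  first_mk <- integer(0)
  last_mk <- integer(0)
  for (k in det) {
    if (length(geno) && geno[length(geno)] == r$values[k]) {
      last_mk[length(geno)] <- ends[k]
    } else {
      geno <- c(geno, r$values[k])
      first_mk <- c(first_mk, firsts[k])
      last_mk <- c(last_mk, ends[k])
    }
  }
  nb <- length(geno)
  bps <- if (nb > 1L) {
    (marker_pos[last_mk[-nb]] + marker_pos[first_mk[-1L]]) / 2
  } else numeric(0)
  bounds <- c(0, bps, chrom_length)
  blocks <- data.frame(genotype = geno,
                       start = bounds[-length(bounds)],
                       end = bounds[-1L],
                       stringsAsFactors = FALSE)
  # undetermined markers join the block whose bp span contains them:
  # leading/trailing runs adopt their single neighbour, interior runs are
  # split at the midpoint breakpoint
  mk_block <- pmin(findInterval(marker_pos, bounds), nb)
  blocks$first_marker <- vapply(seq_len(nb), function(k) {
    min(which(mk_block == k))
  }, integer(1))
  blocks$last_marker <- vapply(seq_len(nb), function(k) {
    max(which(mk_block == k))
  }, integer(1))
  list(blocks = blocks, breakpoints = bps)
}

#' Call blocks and breakpoints for every line of a genotype matrix
#'
#' Runs [call_windows()] and [collapse_blocks()] per line and chromosome.
#'
#' @param m a [snp_matrix()].
#' @param cfg a [bin_call_config()].
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   defaults to the last marker position per chromosome.
#' @return list with `blocks` (data.frame over all lines), `breakpoints`
#'   (data.frame: chrom, pos, line) and `chrom_lengths`.
#' @export
call_blocks <- function(m, cfg = bin_call_config(), chrom_lengths = NULL) {
  stopifnot(inherits(m, "snp_matrix"))
  chroms <- unique(m$markers$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(m$markers$pos[m$markers$chrom == ch])
    }, numeric(1))
  }
  stopifnot(all(chroms %in% names(chrom_lengths)))
  blocks <- list()
  bps <- list()
  for (ch in chroms) {
    sel <- which(m$markers$chrom == ch)
    pos <- m$markers$pos[sel]
    for (i in seq_len(nrow(m$calls))) {
      wc <- call_windows(m$calls[i, sel], cfg)
      cb <- collapse_blocks(wc, pos, chrom_lengths[[ch]], cfg)
      cb$blocks$line <- rownames(m$calls)[i]
      cb$blocks$chrom <- ch
      blocks[[length(blocks) + 1L]] <- cb$blocks
      if (length(cb$breakpoints)) {
        bps[[length(bps) + 1L]] <- data.frame(
          chrom = ch, pos = cb$breakpoints,
          line = rownames(m$calls)[i], stringsAsFactors = FALSE)
      }
    }
  }
  breakpoints <- if (length(bps)) do.call(rbind, bps) else {
    data.frame(chrom = character(0), pos = numeric(0), line = character(0))
  }
  list(blocks = do.call(rbind, blocks), breakpoints = breakpoints,
       chrom_lengths = chrom_lengths)
}

#' Build the population bin map from all breakpoints
#'
#' The unique breakpoint positions observed anywhere in the population
#' partition each chromosome `[0, length)` into recombination bins. With
#' `merge_tol > 0`, breakpoints closer than the tolerance are merged to
#' their mean before partitioning.
#'
#' @param breakpoints data.frame with `chrom` and `pos` (one row per
#'   breakpoint per line), as from [call_blocks()].
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param merge_tol merge radius in bp (default 0: exact positions).
#' @return a `bin_map`: data.frame (chrom, start, end, bin_id) in genome
#'   order, with the contributing breakpoints kept as attribute
#'   `breakpoints`.
#' @export
build_binmap <- function(breakpoints, chrom_lengths, merge_tol = 0) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    p <- sort(unique(breakpoints$pos[breakpoints$chrom == ch]))
    if (length(p) && (min(p) <= 0 || max(p) >= len)) {
      stop("breakpoint outside chromosome bounds on ", ch)
    }
    if (merge_tol > 0 && length(p) > 1L) {
      grp <- cumsum(c(TRUE, diff(p) > merge_tol))
      p <- as.numeric(tapply(p, grp, mean))
    }
    bounds <- c(0, p, len)
    out[[ch]] <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                            end = bounds[-1L], stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  bins$bin_id <- sprintf("bin%04d", seq_len(nrow(bins)))
  structure(bins, class = c("bin_map", "data.frame"),
            breakpoints = breakpoints, chrom_lengths = chrom_lengths)
}

#' Project per-line blocks onto the population bins
#'
#' Because every line's breakpoints are bin boundaries, each bin lies
#' within exactly one block of each line; the bin call is that block's
#' genotype (undetermined blocks give `-`). A bin crossing a line's
#' breakpoint is impossible by construction and raises an error.
#'
#' @param line_blocks result of [call_blocks()].
#' @param binmap a [build_binmap()] result built from the same lines with
#'   `merge_tol = 0`.
#' @return character matrix lines x bins with calls in `{"A","B","-"}`.
#' @export
genotype_bins <- function(line_blocks, binmap) {
  blocks <- line_blocks$blocks
  lines <- unique(blocks$line)
  out <- matrix("-", length(lines), nrow(binmap),
                dimnames = list(lines, binmap$bin_id))
  for (ch in unique(binmap$chrom)) {
    bsel <- which(binmap$chrom == ch)
    bstart <- binmap$start[bsel]
    bend <- binmap$end[bsel]
    chb <- blocks[blocks$chrom == ch, ]
    for (ln in lines) {
      lb <- chb[chb$line == ln, ]
      lb <- lb[order(lb$start), ]
      idx <- findInterval(bstart, lb$start)
      if (any(idx < 1L) || any(bend > lb$end[idx] + 1e-9)) {
        stop("internal error: bin crosses a line breakpoint for ", ln,
             " on ", ch)
      }
      g <- lb$genotype[idx]
      g[g == "undetermined"] <- "-"
      out[ln, bsel] <- g
    }
  }
  out
}

#' Summary statistics of a bin map
#'
#' @param binmap a `bin_map`.
#' @return list with `n_bins` and bin-length statistics in bp (min,
#'   median, mean, max); the median uses the midpoint convention for even
#'   counts.
#' @export
binmap_summary <- function(binmap) {
  stopifnot(inherits(binmap, "bin_map"), nrow(binmap) > 0)
  len <- binmap$end - binmap$start
  list(n_bins = nrow(binmap),
       min_bp = min(len), median_bp = stats::median(len),
       mean_bp = mean(len), max_bp = max(len))
}

#' Write a bin map as BED (0-based half-open)
#'
#' @param binmap a `bin_map`.
#' @param path output file.
#' @export
write_binmap_bed <- function(binmap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dormqtl bin map; 0-based half-open intervals", con)
  utils::write.table(
    data.frame(binmap$chrom,
               format(binmap$start, scientific = FALSE, trim = TRUE),
               format(binmap$end, scientific = FALSE, trim = TRUE),
               binmap$bin_id),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write bin genotypes as CSV (lines x bins)
#'
#' @param bin_geno matrix from [genotype_bins()].
#' @param path output file.
#' @export
write_bin_genotypes <- function(bin_geno, path) {
  utils::write.csv(as.data.frame(bin_geno), path, quote = FALSE)
  invisible(path)
}
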