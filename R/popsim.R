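## Population simulator: meiosis under the Haldane model (no interference),
## CSSL / BIL / F2 designs with full ancestry ground truth.
##
## A haplotype on one chromosome is a step function over [0, L] cM:
## list(br = sorted interior breakpoints, anc = ancestry per segment,
## length(anc) == length(br) + 1), ancestry coded 1 = donor, 0 = recurrent.

#' Haldane map function
#'
#' Converts a genetic map distance to a recombination fraction under the
#' Haldane model (crossovers as a Poisson process, no interference):
#' `r = (1 - exp(-2 d / 100)) / 2` for `d` in centimorgans.
#'
#' @param d map distance in cM (vectorised); must be non-negative.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_rec_frac(c(0, 1, 50, 1000))
#' @export
haldane_rec_frac <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("map distance must be finite and non-negative")
  }
  (1 - exp(-2 * d / 100)) / 2
}

hap_const <- function(anc) list(br = numeric(0), anc = anc)

hap_eval <- function(hap, x) {
  hap$anc[findInterval(x, hap$br) + 1L]
}

hap_simplify <- function(br, anc) {
  if (length(br) == 0L) return(list(br = br, anc = anc))
  keep <- anc[-1L] != anc[-length(anc)]
  list(br = br[keep], anc = c(anc[1L], anc[-1L][keep]))
}

# one meiotic product on one chromosome of length L cM
gamete_chrom <- function(h1, h2, L) {
  n_co <- stats::rpois(1L, L / 100)
  from <- sample.int(2L, 1L) # which parental haplotype at the start
  if (n_co == 0L) return(if (from == 1L) h1 else h2)
  co <- sort(stats::runif(n_co, 0, L))
  br <- sort(unique(c(h1$br, h2$br, co)))
  mids <- (c(0, br) + c(br, L)) / 2
  use_h1 <- ((findInterval(mids, co) %% 2L) == 0L) == (from == 1L)
  anc <- ifelse(use_h1, hap_eval(h1, mids), hap_eval(h2, mids))
  hap_simplify(br, anc)
}

#' Simulate one gamete from a parental diplotype
#'
#' Crossover counts per chromosome are Poisson with mean `length_cM / 100`;
#' crossover positions are uniform on the cM scale (Haldane model). The
#' returned haplotype is a mosaic of the two parental haplotypes switching
#' at each crossover.
#'
#' @param parent a diplotype: list with `h1` and `h2`, each a per-chromosome
#'   list of haplotype step functions as produced by the simulators.
#' @param map a [genetic_map()].
#' @param seed optional integer; when given the draw is reproducible,
#'   otherwise the current RNG stream is used.
#' @return per-chromosome list of haplotypes.
#' @export
simulate_gamete <- function(parent, map, seed = NULL) {
  validate_genetic_map(map)
  if (length(parent$h1) == 0L) stop("empty parental diplotype")
  with_seed(seed, {
    lapply(seq_along(parent$h1), function(i) {
      gamete_chrom(parent$h1[[i]], parent$h2[[i]],
                   map$chromosomes$length_cM[i])
    })
  })
}

dip <- function(h1, h2) list(h1 = h1, h2 = h2)

parent_dip <- function(map, anc) {
  h <- lapply(seq_len(nrow(map$chromosomes)), function(i) hap_const(anc))
  dip(h, h)
}

f1_dip <- function(map) {
  n <- nrow(map$chromosomes)
  dip(lapply(seq_len(n), function(i) hap_const(1L)),
      lapply(seq_len(n), function(i) hap_const(0L)))
}

self_once <- function(ind, map) {
  dip(simulate_gamete(ind, map), simulate_gamete(ind, map))
}

# donor-allele dosage (0/1/2) of a diplotype at cM positions on one chromosome
dip_dosage_chrom <- function(ind, chrom_idx, cm) {
  hap_eval(ind$h1[[chrom_idx]], cm) + hap_eval(ind$h2[[chrom_idx]], cm)
}

dosage_to_call <- function(dos) c("B", "H", "A")[dos + 1L]

# per-line ancestry intervals in bp, tiling each chromosome [0, length_bp)
dip_ancestry <- function(ind, map, line_id) {
  out <- vector("list", nrow(map$chromosomes))
  for (i in seq_len(nrow(map$chromosomes))) {
    L <- map$chromosomes$length_cM[i]
    br <- sort(unique(c(ind$h1[[i]]$br, ind$h2[[i]]$br)))
    mids <- (c(0, br) + c(br, L)) / 2
    dos <- hap_eval(ind$h1[[i]], mids) + hap_eval(ind$h2[[i]], mids)
    simp <- hap_simplify(br, dos)
    bnd <- c(0, round(simp$br * map$kb_per_cM * 1000),
             map$chromosomes$length_bp[i])
    out[[i]] <- data.frame(
      line = line_id,
      chrom = map$chromosomes$chrom[i],
      start = bnd[-length(bnd)],
      end = bnd[-1L],
      geno = dosage_to_call(simp$anc),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Specify a simulated mapping population
#'
#' @param design one of `"CSSL"`, `"BIL"`, `"F2"`.
#' @param n_lines number of lines to produce.
#' @param seed master seed for the population draw.
#' @param selfing_generations BIL only: rounds of single-seed-descent
#'   selfing after the backcross (default 7, i.e. BC1F1 advanced to F8).
#' @param max_donor_segments CSSL only: maximum number of homozygous donor
#'   segments retained per line under selection.
#' @param n_backcross CSSL only: backcross generations used to generate the
#'   candidate pool.
#' @param pool_size CSSL only: size of the candidate pool the selection
#'   step draws from (default `25 * n_lines`).
#' @param donor,recurrent parental labels (metadata only).
#' @return a `population_spec` list.
#' @export
population_spec <- function(design = c("BIL", "CSSL", "F2"), n_lines, seed,
                            selfing_generations = 7L,
                            max_donor_segments = 3L,
                            n_backcross = 3L,
                            pool_size = NULL,
                            donor = "NIP", recurrent = "9311") {
  design <- match.arg(design)
  stopifnot(n_lines >= 1, selfing_generations >= 0, max_donor_segments >= 1,
            n_backcross >= 1)
  spec <- list(design = design, n_lines = as.integer(n_lines),
               seed = as.integer(seed),
               selfing_generations = as.integer(selfing_generations),
               max_donor_segments = as.integer(max_donor_segments),
               n_backcross = as.integer(n_backcross),
               pool_size = as.integer(pool_size %||% (25L * n_lines)),
               donor = donor, recurrent = recurrent)
  class(spec) <- "population_spec"
  spec
}

finish_population <- function(lines, map, spec, extra = NULL) {
  mk <- map$markers
  chrom_ids <- map$chromosomes$chrom
  calls <- matrix("-", length(lines), nrow(mk))
  for (j in seq_along(chrom_ids)) {
    sel <- which(mk$chrom == chrom_ids[j])
    cm <- mk$cM[sel]
    for (i in seq_along(lines)) {
      calls[i, sel] <- dosage_to_call(dip_dosage_chrom(lines[[i]], j, cm))
    }
  }
  line_ids <- sprintf("%s_L%04d", spec$design, seq_along(lines))
  rownames(calls) <- line_ids
  colnames(calls) <- mk$marker_id
  geno <- snp_matrix(calls, mk[, c("chrom", "pos", "marker_id")])
  ancestry <- do.call(rbind, lapply(seq_along(lines), function(i) {
    dip_ancestry(lines[[i]], map, line_ids[i])
  }))
  truth <- structure(
    c(list(ancestry = ancestry, map = map, design = spec$design,
           line_ids = line_ids, qtl = NULL, genetic_values = NULL),
      extra),
    class = "truth_set")
  list(geno = geno, truth = truth)
}

#' Simulate a backcross inbred line (BIL) population
#'
#' Each line descends from one BC1F1 individual (donor x recurrent F1
#' backcrossed to the recurrent parent) advanced by
#' `spec$selfing_generations` rounds of single-seed-descent selfing
#' (default 7, giving F8-equivalent lines). The expected donor allele
#' frequency is 0.25 at every marker and residual heterozygosity halves
#' with each selfing generation.
#'
#' @param spec a [population_spec()] with `design = "BIL"`.
#' @param map a [genetic_map()].
#' @return list with `geno` (a `snp_matrix` of A/H/B calls) and `truth`
#'   (a `truth_set` holding the per-line ancestry mosaic).
#' @export
simulate_bil_population <- function(spec, map) {
  stopifnot(inherits(spec, "population_spec"), spec$design == "BIL")
  validate_genetic_map(map)
  with_seed(substream_seed(spec$seed, "bil"), {
    f1 <- f1_dip(map)
    rec <- parent_dip(map, 0L)
    lines <- lapply(seq_len(spec$n_lines), function(i) {
      ind <- dip(simulate_gamete(f1, map), simulate_gamete(rec, map))
      for (g in seq_len(spec$selfing_generations)) ind <- self_once(ind, map)
      ind
    })
    finish_population(lines, map, spec)
  })
}

#' Simulate an F2 population
#'
#' Each line is the union of two independent F1 gametes.
#'
#' @inheritParams simulate_bil_population
#' @export
simulate_f2_population <- function(spec, map) {
  stopifnot(inherits(spec, "population_spec"), spec$design == "F2")
  validate_genetic_map(map)
  with_seed(substream_seed(spec$seed, "f2"), {
    f1 <- f1_dip(map)
    lines <- lapply(seq_len(spec$n_lines), function(i) {
      dip(simulate_gamete(f1, map), simulate_gamete(f1, map))
    })
    finish_population(lines, map, spec)
  })
}

donor_segments_chrom <- function(hap) {
  # returns matrix of (start_cM, end_cM) of donor segments of a haplotype
  simp <- hap_simplify(hap$br, hap$anc)
  bnd <- c(0, simp$br, Inf)
  idx <- which(simp$anc == 1L)
  cbind(bnd[idx], bnd[idx + 1L])
}

#' Simulate a chromosome segment substitution line (CSSL) population
#'
#' Candidate lines are produced by backcrossing the F1 to the recurrent
#' parent for `spec$n_backcross` generations and fixing one final gamete to
#' homozygosity, so each candidate carries a few homozygous donor segments
#' in an otherwise recurrent background. A greedy selection then retains
#' `spec$n_lines` candidates with at most `spec$max_donor_segments`
#' segments, chosen to tile the genome as completely as the candidate pool
#' allows; genome coverage of the retained set is reported.
#'
#' @inheritParams simulate_bil_population
#' @param spec a [population_spec()] with `design = "CSSL"`.
#' @return as [simulate_bil_population()]; `truth$coverage` holds the
#'   fraction of the genome covered by at least one retained donor segment.
#' @export
simulate_cssl_population <- function(spec, map) {
  stopifnot(inherits(spec, "population_spec"), spec$design == "CSSL")
  validate_genetic_map(map)
  with_seed(substream_seed(spec$seed, "cssl"), {
    f1 <- f1_dip(map)
    rec_hap <- lapply(seq_len(nrow(map$chromosomes)),
                      function(i) hap_const(0L))
    cand <- vector("list", spec$pool_size)
    seg_count <- integer(spec$pool_size)
    for (k in seq_len(spec$pool_size)) {
      ind <- f1
      for (b in seq_len(spec$n_backcross)) {
        ind <- dip(simulate_gamete(ind, map), rec_hap)
      }
      gam <- simulate_gamete(ind, map)
      cand[[k]] <- dip(gam, gam) # selfed to fixation (doubled gamete)
      seg_count[k] <- sum(vapply(gam, function(h) {
        nrow(donor_segments_chrom(h))
      }, integer(1)))
    }
    eligible <- which(seg_count >= 1L & seg_count <= spec$max_donor_segments)
    if (length(eligible) < spec$n_lines) {
      stop(sprintf(paste0(
        "CSSL candidate pool insufficient: %d eligible candidates ",
        "(1..%d donor segments) for %d requested lines from a pool of %d; ",
        "increase pool_size or max_donor_segments"),
        length(eligible), spec$max_donor_segments, spec$n_lines,
        spec$pool_size))
    }
    # greedy tiling on a fine cM grid: pick the eligible candidate adding
    # the most uncovered donor genome, then fill by largest donor share
    grid_step <- 0.5
    grids <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
      seq(grid_step / 2, map$chromosomes$length_cM[i], by = grid_step)
    })
    cand_cover <- lapply(eligible, function(k) {
      unlist(lapply(seq_along(grids), function(i) {
        hap_eval(cand[[k]]$h1[[i]], grids[[i]]) == 1L
      }))
    })
    n_grid <- length(cand_cover[[1]])
    covered <- rep(FALSE, n_grid)
    chosen <- integer(0)
    remaining <- seq_along(eligible)
    for (pick in seq_len(spec$n_lines)) {
      gain <- vapply(remaining, function(j) {
        sum(cand_cover[[j]] & !covered)
      }, numeric(1))
      j <- remaining[which.max(gain)]
      chosen <- c(chosen, j)
      covered <- covered | cand_cover[[j]]
      remaining <- setdiff(remaining, j)
    }
    coverage <- mean(covered)
    lines <- cand[eligible[chosen]]
    res <- finish_population(lines, map, spec, extra = list(coverage = coverage))
    dq_log(sprintf("CSSL selection: %d lines retained, donor-segment genome coverage %.3f",
                   spec$n_lines, coverage))
    res
  })
}

#' Donor-allele dosage of simulated lines at arbitrary positions
#'
#' Looks up the ancestry mosaic of a `truth_set` at a (chrom, bp) position
#' for every line.
#'
#' @param truth a `truth_set` from a population simulator.
#' @param chrom chromosome id.
#' @param pos physical position (bp).
#' @return integer vector of donor-allele dosages (0, 1, 2), one per line.
#' @export
ancestry_dosage <- function(truth, chrom, pos) {
  anc <- truth$ancestry
  sel <- anc[anc$chrom == chrom & anc$start <= pos & anc$end > pos, ]
  if (!all(truth$line_ids %in% sel$line)) {
    stop("position ", chrom, ":", pos, " not covered for every line")
  }
  dos <- c(A = 2L, H = 1L, B = 0L)[sel$geno]
  dos[match(truth$line_ids, sel$line)]
}
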