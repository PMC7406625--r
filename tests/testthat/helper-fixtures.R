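# Shared fixture builders and truth-comparison helpers. All randomness is
# seeded, so every "stochastic" check is reproducible.

options(dormqtl.quiet = TRUE)

# random call matrix for oracle-equivalence checks
random_snp_matrix <- function(n_lines, n_markers, seed,
                              probs = c(A = 0.42, B = 0.42, H = 0.06,
                                        "-" = 0.10)) {
  withr::with_seed(seed, {
    calls <- matrix(sample(names(probs), n_lines * n_markers, TRUE,
                           prob = probs),
                    n_lines, n_markers)
    markers <- data.frame(chrom = "chr1",
                          pos = sort(sample.int(n_markers * 1000, n_markers)),
                          marker_id = sprintf("m%04d", seq_len(n_markers)))
    snp_matrix(calls, markers)
  })
}

# dense-marker BIL population for ancestry-recovery checks
recovery_population <- function(seed, n_lines = 60, markers_per_chrom = 200) {
  map <- genetic_map(2, length_cM = 100,
                     markers_per_chrom = markers_per_chrom)
  spec <- population_spec("BIL", n_lines = n_lines, seed = seed)
  simulate_bil_population(spec, map)
}

# lines whose homozygous ancestry intervals are all at least min_bp long
lines_with_long_segments <- function(truth, min_bp) {
  a <- truth$ancestry[truth$ancestry$geno %in% c("A", "B"), ]
  len_ok <- tapply(a$end - a$start, a$line, function(l) all(l >= min_bp))
  names(len_ok)[len_ok]
}

# truth ancestry evaluated at bin midpoints; concordance over bins whose
# truth is homozygous (het stretches are unidentifiable after the BIL
# het-to-missing recoding)
truth_bin_concordance <- function(truth, binmap, bin_geno) {
  total <- 0L
  agree <- 0L
  for (k in seq_len(nrow(binmap))) {
    mid <- (binmap$start[k] + binmap$end[k]) / 2
    dos <- ancestry_dosage(truth, binmap$chrom[k], mid)
    truth_call <- c("B", "H", "A")[dos + 1L]
    hom <- truth_call %in% c("A", "B")
    lines <- truth$line_ids[hom]
    lines <- intersect(lines, rownames(bin_geno))
    total <- total + length(lines)
    agree <- agree +
      sum(bin_geno[lines, binmap$bin_id[k]] ==
            truth_call[hom][match(lines, truth$line_ids[hom])])
  }
  agree / total
}

# sprinkle missing calls into a snp_matrix at a given rate
add_missing <- function(m, rate, seed) {
  withr::with_seed(seed, {
    idx <- which(runif(length(m$calls)) < rate)
    m$calls[idx] <- "-"
  })
  m
}

# standard bin-map pipeline on a simulated population
binmap_from_population <- function(pop, cfg = bin_call_config()) {
  m <- recode_het_to_missing(pop$geno)
  cl <- setNames(pop$truth$map$chromosomes$length_bp,
                 pop$truth$map$chromosomes$chrom)
  lb <- call_blocks(m, cfg, cl)
  binmap <- build_binmap(lb$breakpoints, lb$chrom_lengths)
  list(line_blocks = lb, binmap = binmap,
       bin_geno = genotype_bins(lb, binmap))
}

# F2 two-locus genotype draw (unlinked loci, 1:2:1 each) and a trait with
# additive, dominance and product-interaction terms
draw_f2_two_locus <- function(n, a1, a2, gamma, sigma, seed) {
  withr::with_seed(seed, {
    g1 <- sample(c(-1L, 0L, 1L), n, TRUE, prob = c(1, 2, 1) / 4)
    g2 <- sample(c(-1L, 0L, 1L), n, TRUE, prob = c(1, 2, 1) / 4)
    y <- a1 * g1 + a2 * g2 + gamma * g1 * g2 + rnorm(n, 0, sigma)
    code <- function(g) c("BB", "AB", "AA")[g + 2L]
    data.frame(g1 = code(g1), g2 = code(g2), y = y,
               stringsAsFactors = FALSE)
  })
}
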