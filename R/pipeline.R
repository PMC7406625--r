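## One-command end-to-end runs: simulate (or load) -> QC -> bin map ->
## germination traits -> ridge scans -> QTL declaration -> SD regions,
## with every intermediate persisted and a provenance JSON sufficient to
## reproduce the run.

default_traits <- c("G3d", "G7d", "T50", "AUC")

#' Pipeline configuration
#'
#' Exactly one of `sim` (a simulation request) or `input` (paths to an
#' existing genotype matrix and count table) must be given.
#'
#' @param sim list describing a simulated run: `design`
#'   (`"BIL"`/`"CSSL"`), `n_lines`, `n_chrom`, `length_cM`,
#'   `markers_per_chrom`, and optionally `effects` (list of
#'   [qtl_effect()]s), `base_curve`, `noise`, `selfing_generations`.
#' @param input list with `genotypes` (CSV path in the package dialect)
#'   and `counts` (tidy germination CSV path), plus optional
#'   `chrom_lengths`.
#' @param bin_cfg a [bin_call_config()].
#' @param scan_cfg a [scan_config()].
#' @param traits traits to scan (subset of G3d, G7d, T50, AUC).
#' @param min_traits SD-region support threshold.
#' @param seed master seed of the run.
#' @param out_dir output directory (created if missing).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, input = NULL,
                            bin_cfg = bin_call_config(),
                            scan_cfg = scan_config(),
                            traits = default_traits,
                            min_traits = 3L,
                            seed = 1L, out_dir = tempfile("dormqtl_run_")) {
  if (is.null(sim) == is.null(input)) {
    stop("exactly one of sim or input must be given")
  }
  stopifnot(all(traits %in% default_traits))
  structure(list(sim = sim, input = input, bin_cfg = bin_cfg,
                 scan_cfg = scan_cfg, traits = traits,
                 min_traits = as.integer(min_traits),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full mapping pipeline
#'
#' Stages run in order (simulate/load, QC, bin map, traits, scans, QTL
#' declaration, SD-region clustering); every stage's output is persisted
#' under `cfg$out_dir` so any stage can be re-run from its inputs.
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the in-memory artifacts (`geno`,
#'   `binmap`, `bin_geno`, `traits`, `scans`, `qtl`, `sd_regions`,
#'   `truth` when simulated) and the output directory.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate/load"
  res <- tryCatch({
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      map <- genetic_map(sim$n_chrom, sim$length_cM, sim$markers_per_chrom,
                         kb_per_cM = sim$kb_per_cM %||% 270)
      spec <- population_spec(sim$design, sim$n_lines, seed = cfg$seed,
                              selfing_generations = sim$selfing_generations %||% 7L,
                              max_donor_segments = sim$max_donor_segments %||% 3L,
                              pool_size = sim$pool_size)
      pop <- switch(sim$design,
                    BIL = simulate_bil_population(spec, map),
                    CSSL = simulate_cssl_population(spec, map),
                    F2 = simulate_f2_population(spec, map))
      germ <- simulate_germination(
        pop$truth, effects = sim$effects %||% list(),
        base_curve = sim$base_curve %||% c(Gmax = 0.95, t50_latent = 60,
                                           slope = 10),
        noise = sim$noise %||% list(line_t50_sd = 9, line_gmax_sd = 0.08,
                                    rep_t50_sd = 3),
        seed = cfg$seed)
      geno <- pop$geno
      counts <- germ$counts
      truth <- germ$truth
      chrom_lengths <- stats::setNames(map$chromosomes$length_bp,
                                       map$chromosomes$chrom)
      write_genotypes(geno, file.path(cfg$out_dir, "genotypes.csv"), "csv")
      write_germination_counts(counts,
                               file.path(cfg$out_dir, "germination_counts.csv"))
    } else {
      geno <- read_genotypes(cfg$input$genotypes, "csv")
      counts <- read_germination_counts(cfg$input$counts)
      truth <- NULL
      chrom_lengths <- cfg$input$chrom_lengths
    }

    stage <- "qc"
    if (is.null(cfg$sim) || cfg$sim$design == "BIL") {
      geno <- recode_het_to_missing(geno)
    }
    qc <- filter_lines_by_missingness(geno, threshold = 0.20)
    geno <- qc$geno
    write_qc_report(qc$report, file.path(cfg$out_dir, "qc_report.json"))

    stage <- "binmap"
    lb <- call_blocks(geno, cfg$bin_cfg, chrom_lengths)
    binmap <- build_binmap(lb$breakpoints, lb$chrom_lengths,
                           merge_tol = cfg$bin_cfg$merge_tol)
    bin_geno <- genotype_bins(lb, binmap)
    write_binmap_bed(binmap, file.path(cfg$out_dir, "binmap.bed"))
    write_bin_genotypes(bin_geno, file.path(cfg$out_dir, "bin_genotypes.csv"))
    jsonlite::write_json(binmap_summary(binmap),
                         file.path(cfg$out_dir, "binmap_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "traits"
    reps <- germination_trait_table(counts)
    traits_tab <- aggregate_replicates(reps)
    traits_tab <- traits_tab[traits_tab$line %in% rownames(bin_geno), ]
    utils::write.csv(traits_tab, file.path(cfg$out_dir, "traits.csv"),
                     quote = FALSE, row.names = FALSE)

    stage <- "scan"
    scans <- list()
    qtl <- list()
    for (tr in cfg$traits) {
      y <- stats::setNames(traits_tab[[tr]], traits_tab$line)
      sc <- ridge_scan(bin_geno, y, cfg$scan_cfg, binmap)
      scans[[tr]] <- sc
      utils::write.table(
        format(as.data.frame(sc), digits = 10, scientific = FALSE,
               trim = TRUE),
        file.path(cfg$out_dir, sprintf("scan_%s.tsv", tr)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      qtl[[tr]] <- declare_qtls(sc, tr, alpha = cfg$scan_cfg$alpha)
    }
    qtl_tab <- do.call(rbind, qtl)
    rownames(qtl_tab) <- NULL
    utils::write.table(
      format(qtl_tab, digits = 10, scientific = FALSE, trim = TRUE),
      file.path(cfg$out_dir, "qtl.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "regions"
    sd_regions <- cluster_sd_regions(qtl_tab, min_traits = cfg$min_traits)
    utils::write.table(
      format(sd_regions, digits = 10, scientific = FALSE, trim = TRUE),
      file.path(cfg$out_dir, "sd_regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    bed_con <- file(file.path(cfg$out_dir, "sd_regions.bed"), "w")
    writeLines("# dormqtl SD regions; 0-based half-open intervals", bed_con)
    if (nrow(sd_regions)) {
      utils::write.table(
        data.frame(sd_regions$chrom,
                   format(sd_regions$start, scientific = FALSE, trim = TRUE),
                   format(sd_regions$end, scientific = FALSE, trim = TRUE),
                   sd_regions$name),
        bed_con, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    }
    close(bed_con)

    stage <- "provenance"
    prov <- list(package = "dormqtl",
                 version = as.character(utils::packageVersion("dormqtl")),
                 seed = cfg$seed,
                 sim = if (!is.null(cfg$sim)) {
                   cfg$sim[setdiff(names(cfg$sim), "effects")]
                 },
                 n_effects = if (!is.null(cfg$sim)) {
                   length(cfg$sim$effects %||% list())
                 },
                 input = cfg$input,
                 bin_cfg = unclass(cfg$bin_cfg),
                 scan_cfg = unclass(cfg$scan_cfg),
                 traits = cfg$traits, min_traits = cfg$min_traits)
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(geno = geno, binmap = binmap, bin_geno = bin_geno,
         traits = traits_tab, scans = scans, qtl = qtl_tab,
         sd_regions = sd_regions, truth = truth, out_dir = cfg$out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Planted QTL effects of the bundled fixtures
#'
#' Four loci on distinct chromosomes, each designed for roughly 10-20%
#' of trait variance under the default noise model: two shift the latent
#' half-germination time (donor allele delaying germination, hence
#' pleiotropic across G3d, T50 and AUC) and two lower the asymptotic
#' germination fraction.
#'
#' @param scale `"default"` (5-chromosome map) or `"tiny"` (2-chromosome
#'   map).
#' @return list of [qtl_effect()]s.
#' @export
fixture_effects <- function(scale = c("default", "tiny")) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    return(list(
      qtl_effect("t50_latent", "chr1", 13500000, add = 6),
      qtl_effect("Gmax", "chr2", 13500000, add = -0.06)))
  }
  # positions coincide with markers (mid-bin), away from breakpoint
  # boundaries, as in standard QTL simulation designs
  list(
    qtl_effect("t50_latent", "chr1", 16065000, add = 5.5),
    qtl_effect("Gmax", "chr2", 10665000, add = -0.05),
    qtl_effect("t50_latent", "chr3", 21465000, add = 6.0),
    qtl_effect("Gmax", "chr4", 13365000, add = -0.05))
}

#' Generate the packaged test fixtures
#'
#' Two fully simulated BIL datasets with known ground truth, regenerated
#' byte-identically from embedded seeds: `tiny` (2 chromosomes, 60
#' markers, 40 lines) for fast checks and `default` (5 chromosomes, 600
#' markers, 400 lines, four planted QTLs) matching the scale of a real
#' BIL mapping population.
#'
#' @param scale `"tiny"` or `"default"`.
#' @param dir optional directory; when given, genotypes and counts are
#'   written there as CSV.
#' @param seed master seed; the fixture defaults are fixed per scale so
#'   fixtures are reproducible.
#' @return list with `geno`, `truth`, `counts`, `line_params`, `map`,
#'   `effects`.
#' @export
make_fixtures <- function(scale = c("tiny", "default"), dir = NULL,
                          seed = NULL) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    seed <- seed %||% 101L
    map <- genetic_map(2, length_cM = 100, markers_per_chrom = 30)
    spec <- population_spec("BIL", n_lines = 40, seed = seed)
  } else {
    seed <- seed %||% 2024L
    map <- genetic_map(5, length_cM = 120, markers_per_chrom = 120)
    spec <- population_spec("BIL", n_lines = 400, seed = seed)
  }
  pop <- simulate_bil_population(spec, map)
  effects <- fixture_effects(if (scale == "tiny") "tiny" else "default")
  germ <- simulate_germination(pop$truth, effects, seed = seed)
  out <- list(geno = pop$geno, truth = germ$truth, counts = germ$counts,
              line_params = germ$line_params, map = map, effects = effects)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(out$geno, file.path(dir, sprintf("%s_genotypes.csv", scale)),
                    "csv")
    write_germination_counts(out$counts,
                             file.path(dir, sprintf("%s_counts.csv", scale)))
  }
  out
}
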