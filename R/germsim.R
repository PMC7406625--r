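## Germination-assay simulator: planted QTL effects act on latent logistic
## curve parameters (Gmax, t50), so the four derived traits (G3d, G7d, T50,
## AUC) inherit a realistic correlation structure automatically.

#' Specify a planted QTL effect on a latent germination parameter
#'
#' Effects use the classical a/d parameterisation relative to the
#' recurrent-parent homozygote: the shift is `add * dosage + dom *
#' (dosage == 1)` where dosage is the donor-allele count, so the donor
#' homozygote is shifted by `2 * add`.
#'
#' @param param latent curve parameter the effect acts on: `"Gmax"`
#'   (asymptotic germination fraction), `"t50_latent"` (hours to half of
#'   `Gmax`) or `"slope"` (logistic scale, hours).
#' @param chrom,pos genomic position of the locus.
#' @param add additive effect (per donor allele, trait units).
#' @param dom dominance effect (deviation of the heterozygote).
#' @return a `qtl_effect` list.
#' @export
qtl_effect <- function(param = c("Gmax", "t50_latent", "slope"),
                       chrom, pos, add, dom = 0) {
  param <- match.arg(param)
  stopifnot(is.finite(add), is.finite(dom))
  structure(list(type = "main", param = param, chrom = chrom, pos = pos,
                 add = add, dom = dom), class = "qtl_effect")
}

#' Specify a planted two-locus epistatic effect
#'
#' Adds `gamma * s1 * s2` to a latent parameter, where `s = dosage - 1`
#' codes each locus as -1 (recurrent hom), 0 (het), +1 (donor hom); the
#' term is orthogonal to the two additive effects in an F2.
#'
#' @inheritParams qtl_effect
#' @param chrom1,pos1,chrom2,pos2 the interacting loci.
#' @param gamma interaction coefficient (trait units).
#' @export
epistatic_effect <- function(param = c("Gmax", "t50_latent", "slope"),
                             chrom1, pos1, chrom2, pos2, gamma) {
  param <- match.arg(param)
  stopifnot(is.finite(gamma))
  structure(list(type = "epistasis", param = param,
                 chrom1 = chrom1, pos1 = pos1,
                 chrom2 = chrom2, pos2 = pos2, gamma = gamma),
            class = "qtl_effect")
}

# realized genetic shift per line for each latent parameter
genetic_shifts <- function(truth, effects) {
  n <- length(truth$line_ids)
  shifts <- data.frame(Gmax = numeric(n), t50_latent = numeric(n),
                       slope = numeric(n), row.names = truth$line_ids)
  for (ef in effects) {
    if (ef$type == "main") {
      dos <- ancestry_dosage(truth, ef$chrom, ef$pos)
      shifts[[ef$param]] <- shifts[[ef$param]] +
        ef$add * dos + ef$dom * (dos == 1L)
    } else {
      s1 <- ancestry_dosage(truth, ef$chrom1, ef$pos1) - 1L
      s2 <- ancestry_dosage(truth, ef$chrom2, ef$pos2) - 1L
      shifts[[ef$param]] <- shifts[[ef$param]] + ef$gamma * s1 * s2
    }
  }
  shifts
}

#' Simulate germination assays for a simulated population
#'
#' Each line's latent cumulative germination curve is
#' `G(t) = Gmax * plogis((t - t50) / slope)`, with `Gmax` and `t50` shifted
#' by the planted QTL effects and line-level environmental noise. Every
#' seed either never germinates (probability `1 - Gmax`) or germinates at a
#' time drawn from the logistic distribution with location `t50` and scale
#' `slope`; replicate dishes are independent draws with a small
#' replicate-level shift of `t50`. Counts are cumulative per scoring time.
#'
#' `Gmax` values pushed outside `[0, 1]` by effects or noise are clipped;
#' the number of clipped lines is reported via a single message and in the
#' `clipped` column of `line_params`.
#'
#' @param truth a `truth_set` from a population simulator.
#' @param effects list of [qtl_effect()] / [epistatic_effect()] objects
#'   (may be empty).
#' @param base_curve named numeric: baseline `Gmax` (fraction),
#'   `t50_latent` (h) and `slope` (h) of the recurrent parent.
#' @param n_seeds seeds per dish.
#' @param timepoints scoring times in hours (24-h scoring over 7 days).
#' @param replicates dishes per line.
#' @param noise named list of standard deviations: `line_t50_sd` and
#'   `line_gmax_sd` (line-level environmental effects), `rep_t50_sd`
#'   (between-dish shift).
#' @param seed integer seed for the assay draw.
#' @return list with `counts` (tidy data.frame: line, replicate, hour,
#'   cumulative_count, n_seeds), `line_params` (per-line realized latent
#'   parameters), and `truth` (input truth with `qtl` and `genetic_values`
#'   filled in).
#' @export
simulate_germination <- function(truth, effects = list(),
                                 base_curve = c(Gmax = 0.95, t50_latent = 60,
                                                slope = 10),
                                 n_seeds = 50L,
                                 timepoints = seq(24, 168, by = 24),
                                 replicates = 3L,
                                 noise = list(line_t50_sd = 9,
                                              line_gmax_sd = 0.08,
                                              rep_t50_sd = 3),
                                 seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), n_seeds >= 1, replicates >= 1,
            all(diff(timepoints) > 0))
  if (base_curve[["Gmax"]] < 0 || base_curve[["Gmax"]] > 1) {
    stop("baseline Gmax must lie in [0, 1]")
  }
  shifts <- genetic_shifts(truth, effects)
  n <- length(truth$line_ids)
  with_seed(substream_seed(seed, "germination"), {
    gmax_raw <- base_curve[["Gmax"]] + shifts$Gmax +
      stats::rnorm(n, 0, noise$line_gmax_sd %||% 0)
    gmax <- pmin(1, pmax(0, gmax_raw))
    clipped <- gmax_raw != gmax
    if (any(clipped)) {
      dq_log(sprintf("simulate_germination: Gmax clipped to [0, 1] for %d of %d lines",
                     sum(clipped), n))
    }
    t50 <- base_curve[["t50_latent"]] + shifts$t50_latent +
      stats::rnorm(n, 0, noise$line_t50_sd %||% 0)
    slope <- pmax(0, base_curve[["slope"]] + shifts$slope)
    rows <- vector("list", n * replicates)
    k <- 0L
    for (i in seq_len(n)) {
      for (r in seq_len(replicates)) {
        t50_r <- t50[i] + stats::rnorm(1, 0, noise$rep_t50_sd %||% 0)
        n_germ <- stats::rbinom(1L, n_seeds, gmax[i])
        times <- if (slope[i] <= 0) {
          rep(t50_r, n_germ) # degenerate limit: a step at t50
        } else {
          stats::rlogis(n_germ, location = t50_r, scale = slope[i])
        }
        counts <- vapply(timepoints, function(t) sum(times <= t), integer(1))
        k <- k + 1L
        rows[[k]] <- data.frame(
          line = truth$line_ids[i], replicate = r, hour = timepoints,
          cumulative_count = counts, n_seeds = n_seeds,
          stringsAsFactors = FALSE)
      }
    }
    line_params <- data.frame(
      line = truth$line_ids, Gmax = gmax, t50_latent = t50, slope = slope,
      clipped = clipped, stringsAsFactors = FALSE)
    truth$qtl <- effects
    truth$genetic_values <- cbind(line = truth$line_ids, shifts)
    list(counts = do.call(rbind, rows), line_params = line_params,
         truth = truth)
  })
}
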