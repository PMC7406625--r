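## Genome scan and downstream QTL statistics.
##
## All bins enter one linear model jointly under an L2 (ridge) penalty,
## which keeps the fit stable despite the strong collinearity of adjacent
## bins; per-bin p-values come from trait permutations of the standardized
## ridge coefficients. Declared QTLs are maximal runs of adjacent
## significant bins collapsed to their lowest-p (peak) bin; their
## phenotypic variance explained is decomposed with the LMG ordering
## average on an OLS refit of the peak bins.

#' Genome-scan configuration
#'
#' @param alpha significance threshold for declaring a QTL (default
#'   0.005).
#' @param ridge_penalty_method `"cv"` (k-fold cross-validation over a
#'   log-spaced grid) or `"fixed"` (use `lambda` as given).
#' @param lambda fixed ridge penalty (required when
#'   `ridge_penalty_method = "fixed"`).
#' @param cv_folds folds for cross-validation.
#' @param n_permutations trait permutations for per-bin p-values (at
#'   least 100 when permutation p-values are requested).
#' @param p_method `"permutation"` (default) or `"ridge_t"`, an analytic
#'   approximation based on the ridge sampling covariance.
#' @param seed integer seed for permutations and Monte-Carlo LMG.
#' @param max_exact_lmg_predictors largest predictor count for exact LMG;
#'   beyond it a seeded Monte-Carlo average over orderings is used.
#' @return a `scan_config` list.
#' @export
scan_config <- function(alpha = 0.005,
                        ridge_penalty_method = c("cv", "fixed"),
                        lambda = NULL, cv_folds = 10L,
                        n_permutations = 2000L,
                        p_method = c("permutation", "ridge_t"),
                        seed = 1L,
                        max_exact_lmg_predictors = 15L) {
  ridge_penalty_method <- match.arg(ridge_penalty_method)
  p_method <- match.arg(p_method)
  stopifnot(alpha > 0, alpha < 1)
  if (p_method == "permutation" && n_permutations < 100) {
    stop("n_permutations must be >= 100 for permutation p-values")
  }
  if (ridge_penalty_method == "fixed" && is.null(lambda)) {
    stop("fixed penalty method requires lambda")
  }
  structure(list(alpha = alpha, ridge_penalty_method = ridge_penalty_method,
                 lambda = lambda, cv_folds = as.integer(cv_folds),
                 n_permutations = as.integer(n_permutations),
                 p_method = p_method, seed = as.integer(seed),
                 max_exact_lmg_predictors = as.integer(max_exact_lmg_predictors)),
            class = "scan_config")
}

# numeric coding of bin genotypes: A = 1, B = 0, "-" mean-imputed per bin
code_bins <- function(bin_geno) {
  X <- matrix(NA_real_, nrow(bin_geno), ncol(bin_geno),
              dimnames = dimnames(bin_geno))
  X[bin_geno == "A"] <- 1
  X[bin_geno == "B"] <- 0
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- mu[j]
  }
  X[is.nan(X)] <- 0 # all-missing bins; dropped later as zero-variance
  X
}

ridge_beta <- function(sv, lambda, y) {
  fac <- sv$d / (sv$d^2 + lambda)
  drop(sv$v %*% (fac * crossprod(sv$u, y)))
}

cv_lambda <- function(X, y, grid, folds, seed) {
  n <- nrow(X)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- matrix(0, folds, length(grid))
  for (f in seq_len(folds)) {
    te <- fold_id == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    sv <- svd(Xtr)
    for (g in seq_along(grid)) {
      b <- ridge_beta(sv, grid[g], ytr)
      err[f, g] <- mean((y[te] - X[te, , drop = FALSE] %*% b)^2)
    }
  }
  grid[which.min(colMeans(err))]
}

#' Ridge-regression genome scan over bins
#'
#' Fits all bins jointly under an L2 penalty (chosen by cross-validation
#' or fixed) and computes per-bin pointwise p-values by permuting the
#' trait and re-estimating the standardized ridge coefficients with the
#' penalty held fixed. The coefficient sign is reported as the allele
#' direction: positive means the donor allele increases the trait.
#'
#' @param bin_geno character matrix lines x bins (`A`/`B`/`-`) from
#'   [genotype_bins()].
#' @param trait numeric per-line trait values, named by line or in row
#'   order of `bin_geno`; at least 30 non-missing lines are required.
#' @param cfg a [scan_config()].
#' @param binmap optional `bin_map` used to attach bin coordinates.
#' @return a `ridge_scan` data.frame (bin_id, chrom, start, end, beta, p,
#'   sign) in genome order, with attributes `lambda`, `p_method`,
#'   `dropped_bins` (zero-variance bins excluded from the fit, which get
#'   `p = NA`) and `n_lines`.
#' @export
ridge_scan <- function(bin_geno, trait, cfg = scan_config(), binmap = NULL) {
  if (!is.null(names(trait))) {
    trait <- trait[rownames(bin_geno)]
  }
  if (!is.null(rownames(bin_geno))) {
    # canonical line order: permutation draws, and hence p-values, are
    # invariant to how the caller happened to order the lines
    ord <- order(rownames(bin_geno))
    bin_geno <- bin_geno[ord, , drop = FALSE]
    trait <- trait[ord]
  }
  keep <- !is.na(trait)
  n <- sum(keep)
  if (n < 30) stop("ridge_scan needs >= 30 lines with non-missing trait")
  y <- trait[keep]
  if (stats::sd(y) == 0) stop("trait is constant")
  X <- code_bins(bin_geno[keep, , drop = FALSE])
  v <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[v == 0]
  if (length(dropped)) {
    dq_log(sprintf("ridge_scan: %d zero-variance bin(s) dropped from the fit",
                   length(dropped)))
  }
  use <- v > 0
  Xs <- scale(X[, use, drop = FALSE])
  yc <- y - mean(y)
  lambda <- if (cfg$ridge_penalty_method == "fixed") cfg$lambda else {
    cv_lambda(Xs, yc, grid = 10^seq(-2, 5, length.out = 25),
              folds = cfg$cv_folds,
              seed = substream_seed(cfg$seed, "ridge_cv"))
  }
  sv <- svd(Xs)
  beta <- ridge_beta(sv, lambda, yc)
  if (cfg$p_method == "permutation") {
    B <- cfg$n_permutations
    Yperm <- with_seed(substream_seed(cfg$seed, "ridge_perm"), {
      vapply(seq_len(B), function(b) sample(yc), numeric(length(yc)))
    })
    fac <- sv$d / (sv$d^2 + lambda)
    beta_perm <- sv$v %*% (fac * crossprod(sv$u, Yperm))
    exceed <- rowSums(abs(beta_perm) >= abs(beta))
    p <- (1 + exceed) / (1 + B)
  } else {
    # analytic approximation: ridge sampling covariance, effective df
    fac2 <- sv$d^2 / (sv$d^2 + lambda)
    edf <- sum(fac2)
    fit <- drop(sv$u %*% (fac2 * crossprod(sv$u, yc)))
    sigma2 <- sum((yc - fit)^2) / max(n - edf, 1)
    se <- sqrt(sigma2 * rowSums((sv$v %*% diag(sv$d / (sv$d^2 + lambda),
                                               length(sv$d)))^2))
    p <- 2 * stats::pt(-abs(beta / se), df = max(n - edf, 1))
  }
  out <- data.frame(bin_id = colnames(bin_geno),
                    beta = NA_real_, p = NA_real_, sign = NA_integer_,
                    stringsAsFactors = FALSE)
  out$beta[use] <- beta
  out$p[use] <- p
  out$sign[use] <- sign(beta)
  if (!is.null(binmap)) {
    m <- match(out$bin_id, binmap$bin_id)
    out$chrom <- binmap$chrom[m]
    out$start <- binmap$start[m]
    out$end <- binmap$end[m]
    out <- out[, c("bin_id", "chrom", "start", "end", "beta", "p", "sign")]
  }
  structure(out, class = c("ridge_scan", "data.frame"),
            lambda = lambda, p_method = cfg$p_method,
            dropped_bins = dropped, n_lines = n)
}

chrom_number <- function(chrom) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", chrom)))
  ifelse(is.na(num), chrom, num)
}

# canonical genome order: numeric chromosome part first, then lexical
genome_order <- function(chrom, pos) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", chrom)))
  order(is.na(num), num, chrom, pos)
}

#' Declare QTLs from a genome scan
#'
#' Maximal runs of adjacent bins with `p < alpha` collapse to a single
#' QTL located at the peak bin (the lowest p in the run; ties break to
#' the lower genomic coordinate). Names follow the rice convention
#' `q<trait><chrom>.<serial>` with serials ordered by position within each
#' chromosome.
#'
#' @param scan a [ridge_scan()] result carrying bin coordinates.
#' @param trait_name trait label used in QTL names (e.g. `"G3d"`).
#' @param alpha declaration threshold (default 0.005).
#' @return data.frame of QTL records: name, trait, chrom, peak bin id and
#'   coordinates, p-value, allele direction (`sign`, positive = donor
#'   allele increases the trait), and the contiguous significant span
#'   (`span_start`, `span_end`, `n_bins`). Empty when nothing passes.
#' @export
declare_qtls <- function(scan, trait_name, alpha = 0.005) {
  stopifnot(all(c("chrom", "start", "end", "p") %in% names(scan)))
  recs <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch, ]
    s <- s[order(s$start), ]
    sig <- !is.na(s$p) & s$p < alpha
    if (!any(sig)) next
    r <- rle(sig)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    for (k in which(r$values)) {
      run <- s[lo[k]:hi[k], ]
      # peak = lowest p; permutation p-values are discrete and whole
      # stretches of a strong QTL run hit the 1/(B+1) floor, so ties are
      # broken by the larger |coefficient| and then by lower coordinate
      best <- which(run$p == min(run$p))
      if (length(best) > 1 && !all(is.na(run$beta[best]))) {
        best <- best[abs(run$beta[best]) == max(abs(run$beta[best]))]
      }
      peak <- best[1]
      recs[[length(recs) + 1L]] <- data.frame(
        trait = trait_name, chrom = ch,
        peak_bin = run$bin_id[peak],
        peak_start = run$start[peak], peak_end = run$end[peak],
        p = run$p[peak], sign = run$sign[peak],
        span_start = run$start[1], span_end = run$end[nrow(run)],
        n_bins = nrow(run), stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(name = character(0), trait = character(0),
                      chrom = character(0), peak_bin = character(0),
                      peak_start = numeric(0), peak_end = numeric(0),
                      p = numeric(0), sign = numeric(0),
                      span_start = numeric(0), span_end = numeric(0),
                      n_bins = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out <- out[genome_order(out$chrom, out$peak_start), ]
  serial <- as.integer(stats::ave(out$peak_start, out$chrom, FUN = seq_along))
  out$name <- sprintf("q%s%s.%d", out$trait, chrom_number(out$chrom), serial)
  rownames(out) <- NULL
  out[, c("name", "trait", "chrom", "peak_bin", "peak_start", "peak_end",
          "p", "sign", "span_start", "span_end", "n_bins")]
}

r2_of <- function(Xsub, y) {
  if (ncol(Xsub) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, Xsub), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG decomposition of phenotypic variance over selected predictors
#'
#' Assigns each predictor the average, over all predictor orderings, of
#' the R-squared increment it contributes when added to the model; shares
#' are non-negative and sum exactly to the full-model OLS R-squared.
#' Exact enumeration is used up to `cfg$max_exact_lmg_predictors`
#' predictors (via subset R-squared values); beyond that a seeded
#' Monte-Carlo average over random orderings is used. Perfectly collinear
#' duplicate predictors are merged (sharing one slot) before the
#' decomposition.
#'
#' @param X numeric matrix of selected predictors (e.g. coded peak bins),
#'   one column per declared QTL.
#' @param y numeric trait vector.
#' @param cfg a [scan_config()] (controls exact/Monte-Carlo switch and
#'   seed).
#' @param n_orderings Monte-Carlo orderings when beyond the exact limit.
#' @return list with `shares` (named R-squared shares), `pve`
#'   (`100 * shares`), `r_squared` (full model), `method`, and `merged`
#'   (named list of merged duplicate columns, if any).
#' @export
lmg_decomposition <- function(X, y, cfg = scan_config(),
                              n_orderings = 5000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  # merge perfectly collinear duplicates
  merged <- list()
  j <- 1L
  while (j < ncol(X)) {
    dup <- which(vapply((j + 1L):ncol(X), function(k) {
      abs(stats::cor(X[, j], X[, k])) > 1 - 1e-12
    }, logical(1))) + j
    if (length(dup)) {
      merged[[colnames(X)[j]]] <- colnames(X)[dup]
      dq_log(sprintf("lmg_decomposition: merged %d duplicate predictor(s) into %s",
                     length(dup), colnames(X)[j]))
      X <- X[, -dup, drop = FALSE]
    }
    j <- j + 1L
  }
  p <- ncol(X)
  if (p == 0L) stop("no usable predictors")
  full_r2 <- r2_of(X, y)
  if (p <= cfg$max_exact_lmg_predictors) {
    nsub <- 2^p
    r2 <- numeric(nsub)
    for (mask in seq_len(nsub - 1L)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
      r2[mask + 1L] <- r2_of(X[, idx, drop = FALSE], y)
    }
    wt <- factorial(0:(p - 1)) * factorial((p - 1):0) / factorial(p)
    shares <- numeric(p)
    for (jj in seq_len(p)) {
      bit <- 2^(jj - 1L)
      others <- setdiff(seq_len(p), jj)
      masks <- 0L
      if (length(others)) {
        for (o in others) masks <- c(masks, masks + 2^(o - 1L))
      }
      k <- vapply(masks, function(mm) sum(bitwAnd(mm, 2^(seq_len(p) - 1L)) > 0),
                  numeric(1))
      shares[jj] <- sum(wt[k + 1] * (r2[masks + bit + 1L] - r2[masks + 1L]))
    }
    method <- "exact"
  } else {
    shares <- numeric(p)
    with_seed(substream_seed(cfg$seed, "lmg_mc"), {
      for (it in seq_len(n_orderings)) {
        ord <- sample.int(p)
        prev <- 0
        for (step in seq_len(p)) {
          cur <- r2_of(X[, ord[seq_len(step)], drop = FALSE], y)
          shares[ord[step]] <- shares[ord[step]] + (cur - prev)
          prev <- cur
        }
      }
    })
    shares <- shares / n_orderings
    method <- "monte_carlo"
  }
  names(shares) <- colnames(X)
  list(shares = shares, pve = 100 * shares, r_squared = full_r2,
       method = method, merged = merged)
}

#' Cluster per-trait QTLs into seed-dormancy regions
#'
#' QTLs detected for different traits whose significant-bin spans are
#' identical or overlapping are grouped; groups supported by at least
#' `min_traits` distinct traits become seed-dormancy (SD) regions, named
#' `qSD<chrom>.<serial>`. Regions supported by all four germination
#' parameters are flagged.
#'
#' @param records row-bound [declare_qtls()] results across traits from
#'   the same bin map.
#' @param min_traits minimum number of distinct traits (default 3).
#' @return data.frame of SD regions: name, chrom, start, end, n_traits,
#'   traits (comma-separated), all_four, members (comma-separated QTL
#'   names).
#' @export
cluster_sd_regions <- function(records, min_traits = 3L) {
  out <- list()
  for (ch in unique(records$chrom)) {
    d <- records[records$chrom == ch, ]
    d <- d[order(d$span_start, d$span_end), ]
    grp <- integer(nrow(d))
    g <- 0L
    cur_end <- -Inf
    for (i in seq_len(nrow(d))) {
      if (d$span_start[i] >= cur_end) { # half-open spans: touching is not
        g <- g + 1L                     # overlapping
        cur_end <- d$span_end[i]
      } else {
        cur_end <- max(cur_end, d$span_end[i])
      }
      grp[i] <- g
    }
    for (gg in unique(grp)) {
      m <- d[grp == gg, ]
      traits <- unique(m$trait)
      if (length(traits) < min_traits) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(m$span_start), end = max(m$span_end),
        n_traits = length(traits),
        traits = paste(sort(traits), collapse = ","),
        all_four = length(traits) >= 4L,
        members = paste(m$name, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_traits = integer(0), traits = character(0),
                      all_four = logical(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[genome_order(res$chrom, res$start), ]
  serial <- as.integer(stats::ave(res$start, res$chrom, FUN = seq_along))
  res$name <- sprintf("qSD%s.%d", chrom_number(res$chrom), serial)
  rownames(res) <- NULL
  res[, c("name", "chrom", "start", "end", "n_traits", "traits",
          "all_four", "members")]
}

#' Single-marker analysis in an F2 population
#'
#' Computes the additive effect `a = (mean(AA) - mean(BB)) / 2` (AA is the
#' donor homozygote), dominance effect `d = mean(AB) - (mean(AA) +
#' mean(BB)) / 2`, a one-way ANOVA p-value across genotype classes, the
#' phenotypic variance explained (between-class sum of squares over total)
#' and `LOD = (n / 2) * log10(SS_total / SS_residual)`.
#'
#' @param geno character/factor vector of marker genotypes in
#'   `{"AA","AB","BB"}`.
#' @param trait numeric trait values.
#' @return one-row data.frame: `a`, `d`, `p`, `pve` (percent), `lod`,
#'   `n`; effects are `NA` when a required genotype class is absent.
#' @export
f2_single_marker <- function(geno, trait) {
  ok <- !is.na(geno) & !is.na(trait)
  geno <- factor(as.character(geno)[ok], levels = c("AA", "AB", "BB"))
  trait <- trait[ok]
  present <- levels(geno)[table(geno) > 0]
  if (length(present) < 2) stop("need >= 2 genotype classes")
  mns <- tapply(trait, geno, mean)
  a <- if (all(c("AA", "BB") %in% present)) {
    unname((mns["AA"] - mns["BB"]) / 2)
  } else NA_real_
  d <- if (all(c("AA", "AB", "BB") %in% present)) {
    unname(mns["AB"] - (mns["AA"] + mns["BB"]) / 2)
  } else NA_real_
  fit <- stats::aov(trait ~ geno)
  tab <- summary(fit)[[1]]
  ss_b <- tab["geno", "Sum Sq"]
  ss_r <- tab["Residuals", "Sum Sq"]
  ss_t <- ss_b + ss_r
  n <- length(trait)
  data.frame(a = a, d = d, p = tab["geno", "Pr(>F)"],
             pve = 100 * ss_b / ss_t,
             lod = (n / 2) * log10(ss_t / ss_r), n = n)
}

#' Two-locus epistasis ANOVA
#'
#' Two-way fixed-effects ANOVA with interaction on the (up to) nine
#' two-locus genotype classes, using Type-II sums of squares for the
#' inherently unbalanced F2 class frequencies. The per-class counts and
#' trait means are reported alongside the ANOVA table.
#'
#' @param geno1,geno2 genotypes at the two loci, each in
#'   `{"AA","AB","BB"}`.
#' @param trait numeric trait values.
#' @return an `epistasis_table` list: `anova` (rows locus1, locus2,
#'   interaction, residual with df, SS, F, p), `cell_means`, `cell_n`
#'   (3 x 3 matrices), `n_classes` and `n_empty_cells`.
#' @export
epistasis_anova <- function(geno1, geno2, trait) {
  ok <- !is.na(geno1) & !is.na(geno2) & !is.na(trait)
  g1 <- factor(as.character(geno1)[ok], levels = c("AA", "AB", "BB"))
  g2 <- factor(as.character(geno2)[ok], levels = c("AA", "AB", "BB"))
  y <- trait[ok]
  if (nlevels(droplevels(g1)) < 2 || nlevels(droplevels(g2)) < 2) {
    stop("need >= 2 classes at each locus")
  }
  g1 <- droplevels(g1)
  g2 <- droplevels(g2)
  cell_n <- table(g1, g2)
  n_empty <- sum(cell_n == 0)
  if (n_empty > 0) {
    dq_log(sprintf("epistasis_anova: %d empty genotype cell(s); interaction df reduced",
                   n_empty))
  }
  # Type-II sums of squares by nested model comparison: each main effect
  # is adjusted for the other, the interaction for both. Robust to empty
  # cells (aliased terms shrink the df) and to zero residual variance,
  # where the classical computation degenerates.
  f1 <- stats::lm(y ~ g1)
  f2 <- stats::lm(y ~ g2)
  f12 <- stats::lm(y ~ g1 + g2)
  full <- stats::lm(y ~ g1 * g2)
  ss_res <- stats::deviance(full)
  df_res <- full$df.residual
  comp <- function(reduced, bigger) {
    df <- reduced$df.residual - bigger$df.residual
    ss <- stats::deviance(reduced) - stats::deviance(bigger)
    Fv <- (ss / df) / (ss_res / df_res)
    data.frame(df = df, ss = ss, F = Fv,
               p = stats::pf(Fv, df, df_res, lower.tail = FALSE))
  }
  anova_tab <- rbind(locus1 = comp(f2, f12), locus2 = comp(f1, f12),
                     interaction = comp(f12, full),
                     residual = data.frame(df = df_res, ss = ss_res,
                                           F = NA_real_, p = NA_real_))
  cm <- tapply(y, list(g1, g2), mean)
  structure(list(anova = anova_tab, cell_means = cm,
                 cell_n = unclass(cell_n),
                 n_classes = sum(cell_n > 0), n_empty_cells = n_empty,
                 n = length(y)),
            class = "epistasis_table")
}

#' @exportS3Method base::print
print.epistasis_table <- function(x, ...) {
  cat("Two-locus epistasis ANOVA (Type-II SS),", x$n, "individuals,",
      x$n_classes, "genotype classes\n")
  print(round(x$anova, 4))
  cat("cell means:\n")
  print(round(x$cell_means, 2))
  invisible(x)
}
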