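# small deterministic bin-genotype matrix for scan unit tests
toy_bins <- function(n = 40, p = 12, seed = 5, missing_rate = 0) {
  withr::with_seed(seed, {
    g <- matrix(sample(c("A", "B"), n * p, TRUE), n, p,
                dimnames = list(sprintf("L%03d", 1:n),
                                sprintf("bin%04d", 1:p)))
    if (missing_rate > 0) {
      g[runif(n * p) < missing_rate] <- "-"
    }
    g
  })
}

toy_binmap <- function(p = 12, per_chrom = 6) {
  n_chrom <- ceiling(p / per_chrom)
  chrom <- rep(paste0("chr", seq_len(n_chrom)), each = per_chrom)[1:p]
  start <- unlist(lapply(rle(chrom)$lengths, function(k) (0:(k - 1)) * 1e5))
  structure(data.frame(chrom = chrom, start = start, end = start + 1e5,
                       bin_id = sprintf("bin%04d", 1:p)),
            class = c("bin_map", "data.frame"))
}

test_that("ridge solver agrees with the direct closed form and glmnet", {
  g <- toy_bins()
  X <- dormqtl:::code_bins(g)
  Xs <- scale(X)
  y <- withr::with_seed(1, rnorm(nrow(X)))
  yc <- y - mean(y)
  lambda <- 7.3
  sv <- svd(Xs)
  b_svd <- dormqtl:::ridge_beta(sv, lambda, yc)
  b_direct <- solve(crossprod(Xs) + diag(lambda, ncol(Xs)),
                    crossprod(Xs, yc))
  expect_equal(unname(b_svd), unname(drop(b_direct)), tolerance = 1e-10)
  skip_if_not_installed("glmnet")
  # glmnet standardizes y internally by its 1/n standard deviation, so
  # its lambda is ours scaled by sd_n(y) / n
  sy <- sqrt(sum(yc^2) / length(yc))
  fit <- glmnet::glmnet(Xs, yc, alpha = 0, lambda = lambda * sy / nrow(Xs),
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14)
  expect_equal(unname(b_svd), as.numeric(fit$beta), tolerance = 1e-6)
})

test_that("scan validates input and handles degenerate bins", {
  g <- toy_bins()
  expect_error(ridge_scan(g, rep(1, nrow(g))), "constant")
  expect_error(ridge_scan(g[1:10, ], rnorm(10)), ">= 30 lines")
  # a zero-variance bin is dropped but reported with NA, not an error
  g[, 3] <- "A"
  y <- withr::with_seed(2, rnorm(nrow(g)))
  sc <- ridge_scan(g, y, scan_config(n_permutations = 200, seed = 1))
  expect_identical(attr(sc, "dropped_bins"), "bin0003")
  expect_true(is.na(sc$p[3]))
  expect_false(anyNA(sc$p[-3]))
})

test_that("duplicated bins do not break the fit and share the signal", {
  g <- toy_bins(n = 60, p = 8, seed = 9)
  X <- dormqtl:::code_bins(g)
  y <- X[, 1] * 2 + withr::with_seed(3, rnorm(60, 0, 0.5))
  g2 <- cbind(g, bin0009 = g[, 1]) # perfect duplicate of the causal bin
  sc <- ridge_scan(g2, y, scan_config(n_permutations = 500, seed = 4))
  expect_false(anyNA(sc$p))
  expect_lt(sc$p[1], 0.01)
  expect_lt(sc$p[9], 0.01)
  expect_equal(sc$beta[1], sc$beta[9], tolerance = 1e-8)
})

test_that("permutation p-values are seed-reproducible and order-invariant", {
  g <- toy_bins(n = 50, p = 10, seed = 12, missing_rate = 0.05)
  y <- setNames(withr::with_seed(5, rnorm(50)), rownames(g))
  cfg <- scan_config(n_permutations = 300, seed = 42)
  sc1 <- ridge_scan(g, y, cfg)
  sc2 <- ridge_scan(g, y, cfg)
  expect_identical(sc1$p, sc2$p)
  # permuting line order (with matching trait names) changes nothing
  idx <- withr::with_seed(6, sample(50))
  sc3 <- ridge_scan(g[idx, ], y, cfg)
  expect_identical(sc1$p, sc3$p)
})

test_that("QTL declaration collapses significant runs to peak bins", {
  bm <- toy_binmap(p = 12, per_chrom = 6)
  sc <- data.frame(bin_id = bm$bin_id, chrom = bm$chrom,
                   start = bm$start, end = bm$end,
                   beta = 1, p = 1, sign = 1)
  # one run of three significant bins -> single QTL at the minimum
  sc$p[1:3] <- c(0.001, 0.002, 0.5)
  q <- declare_qtls(sc, "G3d")
  expect_equal(nrow(q), 1)
  expect_identical(q$peak_bin, "bin0001")
  expect_identical(q$name, "qG3d1.1")
  expect_equal(q$n_bins, 2)
  # two runs split by a non-significant bin -> two QTLs; adjacency does
  # not leak across chromosomes
  sc$p <- 1
  sc$p[c(1, 2, 4, 6, 7)] <- 1e-4
  q2 <- declare_qtls(sc, "AUC")
  expect_equal(nrow(q2), 4)
  expect_identical(q2$name, c("qAUC1.1", "qAUC1.2", "qAUC1.3", "qAUC2.1"))
  expect_equal(q2$n_bins, c(2L, 1L, 1L, 1L))
  # ties in the peak p break to the lower coordinate
  sc$p <- 1
  sc$p[4:5] <- 0.002
  q3 <- declare_qtls(sc, "T50")
  expect_identical(q3$peak_bin, "bin0004")
  # nothing significant -> empty but well-formed table
  sc$p <- 0.5
  expect_equal(nrow(declare_qtls(sc, "G7d")), 0)
})

test_that("declaration is invariant to row shuffling of the scan table", {
  bm <- toy_binmap(p = 12, per_chrom = 6)
  sc <- data.frame(bin_id = bm$bin_id, chrom = bm$chrom, start = bm$start,
                   end = bm$end, beta = 1,
                   p = withr::with_seed(8, runif(12, 0, 0.02)), sign = 1)
  q1 <- declare_qtls(sc, "G3d")
  q2 <- declare_qtls(sc[withr::with_seed(9, sample(12)), ], "G3d")
  expect_equal(q1, q2)
})

test_that("LMG shares obey the conservation and orthogonality identities", {
  n <- 200
  withr::with_seed(11, {
    X <- matrix(rnorm(n * 3), n, 3)
    # exactly orthogonal mean-zero columns, so marginal and joint
    # contributions coincide
    X <- qr.Q(qr(scale(X, center = TRUE, scale = FALSE)))
    y <- X %*% c(3, 2, 1) + rnorm(n)
  })
  dec <- lmg_decomposition(X, y)
  expect_equal(sum(dec$shares), dec$r_squared, tolerance = 1e-9)
  marginal <- vapply(1:3, function(j) {
    summary(lm(y ~ X[, j]))$r.squared
  }, numeric(1))
  expect_equal(unname(dec$shares), marginal, tolerance = 1e-10)
  expect_true(all(dec$shares >= 0))
})

test_that("LMG matches the brute-force ordering average on correlated data", {
  n <- 150
  withr::with_seed(13, {
    z <- rnorm(n)
    X <- cbind(x1 = z + rnorm(n, 0, 0.6), x2 = z + rnorm(n, 0, 0.6),
               x3 = rnorm(n))
    y <- 2 * z + X[, 3] + rnorm(n)
  })
  dec <- lmg_decomposition(X, y)
  expect_equal(unname(dec$shares), oracle_lmg(X, y), tolerance = 1e-9)
  # symmetry under predictor relabeling
  dec_rev <- lmg_decomposition(X[, 3:1], y)
  expect_equal(unname(dec_rev$shares), unname(rev(dec$shares)),
               tolerance = 1e-10)
  # two correlated predictors: average of the 2 orderings by hand
  X2 <- X[, 1:2]
  r2 <- function(cols) summary(lm(y ~ X2[, cols, drop = FALSE]))$r.squared
  hand <- c((r2(1) + (r2(1:2) - r2(2))) / 2,
            (r2(2) + (r2(1:2) - r2(1))) / 2)
  expect_equal(unname(lmg_decomposition(X2, y)$shares), hand,
               tolerance = 1e-9)
})

test_that("LMG merges perfectly collinear duplicates instead of failing", {
  withr::with_seed(14, {
    x <- rnorm(100)
    X <- cbind(a = x, b = x, c = rnorm(100))
    y <- x + rnorm(100)
  })
  dec <- lmg_decomposition(X, y)
  expect_identical(dec$merged, list(a = "b"))
  expect_equal(sum(dec$shares), dec$r_squared, tolerance = 1e-9)
})

test_that("Monte-Carlo LMG approximates the exact decomposition", {
  withr::with_seed(15, {
    X <- matrix(rnorm(120 * 4), 120, 4)
    y <- X %*% c(1, 0.5, 0.5, 0) + rnorm(120)
  })
  exact <- lmg_decomposition(X, y)
  mc <- lmg_decomposition(X, y, scan_config(max_exact_lmg_predictors = 2,
                                            seed = 3),
                          n_orderings = 4000)
  expect_identical(mc$method, "monte_carlo")
  expect_equal(unname(mc$shares), unname(exact$shares), tolerance = 0.02)
})

test_that("cross-trait clustering needs three traits on overlapping spans", {
  rec <- function(trait, name, chrom, s, e) {
    data.frame(name = name, trait = trait, chrom = chrom,
               peak_bin = "x", peak_start = s, peak_end = e, p = 1e-4,
               sign = 1, span_start = s, span_end = e, n_bins = 1)
  }
  shared <- rbind(rec("G3d", "qG3d3.1", "chr3", 100, 200),
                  rec("AUC", "qAUC3.1", "chr3", 100, 200),
                  rec("T50", "qT503.1", "chr3", 150, 250))
  out <- cluster_sd_regions(shared)
  expect_equal(nrow(out), 1)
  expect_identical(out$name, "qSD3.1")
  expect_equal(out$n_traits, 3)
  expect_false(out$all_four)
  # four traits on four disjoint spans: no region
  disjoint <- rbind(rec("G3d", "a", "chr1", 0, 100),
                    rec("AUC", "b", "chr1", 200, 300),
                    rec("T50", "c", "chr1", 400, 500),
                    rec("G7d", "d", "chr1", 600, 700))
  expect_equal(nrow(cluster_sd_regions(disjoint)), 0)
  # touching half-open spans do not overlap
  touching <- rbind(rec("G3d", "a", "chr1", 0, 100),
                    rec("AUC", "b", "chr1", 100, 200),
                    rec("T50", "c", "chr1", 100, 200))
  expect_equal(nrow(cluster_sd_regions(touching)), 0)
  # all four traits on one span sets the flag
  four <- rbind(shared, rec("G7d", "qG7d3.1", "chr3", 120, 180))
  expect_true(cluster_sd_regions(four)$all_four)
})

test_that("F2 single-marker statistics match their closed forms", {
  geno <- rep(c("AA", "AB", "BB"), times = c(30, 60, 30))
  y <- c(rep(20, 30), rep(44, 60), rep(60, 30))
  res <- f2_single_marker(geno, y + withr::with_seed(17, rnorm(120, 0, 1e-8)))
  expect_equal(res$a, -20, tolerance = 1e-6)
  expect_equal(res$d, 4, tolerance = 1e-6)
  expect_equal(res$pve, 100, tolerance = 1e-4) # zero residual limit
  # heterozygote at the midparent: d = 0
  y2 <- c(rep(20, 30), rep(40, 60), rep(60, 30)) +
    withr::with_seed(18, rnorm(120, 0, 5))
  res2 <- f2_single_marker(geno, y2)
  expect_lt(abs(res2$d), 3)
  expect_lt(res2$p, 1e-6)
  # missing classes yield NA effects but a usable test
  res3 <- f2_single_marker(rep(c("AA", "AB"), each = 30),
                           withr::with_seed(19, rnorm(60)))
  expect_true(is.na(res3$a) && is.na(res3$d))
  expect_false(is.na(res3$p))
  expect_error(f2_single_marker(rep("AA", 10), rnorm(10)), "2 genotype")
})

test_that("epistasis ANOVA reproduces hand-computed sums of squares", {
  # balanced 3x3, zero noise, purely additive cell means -> interaction 0
  g1 <- rep(c("AA", "AB", "BB"), each = 9)
  g2 <- rep(rep(c("AA", "AB", "BB"), each = 3), 3)
  mu1 <- c(AA = 10, AB = 5, BB = 0)
  mu2 <- c(AA = 6, AB = 2, BB = 0)
  y_add <- mu1[g1] + mu2[g2]
  tab <- epistasis_anova(g1, g2, y_add)
  expect_equal(tab$anova["interaction", "ss"], 0, tolerance = 1e-9)
  # hand SS for main effects in the balanced case: n_col * sum((row mean
  # - grand mean)^2) etc.
  hand_ss1 <- 9 * sum((tapply(y_add, g1, mean) - mean(y_add))^2)
  hand_ss2 <- 9 * sum((tapply(y_add, g2, mean) - mean(y_add))^2)
  expect_equal(tab$anova["locus1", "ss"], hand_ss1, tolerance = 1e-9)
  expect_equal(tab$anova["locus2", "ss"], hand_ss2, tolerance = 1e-9)
  expect_equal(tab$anova["residual", "ss"], 0, tolerance = 1e-9)
  expect_equal(sum(tab$anova$df), length(y_add) - 1) # total df = n - 1
  expect_equal(tab$n_classes, 9)
  # planted cell deviation lands in the interaction row
  y_int <- y_add
  y_int[g1 == "AA" & g2 == "AA"] <- y_int[g1 == "AA" & g2 == "AA"] + 6
  tab2 <- epistasis_anova(g1, g2, y_int)
  expect_gt(tab2$anova["interaction", "ss"], 0)
})

test_that("empty two-locus cells reduce the interaction df with a note", {
  d <- draw_f2_two_locus(80, a1 = 2, a2 = 1, gamma = 0, sigma = 1,
                         seed = 23)
  drop <- !(d$g1 == "AA" & d$g2 == "AA")
  tab <- epistasis_anova(d$g1[drop], d$g2[drop], d$y[drop])
  expect_equal(tab$n_empty_cells, 1)
  expect_equal(tab$anova["interaction", "df"], 3)
  expect_equal(sum(tab$anova$df), sum(drop) - 1)
})

test_that("model-comparison Type-II SS agree with car::Anova", {
  skip_if_not_installed("car")
  d <- draw_f2_two_locus(175, a1 = 5, a2 = 3, gamma = 2, sigma = 4,
                         seed = 29)
  tab <- epistasis_anova(d$g1, d$g2, d$y)
  ref <- car::Anova(lm(y ~ factor(g1) * factor(g2), data = d), type = 2)
  expect_equal(tab$anova$ss,
               c(ref["factor(g1)", "Sum Sq"], ref["factor(g2)", "Sum Sq"],
                 ref["factor(g1):factor(g2)", "Sum Sq"],
                 ref["Residuals", "Sum Sq"]), tolerance = 1e-9)
  expect_equal(tab$anova$p[1:3],
               c(ref["factor(g1)", "Pr(>F)"], ref["factor(g2)", "Pr(>F)"],
                 ref["factor(g1):factor(g2)", "Pr(>F)"]), tolerance = 1e-9)
})
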