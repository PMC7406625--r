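test_that("window calling implements the 12:3 proportion rule", {
  cfg <- bin_call_config()
  win <- function(a, b, miss = 15 - a - b) {
    c(rep("A", a), rep("B", b), rep("-", miss))
  }
  expect_identical(as.vector(call_windows(win(12, 3), cfg)), "A")
  expect_identical(as.vector(call_windows(win(3, 12), cfg)), "B")
  expect_identical(as.vector(call_windows(win(8, 7), cfg)), "U")
  expect_identical(as.vector(call_windows(win(1, 0), cfg)), "U") # 14 missing
  # proportion form: 8 informative calls split 7:1 is 0.875 >= 0.8
  expect_identical(as.vector(call_windows(win(7, 1), cfg)), "A")
  # H calls are non-informative, like missing: 7 A + 1 B + 7 H behaves
  # exactly like 7 A + 1 B + 7 missing (0.875 of informative -> A)
  expect_identical(as.vector(call_windows(c(rep("A", 7), "B",
                                            rep("H", 7)), cfg)),
                   as.vector(call_windows(win(7, 1), cfg)))
  expect_identical(as.vector(call_windows(c(rep("A", 4), rep("B", 4),
                                            rep("H", 7)), cfg)), "U")
})

test_that("chromosomes shorter than the window become a single window", {
  cfg <- bin_call_config()
  wc <- call_windows(rep("A", 9), cfg)
  expect_length(wc, 1)
  expect_identical(as.vector(wc), "A")
  expect_identical(attr(wc, "width"), 9L)
})

test_that("block collapse places breakpoints at midpoints", {
  # unit-width window calls make the expected geometry unambiguous; the
  # interplay with real multi-marker windows is covered by the oracle test
  fake_windows <- function(calls) {
    structure(calls, starts = seq_along(calls), width = 1L)
  }
  cfg <- bin_call_config()
  pos <- seq(100, 2000, by = 100) # 20 markers
  # homogeneous line: one block, no breakpoints
  cb <- collapse_blocks(fake_windows(rep("A", 20)), pos, 2100, cfg)
  expect_identical(cb$blocks$genotype, "A")
  expect_identical(cb$breakpoints, numeric(0))
  expect_equal(cb$blocks$start, 0)
  expect_equal(cb$blocks$end, 2100)
  expect_equal(cb$blocks$first_marker, 1L)
  expect_equal(cb$blocks$last_marker, 20L)
  # clean A^10 B^10 switch: one breakpoint at the central gap midpoint
  cb <- collapse_blocks(fake_windows(c(rep("A", 10), rep("B", 10))),
                        pos, 2100, cfg)
  expect_identical(cb$blocks$genotype, c("A", "B"))
  expect_equal(cb$breakpoints, (1000 + 1100) / 2)
  expect_equal(cb$blocks$start, c(0, 1050))
  expect_equal(cb$blocks$end, c(1050, 2100))
  # A-run, undetermined-run, B-run: breakpoint at the midpoint of the
  # span between the flanking determined markers
  cb <- collapse_blocks(fake_windows(c(rep("A", 8), rep("U", 4),
                                       rep("B", 8))), pos, 2100, cfg)
  expect_identical(cb$blocks$genotype, c("A", "B"))
  expect_equal(cb$breakpoints, (800 + 1300) / 2)
  # interrupted same-genotype runs merge without a breakpoint
  cb <- collapse_blocks(fake_windows(c(rep("A", 8), rep("U", 4),
                                       rep("A", 8))), pos, 2100, cfg)
  expect_identical(cb$blocks$genotype, "A")
  expect_identical(cb$breakpoints, numeric(0))
  # all-undetermined line: one undetermined block, no breakpoints
  cb <- collapse_blocks(fake_windows(rep("U", 20)), pos, 2100, cfg)
  expect_identical(cb$blocks$genotype, "undetermined")
  expect_identical(cb$breakpoints, numeric(0))
})

test_that("vectorised caller matches the brute-force oracle exactly", {
  cfg <- bin_call_config()
  for (seed in 1:10) {
    m <- random_snp_matrix(10, n_markers = 40 + 16 * seed, seed = seed)
    pos <- m$markers$pos
    len <- max(pos) + 500
    for (i in seq_len(nrow(m$calls))) {
      calls <- m$calls[i, ]
      wc <- call_windows(calls, cfg)
      owc <- oracle_window_calls(calls, cfg)
      expect_identical(as.vector(wc), as.vector(owc))
      cb <- collapse_blocks(wc, pos, len, cfg)
      ocb <- oracle_collapse(owc, pos, len, cfg)
      expect_equal(cb$blocks[, c("genotype", "start", "end")], ocb$blocks)
      expect_equal(cb$breakpoints, ocb$breakpoints)
    }
  }
})

test_that("bin maps partition chromosomes around the breakpoints", {
  cl <- c(chr1 = 30000, chr2 = 50000)
  # no breakpoints: one bin per chromosome
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      line = character(0))
  bm <- build_binmap(empty, cl)
  expect_equal(nrow(bm), 2)
  expect_equal(bm$end - bm$start, unname(cl))
  # stated example: two cuts on a 30-kb chromosome
  bp <- data.frame(chrom = "chr1", pos = c(10000, 20000), line = "L1")
  bm <- build_binmap(bp, cl["chr1"])
  expect_equal(bm$start, c(0, 10000, 20000))
  expect_equal(bm$end, c(10000, 20000, 30000))
  # n unique positions -> n + 1 bins, duplicated positions collapse
  bp <- data.frame(chrom = "chr1", pos = c(5000, 12000, 12000, 24000),
                   line = c("L1", "L1", "L2", "L2"))
  bm <- build_binmap(bp, cl["chr1"])
  expect_equal(nrow(bm), 3 + 1)
  expect_error(build_binmap(data.frame(chrom = "chr1", pos = 40000,
                                       line = "L1"), cl["chr1"]),
               "outside chromosome")
})

test_that("merge tolerance pools nearby breakpoints", {
  bp <- data.frame(chrom = "chr1", pos = c(10000, 10400, 25000),
                   line = c("L1", "L2", "L1"))
  bm <- build_binmap(bp, c(chr1 = 30000), merge_tol = 500)
  expect_equal(nrow(bm), 3)
  expect_equal(bm$start, c(0, 10200, 25000))
})

test_that("bin genotypes project blocks faithfully", {
  pop <- recovery_population(seed = 41, n_lines = 25)
  res <- binmap_from_population(pop)
  bm <- res$binmap
  # partition invariant: disjoint bins summing to the chromosome length
  for (ch in unique(bm$chrom)) {
    b <- bm[bm$chrom == ch, ]
    expect_equal(b$start[-1], b$end[-nrow(b)])
    expect_equal(sum(b$end - b$start),
                 pop$truth$map$chromosomes$length_bp[
                   pop$truth$map$chromosomes$chrom == ch])
  }
  # single-line projection identity: each line's bin calls reproduce its
  # own block genotypes over the bins the block covers
  blocks <- res$line_blocks$blocks
  for (ln in rownames(res$bin_geno)[1:5]) {
    lb <- blocks[blocks$line == ln, ]
    for (k in seq_len(nrow(bm))) {
      blk <- lb[lb$chrom == bm$chrom[k] & lb$start <= bm$start[k] &
                  lb$end >= bm$end[k], ]
      expect_equal(nrow(blk), 1)
      want <- if (blk$genotype == "undetermined") "-" else blk$genotype
      expect_identical(res$bin_geno[ln, bm$bin_id[k]], want)
    }
  }
})

test_that("the breakpoint set and bin map are line-order invariant", {
  pop <- recovery_population(seed = 43, n_lines = 20,
                             markers_per_chrom = 60)
  res1 <- binmap_from_population(pop)
  shuf <- pop
  idx <- rev(seq_len(nrow(pop$geno$calls)))
  shuf$geno$calls <- pop$geno$calls[idx, ]
  res2 <- binmap_from_population(shuf)
  expect_equal(as.data.frame(res1$binmap), as.data.frame(res2$binmap),
               ignore_attr = TRUE)
  expect_identical(res1$bin_geno[rownames(res2$bin_geno), ],
                   res2$bin_geno)
})

test_that("bin summaries use the midpoint median convention", {
  bm <- build_binmap(data.frame(chrom = "chr1", pos = c(1, 3), line = "L"),
                     c(chr1 = 6))
  s <- binmap_summary(bm) # lengths 1, 2, 3
  expect_equal(s$median_bp, 2)
  expect_equal(s$n_bins, 3)
  bm2 <- build_binmap(data.frame(chrom = "chr1", pos = 30000, line = "L"),
                      c(chr1 = 3030000))
  s2 <- binmap_summary(bm2) # lengths 30 kb and 3.0 Mb
  expect_equal(s2$min_bp, 30000)
  expect_equal(s2$max_bp, 3000000)
  one <- build_binmap(data.frame(chrom = character(0), pos = numeric(0),
                                 line = character(0)), c(chr1 = 1000))
  s3 <- binmap_summary(one)
  expect_true(s3$min_bp == s3$median_bp && s3$median_bp == s3$max_bp)
})

test_that("simulated BIL ancestry is recovered bin by bin", {
  pop <- recovery_population(seed = 47, n_lines = 40)
  span_bp <- 15 * 0.5 * 270 * 1000 # window span: 15 markers at 0.5 cM
  keep <- lines_with_long_segments(pop$truth, 2 * span_bp)
  expect_gt(length(keep), 10)
  sub <- pop
  sub$geno$calls <- pop$geno$calls[keep, ]
  sub$truth$ancestry <- pop$truth$ancestry[pop$truth$ancestry$line %in% keep, ]
  sub$truth$line_ids <- keep
  res <- binmap_from_population(sub)
  conc <- truth_bin_concordance(sub$truth, res$binmap, res$bin_geno)
  expect_identical(conc, 1)
})
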