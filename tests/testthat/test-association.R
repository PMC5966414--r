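make_expr <- function(n_genes = 500, n_up = 50, fold = 3, sdlog = 0.15,
                      seed = 55) {
  sheet <- make_sheet("hepatocyte", ages = c(1, 15), reps = 3)
  withr::with_seed(seed, {
    base <- rlnorm(n_genes, log(20), 1)
    vals <- matrix(rep(base, nrow(sheet)), ncol = nrow(sheet))
    up <- seq_len(n_up)
    vals[up, sheet$age_weeks == 15] <- vals[up, sheet$age_weeks == 15] * fold
    vals <- vals * matrix(rlnorm(length(vals), 0, sdlog), nrow(vals))
  })
  rownames(vals) <- sprintf("g%04d", seq_len(n_genes))
  colnames(vals) <- sheet$sample_id
  list(expr = expression_table(vals, sheet),
       up = sprintf("g%04d", seq_len(n_up)))
}

test_that("upregulation rule keeps rising significant genes only", {
  sheet <- make_sheet("hepatocyte", ages = c(1, 15), reps = 3)
  vals <- rbind(c(10, 11, 9, 40, 41, 39),    # clear 4-fold rise
                c(40, 41, 39, 10, 11, 9),    # falls: excluded
                c(10, 10, 10, 12, 12, 12))   # rises < 1.5-fold: excluded
  rownames(vals) <- c("up", "down", "flat")
  colnames(vals) <- sheet$sample_id
  expr <- expression_table(vals, sheet)
  got <- upregulated_genes(expr, 1, 15)
  expect_equal(got, "up")
})

test_that("planted upregulated genes are recovered from noisy expression", {
  fx <- make_expr()
  got <- upregulated_genes(fx$expr, 1, 15)
  expect_gte(sum(fx$up %in% got), 45)
  expect_lte(sum(!got %in% fx$up), 5)
})

test_that("a precomputed DE table takes precedence", {
  fx <- make_expr()
  de <- data.table::data.table(gene_id = c("x1", "x2", "x3"),
                               log2fc = c(2, -2, 1),
                               p = c(0.001, 0.001, 0.2),
                               significant = c(TRUE, TRUE, FALSE))
  expect_equal(upregulated_genes(fx$expr, 1, 15, de_table = de), "x1")
})

test_that("random segments are deterministic and length-proportional", {
  sizes <- c(chr1 = 2e6, chr2 = 1e6)
  expect_equal(nrow(random_segments(sizes, 0, 100)), 0L)
  a <- random_segments(sizes, 50, 100, seed = 9)
  expect_identical(a, random_segments(sizes, 50, 100, seed = 9))
  expect_true(all(a$end - a$start == 100L))
  big <- random_segments(sizes, 10000, 100, seed = 10)
  n1 <- sum(big$chrom == "chr1")
  ## binomial(10000, 2/3)
  expect_lt(abs(n1 - 10000 * 2 / 3), 5 * sqrt(10000 * 2 / 9))
  ## exclusion zones are respected
  excl <- data.table::data.table(chrom = "chr1", start = 0L, end = 1900000L)
  ex <- random_segments(sizes, 200, 100, seed = 11, exclude = excl)
  expect_false(any(ex$chrom == "chr1" & ex$start < 1900000L))
})

test_that("two-proportion z-test matches the formula to high precision", {
  eq <- proportion_ztest(30, 100, 15, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  got <- proportion_ztest(30, 100, 15, 100)
  want <- oracle_ztest(30, 100, 15, 100)
  expect_equal(got$z, want$z, tolerance = 1e-13)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-13)
  ## antisymmetry
  swap <- proportion_ztest(15, 100, 30, 100)
  expect_equal(swap$z, -got$z)
  expect_equal(swap$p_value, got$p_value)
  ## degenerate pooled proportion (all failures or all successes)
  expect_equal(proportion_ztest(0, 10, 0, 10)$z, 0)
  expect_equal(proportion_ztest(0, 10, 0, 10)$p_value, 1)
  expect_equal(proportion_ztest(10, 10, 5, 5)$z, 0)
  expect_error(proportion_ztest(5, 0, 1, 10), "group sizes")
})

enrichment_fixture <- function(n_dmr = 2000, frac_in_up = 0.3, seed = 77) {
  ## sparse gene set: 30 upregulated genes of 5 kb on a 3 Mb toy genome
  ## (~5% of the genome), plus 120 other genes
  sizes <- c(chr1 = 2e6, chr2 = 1e6)
  withr::with_seed(seed, {
    starts1 <- sample.int(190, 100) * 10000L
    starts2 <- sample.int(90, 50) * 10000L
    genes <- data.table::data.table(
      gene_id = sprintf("g%03d", 1:150),
      chrom = c(rep("chr1", 100), rep("chr2", 50)),
      strand = sample(c("+", "-"), 150, TRUE),
      start = c(starts1, starts2))
    genes[, end := start + 5000L]
    genes[, `:=`(tss = ifelse(strand == "+", start, end - 1L),
                 tes = ifelse(strand == "+", end - 1L, start))]
    up <- sample(genes$gene_id, 30)
    n_in <- round(frac_in_up * n_dmr)
    host <- genes[gene_id %in% up][sample.int(30, n_in, replace = TRUE)]
    inside <- data.table::data.table(
      chrom = host$chrom,
      start = host$start + sample.int(4800L, n_in, TRUE))
    inside[, end := start + 150L]
    rest <- random_segments(sizes, n_dmr - n_in, 150L)
    dmrs <- rbind(inside, rest[, .(chrom, start, end)])
  })
  list(dmrs = dmrs, genes = genes, up = up, sizes = sizes)
}

test_that("planted DMR-gene enrichment is detected", {
  fx <- enrichment_fixture()
  res <- dmr_gene_enrichment(fx$dmrs, fx$genes, fx$up, fx$sizes, seed = 3)
  expect_gt(res$prop_dmr, res$prop_bg)
  expect_lt(res$p_value, 1e-6)
  expect_error(dmr_gene_enrichment(fx$dmrs[0], fx$genes, fx$up, fx$sizes),
               "empty")
})

test_that("uniformly placed DMRs show no enrichment", {
  fx <- enrichment_fixture(n_dmr = 400, frac_in_up = 0)
  ps <- sapply(1:20, function(s) {
    dmrs <- random_segments(fx$sizes, 400, 150L, seed = 1000 + s)
    dmr_gene_enrichment(dmrs, fx$genes, fx$up, fx$sizes,
                        seed = 2000 + s)$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("foreground equal to background gives a null statistic", {
  fx <- enrichment_fixture(n_dmr = 300)
  segs <- random_segments(fx$sizes, 300, 150L, seed = 5)
  ## the background draw with the same seed reproduces the foreground,
  ## so both groups pass through identical assignment logic
  res <- dmr_gene_enrichment(segs, fx$genes, fx$up, fx$sizes, seed = 5)
  expect_equal(res$z, 0)
  expect_equal(res$prop_dmr, res$prop_bg)
})
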