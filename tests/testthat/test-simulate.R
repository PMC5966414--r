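test_that("fixed seeds reproduce the dataset exactly", {
  a <- quick_sim(seed = 3, n_tiles = 400, n_genes = 10,
                 n_prenatal = 4, n_early = 4, n_late = 4, n_denovo = 2)
  b <- quick_sim(seed = 3, n_tiles = 400, n_genes = 10,
                 n_prenatal = 4, n_early = 4, n_late = 4, n_denovo = 2)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  c_ <- quick_sim(seed = 4, n_tiles = 400, n_genes = 10,
                  n_prenatal = 4, n_early = 4, n_late = 4, n_denovo = 2)
  expect_false(identical(a$calls, c_$calls))
})

test_that("a null configuration has no tissue-specific structure in truth", {
  sim <- quick_sim(seed = 5, n_tiles = 400, n_genes = 10,
                   n_prenatal = 0, n_early = 0, n_late = 0, n_denovo = 0)
  tt <- sim$truth$tiles
  expect_true(all(tt$class %in% c("background", "island")))
  for (a in sim$config$ages_weeks) {
    expect_equal(tt[[paste0("mu_target_", a, "w")]], tt$mu_other)
  }
})

test_that("empirical tile means track the ground truth", {
  sim <- quick_sim(seed = 6)
  tm <- tile_samples(sim$calls, sim$sheet)
  tt <- sim$truth$tiles
  idx <- match(tt$tile_id, rownames(tm$pct))
  ## pooled adult replicates of target and one non-target tissue; tiles
  ## surviving dropout in a single replicate (~150 reads) have a binomial
  ## standard error near 3 points, so the tight envelope is asserted on
  ## tiles seen in at least two replicates
  for (tis in c("hepatocyte", "lung")) {
    cols <- which(tm$samples$tissue == tis & tm$samples$age_weeks == 15)
    emp <- rowMeans(tm$pct[idx, cols], na.rm = TRUE)
    nrep <- rowSums(!is.na(tm$pct[idx, cols]))
    want <- 100 * (if (tis == "hepatocyte") tt$mu_target_15w else tt$mu_other)
    off <- abs(emp - want)
    expect_gte(mean(off[nrep >= 2] <= 5, na.rm = TRUE), 0.99)
    expect_gte(mean(off[nrep >= 1] <= 5, na.rm = TRUE), 0.95)
  }
})

test_that("planted trajectory classes behave as specified in truth", {
  sim <- quick_sim(seed = 8)
  tt <- sim$truth$tiles
  expect_true(all(tt[class == "prenatal",
                     c(mu_target_1w, mu_target_3w, mu_target_15w)] < 0.05))
  expect_true(all(tt[class == "early", mu_target_1w] > 0.5 &
                    tt[class == "early", mu_target_3w] < 0.5))
  expect_true(all(tt[class == "late", mu_target_3w] > 0.5 &
                    tt[class == "late", mu_target_15w] < 0.5))
  expect_true(all(tt[class %in% c("prenatal", "early", "late"),
                     mu_other] > 0.5))
  expect_true(all(tt[class == "denovo", mu_other] < 0.5))
})

test_that("genotype modes freeze the right trajectories with shared truth", {
  wt <- quick_sim(seed = 9)
  dko <- quick_sim(seed = 9, dko_mode = TRUE)
  insr <- quick_sim(seed = 9, insr_mode = TRUE)
  ## layout is identical across genotypes of one seed
  expect_equal(wt$truth$tiles$class, dko$truth$tiles$class)
  expect_equal(wt$truth$tiles$class, insr$truth$tiles$class)
  w <- wt$truth$tiles; d <- dko$truth$tiles; i <- insr$truth$tiles
  ## DKO: early and late tiles stay at the newborn (methylated) state
  expect_true(all(d[class %in% c("early", "late"), mu_target_15w] > 0.5))
  ## InsR: late blocked, early proceeds
  expect_true(all(i[class == "late", mu_target_15w] > 0.5))
  expect_true(all(i[class == "early", mu_target_15w] < 0.5))
  expect_true(all(w[class %in% c("early", "late"), mu_target_15w] < 0.5))
})

test_that("written files round-trip through the standard readers", {
  dir <- tempfile("simout")
  sim <- quick_sim(seed = 10, n_tiles = 300, n_genes = 5,
                   gene_length = 2000, gene_gap = 2000,
                   n_prenatal = 2, n_early = 2, n_late = 2, n_denovo = 2,
                   out_dir = dir)
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_equal(sheet$sample_id, sim$sheet$sample_id)
  sid <- sheet$sample_id[1]
  back <- read_cpg_calls(sheet[sample_id == sid, path], "bismark_cov")
  expect_equal(back$pos, sim$calls[[sid]]$pos)
  expect_equal(back$meth_reads, sim$calls[[sid]]$meth_reads)
  expect_equal(back$total_reads, sim$calls[[sid]]$total_reads)
  genes <- read_gene_models(file.path(dir, "genes.bed"), "bed12")
  expect_equal(nrow(genes), nrow(sim$genes))
  expect_equal(genes$tss, sim$genes$tss)
})

test_that("linked genes are induced from their onset age", {
  sim <- quick_sim(seed = 12)
  expr <- simulate_expression(sim)
  tg <- sim$truth$genes
  age_mean <- function(g, a)
    mean(expr$values[g, expr$samples$age_weeks == a])
  late_genes <- tg[class == "late", gene_id]
  for (g in head(late_genes, 5)) {
    expect_lt(age_mean(g, 3) / age_mean(g, 1), 1.5)
    expect_gt(age_mean(g, 15) / age_mean(g, 1), 2)
  }
  early_genes <- tg[class == "early", gene_id]
  for (g in head(early_genes, 5)) {
    expect_gt(age_mean(g, 3) / age_mean(g, 1), 2)
  }
  ## unlinked genes drift by noise only
  unlinked <- setdiff(rownames(expr$values), tg$gene_id)
  lfc <- sapply(unlinked, function(g) abs(log(age_mean(g, 15) /
                                                age_mean(g, 1))))
  expect_lt(mean(lfc), 0.2)
  ## DKO attenuates the induction of linked genes
  dko <- quick_sim(seed = 12, dko_mode = TRUE)
  edko <- simulate_expression(dko)
  g <- late_genes[1]
  wt_fold <- age_mean(g, 15) / age_mean(g, 1)
  dk_fold <- mean(edko$values[g, edko$samples$age_weeks == 15]) /
    mean(edko$values[g, edko$samples$age_weeks == 1])
  expect_lt(dk_fold, wt_fold)
  expect_gt(dk_fold, 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_tiles = 10, n_prenatal = 20), "exceed")
  expect_error(sim_config(effect_delta = 0), "effect_delta")
  expect_error(sim_config(effect_delta = 95), "background mean")
})
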