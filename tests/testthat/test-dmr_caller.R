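test_that("tissue means average replicates and respect missingness", {
  sheet <- make_sheet(c("liver", "liver2"), reps = 2)
  sheet$tissue <- c("liver", "liver", "lung", "lung")
  withr::with_seed(3, {
    pct <- matrix(round(runif(80, 0, 100)), 20, 4)
    pct[sample.int(80, 12)] <- NA
  })
  tm <- make_tm(pct, sheet)
  means <- tissue_means(tm)
  ## brute-force group means
  for (i in seq_len(20)) {
    for (tis in c("liver", "lung")) {
      v <- tm$pct[i, sheet$tissue == tis]
      want <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      expect_equal(unname(means[i, tis]), want)
    }
  }
  ## two replicates 40 and 60 average to 50; a single replicate is itself
  tm2 <- make_tm(matrix(c(40, 60, 30, NA), 1, 4), sheet)
  m2 <- tissue_means(tm2)
  expect_equal(unname(m2[1, "liver"]), 50)
  expect_equal(unname(m2[1, "lung"]), 30)
})

specific_means <- function(target, others) {
  m <- matrix(c(target, others), nrow = 1,
              dimnames = list(NULL, c("liver", paste0("t", seq_along(others)))))
  attr(m, "tiles") <- data.table::data.table(chrom = "chr1", start = 0L,
                                             end = 100L)
  m
}

test_that("tissue-specific calling follows the 5-of-panel delta rule", {
  ## 7 of 8 tissues at least 50 points above the target -> called
  m <- specific_means(10, c(70, 75, 80, 90, 65, 60, 58, 85))
  got <- call_tissue_specific(m, "liver", "hypo")
  expect_equal(nrow(got), 1L)
  expect_equal(got$n_discriminating,
               sum(c(70, 75, 80, 90, 65, 60, 58, 85) - 10 >= 50))
  expect_equal(got$n_discriminating, 7L)

  ## only 1 of 8 differs by >= 50 -> not called
  m2 <- specific_means(10, c(55, 58, 45, 50, 40, 30, 20, 35))
  expect_equal(nrow(call_tissue_specific(m2, "liver", "hypo")), 0L)

  ## all tissues equal -> called in neither direction
  m3 <- specific_means(80, rep(80, 8))
  expect_equal(nrow(call_tissue_specific(m3, "liver", "hypo")), 0L)
  expect_equal(nrow(call_tissue_specific(m3, "liver", "denovo")), 0L)

  ## the threshold is inclusive
  m4 <- specific_means(10, c(60, 60, 60, 60, 60, 10, 10, 10))
  expect_equal(nrow(call_tissue_specific(m4, "liver", "hypo")), 1L)
})

test_that("tiles with too few informative tissues are reported untestable", {
  m <- specific_means(10, c(70, 75, NA, NA, NA, NA, 80, NA))
  got <- call_tissue_specific(m, "liver", "hypo")
  expect_equal(nrow(got), 0L)
  expect_equal(nrow(attr(got, "untestable")), 1L)
  expect_error(call_tissue_specific(m, "kidney", "hypo"), "absent")
})

test_that("the per-tile exact test matches hypergeometric enumeration", {
  expect_lt(tile_test(c(90, 100), c(20, 100)), 1e-15)
  expect_equal(tile_test(c(50, 100), c(50, 100)), 1)
  expect_equal(tile_test(c(6, 10), c(4, 10)), oracle_fisher2x2(6, 10, 4, 10),
               tolerance = 1e-12)
  expect_error(tile_test(c(0, 0), c(5, 10)), "total reads")
})

test_that("postnatal timing follows the delta, significance and boundary rules", {
  sheet <- make_sheet("liver", ages = c(1, 3, 15))
  pct <- rbind(c(85, 80, 15),   # drop of 70, not yet at 3 wk -> late
               c(85, 20, 15),   # drop achieved by 3 wk -> early
               c(3, 3, 2),      # already unmethylated in newborns
               c(50, 50, 48))   # no postnatal change
  tm <- make_tm(pct, sheet)
  dmrs <- data.table::data.table(
    chrom = tm$tiles$chrom, start = tm$tiles$start, end = tm$tiles$end,
    category = "tissue_hypo", n_discriminating = 8L,
    target_mean = pct[, 3], timing = "none",
    delta_newborn_adult = NA_real_, p_tile = NA_real_)
  got <- call_postnatal(tm, dmrs, "liver")
  expect_equal(got$timing, c("late_postnatal", "early_postnatal",
                             "prenatal", "none"))
  expect_equal(got$delta_newborn_adult, c(70, 70, 1, 2))
  ## without a boundary-age sample the early/late split is unavailable
  tm2 <- make_tm(pct[, c(1, 3)], make_sheet("liver", ages = c(1, 15)),
                 tiles = tm$tiles)
  got2 <- call_postnatal(tm2, dmrs, "liver")
  expect_equal(got2$timing, c("early_or_late_unknown",
                              "early_or_late_unknown", "prenatal", "none"))
})

test_that("a large delta without statistical support is not called postnatal", {
  sheet <- make_sheet("liver", ages = c(1, 3, 15))
  pct <- matrix(c(80, 40, 20), 1)
  tm <- make_tm(pct, sheet, depth = 5L)  # 4/5 vs 1/5: Fisher p > 0.05
  dmrs <- data.table::data.table(
    chrom = tm$tiles$chrom, start = tm$tiles$start, end = tm$tiles$end,
    category = "tissue_hypo", n_discriminating = 8L, target_mean = 20,
    timing = "none", delta_newborn_adult = NA_real_, p_tile = NA_real_)
  got <- call_postnatal(tm, dmrs, "liver")
  expect_equal(got$timing, "none")
  expect_gt(got$p_tile, 0.05)
})

test_that("swapping methylated and unmethylated maps hypo onto denovo calls", {
  sim <- quick_sim(seed = 13)
  tm <- tile_samples(sim$calls, sim$sheet)
  flip <- tm
  flip$pct <- 100 - tm$pct
  flip$meth <- tm$total - tm$meth
  hypo <- call_postnatal(tm, call_tissue_specific(
    tissue_means(tm, 15), "hepatocyte", "hypo"), "hepatocyte")
  denovo <- call_postnatal(flip, call_tissue_specific(
    tissue_means(flip, 15), "hepatocyte", "denovo"), "hepatocyte")
  expect_equal(hypo[, .(chrom, start, end)], denovo[, .(chrom, start, end)])
  expect_equal(hypo$n_discriminating, denovo$n_discriminating)
  expect_equal(hypo$timing, denovo$timing)
  expect_equal(hypo$p_tile, denovo$p_tile)
})

test_that("each called tile receives exactly one timing label", {
  sim <- quick_sim(seed = 17)
  tm <- tile_samples(sim$calls, sim$sheet)
  dmrs <- call_postnatal(tm, call_tissue_specific(
    tissue_means(tm, 15), "hepatocyte", "hypo"), "hepatocyte")
  expect_true(all(dmrs$timing %in% c("prenatal", "early_postnatal",
                                     "late_postnatal", "none")))
  expect_equal(nrow(dmrs), length(dmrs$timing))
  ## postnatal labels satisfy the delta and significance invariants
  post <- dmrs[timing %in% c("early_postnatal", "late_postnatal")]
  expect_true(all(post$delta_newborn_adult >= 35))
  expect_true(all(post$p_tile < 0.05))
  expect_true(all(dmrs[timing == "prenatal", pct_newborn] < 5))
})
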