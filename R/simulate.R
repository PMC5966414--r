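## Beta-binomial simulator of multi-tissue, multi-age bisulfite datasets
## with known ground truth. Each tile carries a true methylation mean per
## (tissue, age); per CpG site and sample a methylation probability is
## drawn from a Beta around that mean, read depth from a shifted Poisson,
## and methylated reads from a Binomial. RRBS sparsity is emulated as
## tile-level dropout. Planted trajectory classes in the target tissue:
## prenatal (low at all ages), early postnatal (high at 1 wk, low from the
## 3-wk boundary), late postnatal (high through 3 wk, low only in adults),
## and constitutive de novo (high in the target, low elsewhere). dko_mode
## freezes the target tissue at its newborn state (no postnatal
## transitions); insr_mode freezes only late-class tiles.

#' Simulation configuration
#'
#' All distributions and effect sizes are generator choices exposed here;
#' defaults describe a 9-tissue, 3-age RRBS-like design with 3 replicates,
#' mean depth 30x and 200 planted target-hypomethylated tiles at a 60-point
#' effect.
#'
#' @param n_tissues Number of tissues (default 9, target included).
#' @param target_tissue Name of the target tissue (default "hepatocyte").
#' @param ages_weeks Ages sampled per tissue (default 1, 3, 15 weeks).
#' @param n_replicates Replicates per (tissue, age) (default 3).
#' @param n_tiles Number of genomic tiles on the simulated grid.
#' @param tile_size Tile width in bp (default 100).
#' @param depth_mean Mean read depth per CpG site (default 30).
#' @param missing_frac Probability a tile is unobserved in a sample
#'   (RRBS-like dropout; default 0.2).
#' @param cpg_per_tile Range (min, max) of CpG sites per covered tile.
#' @param n_prenatal,n_early,n_late Planted target-hypo tiles per timing
#'   class (defaults 60/70/70; 200 total).
#' @param n_denovo Planted target de novo methylated tiles (default 50).
#' @param effect_delta Methylation difference between the target and other
#'   tissues at planted tiles, percentage points (default 60).
#' @param bg_mean,bg_concentration Beta parameters of per-tile background
#'   methylation (mean 0.85, modest dispersion).
#' @param site_concentration Beta concentration of per-site noise around
#'   the tile mean.
#' @param island_frac,island_mean Fraction and mean methylation of
#'   hypomethylated-island tiles (low in every tissue).
#' @param prenatal_level Target-tissue methylation of prenatal tiles (kept
#'   below 5 percent at all ages; default 0.03).
#' @param n_genes,gene_length,gene_gap Gene-model layout (count, body
#'   length, minimum spacing, bp).
#' @param linked_frac Fraction of planted hypo tiles placed inside a gene
#'   body and linked to its expression (default 0.5).
#' @param expr_fold Expression fold-change of linked genes from their onset
#'   age (default 3).
#' @param expr_sdlog,expr_base_meanlog,expr_base_sdlog Log-normal
#'   replicate noise and baseline expression parameters.
#' @param dko_attenuation In dko_mode, multiplier on the log fold-change of
#'   linked genes (default 0.5).
#' @param dko_mode Freeze the target tissue at its newborn methylation
#'   state at every age (no postnatal demethylation or de novo gain).
#' @param insr_mode Freeze only late-class tiles (demethylation after the
#'   3-week boundary is blocked; early transitions proceed).
#' @param late_age_boundary_weeks Early/late boundary age (default 3).
#' @param n_chrom Number of simulated chromosomes (default 5).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_tissues = 9L, target_tissue = "hepatocyte",
                       ages_weeks = c(1, 3, 15), n_replicates = 3L,
                       n_tiles = 20000L, tile_size = 100L,
                       depth_mean = 30, missing_frac = 0.2,
                       cpg_per_tile = c(5L, 15L),
                       n_prenatal = 60L, n_early = 70L, n_late = 70L,
                       n_denovo = 50L, effect_delta = 60,
                       bg_mean = 0.85, bg_concentration = 30,
                       site_concentration = 60,
                       island_frac = 0.10, island_mean = 0.08,
                       prenatal_level = 0.03,
                       n_genes = 500L, gene_length = 5000L,
                       gene_gap = 5000L, linked_frac = 0.5,
                       expr_fold = 3, expr_sdlog = 0.15,
                       expr_base_meanlog = log(20), expr_base_sdlog = 1,
                       dko_attenuation = 0.5,
                       dko_mode = FALSE, insr_mode = FALSE,
                       late_age_boundary_weeks = 3,
                       n_chrom = 5L, seed = 1L) {
  n_planted <- n_prenatal + n_early + n_late + n_denovo
  .assert(n_planted <= n_tiles, "planted tiles (%d) exceed n_tiles (%d)",
          n_planted, n_tiles)
  .assert(effect_delta > 0 && effect_delta <= 100,
          "effect_delta must be in (0, 100]")
  .assert(bg_mean - effect_delta / 100 >= 0,
          "effect_delta larger than the background mean allows")
  .assert(n_tissues >= 2, "need at least two tissues")
  tissues <- c("hepatocyte", "lung", "heart", "neutrophil", "brain", "fat",
               "hippocampus", "kidney", "spleen",
               paste0("tissue", seq_len(max(0, n_tissues - 9))))[seq_len(n_tissues)]
  if (!target_tissue %in% tissues) tissues[1] <- target_tissue
  cfg <- list(n_tissues = as.integer(n_tissues), tissues = tissues,
              target_tissue = target_tissue,
              ages_weeks = sort(ages_weeks),
              n_replicates = as.integer(n_replicates),
              n_tiles = as.integer(n_tiles),
              tile_size = as.integer(tile_size),
              depth_mean = depth_mean, missing_frac = missing_frac,
              cpg_per_tile = as.integer(cpg_per_tile),
              n_prenatal = as.integer(n_prenatal),
              n_early = as.integer(n_early), n_late = as.integer(n_late),
              n_denovo = as.integer(n_denovo), effect_delta = effect_delta,
              bg_mean = bg_mean, bg_concentration = bg_concentration,
              site_concentration = site_concentration,
              island_frac = island_frac, island_mean = island_mean,
              prenatal_level = prenatal_level,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              gene_gap = as.integer(gene_gap),
              linked_frac = linked_frac, expr_fold = expr_fold,
              expr_sdlog = expr_sdlog,
              expr_base_meanlog = expr_base_meanlog,
              expr_base_sdlog = expr_base_sdlog,
              dko_attenuation = dko_attenuation,
              dko_mode = isTRUE(dko_mode), insr_mode = isTRUE(insr_mode),
              late_age_boundary_weeks = late_age_boundary_weeks,
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Named simulation presets
#'
#' \code{rrbs}: the default design. \code{wgbs}: 200-bp tiles.
#' \code{null}: no planted tiles (fully label-exchangeable).
#' \code{dko} / \code{insr}: genotype modes freezing all, or only late,
#' postnatal transitions.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [sim_config()].
#' @return A \code{sim_config}.
#' @export
sim_preset <- function(preset = c("rrbs", "wgbs", "null", "dko", "insr"),
                       ...) {
  preset <- match.arg(preset)
  switch(preset,
         rrbs = sim_config(...),
         wgbs = sim_config(tile_size = 200L, ...),
         null = sim_config(n_prenatal = 0L, n_early = 0L, n_late = 0L,
                           n_denovo = 0L, ...),
         dko = sim_config(dko_mode = TRUE, ...),
         insr = sim_config(insr_mode = TRUE, ...))
}

## Genome layout: tile grid, gene placement, planted-class assignment and
## true per-(tissue, age) methylation means. Deterministic given the seed;
## identical across genotype modes of the same seed, so a WT / DKO / InsR
## trio shares one truth table.
.sim_layout <- function(cfg) {
  spacing <- 3L * cfg$tile_size
  offset <- 20000L
  per_chrom <- rep(cfg$n_tiles %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_tiles %% cfg$n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_sizes <- setNames(2L * offset + per_chrom * spacing, chroms)

  tiles <- data.table::rbindlist(lapply(seq_len(cfg$n_chrom), function(i) {
    data.table::data.table(
      chrom = chroms[i],
      start = offset + (seq_len(per_chrom[i]) - 1L) * spacing)
  }))
  tiles[, end := start + cfg$tile_size]
  tiles[, tile_id := .tile_key(chrom, start, end)]
  n <- nrow(tiles)

  ## genes: one per sampled block of (gene_length + gene_gap) bp
  block <- cfg$gene_length + cfg$gene_gap
  gene_rows <- data.table::rbindlist(lapply(seq_len(cfg$n_chrom), function(i) {
    n_blocks <- (chrom_sizes[i] - 2L * offset) %/% block
    data.table::data.table(chrom = chroms[i],
                           block_start = offset + (seq_len(n_blocks) - 1L) * block)
  }))
  .assert(nrow(gene_rows) >= cfg$n_genes,
          "genome too small for %d genes; reduce n_genes or gene spacing",
          cfg$n_genes)
  pick <- sort(sample.int(nrow(gene_rows), cfg$n_genes))
  genes <- gene_rows[pick]
  genes[, `:=`(start = block_start, end = block_start + cfg$gene_length,
               strand = sample(c("+", "-"), .N, replace = TRUE))]
  genes[, block_start := NULL]
  genes <- .order_tiles(genes)
  genes[, gene_id := sprintf("gene_%04d", .I)]
  genes[, `:=`(tss = ifelse(strand == "+", start, end - 1L),
               tes = ifelse(strand == "+", end - 1L, start))]

  ## which tiles lie fully inside a gene body
  hit <- GenomicRanges::findOverlaps(
    .as_gr(tiles[, .(chrom, start, end)]),
    .as_gr(genes[, .(chrom, start, end)]), type = "within")
  tile_gene <- rep(NA_character_, n)
  tile_gene[S4Vectors::queryHits(hit)] <- genes$gene_id[S4Vectors::subjectHits(hit)]

  ## planted classes; linked hypo tiles go inside distinct genes
  class <- rep("background", n)
  gene_of <- rep(NA_character_, n)
  hypo_counts <- c(prenatal = cfg$n_prenatal, early = cfg$n_early,
                   late = cfg$n_late)
  n_link <- round(cfg$linked_frac * hypo_counts)
  genic_tiles <- which(!is.na(tile_gene))
  cand_genes <- unique(tile_gene[genic_tiles])
  .assert(sum(n_link) <= length(cand_genes),
          "not enough genes with contained tiles for the linked fraction")
  linked_genes <- sample(cand_genes, sum(n_link))
  linked_tiles <- vapply(linked_genes, function(g) {
    opts <- genic_tiles[tile_gene[genic_tiles] == g]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, integer(1))
  lk_class <- rep(names(hypo_counts), n_link)
  class[linked_tiles] <- lk_class
  gene_of[linked_tiles] <- linked_genes

  free <- setdiff(seq_len(n), linked_tiles)
  n_unlinked <- c(hypo_counts - n_link, denovo = cfg$n_denovo)
  un_tiles <- sample(free, sum(n_unlinked))
  class[un_tiles] <- rep(names(n_unlinked), n_unlinked)
  free <- setdiff(free, un_tiles)
  n_island <- round(cfg$island_frac * n)
  isl <- sample(free, min(n_island, length(free)))
  class[isl] <- "island"

  ## true means: mu_other per tile (all non-target tissues, all ages) and
  ## mu_target per (tile, age)
  high <- cfg$bg_mean
  low <- cfg$bg_mean - cfg$effect_delta / 100
  bc <- cfg$bg_concentration
  baseline <- rbeta(n, cfg$bg_mean * bc, (1 - cfg$bg_mean) * bc)
  baseline[class == "island"] <- rbeta(sum(class == "island"),
                                       cfg$island_mean * bc,
                                       (1 - cfg$island_mean) * bc)
  mu_other <- baseline
  mu_other[class %in% c("prenatal", "early", "late")] <- high
  mu_other[class == "denovo"] <- low

  ages <- cfg$ages_weeks
  bnd <- cfg$late_age_boundary_weeks
  mu_target <- matrix(rep(baseline, length(ages)), ncol = length(ages),
                      dimnames = list(NULL, paste0("age_", ages)))
  for (j in seq_along(ages)) {
    a <- ages[j]
    mu_target[class == "prenatal", j] <- cfg$prenatal_level
    mu_target[class == "early", j] <- if (a >= bnd) low else high
    mu_target[class == "late", j] <- if (a > bnd) low else high
    mu_target[class == "denovo", j] <- high
  }
  if (cfg$dko_mode) {
    frozen <- class %in% c("early", "late", "denovo")
    mu_target[frozen, ] <- mu_target[frozen, 1L]
  } else if (cfg$insr_mode) {
    mu_target[class == "late", ] <- mu_target[class == "late", 1L]
  }

  ## CpG sites: fixed positions shared by all samples
  n_sites <- sample(seq(cfg$cpg_per_tile[1], cfg$cpg_per_tile[2]),
                    n, replace = TRUE)
  even <- seq(0L, cfg$tile_size - 2L, by = 2L)
  offsets <- lapply(n_sites, function(k) sort(sample(even, k)))
  sites <- data.table::data.table(
    tile_idx = rep(seq_len(n), n_sites),
    pos = rep(tiles$start, n_sites) + unlist(offsets))
  sites[, chrom := tiles$chrom[tile_idx]]

  truth_tiles <- cbind(tiles, data.table::data.table(
    class = class, gene_id = gene_of, mu_other = mu_other))
  for (j in seq_along(ages))
    truth_tiles[[paste0("mu_target_", ages[j], "w")]] <- mu_target[, j]

  onset <- c(prenatal = min(ages), early = bnd,
             late = suppressWarnings(min(ages[ages > bnd])))
  truth_genes <- data.table::data.table(
    gene_id = gene_of[linked_tiles],
    class = lk_class,
    linked_tile = tiles$tile_id[linked_tiles],
    fold = cfg$expr_fold,
    onset_age = unname(onset[lk_class]))

  list(tiles = tiles, genes = genes, chrom_sizes = chrom_sizes,
       class = class, mu_other = mu_other, mu_target = mu_target,
       sites = sites, truth_tiles = truth_tiles, truth_genes = truth_genes)
}

#' Simulate a multi-tissue, multi-age bisulfite dataset
#'
#' Generates per-sample CpG call tables (Bismark-coverage-like, strand
#' combined), the sample sheet, gene models, chromosome sizes and the
#' ground-truth tables. With \code{out_dir}, also writes everything to
#' disk: one \code{<sample_id>.cov} per sample, \code{sample_sheet.tsv}
#' (with a \code{path} column), \code{genes.bed} (BED12),
#' \code{chrom_sizes.tsv}, \code{truth_tiles.tsv}, \code{truth_genes.tsv}.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return A \code{sim_dataset} list: \code{config}, \code{sheet},
#'   \code{calls} (named list of call tables), \code{truth} (tile and gene
#'   truth tables), \code{genes}, \code{chrom_sizes}.
#' @export
simulate_methylomes <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  layout <- .with_seed(.derive_seed(cfg$seed, 1L), .sim_layout(cfg))

  genotype <- if (cfg$dko_mode) "DKO" else if (cfg$insr_mode) "InsR-KO" else "WT"
  sheet <- data.table::CJ(tissue = cfg$tissues, age_weeks = cfg$ages_weeks,
                          replicate = paste0("r", seq_len(cfg$n_replicates)),
                          sorted = FALSE)
  sheet[, `:=`(sample_id = sprintf("%s_%gw_%s", tissue, age_weeks, replicate),
               genotype = genotype)]
  data.table::setcolorder(sheet, c("sample_id", "tissue", "age_weeks",
                                   "genotype", "replicate"))

  ages <- cfg$ages_weeks
  sites <- layout$sites
  conc <- cfg$site_concentration
  calls <- .with_seed(.derive_seed(cfg$seed, 2L), {
    out <- vector("list", nrow(sheet))
    names(out) <- sheet$sample_id
    for (s in seq_len(nrow(sheet))) {
      is_target <- sheet$tissue[s] == cfg$target_tissue
      aj <- match(sheet$age_weeks[s], ages)
      mu_tile <- if (is_target) layout$mu_target[, aj] else layout$mu_other
      keep_tile <- runif(cfg$n_tiles) >= cfg$missing_frac
      sub <- sites[keep_tile[tile_idx]]
      mu <- pmin(pmax(mu_tile[sub$tile_idx], 1e-3), 1 - 1e-3)
      depth <- 1L + rpois(nrow(sub), cfg$depth_mean - 1)
      prob <- rbeta(nrow(sub), mu * conc, (1 - mu) * conc)
      meth <- rbinom(nrow(sub), depth, prob)
      out[[s]] <- data.table::data.table(
        chrom = sub$chrom, pos = sub$pos, strand = "+",
        meth_reads = as.integer(meth), total_reads = as.integer(depth))
    }
    out
  })

  sim <- structure(list(config = cfg, sheet = sheet, calls = calls,
                        truth = list(tiles = layout$truth_tiles,
                                     genes = layout$truth_genes),
                        genes = layout$genes,
                        chrom_sizes = layout$chrom_sizes),
                   class = "sim_dataset")
  if (!is.null(out_dir)) .write_sim(sim, out_dir)
  sim
}

.write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(sim$calls))
  for (i in seq_along(sim$calls)) {
    sid <- names(sim$calls)[i]
    dt <- sim$calls[[i]]
    cov <- dt[, .(chrom, start1 = pos + 1L, end1 = pos + 1L,
                  pct = 100 * meth_reads / total_reads,
                  n_meth = meth_reads,
                  n_unmeth = total_reads - meth_reads)]
    paths[i] <- file.path(out_dir, paste0(sid, ".cov"))
    data.table::fwrite(cov, paths[i], sep = "\t", col.names = FALSE,
                       quote = FALSE)
  }
  sheet_out <- data.table::copy(sim$sheet)
  sheet_out[, path := paths]
  data.table::fwrite(sheet_out, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE)
  g <- sim$genes
  bed12 <- data.table::data.table(
    g$chrom, g$start, g$end, g$gene_id, 0L, g$strand, g$start, g$end,
    "0", 1L, paste0(g$end - g$start, ","), "0,")
  data.table::fwrite(bed12, file.path(out_dir, "genes.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  data.table::fwrite(
    data.table::data.table(chrom = names(sim$chrom_sizes),
                           length = as.integer(sim$chrom_sizes)),
    file.path(out_dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(sim$truth$tiles, file.path(out_dir, "truth_tiles.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(out_dir)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "sim_dataset: %d tissues x ages {%s} x %d replicates, %d tiles\n",
    cfg$n_tissues, paste(cfg$ages_weeks, collapse = ", "),
    cfg$n_replicates, cfg$n_tiles))
  tab <- table(x$truth$tiles$class)
  cat("tile classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulate an expression table linked to the methylation ground truth
#'
#' Target-tissue samples only. Baseline expression is log-normal; genes
#' linked to planted tiles are multiplied by the configured fold change in
#' samples at or beyond the class onset age (prenatal: from the first age;
#' early: from the 3-week boundary; late: adults only). In dko_mode the
#' log fold-change of linked genes is attenuated by
#' \code{dko_attenuation}, emulating the blunted postnatal induction when
#' demethylation is prevented. Replicate noise is log-normal.
#'
#' @param sim A \code{sim_dataset}.
#' @return An [expression_table()] over all simulated genes and the target
#'   tissue's samples.
#' @export
simulate_expression <- function(sim) {
  stopifnot(inherits(sim, "sim_dataset"))
  cfg <- sim$config
  samples <- sim$sheet[tissue == cfg$target_tissue]
  gene_ids <- sim$genes$gene_id
  tg <- sim$truth$genes
  lfc <- log(cfg$expr_fold)
  if (cfg$dko_mode) lfc <- lfc * cfg$dko_attenuation
  .with_seed(.derive_seed(cfg$seed, 3L), {
    base <- rlnorm(length(gene_ids), cfg$expr_base_meanlog,
                   cfg$expr_base_sdlog)
    vals <- matrix(rep(base, nrow(samples)), ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
    li <- match(tg$gene_id, gene_ids)
    for (j in seq_len(nrow(samples))) {
      induced <- li[samples$age_weeks[j] >= tg$onset_age]
      vals[induced, j] <- vals[induced, j] * exp(lfc)
    }
    noise <- matrix(rlnorm(length(vals), 0, cfg$expr_sdlog),
                    nrow = nrow(vals))
    expression_table(vals * noise, samples)
  })
}
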