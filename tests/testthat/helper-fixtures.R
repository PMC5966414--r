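## Fixtures are built in code at test time; nothing is stored on disk.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## Five hand-constructed methratio-style rows (1-based positions).
methratio_fixture <- function() {
  write_lines_tmp(c(
    "chr\tpos\tstrand\tcontext\tratio\teff_CT\tC_count\tCT_count",
    "chr1\t101\t+\tCG\t0.250\t12.0\t3\t12",
    "chr1\t150\t+\tCG\t0.500\t10.0\t5\t10",
    "chr1\t151\t-\tCG\t0.400\t10.0\t4\t10",
    "chr2\t75\t+\tCHH\t0.100\t10.0\t1\t10",
    "chr2\t300\t-\tCG\t1.000\t8.0\t8\t8"))
}

## A small sample-sheet data.table.
make_sheet <- function(tissues, ages = 15, reps = 1, genotype = "WT") {
  grid <- data.table::CJ(tissue = tissues, age_weeks = ages,
                         replicate = paste0("r", seq_len(reps)),
                         sorted = FALSE)
  grid[, `:=`(sample_id = sprintf("%s_%gw_%s", tissue, age_weeks, replicate),
              genotype = genotype)]
  data.table::setcolorder(grid, c("sample_id", "tissue", "age_weeks",
                                  "genotype", "replicate"))
  grid[]
}

## Build a tile_matrix directly from a tiles x samples percent matrix,
## fabricating counts at the given read depth so pooled-count tests have
## consistent data (meth = round(pct/100 * depth)).
make_tm <- function(pct, sheet, tiles = NULL, depth = 100L) {
  n <- nrow(pct)
  if (is.null(tiles))
    tiles <- data.table::data.table(chrom = "chr1",
                                    start = seq_len(n) * 100L - 100L,
                                    end = seq_len(n) * 100L)
  meth <- matrix(as.integer(round(pct / 100 * depth)), n, ncol(pct))
  total <- matrix(as.integer(depth), n, ncol(pct))
  total[is.na(pct)] <- NA_integer_
  meth[is.na(pct)] <- NA_integer_
  pctc <- 100 * meth / total
  dimnames(pctc) <- dimnames(meth) <- dimnames(total) <-
    list(sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end),
         sheet$sample_id)
  structure(list(tiles = tiles, samples = sheet, pct = pctc, meth = meth,
                 total = total), class = "tile_matrix")
}

## Small simulated dataset used across tests (fast: ~1 s).
quick_sim <- function(seed = 7, ..., out_dir = NULL) {
  args <- list(n_tiles = 1500L, n_prenatal = 15L, n_early = 15L,
               n_late = 15L, n_denovo = 10L, n_genes = 40L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_methylomes(do.call(sim_config, args), out_dir = out_dir)
}
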