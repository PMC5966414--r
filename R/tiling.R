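## Collapse strand-resolved CpG calls into fixed-width tiles and assemble
## the cross-sample percent-methylation matrix.

#' Tiling parameters
#'
#' @param tile_size Tile width in bp. 100 is the RRBS convention here,
#'   200 the WGBS one.
#' @param min_cpg_obs Minimum pooled CpG read observations (sum of total
#'   reads over the tile's CpGs) for a tile to be emitted; 10 for 100-bp
#'   RRBS tiles, 15 for 200-bp WGBS tiles.
#' @param strict_sites If \code{TRUE}, the minimum is instead applied to the
#'   number of distinct CpG sites covered at least once.
#' @return A \code{tiling_params} list.
#' @export
tiling_params <- function(tile_size = 100L, min_cpg_obs = 10L,
                          strict_sites = FALSE) {
  .assert(tile_size > 0, "tile_size must be positive")
  .assert(min_cpg_obs >= 1, "min_cpg_obs must be >= 1")
  structure(list(tile_size = as.integer(tile_size),
                 min_cpg_obs = as.integer(min_cpg_obs),
                 strict_sites = isTRUE(strict_sites)),
            class = "tiling_params")
}

#' Pool plus- and minus-strand calls of a CpG dinucleotide
#'
#' CpG methylation is symmetric: a minus-strand cytosine at position p
#' belongs to the CpG whose plus-strand cytosine sits at p - 1. Minus-strand
#' calls are shifted to the plus-strand position and counts are added; a
#' lone minus-strand call is likewise reported at p - 1 with its own counts.
#'
#' @param calls Call table from [read_cpg_calls()].
#' @return A call table with \code{strand == "+"} throughout and pooled
#'   counts; total reads are conserved.
#' @export
merge_strands <- function(calls) {
  if (nrow(calls) == 0L) return(.empty_calls())
  dt <- data.table::copy(calls)
  dt[, pos := ifelse(strand == "-", pos - 1L, pos)]
  merged <- dt[, .(strand = "+", meth_reads = sum(meth_reads),
                   total_reads = sum(total_reads)), by = .(chrom, pos)]
  data.table::setcolorder(merged, c("chrom", "pos", "strand",
                                    "meth_reads", "total_reads"))
  merged[order(chrom, pos)][]
}

#' Aggregate CpG calls into fixed-width tiles
#'
#' Tiles are anchored at genome coordinate 0 in steps of \code{tile_size}
#' (non-sliding); a call at position p falls into the tile starting at
#' \code{floor(p / tile_size) * tile_size}. Tile percent methylation is the
#' read-weighted pooled value \code{100 * sum(meth) / sum(total)}, not the
#' mean of per-CpG ratios. Tiles below the coverage minimum are suppressed
#' unless \code{drop_low = FALSE}.
#'
#' @param calls Strand-merged call table.
#' @param params A [tiling_params()] object.
#' @param drop_low Suppress tiles failing the coverage filter (default).
#' @return A \code{data.table} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{n_cpg_sites}, \code{meth_reads}, \code{total_reads},
#'   \code{pct_meth}.
#' @export
aggregate_tiles <- function(calls, params = tiling_params(),
                            drop_low = TRUE) {
  stopifnot(inherits(params, "tiling_params"))
  if (nrow(calls) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_cpg_sites = integer(),
                                  meth_reads = integer(),
                                  total_reads = integer(),
                                  pct_meth = numeric()))
  }
  ts <- params$tile_size
  dt <- calls[, .(chrom, pos, meth_reads, total_reads)]
  dt[, tile_start := (pos %/% ts) * ts]
  tiles <- dt[, .(n_cpg_sites = data.table::uniqueN(pos),
                  meth_reads = sum(meth_reads),
                  total_reads = sum(total_reads)),
              by = .(chrom, start = tile_start)]
  tiles[, `:=`(end = start + ts,
               pct_meth = 100 * meth_reads / total_reads)]
  if (drop_low) {
    tiles <- if (params$strict_sites) {
      tiles[n_cpg_sites >= params$min_cpg_obs]
    } else {
      tiles[total_reads >= params$min_cpg_obs]
    }
  }
  data.table::setcolorder(tiles, c("chrom", "start", "end", "n_cpg_sites",
                                   "meth_reads", "total_reads", "pct_meth"))
  .order_tiles(tiles)[]
}

#' Assemble the tiles x samples methylation matrix
#'
#' The tile universe is the union of tiles emitted in any sample; a cell is
#' missing (NA) exactly when its tile did not pass the coverage filter in
#' that sample. Column order follows the sample sheet.
#'
#' @param per_sample_tiles Named list (by \code{sample_id}) of tile tables
#'   from [aggregate_tiles()].
#' @param sheet Sample sheet (\code{data.table} with \code{sample_id},
#'   \code{tissue}, \code{age_weeks}, \code{genotype}, \code{replicate}).
#' @return A \code{tile_matrix}: list with \code{tiles} (coordinates),
#'   \code{samples} (the sheet), and tiles x samples matrices \code{pct},
#'   \code{meth}, \code{total}.
#' @export
build_matrix <- function(per_sample_tiles, sheet) {
  missing <- setdiff(sheet$sample_id, names(per_sample_tiles))
  .assert(length(missing) == 0L, "samples in sheet without tile data: %s",
          paste(missing, collapse = ", "))
  universe <- unique(data.table::rbindlist(
    lapply(sheet$sample_id,
           function(s) per_sample_tiles[[s]][, .(chrom, start, end)])))
  universe <- .order_tiles(universe)
  keys <- .tile_key(universe$chrom, universe$start, universe$end)
  n <- nrow(universe); m <- nrow(sheet)
  pct <- matrix(NA_real_, n, m, dimnames = list(keys, sheet$sample_id))
  meth <- matrix(NA_integer_, n, m, dimnames = list(keys, sheet$sample_id))
  total <- matrix(NA_integer_, n, m, dimnames = list(keys, sheet$sample_id))
  for (j in seq_len(m)) {
    tl <- per_sample_tiles[[sheet$sample_id[j]]]
    if (nrow(tl) == 0L) next
    idx <- match(.tile_key(tl$chrom, tl$start, tl$end), keys)
    pct[idx, j] <- tl$pct_meth
    meth[idx, j] <- tl$meth_reads
    total[idx, j] <- tl$total_reads
  }
  structure(list(tiles = universe, samples = data.table::as.data.table(sheet),
                 pct = pct, meth = meth, total = total),
            class = "tile_matrix")
}

#' @export
print.tile_matrix <- function(x, ...) {
  cat(sprintf("tile_matrix: %d tiles x %d samples (%.1f%% cells missing)\n",
              nrow(x$pct), ncol(x$pct), 100 * mean(is.na(x$pct))))
  cat(sprintf("tissues: %s\n",
              paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("ages (weeks): %s\n",
              paste(sort(unique(x$samples$age_weeks)), collapse = ", ")))
  invisible(x)
}

## Column indices of samples matching tissue/age/genotype filters.
.select_samples <- function(tm, tissue = NULL, age_weeks = NULL,
                            genotype = NULL) {
  keep <- rep(TRUE, nrow(tm$samples))
  if (!is.null(tissue)) keep <- keep & tm$samples$tissue %in% tissue
  if (!is.null(age_weeks)) keep <- keep & tm$samples$age_weeks %in% age_weeks
  if (!is.null(genotype)) keep <- keep & tm$samples$genotype %in% genotype
  which(keep)
}
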