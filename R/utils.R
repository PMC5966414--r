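## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Canonical tile label used as matrix rownames and in serialized output.
.tile_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

## Order a tiles table by (chrom, start) with chromosome names sorted
## naturally (chr2 before chr10).
.order_tiles <- function(dt) {
  chr_levels <- unique(dt$chrom)
  chr_levels <- chr_levels[order(nchar(chr_levels), chr_levels)]
  dt[order(factor(chrom, levels = chr_levels), start)]
}

## Deterministic child seeds for independent stochastic stages, kept within
## 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
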