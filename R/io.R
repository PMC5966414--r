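## Readers and writers for the file dialects the pipeline touches.
## All internal coordinates are 0-based half-open (BED convention); the
## 1-based input dialects are converted on read.

#' Read per-cytosine bisulfite methylation calls
#'
#' Parses one sample's CpG-level counts into the internal call table.
#' Two dialects are supported:
#' \describe{
#'   \item{\code{bismark_cov}}{Bismark coverage format, headerless TSV:
#'     \code{chrom, start (1-based), end, percent_methylation, count_methylated,
#'     count_unmethylated}. Positions are strand-combined; records are
#'     reported on the \code{+} strand.}
#'   \item{\code{methratio}}{BSMAP methratio-style TSV with a header line and
#'     columns \code{chr, pos (1-based), strand, context, ratio, eff_CT,
#'     C_count, CT_count, ...}. Only chromosome, position, strand and the two
#'     count columns are consumed. When a context column is present, only
#'     CpG-context rows are kept.}
#' }
#'
#' Rows with zero total reads carry no information and are dropped with a
#' warning; rows where methylated exceeds total reads raise an error naming
#' the offending line.
#'
#' @param path Path to the input file.
#' @param dialect One of \code{"bismark_cov"}, \code{"methratio"}.
#' @param cpg_only For \code{methratio} input, keep only CpG-context rows
#'   when the context column is present (default \code{TRUE}).
#' @return A \code{data.table} with columns \code{chrom}, \code{pos}
#'   (0-based position of the cytosine), \code{strand}, \code{meth_reads},
#'   \code{total_reads}.
#' @export
read_cpg_calls <- function(path, dialect = c("bismark_cov", "methratio"),
                           cpg_only = TRUE) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "file not found: %s", path)
  if (file.size(path) == 0L) return(.empty_calls())
  if (dialect == "bismark_cov") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) == 0L) return(.empty_calls())
    .assert(ncol(dt) >= 6L,
            "bismark_cov file %s has %d columns, expected >= 6", path, ncol(dt))
    data.table::setnames(dt, 1:6, c("chrom", "start1", "end1", "pct",
                                    "n_meth", "n_unmeth"))
    bad <- which(!is.finite(dt$start1) | !is.finite(dt$n_meth) |
                   !is.finite(dt$n_unmeth))
    if (length(bad))
      stop(sprintf("malformed row at line %d of %s", bad[1], path),
           call. = FALSE)
    calls <- dt[, .(chrom, pos = as.integer(start1) - 1L, strand = "+",
                    meth_reads = as.integer(n_meth),
                    total_reads = as.integer(n_meth) + as.integer(n_unmeth))]
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    if (nrow(dt) == 0L) return(.empty_calls())
    cols <- tolower(names(dt))
    ix <- function(nms) {
      hit <- which(cols %in% nms)
      if (!length(hit))
        stop(sprintf("methratio file %s lacks a '%s' column", path, nms[1]),
             call. = FALSE)
      hit[1]
    }
    i_chr <- ix(c("chr", "chrom", "chromosome"))
    i_pos <- ix("pos")
    i_str <- ix("strand")
    i_c   <- ix(c("c_count", "meth", "c"))
    i_ct  <- ix(c("ct_count", "cov", "ct"))
    i_ctx <- which(cols == "context")
    keep <- rep(TRUE, nrow(dt))
    if (cpg_only && length(i_ctx))
      keep <- grepl("CG", toupper(dt[[i_ctx[1]]]), fixed = TRUE)
    calls <- data.table::data.table(
      chrom       = as.character(dt[[i_chr]]),
      pos         = as.integer(dt[[i_pos]]) - 1L,
      strand      = as.character(dt[[i_str]]),
      meth_reads  = as.integer(dt[[i_c]]),
      total_reads = as.integer(dt[[i_ct]])
    )[keep]
    bad <- which(is.na(calls$pos) | is.na(calls$meth_reads) |
                   is.na(calls$total_reads))
    if (length(bad))
      stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path),
           call. = FALSE)
  }
  over <- which(calls$meth_reads > calls$total_reads)
  if (length(over))
    stop(sprintf(
      "meth_reads > total_reads at line %d of %s", over[1] +
        (dialect == "methratio"), path), call. = FALSE)
  n0 <- sum(calls$total_reads == 0L)
  if (n0 > 0L) {
    warning(sprintf("%s: dropped %d rows with zero total reads", path, n0),
            call. = FALSE)
    calls <- calls[total_reads > 0L]
  }
  .assert(all(calls$pos >= 0L), "negative position after conversion in %s", path)
  calls[]
}

.empty_calls <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         strand = character(), meth_reads = integer(),
                         total_reads = integer())
}

#' Read a sample sheet
#'
#' TSV with header columns \code{sample_id, tissue, age_weeks, genotype,
#' replicate} and optionally \code{path} (per-sample CpG call file).
#'
#' @param path Path to the sample sheet TSV.
#' @return A \code{data.table}, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- data.table::fread(path, header = TRUE, sep = "\t",
                             colClasses = list(character = "replicate"))
  required <- c("sample_id", "tissue", "age_weeks", "genotype", "replicate")
  missing <- setdiff(required, names(sheet))
  .assert(length(missing) == 0L, "sample sheet lacks columns: %s",
          paste(missing, collapse = ", "))
  .assert(!anyDuplicated(sheet$sample_id), "duplicated sample_id in %s", path)
  sheet[]
}

#' Read gene models from BED12 or GTF
#'
#' Each gene is reduced to one record spanning the union of its transcripts
#' (for GTF, the union of all features sharing a \code{gene_id}; for BED12,
#' the union of lines sharing a name). The transcription start site of a
#' minus-strand gene is its higher genomic coordinate.
#'
#' @param path Path to the gene model file.
#' @param dialect \code{"bed12"} or \code{"gtf"}.
#' @return A \code{data.table} with columns \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (0-based half-open gene body),
#'   \code{tss}, \code{tes} (0-based positions).
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gtf")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), "file not found: %s", path)
  if (dialect == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- gr$name
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    .assert(!is.null(gr$gene_id), "GTF %s has no gene_id attribute", path)
    ids <- gr$gene_id
  }
  if (length(gr) == 0L) {
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  strand = character(), start = integer(),
                                  end = integer(), tss = integer(),
                                  tes = integer()))
  }
  str <- as.character(BiocGenerics::strand(gr))
  if (any(str == "*"))
    stop("gene model without strand: the promoter rule requires strand",
         call. = FALSE)
  dt <- data.table::data.table(
    gene_id = as.character(ids),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = str,
    start   = BiocGenerics::start(gr) - 1L,   # back to 0-based half-open
    end     = BiocGenerics::end(gr)
  )
  genes <- dt[, .(chrom = chrom[1], strand = strand[1],
                  start = min(start), end = max(end)), by = gene_id]
  genes[, `:=`(tss = ifelse(strand == "+", start, end - 1L),
               tes = ifelse(strand == "+", end - 1L, start))]
  .order_tiles(genes)[]
}

#' Write DMR calls as BED6+4
#'
#' Columns: chrom, start, end, name, score (number of discriminating
#' tissues), strand (\code{.}), then category, timing, newborn-adult delta
#' and per-tile p-value. Coordinates are 0-based half-open. The file
#' round-trips losslessly through [read_dmr_bed()].
#'
#' @param dmrs DMR call table as returned by [call_postnatal()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  header <- paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                   "category\ttiming\tdelta_newborn_adult\tp_tile")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(dmrs) == 0L) return(invisible(path))
  d <- .order_tiles(data.table::copy(dmrs))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s\t%s\t%s\t%s",
                   d$chrom, d$start, d$end,
                   sprintf("dmr_%05d", seq_len(nrow(d))),
                   d$n_discriminating, d$category, d$timing,
                   sprintf("%.17g", d$delta_newborn_adult),
                   sprintf("%.17g", d$p_tile))
  writeLines(lines, con)
  invisible(path)
}

#' Read DMR calls written by [write_dmr_bed()]
#'
#' @param path Path to a BED6+4 DMR file.
#' @return A DMR call \code{data.table}.
#' @export
read_dmr_bed <- function(path) {
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    category = character(), n_discriminating = integer(),
    timing = character(), delta_newborn_adult = numeric(),
    p_tile = numeric())
  first <- readLines(path, n = 1L)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", skip = 1L),
    error = function(e) NULL)
  if (is.null(dt) || nrow(dt) == 0L) return(empty)
  data.table::setnames(dt, c("chrom", "start", "end", "name", "score",
                             "strand", "category", "timing",
                             "delta_newborn_adult", "p_tile"))
  dt[, .(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), category = as.character(category),
         n_discriminating = as.integer(score), timing = as.character(timing),
         delta_newborn_adult = as.numeric(delta_newborn_adult),
         p_tile = as.numeric(p_tile))]
}

#' Serialize a tile matrix to TSV
#'
#' Writes two files: \code{<prefix>.pct.tsv} (rows \code{chrom:start-end},
#' one column per sample, percent methylation or NA) and
#' \code{<prefix>.counts.tsv} with \code{meth|total} pairs per cell.
#'
#' @param tm A \code{tile_matrix} from [build_matrix()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_tile_matrix <- function(tm, prefix) {
  stopifnot(inherits(tm, "tile_matrix"))
  keys <- .tile_key(tm$tiles$chrom, tm$tiles$start, tm$tiles$end)
  pct <- data.table::data.table(tile = keys)
  cnt <- data.table::data.table(tile = keys)
  for (j in seq_len(ncol(tm$pct))) {
    sid <- colnames(tm$pct)[j]
    pct[[sid]] <- tm$pct[, j]
    cell <- ifelse(is.na(tm$total[, j]), NA_character_,
                   sprintf("%d|%d", tm$meth[, j], tm$total[, j]))
    cnt[[sid]] <- cell
  }
  p1 <- paste0(prefix, ".pct.tsv")
  p2 <- paste0(prefix, ".counts.tsv")
  data.table::fwrite(pct, p1, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(cnt, p2, sep = "\t", na = "NA", quote = FALSE)
  invisible(c(p1, p2))
}
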