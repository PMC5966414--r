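## Genomic-feature annotation of DMRs against gene models.
##
## Feature definitions: promoter = strand-aware [TSS - 1 kb, TSS + 100 bp];
## intragenic = the gene body (exons, UTRs, introns) extended 1 kb beyond
## the transcription end site; everything else intergenic. Promoter takes
## precedence over intragenic. All intervals 0-based half-open internally.

## 0-based half-open promoter interval per gene.
.promoter_intervals <- function(genes) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - 1000L, genes$tss - 100L)
  end <- ifelse(plus, genes$tss + 101L, genes$tss + 1001L)
  data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                         start = pmax(0L, as.integer(start)),
                         end = as.integer(end))
}

## Gene body extended 1 kb past the TES (strand-aware).
.body_intervals <- function(genes) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start, genes$start - 1000L)
  end <- ifelse(plus, genes$end + 1000L, genes$end)
  data.table::data.table(gene_id = genes$gene_id, chrom = genes$chrom,
                         start = pmax(0L, as.integer(start)),
                         end = as.integer(end))
}

.as_gr <- function(dt) {
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(dt$start + 1L, dt$end))
}

#' Classify DMRs as promoter, intragenic or intergenic
#'
#' A DMR overlapping (>= 1 bp) any promoter is \code{promoter}; otherwise
#' one overlapping any extended gene body is \code{intragenic}; otherwise
#' \code{intergenic}. The classification is total and mutually exclusive.
#'
#' @param dmrs \code{data.table} with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param genes Gene models from [read_gene_models()].
#' @return Character vector, one class per DMR.
#' @export
classify_feature <- function(dmrs, genes) {
  if (nrow(dmrs) == 0L) return(character())
  dgr <- .as_gr(dmrs)
  in_prom <- IRanges::overlapsAny(dgr, .as_gr(.promoter_intervals(genes)))
  in_body <- IRanges::overlapsAny(dgr, .as_gr(.body_intervals(genes)))
  ifelse(in_prom, "promoter", ifelse(in_body, "intragenic", "intergenic"))
}

#' Signed distance from DMR center to the nearest TSS
#'
#' Distance is measured from the DMR center (floor of the interval
#' midpoint) to the nearest gene's TSS; the sign is positive downstream of
#' the TSS in the gene's orientation and negative upstream. Ties (equal
#' absolute distance) are broken by the lexicographically smaller gene_id.
#' DMRs on chromosomes without genes get \code{NA} distance and gene.
#'
#' @param dmrs DMR interval table.
#' @param genes Gene models.
#' @return \code{data.table} with \code{dist_tss} (signed bp) and
#'   \code{nearest_gene} per DMR, in input order.
#' @export
distance_to_tss <- function(dmrs, genes) {
  n <- nrow(dmrs)
  out <- data.table::data.table(dist_tss = rep(NA_integer_, n),
                                nearest_gene = rep(NA_character_, n))
  if (n == 0L || nrow(genes) == 0L) return(out)
  ## one representative gene per TSS position: the smallest gene_id, which
  ## is also the tie-break winner at that position
  reps <- genes[order(gene_id)][, .SD[1L], by = .(chrom, tss)]
  centers <- as.integer((dmrs$start + dmrs$end) %/% 2L)
  for (ch in unique(dmrs$chrom)) {
    rows <- which(dmrs$chrom == ch)
    g <- reps[chrom == ch][order(tss)]
    if (nrow(g) == 0L) next
    cen <- centers[rows]
    i <- findInterval(cen, g$tss)
    li <- pmax(i, 1L); ri <- pmin(i + 1L, nrow(g))
    dl <- abs(cen - g$tss[li]); dr <- abs(cen - g$tss[ri])
    use_right <- (dr < dl) | (dr == dl & g$gene_id[ri] < g$gene_id[li])
    best <- ifelse(use_right, ri, li)
    tss_b <- g$tss[best]
    plus <- g$strand[best] == "+"
    out$dist_tss[rows] <- as.integer(ifelse(plus, cen - tss_b, tss_b - cen))
    out$nearest_gene[rows] <- g$gene_id[best]
  }
  out
}

#' Assign DMRs to genes
#'
#' Default mode assigns a DMR to every gene for which it lies in the
#' promoter or is intragenic (gene body + 1 kb past the TES); a DMR may map
#' to several overlapping genes, and DMRs with no assignment are intergenic
#' for association purposes. Window mode instead assigns every gene whose
#' TSS lies within \code{window_bp} of the DMR.
#'
#' @param dmrs DMR interval table.
#' @param genes Gene models.
#' @param mode \code{"intragenic_plus_promoter"} (default) or
#'   \code{"window"}.
#' @param window_bp Window half-width for window mode (bp).
#' @return Long-format \code{data.table} mapping \code{dmr_idx} (row index
#'   into \code{dmrs}) to \code{gene_id}; zero rows for unassigned DMRs.
#' @export
assign_genes <- function(dmrs, genes,
                         mode = c("intragenic_plus_promoter", "window"),
                         window_bp = 10000L) {
  mode <- match.arg(mode)
  empty <- data.table::data.table(dmr_idx = integer(), gene_id = character())
  if (nrow(dmrs) == 0L || nrow(genes) == 0L) return(empty)
  dgr <- .as_gr(dmrs)
  if (mode == "intragenic_plus_promoter") {
    prom <- .promoter_intervals(genes)
    body <- .body_intervals(genes)
    h1 <- GenomicRanges::findOverlaps(dgr, .as_gr(prom))
    h2 <- GenomicRanges::findOverlaps(dgr, .as_gr(body))
    map <- unique(rbind(
      data.table::data.table(dmr_idx = S4Vectors::queryHits(h1),
                             gene_id = prom$gene_id[S4Vectors::subjectHits(h1)]),
      data.table::data.table(dmr_idx = S4Vectors::queryHits(h2),
                             gene_id = body$gene_id[S4Vectors::subjectHits(h2)])))
  } else {
    win <- data.table::data.table(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = pmax(0L, genes$tss - as.integer(window_bp)),
      end = genes$tss + as.integer(window_bp) + 1L)
    h <- GenomicRanges::findOverlaps(dgr, .as_gr(win))
    map <- unique(data.table::data.table(
      dmr_idx = S4Vectors::queryHits(h),
      gene_id = win$gene_id[S4Vectors::subjectHits(h)]))
  }
  map[order(dmr_idx, gene_id)][]
}

#' Annotate a DMR table with feature class, nearest TSS and gene assignment
#'
#' @param dmrs DMR calls.
#' @param genes Gene models.
#' @param mode,window_bp Passed to [assign_genes()].
#' @param path Optional TSV output path.
#' @return \code{dmrs} with \code{feature}, \code{dist_tss},
#'   \code{nearest_gene} and comma-joined \code{genes} columns.
#' @export
annotate_dmrs <- function(dmrs, genes,
                          mode = c("intragenic_plus_promoter", "window"),
                          window_bp = 10000L, path = NULL) {
  out <- data.table::copy(dmrs)
  out[, feature := classify_feature(dmrs, genes)]
  nt <- distance_to_tss(dmrs, genes)
  out[, `:=`(dist_tss = nt$dist_tss, nearest_gene = nt$nearest_gene)]
  map <- assign_genes(dmrs, genes, mode, window_bp)
  joined <- map[, .(genes = paste(sort(gene_id), collapse = ",")),
                by = dmr_idx]
  out[, genes := ""]
  if (nrow(joined)) out[joined$dmr_idx, genes := joined$genes]
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(out))
  }
  out[]
}
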