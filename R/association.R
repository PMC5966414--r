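## DMR - gene-expression association: which DMR-linked genes are
## postnatally upregulated, and is that fraction higher than for random
## length-matched genomic segments (two-proportion z-test)?

#' Construct an expression table
#'
#' @param values Numeric genes x samples matrix (non-negative, e.g.
#'   FPKM-like normalized expression) with gene ids as rownames and sample
#'   ids as colnames.
#' @param samples \code{data.table} describing the columns (\code{sample_id},
#'   \code{age_weeks}, \code{replicate}, optionally \code{genotype}).
#' @return An \code{expression_table}.
#' @export
expression_table <- function(values, samples) {
  .assert(is.matrix(values) && !is.null(rownames(values)),
          "values must be a matrix with gene rownames")
  .assert(all(colnames(values) == samples$sample_id),
          "column order must match samples$sample_id")
  .assert(all(values >= 0, na.rm = TRUE), "expression values must be >= 0")
  structure(list(values = values,
                 samples = data.table::as.data.table(samples)),
            class = "expression_table")
}

#' Read a genes x samples expression TSV
#'
#' First column gene ids, remaining columns one per sample (header =
#' sample ids); sample metadata is taken from the matching rows of
#' \code{sheet}.
#'
#' @param path Expression TSV path.
#' @param sheet Sample sheet covering the table's columns.
#' @return An [expression_table()].
#' @export
read_expression <- function(path, sheet) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1]])
  values <- as.matrix(dt[, -1, with = FALSE])
  rownames(values) <- ids
  samples <- data.table::as.data.table(sheet)[match(colnames(values), sample_id)]
  .assert(!anyNA(samples$sample_id),
          "expression columns missing from the sample sheet")
  expression_table(values, samples)
}

#' Genes upregulated between two ages
#'
#' When a precomputed differential-expression table is supplied (columns
#' \code{gene_id}, \code{log2fc}, \code{p}, \code{significant}) it takes
#' precedence and the up-and-significant genes are returned. Otherwise a
#' stand-in rule is applied to the expression table: mean expression at
#' \code{age_to} at least \code{min_fold} times the mean at \code{age_from},
#' with a Welch two-sample t-test on log2-transformed replicate values below
#' \code{alpha}.
#'
#' @param expr An [expression_table()].
#' @param age_from,age_to Ages (weeks) being compared.
#' @param min_fold Minimum fold increase (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @param de_table Optional precomputed DE \code{data.table}.
#' @return Character vector of upregulated gene ids.
#' @export
upregulated_genes <- function(expr, age_from, age_to, min_fold = 1.5,
                              alpha = 0.05, de_table = NULL) {
  if (!is.null(de_table)) {
    de <- data.table::as.data.table(de_table)
    return(de[significant == TRUE & log2fc > 0, as.character(gene_id)])
  }
  stopifnot(inherits(expr, "expression_table"))
  c1 <- which(expr$samples$age_weeks == age_from)
  c2 <- which(expr$samples$age_weeks == age_to)
  .assert(length(c1) >= 2 && length(c2) >= 2,
          "need >= 2 replicates in both age groups (have %d and %d)",
          length(c1), length(c2))
  x <- expr$values[, c1, drop = FALSE]
  y <- expr$values[, c2, drop = FALSE]
  l1 <- log2(x + 0.5); l2 <- log2(y + 0.5)
  n1 <- ncol(l1); n2 <- ncol(l2)
  m1 <- rowMeans(l1); m2 <- rowMeans(l2)
  v1 <- rowSums((l1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((l2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  up <- rowMeans(y) >= min_fold * rowMeans(x) & !is.na(p) & p < alpha
  rownames(expr$values)[up]
}

#' Random genomic segments
#'
#' Draws n segments uniformly over the genome: chromosomes are sampled with
#' probability proportional to their length, then a start position uniform
#' over the admissible range. Segment lengths follow \code{lengths}
#' (recycled to n), so passing the observed DMR lengths gives a
#' length-matched background. Segments overlapping \code{exclude} are
#' redrawn up to \code{max_tries} rounds.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param n Number of segments.
#' @param lengths Segment length(s) in bp.
#' @param seed Optional integer seed.
#' @param exclude Optional interval table (\code{chrom}, \code{start},
#'   \code{end}) that segments must not overlap.
#' @param max_tries Resampling rounds before giving up (default 100).
#' @return \code{data.table} of segments (\code{chrom}, \code{start},
#'   \code{end}), 0-based half-open.
#' @export
random_segments <- function(chrom_sizes, n, lengths, seed = NULL,
                            exclude = NULL, max_tries = 100L) {
  if (n == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  }
  lengths <- as.integer(rep_len(lengths, n))
  .assert(all(lengths <= min(chrom_sizes)),
          "segment length exceeds the shortest chromosome")
  draw <- function(m, len) {
    ch <- sample(names(chrom_sizes), m, replace = TRUE,
                 prob = as.numeric(chrom_sizes))
    start <- floor(runif(m) * (chrom_sizes[ch] - len + 1))
    data.table::data.table(chrom = ch, start = as.integer(start),
                           end = as.integer(start + len))
  }
  run <- function() {
    segs <- draw(n, lengths)
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      ex_gr <- .as_gr(data.table::as.data.table(exclude))
      for (i in seq_len(max_tries)) {
        bad <- which(IRanges::overlapsAny(.as_gr(segs), ex_gr))
        if (!length(bad)) break
        redo <- draw(length(bad), lengths[bad])
        segs[bad, `:=`(chrom = redo$chrom, start = redo$start,
                       end = redo$end)]
      }
      if (any(IRanges::overlapsAny(.as_gr(segs), ex_gr)))
        stop("could not place segments outside the exclusion set",
             call. = FALSE)
    }
    segs
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Two-proportion z-test (pooled variance)
#'
#' z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2)) with the pooled
#' proportion p = (k1 + k2) / (n1 + n2); two-sided normal p-value. When the
#' pooled proportion is degenerate (0 or 1) the statistic is 0 if the group
#' proportions agree and signed infinity otherwise.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with \code{z}, \code{p_value}, \code{p1}, \code{p2}.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  .assert(n1 >= 1 && n2 >= 1, "both group sizes must be >= 1")
  .assert(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
          "successes must satisfy 0 <= k <= n")
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    z <- if (p1 == p2) 0 else sign(p1 - p2) * Inf
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Enrichment of DMRs in postnatally upregulated genes
#'
#' Foreground: the fraction of gene-assigned DMRs whose assigned gene set
#' intersects the upregulated set. Background: random length-matched
#' segments (sampling the DMR length distribution) passed through the
#' byte-identical [assign_genes()] and intersection logic. The two
#' fractions are compared with [proportion_ztest()].
#'
#' @param dmrs DMR calls (non-empty).
#' @param genes Gene models.
#' @param upregulated Character vector of upregulated gene ids (e.g. from
#'   [upregulated_genes()]).
#' @param chrom_sizes Named chromosome lengths for background sampling.
#' @param mode,window_bp Gene-assignment mode, see [assign_genes()].
#' @param bg_multiplier Draw this many background segments per DMR
#'   (default 1).
#' @param seed Integer seed for the background draw.
#' @return An \code{association_result}: counts, proportions, z statistic
#'   and two-sided p-value.
#' @export
dmr_gene_enrichment <- function(dmrs, genes, upregulated, chrom_sizes,
                                mode = c("intragenic_plus_promoter", "window"),
                                window_bp = 10000L, bg_multiplier = 1L,
                                seed = 1L) {
  mode <- match.arg(mode)
  .assert(nrow(dmrs) > 0L, "empty DMR set")
  count_hits <- function(intervals) {
    map <- assign_genes(intervals, genes, mode, window_bp)
    if (nrow(map) == 0L) return(c(k = 0L, n = 0L))
    per <- map[, .(hit = any(gene_id %in% upregulated)), by = dmr_idx]
    c(k = sum(per$hit), n = nrow(per))
  }
  fg <- count_hits(dmrs[, .(chrom, start, end)])
  lens <- rep(dmrs$end - dmrs$start, bg_multiplier)
  segs <- random_segments(chrom_sizes, n = length(lens), lengths = lens,
                          seed = seed)
  bg <- count_hits(segs)
  .assert(fg["n"] >= 1, "no DMR is assigned to any gene")
  .assert(bg["n"] >= 1, "no background segment is assigned to any gene")
  zt <- proportion_ztest(unname(fg["k"]), unname(fg["n"]),
                         unname(bg["k"]), unname(bg["n"]))
  structure(list(k_dmr = unname(fg["k"]), n_dmr = unname(fg["n"]),
                 k_bg = unname(bg["k"]), n_bg = unname(bg["n"]),
                 prop_dmr = zt$p1, prop_bg = zt$p2,
                 z = zt$z, p_value = zt$p_value, seed = as.integer(seed)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "DMR-gene association: %d/%d DMRs (%.1f%%) vs %d/%d random segments (%.1f%%) in upregulated genes\n",
    x$k_dmr, x$n_dmr, 100 * x$prop_dmr, x$k_bg, x$n_bg, 100 * x$prop_bg))
  cat(sprintf("two-proportion z = %.3f, p = %.3g\n", x$z, x$p_value))
  invisible(x)
}

#' Write an association report TSV
#'
#' @param res An \code{association_result}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_association_report <- function(res, path) {
  stopifnot(inherits(res, "association_result"))
  dt <- data.table::as.data.table(unclass(res))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
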