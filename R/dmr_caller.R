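## Tissue-specific and postnatal DMR calling.
##
## A tile is tissue-specifically hypomethylated when its mean percent
## methylation in the target tissue is at least `delta_specific` percentage
## points below that of at least `min_discriminating_tissues` other tissues
## in the panel; de novo methylation is the sign-reversed rule. Among
## tissue-hypo tiles, postnatal demethylation is a newborn-vs-adult drop of
## at least `delta_postnatal` points with a per-tile test p below
## `alpha_tile`; timing is "early" when the drop is already achieved at the
## boundary age (3 weeks), "late" otherwise, and "prenatal" when the tile is
## essentially unmethylated (< 5%) already in newborns.

#' DMR-calling parameters
#'
#' @param delta_specific Tissue-specificity threshold in percentage points
#'   (default 50).
#' @param min_discriminating_tissues Minimum number of non-target tissues
#'   that must satisfy the delta (default 5, against a nine-tissue panel).
#' @param delta_postnatal Newborn-vs-adult threshold in percentage points
#'   (default 35).
#' @param alpha_tile Per-tile significance level (default 0.05).
#' @param prenatal_max_newborn_pct Tiles below this percent methylation in
#'   newborns are classed prenatal (default 5).
#' @param late_age_boundary_weeks Age separating early from late postnatal
#'   demethylation (default 3).
#' @param relative_delta Interpret \code{delta_specific} as a relative
#'   fraction of the comparison tissue's methylation instead of an absolute
#'   percentage-point difference (default \code{FALSE}).
#' @param tile_test \code{"fisher"}: Fisher's exact test on replicate-pooled
#'   2x2 counts (default); \code{"ttest"}: Welch t-test on replicate percent
#'   values.
#' @param fdr Apply Benjamini-Hochberg correction to per-tile p-values
#'   before comparing with \code{alpha_tile} (default \code{FALSE}; the
#'   baseline rule is an uncorrected p < 0.05).
#' @return A \code{dmr_params} list.
#' @export
dmr_params <- function(delta_specific = 50, min_discriminating_tissues = 5L,
                       delta_postnatal = 35, alpha_tile = 0.05,
                       prenatal_max_newborn_pct = 5,
                       late_age_boundary_weeks = 3,
                       relative_delta = FALSE,
                       tile_test = c("fisher", "ttest"), fdr = FALSE) {
  .assert(delta_specific > 0 && delta_specific <= 100,
          "delta_specific must be in (0, 100]")
  .assert(delta_postnatal > 0 && delta_postnatal <= 100,
          "delta_postnatal must be in (0, 100]")
  .assert(alpha_tile > 0 && alpha_tile < 1, "alpha_tile must be in (0, 1)")
  structure(list(delta_specific = delta_specific,
                 min_discriminating_tissues = as.integer(min_discriminating_tissues),
                 delta_postnatal = delta_postnatal,
                 alpha_tile = alpha_tile,
                 prenatal_max_newborn_pct = prenatal_max_newborn_pct,
                 late_age_boundary_weeks = late_age_boundary_weeks,
                 relative_delta = isTRUE(relative_delta),
                 tile_test = match.arg(tile_test),
                 fdr = isTRUE(fdr)),
            class = "dmr_params")
}

#' Per-tissue mean methylation across replicates
#'
#' Averages non-missing replicate percent-methylation values within each
#' tissue, optionally restricted by age and genotype.
#'
#' @param tm A \code{tile_matrix}.
#' @param age_filter Keep only samples at these ages (weeks); \code{NULL}
#'   keeps all.
#' @param genotype_filter Keep only these genotypes; \code{NULL} keeps all.
#' @return A tiles x tissues matrix of mean percent methylation (NA where a
#'   tissue has no data for a tile), with the tile coordinate table attached
#'   as attribute \code{"tiles"} and the per-cell replicate count as
#'   attribute \code{"n_obs"}.
#' @export
tissue_means <- function(tm, age_filter = NULL, genotype_filter = NULL) {
  stopifnot(inherits(tm, "tile_matrix"))
  cols <- .select_samples(tm, age_weeks = age_filter,
                          genotype = genotype_filter)
  .assert(length(cols) > 0L, "no samples match the age/genotype filter")
  tissues <- unique(tm$samples$tissue[cols])
  sums <- .grouped_sums(tm$pct[, cols, drop = FALSE],
                        tm$samples$tissue[cols], tissues)
  means <- sums$S / sums$N
  means[sums$N == 0] <- NA_real_
  attr(means, "tiles") <- tm$tiles
  attr(means, "n_obs") <- sums$N
  means
}

## Column-group sums treating NA as absent; returns value sums S and
## non-missing counts N, one column per group level.
.grouped_sums <- function(x, groups, levels) {
  x0 <- x; x0[is.na(x0)] <- 0
  msk <- !is.na(x)
  ind <- matrix(0, ncol(x), length(levels),
                dimnames = list(NULL, levels))
  ind[cbind(seq_along(groups), match(groups, levels))] <- 1
  list(S = x0 %*% ind, N = msk %*% ind)
}

#' Call tissue-specific hypo- or de-novo-methylated tiles
#'
#' A tile is called for direction \code{hypo} when at least
#' \code{min_discriminating_tissues} non-target tissues are each at least
#' \code{delta_specific} percentage points more methylated than the target
#' (inclusive threshold); \code{denovo} reverses the sign. Tiles whose
#' target mean is missing or with fewer than
#' \code{min_discriminating_tissues} informative comparison tissues are
#' untestable and returned in the \code{"untestable"} attribute rather than
#' silently dropped.
#'
#' @param means Tiles x tissues matrix from [tissue_means()].
#' @param target_tissue Column name of the target tissue.
#' @param direction \code{"hypo"} or \code{"denovo"}.
#' @param params A [dmr_params()] object.
#' @return A \code{data.table} of calls: \code{chrom}, \code{start},
#'   \code{end}, \code{category}, \code{n_discriminating},
#'   \code{target_mean}, plus \code{timing}/\code{delta_newborn_adult}/
#'   \code{p_tile} placeholders filled by [call_postnatal()].
#' @export
call_tissue_specific <- function(means, target_tissue,
                                 direction = c("hypo", "denovo"),
                                 params = dmr_params()) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "dmr_params"))
  .assert(target_tissue %in% colnames(means),
          "target tissue '%s' absent from the means matrix", target_tissue)
  tiles <- attr(means, "tiles")
  target <- means[, target_tissue]
  others <- means[, setdiff(colnames(means), target_tissue), drop = FALSE]
  disc <- .discriminating_counts(target, others, direction, params)
  testable <- !is.na(target) &
    rowSums(!is.na(others)) >= params$min_discriminating_tissues
  called <- testable & disc >= params$min_discriminating_tissues
  out <- cbind(
    tiles[called, .(chrom, start, end)],
    data.table::data.table(
      category = if (direction == "hypo") "tissue_hypo" else "tissue_denovo",
      n_discriminating = disc[called],
      target_mean = unname(target[called]),
      timing = "none",
      delta_newborn_adult = NA_real_,
      p_tile = NA_real_))
  data.table::setattr(out, "untestable", tiles[!testable, .(chrom, start, end)])
  out[]
}

## Elementwise "does this comparison value discriminate from the target"
## (recycles a target vector against a comparison matrix).
.disc_pair <- function(target, others, direction, params) {
  if (params$relative_delta) {
    f <- params$delta_specific / 100
    if (direction == "hypo") {
      (others - target) >= f * others & others > 0
    } else {
      (target - others) >= f * target & target > 0
    }
  } else {
    if (direction == "hypo") {
      (others - target) >= params$delta_specific
    } else {
      (target - others) >= params$delta_specific
    }
  }
}

## Number of comparison tissues satisfying the specificity delta per tile.
.discriminating_counts <- function(target, others, direction, params) {
  rowSums(.disc_pair(target, others, direction, params), na.rm = TRUE)
}

#' Per-tile significance test on pooled newborn vs adult counts
#'
#' Two-sided Fisher's exact test on the 2x2 table of (methylated,
#' unmethylated) reads in newborn vs adult samples.
#'
#' @param newborn_counts,adult_counts Length-2 integer vectors
#'   \code{c(meth_reads, total_reads)}.
#' @return Two-sided p-value in (0, 1].
#' @export
tile_test <- function(newborn_counts, adult_counts) {
  m1 <- newborn_counts[1]; t1 <- newborn_counts[2]
  m2 <- adult_counts[1]; t2 <- adult_counts[2]
  .assert(t1 >= 1 && t2 >= 1, "tile_test requires total reads >= 1 per group")
  .assert(m1 <= t1 && m2 <= t2, "meth_reads exceeds total_reads")
  tab <- matrix(c(m1, t1 - m1, m2, t2 - m2), nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Classify postnatal demethylation timing of tissue-specific DMRs
#'
#' For hypo DMRs of the target tissue: a tile is postnatally demethylated
#' when mean percent methylation drops by at least \code{delta_postnatal}
#' points from newborn to adult with per-tile test p below
#' \code{alpha_tile}; it is \code{late_postnatal} when the drop is not yet
#' achieved at the boundary age (newborn minus boundary-age methylation
#' below \code{delta_postnatal}), \code{early_postnatal} otherwise. Tiles
#' already below \code{prenatal_max_newborn_pct} percent in newborns are
#' \code{prenatal}; everything else is \code{none}. For de novo DMRs all
#' comparisons run on 100 minus percent methylation, so the same rules
#' describe postnatal gain of methylation. The delta threshold is applied
#' to replicate means; the significance test uses replicate-pooled counts
#' (or replicate percent values under \code{tile_test = "ttest"}).
#'
#' @param tm The \code{tile_matrix}.
#' @param dmrs Calls from [call_tissue_specific()].
#' @param target_tissue Tissue whose trajectory is classified.
#' @param newborn_age,adult_age Ages (weeks) of the newborn and adult
#'   samples (defaults 1 and 15).
#' @param params A [dmr_params()] object.
#' @param genotype_filter Optional genotype restriction for the trajectory
#'   samples.
#' @return \code{dmrs} with \code{timing}, \code{delta_newborn_adult}
#'   (newborn-to-adult change in the direction of the category, percentage
#'   points), \code{p_tile}, and audit columns \code{pct_newborn},
#'   \code{pct_boundary}, \code{pct_adult} filled in. When no sample exists
#'   at the boundary age, postnatal calls are labeled
#'   \code{early_or_late_unknown}.
#' @export
call_postnatal <- function(tm, dmrs, target_tissue, newborn_age = 1,
                           adult_age = 15, params = dmr_params(),
                           genotype_filter = NULL) {
  stopifnot(inherits(tm, "tile_matrix"), inherits(params, "dmr_params"))
  if (nrow(dmrs) == 0L) return(dmrs)
  idx <- match(.tile_key(dmrs$chrom, dmrs$start, dmrs$end),
               .tile_key(tm$tiles$chrom, tm$tiles$start, tm$tiles$end))
  .assert(!anyNA(idx), "DMR tiles absent from the tile matrix")

  age_cols <- function(age) {
    cols <- .select_samples(tm, tissue = target_tissue, age_weeks = age,
                            genotype = genotype_filter)
    cols
  }
  nb_cols <- age_cols(newborn_age)
  ad_cols <- age_cols(adult_age)
  .assert(length(nb_cols) > 0L, "no %s samples at newborn age %s",
          target_tissue, newborn_age)
  .assert(length(ad_cols) > 0L, "no %s samples at adult age %s",
          target_tissue, adult_age)
  bd_cols <- age_cols(params$late_age_boundary_weeks)

  row_mean <- function(cols) {
    rowMeans(tm$pct[idx, cols, drop = FALSE], na.rm = TRUE)
  }
  row_counts <- function(cols) {
    list(m = rowSums(tm$meth[idx, cols, drop = FALSE], na.rm = TRUE),
         t = rowSums(tm$total[idx, cols, drop = FALSE], na.rm = TRUE))
  }
  pct_nb <- row_mean(nb_cols)
  pct_ad <- row_mean(ad_cols)
  pct_bd <- if (length(bd_cols)) row_mean(bd_cols) else rep(NA_real_, length(idx))

  out <- data.table::copy(dmrs)
  out[, `:=`(pct_newborn = pct_nb, pct_boundary = pct_bd, pct_adult = pct_ad)]

  ## orient so that demethylation (hypo) and de novo gain (denovo) both
  ## appear as a decrease of q
  sgn <- ifelse(out$category == "tissue_denovo", -1, 1)
  q_nb <- ifelse(sgn > 0, pct_nb, 100 - pct_nb)
  q_ad <- ifelse(sgn > 0, pct_ad, 100 - pct_ad)
  q_bd <- ifelse(sgn > 0, pct_bd, 100 - pct_bd)
  out[, delta_newborn_adult := q_nb - q_ad]

  ## per-tile significance on pooled counts (or replicate t-test)
  cnb <- row_counts(nb_cols); cad <- row_counts(ad_cols)
  p <- rep(NA_real_, nrow(out))
  if (params$tile_test == "fisher") {
    ok <- cnb$t >= 1 & cad$t >= 1
    for (i in which(ok)) {
      p[i] <- tile_test(c(cnb$m[i], cnb$t[i]), c(cad$m[i], cad$t[i]))
    }
  } else {
    for (i in seq_len(nrow(out))) {
      x <- tm$pct[idx[i], nb_cols]; y <- tm$pct[idx[i], ad_cols]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) >= 2 && length(y) >= 2 &&
          (stats::sd(x) > 0 || stats::sd(y) > 0)) {
        p[i] <- stats::t.test(x, y)$p.value
      }
    }
  }
  p_eff <- if (params$fdr) stats::p.adjust(p, method = "BH") else p
  out[, p_tile := p]

  tim <- rep("none", nrow(out))
  prenatal <- !is.na(q_nb) & q_nb < params$prenatal_max_newborn_pct
  postnatal <- !prenatal & !is.na(q_nb) & !is.na(q_ad) &
    (q_nb - q_ad) >= params$delta_postnatal &
    !is.na(p_eff) & p_eff < params$alpha_tile
  tim[prenatal] <- "prenatal"
  if (length(bd_cols)) {
    late <- postnatal & !is.na(q_bd) & (q_nb - q_bd) < params$delta_postnatal
    tim[postnatal & late] <- "late_postnatal"
    tim[postnatal & !late] <- "early_postnatal"
  } else {
    tim[postnatal] <- "early_or_late_unknown"
  }
  out[, timing := tim]
  out[]
}

#' Audit table of a DMR call set
#'
#' Per-tile means, deltas, discriminating-tissue counts, p-values and
#' timing, suitable for TSV export alongside the BED output.
#'
#' @param dmrs Calls from [call_postnatal()].
#' @param path Optional output TSV path.
#' @return The audit \code{data.table}, invisibly when written to file.
#' @export
dmr_audit_table <- function(dmrs, path = NULL) {
  if (!is.null(path)) {
    data.table::fwrite(dmrs, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(dmrs))
  }
  dmrs
}
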