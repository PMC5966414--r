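## Label-replacement permutation test for the size of a tissue-specific
## DMR set. The null replaces the target tissue's samples with randomly
## drawn non-target samples (which simultaneously leave the comparison
## panel) and reruns the identical caller; the p-value is the add-one
## quantile of the observed DMR count among the permuted counts.

#' Replace target-tissue samples with random non-target samples
#'
#' Builds one permuted sample sheet: the k target-tissue samples are
#' removed and k samples drawn uniformly without replacement from the
#' non-target pool become the pseudo-target (their original tissue is kept
#' in \code{source_tissue}); the drawn samples leave the comparison panel.
#'
#' @param sheet Sample sheet.
#' @param target_tissue Tissue to permute.
#' @param seed Optional integer seed (draws from the current RNG stream
#'   when \code{NULL}).
#' @return The permuted sheet.
#' @export
permute_target <- function(sheet, target_tissue, seed = NULL) {
  tgt <- which(sheet$tissue == target_tissue)
  pool <- which(sheet$tissue != target_tissue)
  k <- length(tgt)
  .assert(k > 0L, "no samples of target tissue '%s'", target_tissue)
  .assert(length(pool) >= k,
          "non-target pool (%d) smaller than target sample count (%d)",
          length(pool), k)
  draw <- if (is.null(seed)) sample(pool, k) else
    .with_seed(seed, sample(pool, k))
  out <- data.table::copy(sheet[pool])
  out[, source_tissue := tissue]
  out[match(draw, pool), tissue := target_tissue]
  out[]
}

#' Permutation test for the size of a tissue-specific DMR set
#'
#' The observed count is the number of tiles called by
#' [call_tissue_specific()] on the true labels. Each permutation relabels
#' k random non-target samples as pseudo-target (true target samples are
#' excluded entirely), recomputes tissue means from the counts matrix and
#' recounts calls with the identical rule; no re-tiling is involved. The
#' p-value uses the add-one estimator
#' \code{(1 + #(permuted >= observed)) / (n_perm + 1)}, which never returns
#' zero; when no permutation reaches the observed count the value is an
#' upper bound and \code{p_is_upper_bound} is set.
#'
#' @param tm A \code{tile_matrix}.
#' @param target_tissue Target tissue name.
#' @param params A [dmr_params()] object.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; identical seeds give identical results.
#' @param age_filter Ages (weeks) defining the comparison panel, e.g. the
#'   adult age; \code{NULL} uses all samples.
#' @param direction \code{"hypo"} or \code{"denovo"}.
#' @return A \code{perm_result}: \code{observed_count},
#'   \code{permuted_counts}, \code{p_value}, \code{p_is_upper_bound},
#'   \code{seed}, \code{n_perm}.
#' @export
permutation_test <- function(tm, target_tissue, params = dmr_params(),
                             n_perm = 10000L, seed = 1L, age_filter = NULL,
                             direction = c("hypo", "denovo")) {
  direction <- match.arg(direction)
  stopifnot(inherits(tm, "tile_matrix"))
  .assert(n_perm >= 1L, "n_perm must be >= 1")

  means_obs <- tissue_means(tm, age_filter = age_filter)
  observed <- nrow(call_tissue_specific(means_obs, target_tissue,
                                        direction, params))

  cols <- .select_samples(tm, age_weeks = age_filter)
  tiss <- tm$samples$tissue[cols]
  k <- sum(tiss == target_tissue)
  pool_cols <- cols[tiss != target_tissue]
  pool_tiss <- tiss[tiss != target_tissue]
  m <- length(pool_cols)
  .assert(k > 0L, "no samples of target tissue '%s' in the panel",
          target_tissue)
  .assert(m >= k, "non-target pool (%d) smaller than target count (%d)", m, k)

  X <- tm$pct[, pool_cols, drop = FALSE]
  X0 <- X; X0[is.na(X0)] <- 0
  MSK <- matrix(as.numeric(!is.na(X)), nrow(X), ncol(X))
  levels <- unique(pool_tiss)
  base <- .grouped_sums(X, pool_tiss, levels)

  picks <- .with_seed(seed, {
    matrix(replicate(n_perm, sample.int(m, k)), nrow = k)
  })

  ## vectorized re-evaluation: process permutations in chunks, expressing
  ## pseudo-target sums and tissue-panel adjustments as matrix products of
  ## the (NA-zeroed) percent matrix with 0/1 permutation indicators
  counts <- integer(n_perm)
  min_disc <- params$min_discriminating_tissues
  chunk <- max(1L, min(n_perm, as.integer(2e6 / max(1, nrow(X)))))
  for (lo in seq(1L, n_perm, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_perm)
    cb <- hi - lo + 1L
    P <- matrix(0, m, cb)
    P[cbind(as.vector(picks[, lo:hi]), rep(seq_len(cb), each = k))] <- 1
    Nt <- MSK %*% P
    MUt <- (X0 %*% P) / Nt         # tiles x perms pseudo-target means
    MUt[Nt == 0] <- NA_real_
    ndisc <- matrix(0L, nrow(X), cb)
    ninfo <- matrix(0L, nrow(X), cb)
    for (t in levels) {
      rows_t <- which(pool_tiss == t)
      Pt <- P[rows_t, , drop = FALSE]
      Nmat <- base$N[, t] - MSK[, rows_t, drop = FALSE] %*% Pt
      Mmat <- (base$S[, t] - X0[, rows_t, drop = FALSE] %*% Pt) / Nmat
      d <- .disc_pair(MUt, Mmat, direction, params)
      d[Nmat == 0 | is.na(d)] <- FALSE
      ndisc <- ndisc + d
      ninfo <- ninfo + (Nmat > 0)
    }
    ok <- ndisc >= min_disc & Nt > 0 & ninfo >= min_disc
    counts[lo:hi] <- as.integer(colSums(ok))
  }

  n_ge <- sum(counts >= observed)
  structure(list(observed_count = observed,
                 permuted_counts = counts,
                 p_value = (1 + n_ge) / (n_perm + 1),
                 p_is_upper_bound = (n_ge == 0L),
                 seed = as.integer(seed),
                 n_perm = as.integer(n_perm)),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "permutation test: observed %d DMRs; %d permutations (max %d, mean %.2f)\n",
    x$observed_count, x$n_perm, max(x$permuted_counts),
    mean(x$permuted_counts)))
  cat(sprintf("p %s %.3g (seed %d)\n",
              if (x$p_is_upper_bound) "<=" else "=", x$p_value, x$seed))
  invisible(x)
}

#' Write a permutation-test report TSV
#'
#' @param res A \code{perm_result}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_permutation_report <- function(res, path) {
  stopifnot(inherits(res, "perm_result"))
  dt <- data.table::data.table(
    observed_count = res$observed_count,
    n_perm = res$n_perm,
    max_permuted = max(res$permuted_counts),
    mean_permuted = mean(res$permuted_counts),
    p_value = res$p_value,
    p_is_upper_bound = res$p_is_upper_bound,
    seed = res$seed)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
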