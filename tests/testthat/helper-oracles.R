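## Independent brute-force oracles used to cross-check the implementation.
## These deliberately share no code with the package internals.

## Two-sided Fisher exact p for a 2x2 table, by enumeration over the
## hypergeometric support: sum the probabilities of all tables (fixed
## margins) no more likely than the observed one. The standard relative
## tolerance guards against ties lost to floating-point rounding.
oracle_fisher2x2 <- function(m1, t1, m2, t2) {
  u1 <- t1 - m1
  k <- m1 + m2          # total methylated
  n <- t1 + t2          # total reads
  support <- max(0L, k - t2):min(k, t1)
  dens <- dhyper(support, t1, t2, k)
  d_obs <- dhyper(m1, t1, t2, k)
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

## Pooled-variance two-proportion z-test, direct formula evaluation.
oracle_ztest <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

## O(n * m) nearest-TSS scan with the package's tie rule (smaller absolute
## distance, then lexicographically smaller gene id); sign positive
## downstream in the gene's orientation.
oracle_nearest_tss <- function(dmrs, genes) {
  out <- data.frame(dist_tss = rep(NA_integer_, nrow(dmrs)),
                    nearest_gene = rep(NA_character_, nrow(dmrs)))
  for (i in seq_len(nrow(dmrs))) {
    center <- (dmrs$start[i] + dmrs$end[i]) %/% 2L
    g <- genes[genes$chrom == dmrs$chrom[i], ]
    if (nrow(g) == 0L) next
    ad <- abs(center - g$tss)
    best <- which(ad == min(ad))
    best <- best[order(g$gene_id[best])][1]
    signed <- if (g$strand[best] == "+") center - g$tss[best] else
      g$tss[best] - center
    out$dist_tss[i] <- as.integer(signed)
    out$nearest_gene[i] <- g$gene_id[best]
  }
  out
}

## Brute-force per-tile pooling of CpG calls: loop over tiles, sum every
## call whose position falls inside.
oracle_tile_sums <- function(calls, tile_size) {
  df <- as.data.frame(calls)
  keys <- unique(data.frame(chrom = df$chrom,
                            start = (df$pos %/% tile_size) * tile_size))
  res <- NULL
  for (i in seq_len(nrow(keys))) {
    inside <- df$chrom == keys$chrom[i] & df$pos >= keys$start[i] &
      df$pos < keys$start[i] + tile_size
    res <- rbind(res, data.frame(
      chrom = keys$chrom[i], start = keys$start[i],
      n_cpg_sites = length(unique(df$pos[inside])),
      meth_reads = sum(df$meth_reads[inside]),
      total_reads = sum(df$total_reads[inside])))
  }
  res[order(res$chrom, res$start), ]
}

## Brute-force DMR -> gene overlap using the feature definitions
## (promoter [TSS-1kb, TSS+100], body + 1 kb past the TES), quadratic scan.
oracle_assigned_genes <- function(dmrs, genes) {
  hits <- list()
  for (i in seq_len(nrow(dmrs))) {
    gs <- character()
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      if (genes$strand[j] == "+") {
        prom <- c(genes$tss[j] - 1000L, genes$tss[j] + 101L)
        body <- c(genes$start[j], genes$end[j] + 1000L)
      } else {
        prom <- c(genes$tss[j] - 100L, genes$tss[j] + 1001L)
        body <- c(genes$start[j] - 1000L, genes$end[j])
      }
      ov <- function(iv) dmrs$start[i] < iv[2] && dmrs$end[i] > iv[1]
      if (ov(prom) || ov(body)) gs <- c(gs, genes$gene_id[j])
    }
    hits[[i]] <- gs
  }
  hits
}
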