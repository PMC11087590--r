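# Independent oracles and small in-code fixtures shared across the suite.
# Each oracle is a deliberately naive reimplementation used only to check
# the package's vectorized/structured code paths.

# Shannon entropy by direct per-element evaluation
entropy_oracle <- function(E) {
  R <- E / sum(E)
  h <- 0
  for (r in R) if (r > 0) h <- h - r * log2(r)
  h
}

# brute-force quantile normalization: mean of tied rank quantiles
quantile_norm_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

# per-gene Welch t + BH through stats::t.test
welch_oracle <- function(a, b) {
  res <- t(vapply(seq_len(nrow(a)), function(i) {
    tt <- stats::t.test(a[i, ], b[i, ])
    c(t = unname(tt$statistic), p = tt$p.value)
  }, c(t = 0, p = 0)))
  data.frame(t = res[, "t"], p = res[, "p"],
             fdr = stats::p.adjust(res[, "p"], method = "BH"))
}

# per-site brute-force windowed Hudson FST from raw dosages
windowed_fst_oracle <- function(g, pops, window) {
  idx1 <- which(g$populations == pops[1])
  idx2 <- which(g$populations == pops[2])
  n_var <- nrow(g$geno)
  num <- den <- numeric(n_var)
  for (i in seq_len(n_var)) {
    g1 <- g$geno[i, idx1]; g2 <- g$geno[i, idx2]
    n1 <- 2 * sum(!is.na(g1)); n2 <- 2 * sum(!is.na(g2))
    p1 <- sum(g1, na.rm = TRUE) / n1; p2 <- sum(g2, na.rm = TRUE) / n2
    d <- p1 * (1 - p2) + p2 * (1 - p1)
    if (d > 0) {
      num[i] <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
        p2 * (1 - p2) / (n2 - 1)
      den[i] <- d
    }
  }
  win <- floor((g$variants$pos - 1) / window)
  sapply(split(seq_len(n_var), paste(g$variants$chrom, win)), function(i) {
    if (sum(den[i]) > 0) sum(num[i]) / sum(den[i]) else NA_real_
  })
}

# all-pairs interval/gene overlap (0-based half-open), no index structures
region_gene_overlap_oracle <- function(regions, genes, flank = 0) {
  hits <- character(0)
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      if (regions$chrom[i] == genes$chrom[j] &&
          regions$start[i] < genes$end[j] + flank &&
          genes$start[j] - flank < regions$end[i]) {
        hits <- c(hits, genes$gene_id[j])
      }
    }
  }
  sort(unique(hits))
}

# a tiny deterministic annotation used by interval/annotation tests
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    start = c(9999L, 30000L, 5000L),
    end = c(12000L, 34000L, 8000L),
    tss = c(9999L, 33999L, 5000L),
    stringsAsFactors = FALSE)
  genome_annotation(c(chr1 = 50000, chr2 = 20000), genes)
}

# small expression fixture: NB counts for two groups with planted shifts
nb_two_group <- function(n_genes, n_per_group, mu = 100, dispersion = 0.1,
                         lfc = numeric(n_genes), seed = 42L) {
  set.seed(seed)
  mu_g <- rep(mu, n_genes)
  a <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu_g,
                             size = 1 / dispersion),
              n_genes, n_per_group)
  b <- matrix(stats::rnbinom(n_genes * n_per_group, mu = mu_g * 2^lfc,
                             size = 1 / dispersion),
              n_genes, n_per_group)
  values <- cbind(a, b)
  rownames(values) <- sprintf("g%04d", seq_len(n_genes))
  colnames(values) <- c(sprintf("a%02d", seq_len(n_per_group)),
                        sprintf("b%02d", seq_len(n_per_group)))
  meta <- data.frame(sample_id = colnames(values),
                     tissue = "t", time_point = rep(c(0, 7), each = n_per_group),
                     group = rep(c("A", "B"), each = n_per_group),
                     animal_id = colnames(values))
  omics_matrix(values, "count", meta)
}
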