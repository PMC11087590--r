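# shared small linkage fixture: one genome + matrices with planted links
linkage_fixture <- function(seed = 27) {
  cfg <- sim_config(seed = seed, n_genes = 400L, n_tads = 20L,
                    n_peaks = 250L, n_links = 40L, replicates = 2L)
  g <- simulate_genome(cfg)
  e <- simulate_expression(cfg, g$annotation)
  a <- suppressMessages(simulate_accessibility(cfg, g, e$tpm, e$truth))
  list(cfg = cfg, genome = g, expr = e, acc = a)
}

test_that("TAD assignment uses peak midpoints and gene TSSs, half-open", {
  ann <- toy_annotation()
  tads <- interval_set(data.frame(chrom = "chr1", start = 0L,
                                  end = 100000L, id = "tadA"), role = "TAD")
  peaks <- interval_set(data.frame(chrom = "chr1",
                                   start = c(49750L, 99900L),
                                   end = c(50250L, 100300L),
                                   id = c("pIn", "pBoundary")),
                        role = "peak")
  cand <- suppressMessages(assign_to_tads(peaks, ann, tads))
  # midpoint 50000 is in; midpoint 100100 is out; both chr1 TSSs are in
  expect_setequal(cand$peak_id, "pIn")
  expect_setequal(cand$gene_id, c("gA", "gB"))

  # TSS exactly at the half-open end is excluded
  genes2 <- ann$genes
  genes2$tss[1] <- 100000L; genes2$start[1] <- 100000L
  genes2$end[1] <- 102000L
  ann2 <- genome_annotation(c(chr1 = 200000, chr2 = 20000), genes2)
  cand2 <- suppressMessages(assign_to_tads(peaks, ann2, tads))
  expect_false("gA" %in% cand2$gene_id)
})

test_that("TAD candidate pairs equal the brute-force all-pairs oracle", {
  fx <- linkage_fixture()
  cand <- suppressMessages(
    assign_to_tads(fx$acc$peaks, fx$genome$annotation, fx$genome$tads))
  peaks <- fx$acc$peaks; genes <- fx$genome$annotation$genes
  tads <- fx$genome$tads
  oracle <- character(0)
  for (ti in seq_len(nrow(tads))) {
    pin <- peaks$id[peaks$chrom == tads$chrom[ti] &
                      floor((peaks$start + peaks$end) / 2) >= tads$start[ti] &
                      floor((peaks$start + peaks$end) / 2) < tads$end[ti]]
    gin <- genes$gene_id[genes$chrom == tads$chrom[ti] &
                           genes$tss >= tads$start[ti] &
                           genes$tss < tads$end[ti]]
    if (length(pin) && length(gin)) {
      oracle <- c(oracle, as.vector(outer(pin, gin, paste,
                                          sep = "|", tads$id[ti])))
    }
  }
  expect_setequal(paste(cand$peak_id, cand$gene_id, cand$tad_id, sep = "|"),
                  unique(oracle))
})

test_that("link correlation equals the textbook Pearson formula", {
  set.seed(44)
  n <- 12
  meta <- data.frame(sample_id = sprintf("s%02d", 1:n), tissue = "t")
  gvec <- stats::rgamma(n, 5)
  expr <- omics_matrix(matrix(gvec, 1, n,
                              dimnames = list("gX", meta$sample_id)),
                       "TPM", meta)
  pvals <- rbind(pSame = gvec,
                 pAnti = max(gvec) - gvec,
                 pNoise = stats::rgamma(n, 5))
  colnames(pvals) <- meta$sample_id
  access <- omics_matrix(pvals, "RPKM", meta)
  cand <- data.frame(tad_id = "tad1",
                     peak_id = c("pSame", "pAnti", "pNoise"),
                     gene_id = "gX")
  links <- link_correlation(cand, access, expr)
  lg <- log2(gvec + 1)
  oracle <- c(1,
              stats::cor(log2(max(gvec) - gvec + 1), lg),
              stats::cor(log2(pvals["pNoise", ] + 1), lg))
  expect_equal(links$pcc, oracle, tolerance = 1e-12)
  expect_equal(links$pcc[1], 1)
  expect_lt(links$pcc[2], 0)

  const <- access
  const$values["pNoise", ] <- 3
  expect_message(link_correlation(cand, const, expr), "constant vector")
})

test_that("empirical null p-values are monotone in pcc and follow the formula", {
  fx <- linkage_fixture()
  cand <- suppressMessages(
    assign_to_tads(fx$acc$peaks, fx$genome$annotation, fx$genome$tads))
  links <- link_correlation(cand, fx$acc$rpkm, fx$expr$tpm)
  links <- suppressMessages(
    empirical_null_p(links, fx$acc$rpkm, fx$expr$tpm, fx$acc$peaks,
                     fx$genome$annotation, seed = 2))
  # monotone within each chromosome's null distribution
  chrom_of <- stats::setNames(fx$acc$peaks$chrom, fx$acc$peaks$id)
  for (chr in unique(chrom_of[links$peak_id])) {
    sub <- links[chrom_of[links$peak_id] == chr, ]
    ord <- order(sub$pcc)
    expect_true(all(diff(sub$empirical_p[ord]) <= 1e-12))
  }
  expect_true(all(links$empirical_p > 0 & links$empirical_p <= 1))
  # a link's p can never undercut the +1-corrected floor
  expect_gte(min(links$empirical_p), 1 / (1 + 1e5))
})

test_that("significance gates and planted-link recovery behave as specified", {
  links <- data.frame(tad_id = "t", peak_id = c("a", "b"),
                      gene_id = c("g1", "g2"),
                      pcc = c(0.3, 0.2), empirical_p = c(0.01, 0.001))
  flagged <- significant_links(links)
  expect_equal(flagged$significant, c(TRUE, FALSE))  # pcc gate blocks b

  fx <- linkage_fixture()
  cand <- suppressMessages(
    assign_to_tads(fx$acc$peaks, fx$genome$annotation, fx$genome$tads))
  res <- link_correlation(cand, fx$acc$rpkm, fx$expr$tpm)
  res <- suppressMessages(
    empirical_null_p(res, fx$acc$rpkm, fx$expr$tpm, fx$acc$peaks,
                     fx$genome$annotation, seed = 2))
  res <- significant_links(res)
  sig <- res[res$significant, ]
  truth <- fx$acc$truth$links
  expect_gte(mean(paste(truth$peak_id, truth$gene_id) %in%
                    paste(sig$peak_id, sig$gene_id)), 0.8)
  # structural guarantee: every reported link stays within one TAD
  tad_of_peak <- hypoxlink:::locate_in_intervals(
    fx$acc$peaks$chrom,
    floor((fx$acc$peaks$start + fx$acc$peaks$end) / 2), fx$genome$tads)
  names(tad_of_peak) <- fx$acc$peaks$id
  genes <- fx$genome$annotation$genes
  tad_of_gene <- hypoxlink:::locate_in_intervals(genes$chrom, genes$tss,
                                                 fx$genome$tads)
  names(tad_of_gene) <- genes$gene_id
  expect_true(all(fx$genome$tads$id[tad_of_peak[sig$peak_id]] == sig$tad_id))
  expect_true(all(fx$genome$tads$id[tad_of_gene[sig$gene_id]] == sig$tad_id))
})

test_that("differential accessibility gates on raw p as specified", {
  tab <- data.frame(peak_id = c("p1", "p2"), log2FC = c(0.6, 0.4),
                    p = c(0.01, 0.01), FDR = c(0.2, 0.2))
  res <- differential_accessibility(external_table = tab)
  expect_equal(res$is_dar, c(TRUE, FALSE))
  res_fdr <- differential_accessibility(external_table = tab, use_fdr = TRUE)
  expect_false(any(res_fdr$is_dar))
})

test_that("common genes keep concordant DAR-DEG links only", {
  links <- data.frame(
    tad_id = "t1", peak_id = paste0("p", 1:6),
    gene_id = paste0("g", 1:6), pcc = 0.5,
    empirical_p = 0.01, significant = TRUE)
  dars <- data.frame(peak_id = paste0("p", 1:6),
                     log2FC = c(1, 2, 0.8, -1, -2, 1.5),
                     p = 0.01, FDR = 0.01, is_dar = TRUE)
  degs <- data.frame(gene_id = paste0("g", 1:6),
                     log2FC = c(1.5, 1, 2, -1, -0.9, -2),
                     p = 0.001, FDR = 0.001, is_deg = TRUE)
  res <- common_genes(dars, degs, links)
  expect_equal(sum(res$genes$direction == "up"), 3L)
  expect_equal(sum(res$genes$direction == "down"), 2L)
  expect_false("g6" %in% res$genes$gene_id)  # discordant pair excluded

  empty <- common_genes(dars, degs,
                        transform(links, significant = FALSE))
  expect_equal(nrow(empty$genes), 0L)
})

test_that("peak annotation follows the promoter/genic/downstream precedence", {
  ann <- toy_annotation()
  # gA: chr1 + strand, TSS 9999; gB: chr1 - strand, TSS 33999
  peaks <- interval_set(data.frame(
    chrom = "chr1",
    start = c(8250L, 20000L, 31000L, 28000L, 45000L),
    end = c(8750L, 20500L, 31500L, 28500L, 45500L),
    id = c("upstream1500", "betweenGenes", "inGeneB", "pastGeneB",
           "farAway")), role = "peak")
  res <- annotate_peaks(peaks, ann)
  got <- stats::setNames(res$category, res$peak_id)
  expect_equal(unname(got["upstream1500"]), "promoter")  # TSS +/- 2 kb
  expect_equal(unname(got["inGeneB"]), "intron")  # genic collapses to intron
  expect_equal(unname(got["pastGeneB"]), "downstream")  # 3' of minus gene
  expect_equal(unname(got["farAway"]), "distal_intergenic")
  expect_equal(unname(got["betweenGenes"]), "distal_intergenic")
  # signed distance: 1500 bp upstream of a plus-strand TSS is negative
  expect_equal(res$distance_to_tss[res$peak_id == "upstream1500"], -1499)

  # with sub-features, exon/UTR take precedence over intron
  ann$features <- data.frame(chrom = "chr1", start = 31000L, end = 31600L,
                             type = "exon")
  res2 <- annotate_peaks(peaks, ann)
  expect_equal(res2$category[res2$peak_id == "inGeneB"], "exon")
})
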