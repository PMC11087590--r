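#!/usr/bin/env Rscript
# Stage 5: TAD-constrained cis-regulatory linkage. Candidate peak-gene
# pairs within shared TADs, Pearson correlation of log2(RPKM+1) vs
# log2(TPM+1), empirical per-chromosome null, significance at p < 0.05 and
# PCC >= 0.25, differential accessibility, DAR-DEG concordant "common
# genes", and genomic annotation of the peaks.

suppressMessages(library(hypoxlink))

annotation <- read_gene_annotation("results/data/genome.gff3")
tads <- read_bed("results/data/tads.bed", role = "TAD")
peaks <- read_bed("results/data/peaks.bed", role = "peak")
rpkm <- read_matrix_tsv("results/data/rpkm.tsv",
                        "results/data/atac_samples.tsv", unit = "RPKM")
tpm <- read_matrix_tsv("results/data/tpm.tsv",
                       "results/data/samples.tsv", unit = "TPM")
counts <- read_matrix_tsv("results/data/counts.tsv",
                          "results/data/samples.tsv", unit = "count")
truth_links <- utils::read.delim("results/data/truth_links.tsv",
                                 comment.char = "#")

cand <- assign_to_tads(peaks, annotation, tads)
links <- link_correlation(cand, rpkm, tpm)
links <- empirical_null_p(links, rpkm, tpm, peaks, annotation, seed = 1)
links <- significant_links(links, p_threshold = 0.05, pcc_threshold = 0.25)
sig <- links[links$significant, ]
message(nrow(cand), " candidate pairs; ", nrow(links), " scored; ",
        nrow(sig), " significant links")
message(sprintf("planted-link recall at the significance gates: %.3f",
                mean(paste(truth_links$peak_id, truth_links$gene_id) %in%
                       paste(sig$peak_id, sig$gene_id))))
write_result_tsv(links, "results/links.tsv",
                 provenance = list(p = 0.05, pcc = 0.25))

## differential accessibility and common genes (first vs last time point) ---
ameta <- rpkm$meta
t0 <- min(ameta$time_point); t1 <- max(ameta$time_point)
dars <- differential_accessibility(
  omics_matrix(round(rpkm$values), "count", ameta),
  ameta$sample_id[ameta$time_point == t0],
  ameta$sample_id[ameta$time_point == t1])
emeta <- counts$meta
degs <- differential_expression(
  counts,
  emeta$sample_id[emeta$time_point == t0],
  emeta$sample_id[emeta$time_point == t1])
cg <- common_genes(dars, degs, links)
message(sum(dars$is_dar), " DARs and ", sum(degs$is_deg),
        " DEGs in the contrast; ", nrow(cg$pairs),
        " concordant peak-gene pairs (",
        sum(cg$genes$direction == "up"), " up / ",
        sum(cg$genes$direction == "down"), " down genes)")
write_result_tsv(cg$pairs, "results/common_gene_pairs.tsv",
                 provenance = list(dar_p = 0.05, dar_lfc = 0.5,
                                   deg_fdr = 0.05, deg_lfc = 0.75))

## genomic annotation of peaks ----------------------------------------------
anno <- annotate_peaks(peaks, annotation, promoter_flank = 2000)
message("peak categories:")
print(table(anno$category))
write_result_tsv(anno, "results/peak_annotation.tsv",
                 provenance = list(promoter_flank = 2000))
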