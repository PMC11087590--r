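#!/usr/bin/env Rscript
# Stage 2: entropy-based chromatin tissue specificity. Quantile-normalize
# the peak RPKM matrix, score each peak's Shannon entropy across tissues,
# call tissue-restricted (H < 2.5) and conserved (top-500 H) peaks, and
# check recovery of the planted peak classes. Also ranks tissue-specific
# genes by Welch t on the expression side.

suppressMessages(library(hypoxlink))

rpkm <- read_matrix_tsv("results/data/rpkm.tsv",
                        "results/data/atac_samples.tsv", unit = "RPKM")
truth <- utils::read.delim("results/data/truth_peak_classes.tsv",
                           comment.char = "#")
dir.create("results", showWarnings = FALSE)

normed <- normalize_peak_matrix(rpkm)
ent <- classify_peaks(normed, entropy_threshold = 2.5, conserved_top = 500)
write_result_tsv(ent, "results/peak_entropy.tsv",
                 provenance = list(entropy_threshold = 2.5,
                                   conserved_top = 500))

message("peak classes: ", paste(names(table(ent$class)), table(ent$class),
                                sep = "=", collapse = " "))
restricted_truth <- truth$peak_id[truth$class == "restricted"]
called <- ent$peak_id[ent$class == "restricted"]
message(sprintf("planted restricted peaks recovered: %.3f",
                mean(restricted_truth %in% called)))
message(sprintf("ubiquitous peaks wrongly called restricted: %d",
                sum(truth$peak_id[truth$class == "ubiquitous"] %in% called)))

agree <- merge(ent[ent$class == "restricted",
                   c("peak_id", "assigned_tissue")],
               truth[truth$class == "restricted",
                     c("peak_id", "assigned_tissue")], by = "peak_id")
message(sprintf("tissue assignment agreement on restricted peaks: %.3f",
                mean(agree$assigned_tissue.x == agree$assigned_tissue.y)))

# tissue-specific genes: top-5% |t|, |log2FC| > 1, FDR < 0.01
tpm <- read_matrix_tsv("results/data/tpm.tsv",
                       "results/data/samples.tsv", unit = "TPM")
tissues <- unique(tpm$meta$tissue)
categories <- stats::setNames(tissues, tissues)  # every tissue its own category
tsg <- tissue_specific_genes(tpm, categories)
write_result_tsv(tsg[tsg$is_tsg, ], "results/tissue_specific_genes.tsv",
                 provenance = list(top = 0.05, lfc = 1, fdr = 0.01))
message("tissue-specific genes per tissue:")
print(table(tsg$tissue[tsg$is_tsg]))
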