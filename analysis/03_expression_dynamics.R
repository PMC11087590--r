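#!/usr/bin/env Rscript
# Stage 3: transcriptome dynamics. Per-tissue differential expression
# between the first two time points (FDR < 0.05, |log2FC| > 0.75),
# tissue-shared/specific classification, k-means on the multi-tissue
# log2FC matrix, polynomial time-series DCG detection (degree 4,
# R2 >= 0.4) and fuzzy c-means trajectory clustering with the
# center-splitting rule for the cluster count.

suppressMessages(library(hypoxlink))

counts <- read_matrix_tsv("results/data/counts.tsv",
                          "results/data/samples.tsv", unit = "count")
truth_degs <- utils::read.delim("results/data/truth_degs.tsv",
                                comment.char = "#")
truth_dcgs <- utils::read.delim("results/data/truth_dcgs.tsv",
                                comment.char = "#")
meta <- counts$meta
tissues <- unique(meta$tissue)
times <- sort(unique(meta$time_point))

## per-tissue DE between the first two time points --------------------------
de_tables <- lapply(tissues, function(ts) {
  differential_expression(
    counts,
    meta$sample_id[meta$tissue == ts & meta$time_point == times[1]],
    meta$sample_id[meta$tissue == ts & meta$time_point == times[2]])
})
names(de_tables) <- tissues
deg_sets <- lapply(de_tables, function(d) d$gene_id[d$is_deg])
message("DEGs per tissue: ", paste(tissues, lengths(deg_sets), sep = "=",
                                   collapse = " "))
recall <- vapply(tissues, function(ts)
  mean(truth_degs$gene_id[truth_degs$tissue == ts] %in% deg_sets[[ts]]), 0)
message(sprintf("mean planted-DEG recall across tissues: %.3f",
                mean(recall, na.rm = TRUE)))
write_result_tsv(do.call(rbind, Map(function(d, ts)
  data.frame(tissue = ts, d), de_tables, tissues)), "results/degs.tsv",
  provenance = list(fdr = 0.05, lfc = 0.75))

shared <- classify_shared_specific(deg_sets, min_shared = 5)
message(length(shared$shared), " tissue-shared DEGs (>= 5 tissues); ",
        sum(lengths(shared$specific)), " tissue-specific DEGs")

## multi-tissue interaction clustering on log2FC ----------------------------
common <- Reduce(intersect, lapply(de_tables, `[[`, "gene_id"))
fc <- vapply(de_tables, function(d) d$log2FC[match(common, d$gene_id)],
             numeric(length(common)))
rownames(fc) <- common
moved <- rowSums(abs(fc) > 0.75) > 0
km <- multi_tissue_kmeans(fc[moved, , drop = FALSE], k_range = 2:8, seed = 1)
message("k-means on ", sum(moved), " responsive genes chose k = ", km$k,
        " (silhouette ", round(max(km$silhouette), 3), ")")

## time-series DCG detection and trajectory clustering ----------------------
vst <- om_log2cpm(counts)
dcg_sets <- list()
for (ts in tissues) {
  cols <- vst$meta$tissue == ts
  dcg <- detect_dcgs(vst$values[, cols], vst$meta$time_point[cols])
  dcg_sets[[ts]] <- dcg$gene_id[dcg$is_dcg]
}
message("DCGs per tissue: ", paste(tissues, lengths(dcg_sets), sep = "=",
                                   collapse = " "))
dcg_recall <- vapply(tissues, function(ts)
  mean(truth_dcgs$gene_id[truth_dcgs$tissue == ts] %in% dcg_sets[[ts]]), 0)
message(sprintf("mean planted-DCG recall across tissues: %.3f",
                mean(dcg_recall, na.rm = TRUE)))
write_result_tsv(data.frame(tissue = rep(tissues, lengths(dcg_sets)),
                            gene_id = unlist(dcg_sets)),
                 "results/dcgs.tsv",
                 provenance = list(degree = 4, r2 = 0.4, fdr = 0.05))

# soft-cluster the mean trajectories of the tissue with the most DCGs
ts_top <- tissues[which.max(lengths(dcg_sets))]
cols <- vst$meta$tissue == ts_top
traj <- t(vapply(dcg_sets[[ts_top]], function(g)
  tapply(vst$values[g, cols], vst$meta$time_point[cols], mean),
  numeric(length(times))))
traj <- standardize_rows(traj)
cc <- choose_cluster_number(traj, c_range = 2:8, seed = 1)
fit <- fuzzy_cmeans(traj, c = cc, seed = 1)
message("fuzzy c-means in ", ts_top, ": ", cc, " clusters over ",
        nrow(traj), " DCG trajectories (final objective ",
        round(fit$objective[length(fit$objective)], 1), ")")
write_result_tsv(data.frame(gene_id = rownames(traj),
                            cluster = fit$cluster,
                            max_membership = apply(fit$membership, 1, max)),
                 "results/dcg_clusters.tsv",
                 provenance = list(tissue = ts_top, c = cc, m = 2))
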