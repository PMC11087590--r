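#!/usr/bin/env Rscript
# Stage 4: selection scan and its intersection with expression. SNP QC
# (call rate > 90%, MAF > 0.05), 10-kb windowed Hudson FST between the
# lowland and highland populations, top-5% region calling, annotation to
# genes, multi-tissue intersection with the DEG/DCG sets, a permutation
# test of the FST-gene x DEG overlap, and the four-taxon D-statistic.

suppressMessages(library(hypoxlink))

geno <- read_vcf_subset("results/data/genotypes.vcf")
pops <- utils::read.delim("results/data/populations.tsv",
                          comment.char = "#")
geno <- genotype_matrix(geno$variants, geno$geno,
                        stats::setNames(pops$population, pops$sample_id))
truth_win <- utils::read.delim("results/data/truth_selected_windows.tsv",
                               comment.char = "#")

filt <- filter_snps(geno, call_rate = 0.9, maf = 0.05)
windows <- windowed_fst(filt, c("lowland", "highland"),
                        window = 1e4, step = 1e4, min_snps = 5)
regions <- top_windows(windows, top_fraction = 0.05)
write_result_tsv(windows, "results/fst_windows.tsv",
                 provenance = list(window = 1e4, step = 1e4, top = 0.05))
write_bed(regions, "results/fst_regions.bed")

hit <- vapply(seq_len(nrow(truth_win)), function(i)
  any(regions$chrom == truth_win$chrom[i] &
        regions$start < truth_win$end[i] &
        regions$end > truth_win$start[i]), TRUE)
message(sprintf(
  "windows: %d (%d eligible); %d candidate regions; planted sensitivity %.2f",
  nrow(windows), sum(windows$eligible), nrow(regions), mean(hit)))

annotation <- read_gene_annotation("results/data/genome.gff3")
fst_genes <- annotate_regions_to_genes(regions, annotation)
message(length(fst_genes), " genes overlap candidate selected regions")

## intersect with per-tissue DEG and DCG sets -------------------------------
degs <- utils::read.delim("results/degs.tsv", comment.char = "#")
deg_sets <- split(degs$gene_id[degs$is_deg == "TRUE" | degs$is_deg == TRUE],
                  degs$tissue[degs$is_deg == "TRUE" | degs$is_deg == TRUE])
deg_sets <- deg_sets[lengths(deg_sets) > 0]
dcgs <- utils::read.delim("results/dcgs.tsv", comment.char = "#")
dcg_sets <- split(dcgs$gene_id, dcgs$tissue)

if (length(deg_sets) >= 5) {
  mt_deg <- multi_tissue_intersection(fst_genes, deg_sets, min_tissues = 5)
  message(nrow(mt_deg), " multi-tissue FST genes among DEGs (>= 5 tissues)")
}
mt_dcg <- multi_tissue_intersection(fst_genes, dcg_sets, min_tissues = 5)
message(nrow(mt_dcg), " multi-tissue FST genes among DCGs (>= 5 tissues)")

## permutation test: FST genes vs all DEGs over the tested universe ---------
universe <- unique(degs$gene_id)
all_degs <- unique(unlist(deg_sets))
ot <- overlap_permutation_test(intersect(fst_genes, universe), all_degs,
                               universe, n_perm = 1000, seed = 1)
print(ot)

## four-taxon D-statistic ----------------------------------------------------
freqs <- utils::read.delim("results/data/four_taxon_freqs.tsv",
                           comment.char = "#")
ds <- d_statistic(freqs, block_size = 5e6)
print(ds)
write_result_tsv(data.frame(abba = ds$abba, baba = ds$baba, D = ds$D,
                            se = ds$se, Z = ds$Z,
                            significant = ds$significant),
                 "results/dstat.tsv", provenance = list(block_size = 5e6))
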