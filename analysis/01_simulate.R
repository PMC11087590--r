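#!/usr/bin/env Rscript
# Stage 1: simulate every pipeline input with planted truth and serialize
# it in the standard formats (GFF3, BED, TSV + metadata, VCF), so the later
# stages consume files exactly as a real study would.

suppressMessages(library(hypoxlink))

cfg <- read_run_config("analysis/config.yaml")
sim <- cfg$sim
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("simulating genome: ", sim$n_genes, " genes, ", sim$n_tads,
        " TADs on ", sim$n_chromosomes, " chromosomes")
genome <- simulate_genome(sim)
write_gene_annotation(genome$annotation, "results/data/genome.gff3")
write_bed(genome$tads, "results/data/tads.bed")

message("simulating expression: ", length(sim$tissues), " tissues x ",
        length(sim$time_points), " time points x ", sim$replicates,
        " replicates")
expr <- simulate_expression(sim, genome$annotation)
write_matrix_tsv(expr$counts, "results/data/counts.tsv",
                 "results/data/samples.tsv",
                 provenance = list(seed = sim$seed, unit = "count"))
write_matrix_tsv(expr$tpm, "results/data/tpm.tsv",
                 provenance = list(seed = sim$seed, unit = "TPM"))

message("simulating accessibility with ", sim$n_links,
        " planted peak-gene links at r = ", sim$r_true)
acc <- simulate_accessibility(sim, genome, expr$tpm, expr$truth)
write_matrix_tsv(acc$rpkm, "results/data/rpkm.tsv",
                 "results/data/atac_samples.tsv",
                 provenance = list(seed = sim$seed, unit = "RPKM"))
write_bed(acc$peaks, "results/data/peaks.bed")

message("simulating genotypes: Balding-Nichols F = ", sim$f_background,
        " with ", sim$n_planted_windows, " windows at F = ", sim$f_high)
gen <- simulate_genotypes(sim)
write_vcf_subset(gen$genotypes, "results/data/genotypes.vcf")
write_result_tsv(data.frame(sample_id = gen$genotypes$samples,
                            population = unname(gen$genotypes$populations)),
                 "results/data/populations.tsv",
                 provenance = list(seed = sim$seed))

four <- simulate_four_taxon(sim)
write_result_tsv(four$freqs, "results/data/four_taxon_freqs.tsv",
                 provenance = list(seed = sim$seed,
                                   introgression_f = sim$introgression_f))

truth <- acc$truth
for (nm in c("degs", "dcgs", "links", "peak_classes")) {
  write_result_tsv(truth[[nm]], sprintf("results/data/truth_%s.tsv", nm),
                   provenance = list(seed = sim$seed))
}
write_result_tsv(gen$truth$selected_windows,
                 "results/data/truth_selected_windows.tsv",
                 provenance = list(seed = sim$seed))

message("done: planted ", nrow(truth$degs), " DEG assignments, ",
        nrow(truth$dcgs), " DCG assignments, ", nrow(truth$links),
        " links, ", nrow(gen$truth$selected_windows),
        " elevated-FST windows")
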