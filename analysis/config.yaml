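# Shared configuration for the numbered analysis scripts.
# Study-design defaults: 8 ATAC tissues, 5 acclimatization time points
# (0, 7, 14, 21, ~245 days), 10 RNA replicates per cell.
seed: 1
sim:
  seed: 1
  n_genes: 2000
  n_tads: 50
  n_peaks: 1000
  n_links: 100
  replicates: 10
  n_snps: 2000
  n_planted_windows: 5
out_dir: results/pipeline
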