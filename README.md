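# hypoxlink

Statistical toolkit for multi-omics studies of **high-altitude hypoxia
acclimatization** in a translocated large-animal model. A lowland breed
moved to altitude and profiled across whole-body tissues at several time
points produces four data layers — expression counts/TPM, ATAC-seq peak
RPKM, TAD intervals, and lowland/highland genotypes — and this package
implements the bespoke statistics that tie them together:

- **Entropy tissue specificity of chromatin.** Per peak, relative
  accessibility `R_i = E_i / Σ E_i` over per-tissue medians of
  quantile-normalized RPKM, and the Shannon score
  `H = Σ −R_i log2(R_i)` (bits, `0 ≤ H ≤ log2 N`). Peaks with `H < 2.5`
  are tissue-restricted (assigned to the tissue with maximal signal);
  the top-500 `H` peaks are conserved.
- **TAD-constrained peak–gene linkage.** All peak × gene pairs within a
  shared TAD (peak by midpoint, gene by TSS), scored by Pearson
  correlation of `log2(RPKM+1)` vs `log2(TPM+1)` across matched samples,
  against an empirical per-chromosome null (TAD peaks × all genes on the
  chromosome); significant at empirical `p < 0.05` and `PCC ≥ 0.25`.
- **Differential expression/accessibility concordance.** DEGs at
  `FDR < 0.05, |log2FC| > 0.75`; DARs at raw `p < 0.05, |log2FC| > 0.5`;
  "common genes" are significant links whose DAR and DEG move in the
  same direction. Engines are pluggable — external DE/DAR tables are
  accepted verbatim.
- **Selection scan.** SNP QC (call rate > 90%, MAF > 0.05), Hudson FST
  in 10-kb windows as a ratio of sums, top-5% regions, gene annotation,
  multi-tissue intersection with DEG/DCG sets, and a permutation overlap
  test with the +1-corrected empirical p.
- **Time-series dynamics.** Dynamically changed genes by degree-4
  polynomial regression (`R² ≥ 0.4`, FDR < 0.05) and fuzzy c-means
  trajectory clustering (Bezdek updates, fuzzifier `m = 2`) with a
  center-splitting rule for the cluster count.
- **Introgression.** Four-taxon ABBA-BABA
  `D = Σ(ABBA−BABA)/Σ(ABBA+BABA)` with block-jackknife SE and the
  `|Z| > 3` two-tailed rule.

A first-class synthetic-data generator plants known truth (DEGs, DCGs,
restricted peaks, links, elevated-FST windows, gene flow) so the whole
pipeline is testable end-to-end with no external data. See the methods
vignette (`vignettes/hypoxlink-methods.Rmd`) for the models, parameter
choices and limitations.

## Worked example

Small self-contained calls, with the output they print:

```r
library(hypoxlink)

# entropy of a peak with per-tissue medians E = (4, 2, 1, 1)
peak_entropy(relative_accessibility(c(4, 2, 1, 1)))
#> [1] 1.75          # bits; < 2.5, so this peak would be tissue-restricted

# permutation overlap test: 5 selection-scan genes, 8 DEGs, universe of 20,
# all 5 overlap
overlap_permutation_test(sprintf("g%02d", 1:5), sprintf("g%02d", 1:8),
                         sprintf("g%02d", 1:20), n_perm = 10000, seed = 3)
#> Overlap test: |A|=5 |B|=8 N=20 observed=5 null=2.00+/-0.97 p=0.0044 (10000 perms)
# (exhaustive enumeration gives P = 56/15504 ≈ 0.0036; the null mean is |A||B|/N = 2)

# four-taxon D from 30 ABBA-patterned and 10 BABA-patterned sites
toy <- data.frame(chrom = "chr1", pos = seq(1e5, by = 5e6, length.out = 40),
                  p1 = c(rep(0, 30), rep(1, 10)),
                  p2 = c(rep(1, 30), rep(0, 10)), p3 = 1)
d_statistic(toy)
#> D = 0.5000 (SE 0.1387, Z = 3.61, 40 blocks) *
```

The end-to-end demonstration simulates every input, runs all stages, and
asserts the planted-truth recovery checks (restricted-peak sensitivity
≥ 0.95, FST-window sensitivity ≥ 0.9, link recall ≥ 0.8, D-statistic
flag matching the planted truth):

```r
report <- run_demo(seed = 1, scale = "tiny")
#> demo: all planted-truth checks passed
print(report)
#> hypoxlink run (seed 1 )
#>   simulate   genes=400 tads=20 peaks=250 snps=1500
#>   entropy    conserved=208 restricted=42
#>   ...
#>   link       candidates=1285 links=1285 significant=63
#> truth recovery:
#>   restricted_recall                1.000
#>   fst_window_sensitivity           1.000
#>   link_recall                      1.000
```

(At the tiny 3-replicate scale the Welch DE engine is underpowered and
planted DEG recall is near zero — expected; at the 10-replicate study
scale used by `analysis/03_expression_dynamics.R` it recovers ≈ 0.9.)

## Analysis workflow

The `analysis/` scripts run the study workflow as a narrative over files
in the standard formats, controlled by `analysis/config.yaml`:

```sh
Rscript analysis/01_simulate.R             # write GFF3/BED/TSV/VCF inputs + truth
Rscript analysis/02_tissue_specificity.R   # entropy classes + tissue-specific genes
Rscript analysis/03_expression_dynamics.R  # DEGs, shared/specific, k-means, DCGs, c-means
Rscript analysis/04_selection_scan.R       # FST windows, regions, overlap test, D
Rscript analysis/05_cre_linkage.R          # TAD linkage, DARs, common genes, annotation
```

Outputs land under `results/` as provenance-stamped TSV/BED.

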