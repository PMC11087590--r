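# SNP QC, windowed Hudson FST scan, gene annotation of selected regions,
# multi-tissue intersections with permutation overlap testing, and the
# four-taxon ABBA-BABA D-statistic.

#' Filter SNPs on call rate and minor allele frequency
#'
#' Retains SNPs with call rate strictly above `call_rate` AND minor allele
#' frequency strictly above `maf`, both computed over all samples; missing
#' genotypes are excluded from both the numerator and denominator of the
#' allele frequency.
#'
#' @param g A `GenotypeMatrix`.
#' @param call_rate Call-rate threshold (default 0.9).
#' @param maf MAF threshold (default 0.05).
#' @return The filtered `GenotypeMatrix`; removal counts reported via
#'   `message`.
#' @export
filter_snps <- function(g, call_rate = 0.9, maf = 0.05) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  called <- !is.na(g$geno)
  cr <- rowMeans(called)
  alt <- rowSums(g$geno, na.rm = TRUE) / (2 * rowSums(called))
  freq_minor <- pmin(alt, 1 - alt)
  pass_cr <- cr > call_rate
  pass_maf <- freq_minor > maf & !is.na(freq_minor)
  keep <- pass_cr & pass_maf
  message(sprintf(
    "filter_snps: removed %d low-call-rate and %d low-MAF SNP(s); %d retained",
    sum(!pass_cr), sum(pass_cr & !pass_maf), sum(keep)))
  if (!any(keep)) warning("no SNPs survive QC")
  genotype_matrix(g$variants[keep, , drop = FALSE],
                  g$geno[keep, , drop = FALSE], g$populations)
}

#' Hudson per-site FST components
#'
#' num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1);
#' den = p1(1-p2) + p2(1-p1), with n the number of called chromosomes.
#' Sites with den = 0 (both populations fixed for the same allele)
#' contribute (0, 0) and are excluded from window sums.
#'
#' @param p1,p2 Alternate-allele frequencies in the two populations
#'   (vectorized).
#' @param n1,n2 Called chromosome counts (>= 2).
#' @return list with `num` and `den` vectors (0/0 at excluded sites).
#' @export
hudson_fst_site <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("need >= 2 called chromosomes per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  drop <- den == 0
  num[drop] <- 0
  den[drop] <- 0
  list(num = num, den = den)
}

# per-population alternate-allele frequency and called-chromosome count
pop_freqs <- function(g, pop) {
  cols <- which(g$populations == pop)
  if (!length(cols)) stop("unknown population: ", pop)
  sub <- g$geno[, cols, drop = FALSE]
  called <- !is.na(sub)
  n_chr <- 2 * rowSums(called)
  list(p = rowSums(sub, na.rm = TRUE) / pmax(n_chr, 1), n = n_chr)
}

#' Windowed Hudson FST (ratio of sums)
#'
#' Windows tile [0, chrom length) with the given size and step; each
#' window's FST is the ratio of summed per-site numerators and denominators
#' over its SNPs. Windows with fewer than `min_snps` informative sites are
#' flagged ineligible and excluded from downstream quantiles.
#'
#' @param g A filtered `GenotypeMatrix` with population labels.
#' @param pops Character vector of the two population names.
#' @param window,step Window size and step in bp (defaults 10 kb / 10 kb).
#' @param min_snps Minimum informative SNPs per eligible window (default 5).
#' @param chrom_lengths Optional named lengths; defaults to the last SNP
#'   position per chromosome rounded up to a full window.
#' @return data.frame (class `FstWindow`) with chrom, start, end, n_snps,
#'   numerator_sum, denominator_sum, fst, eligible.
#' @export
windowed_fst <- function(g, pops, window = 1e4, step = 1e4, min_snps = 5,
                         chrom_lengths = NULL) {
  stopifnot(inherits(g, "GenotypeMatrix"), length(pops) == 2)
  if (is.null(g$populations)) stop("genotype matrix lacks population labels")
  if (window %% step != 0) {
    message("window is not a multiple of step; windows will overlap unevenly")
  }
  f1 <- pop_freqs(g, pops[1])
  f2 <- pop_freqs(g, pops[2])
  site <- hudson_fst_site(f1$p, f1$n, f2$p, f2$n)
  informative <- site$den > 0
  out <- list()
  for (chrom in unique(g$variants$chrom)) {
    on_chr <- g$variants$chrom == chrom
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else
      ceiling(max(g$variants$pos[on_chr]) / window) * window
    starts <- seq(0, L - 1, by = step)
    pos0 <- g$variants$pos[on_chr] - 1L  # to 0-based
    num <- site$num[on_chr]; den <- site$den[on_chr]
    inf <- informative[on_chr]
    idx <- lapply(starts, function(s) which(pos0 >= s & pos0 < s + window & inf))
    out[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = pmin(starts + window, L),
      n_snps = lengths(idx),
      numerator_sum = vapply(idx, function(i) sum(num[i]), 0),
      denominator_sum = vapply(idx, function(i) sum(den[i]), 0))
  }
  res <- do.call(rbind, out)
  res$fst <- ifelse(res$denominator_sum > 0,
                    res$numerator_sum / res$denominator_sum, NA_real_)
  res$eligible <- res$n_snps >= min_snps
  rownames(res) <- NULL
  class(res) <- c("FstWindow", "data.frame")
  res
}

#' Call the top-FST windows and merge them into candidate selected regions
#'
#' Eligible windows at or above the empirical (1 - `top_fraction`) quantile
#' of window FST are selected (ties at the quantile all included); adjacent
#' selected windows are merged.
#'
#' @param windows A `FstWindow` data.frame.
#' @param top_fraction Upper tail to call (default 0.05).
#' @return An `IntervalSet` of merged regions (score = max window FST).
#' @export
top_windows <- function(windows, top_fraction = 0.05) {
  elig <- windows[windows$eligible & !is.na(windows$fst), , drop = FALSE]
  if (nrow(elig) < 20) stop("need >= 20 eligible windows for a stable quantile")
  cut <- stats::quantile(elig$fst, 1 - top_fraction, names = FALSE)
  sel <- elig[elig$fst >= cut, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$start), ]
  new_region <- c(TRUE, sel$chrom[-1] != sel$chrom[-nrow(sel)] |
                    sel$start[-1] != sel$end[-nrow(sel)])
  grp <- cumsum(new_region)
  merged <- do.call(rbind, lapply(split(sel, grp), function(b) {
    data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end),
               score = max(b$fst))
  }))
  merged$id <- sprintf("region_%03d", seq_len(nrow(merged)))
  interval_set(merged, role = "region")
}

#' Genes overlapping candidate regions
#'
#' A gene is annotated to the region set when its body (extended by `flank`
#' on both sides) overlaps any region by at least 1 bp (0-based half-open
#' arithmetic).
#'
#' @param regions An `IntervalSet` of regions.
#' @param annotation A `GenomeAnnotation`.
#' @param flank Symmetric extension of gene bodies in bp (default 0).
#' @return Character vector of gene ids.
#' @export
annotate_regions_to_genes <- function(regions, annotation, flank = 0) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  genes <- annotation$genes
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank, 0) + 1L, genes$end + flank))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Multi-tissue intersection of a selection gene set with per-tissue sets
#'
#' @param fst_genes Character vector of selection-scan genes.
#' @param per_tissue_gene_sets Named list of per-tissue gene-id vectors
#'   (e.g. DEGs or DCGs per tissue).
#' @param min_tissues Minimum tissue support (default 5).
#' @return data.frame with gene_id, n_tissues, tissues (comma-joined) for
#'   genes in `fst_genes` present in at least `min_tissues` sets.
#' @export
multi_tissue_intersection <- function(fst_genes, per_tissue_gene_sets,
                                      min_tissues = 5) {
  if (length(per_tissue_gene_sets) < min_tissues) {
    stop("fewer tissues provided than min_tissues")
  }
  hits <- lapply(fst_genes, function(g) {
    ts <- names(per_tissue_gene_sets)[vapply(per_tissue_gene_sets,
                                             function(s) g %in% s, TRUE)]
    if (length(ts) >= min_tissues) {
      data.frame(gene_id = g, n_tissues = length(ts),
                 tissues = paste(ts, collapse = ","),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), n_tissues = integer(0),
                      tissues = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Permutation test for gene-set overlap enrichment
#'
#' Null: redraw a uniform random subset of the universe of size |A| and
#' intersect it with B, `n_perm` times. Empirical one-sided (greater) p
#' with the +1 correction: p = (1 + #(null >= observed)) / (1 + n_perm).
#'
#' @param set_a,set_b Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return list (class `OverlapTestResult`) with observed, null_mean,
#'   null_sd, p, n_perm, sizes.
#' @export
overlap_permutation_test <- function(set_a, set_b, universe, n_perm = 1000,
                                     seed = 1L) {
  bad <- setdiff(set_a, universe)
  if (length(bad)) {
    stop("set A members outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad_b <- setdiff(set_b, universe)
  if (length(bad_b)) {
    stop("set B members outside the universe: ",
         paste(utils::head(bad_b, 5), collapse = ", "))
  }
  observed <- length(intersect(set_a, set_b))
  in_b <- universe %in% set_b
  set.seed(derive_seed(seed, "null"))
  null <- vapply(seq_len(n_perm), function(i)
    sum(in_b[sample.int(length(universe), length(set_a))]), 0L)
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(observed = observed, null_mean = mean(null),
                 null_sd = stats::sd(null), p = p, n_perm = n_perm,
                 size_a = length(set_a), size_b = length(set_b),
                 size_universe = length(universe)),
            class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
  cat(sprintf(
    "Overlap test: |A|=%d |B|=%d N=%d observed=%d null=%.2f+/-%.2f p=%.4g (%d perms)\n",
    x$size_a, x$size_b, x$size_universe, x$observed, x$null_mean, x$null_sd,
    x$p, x$n_perm))
  invisible(x)
}

#' Four-taxon ABBA-BABA D-statistic with block-jackknife Z
#'
#' Site contributions on derived-allele frequencies (outgroup-polarized):
#' ABBA = (1-p1) p2 p3, BABA = p1 (1-p2) p3;
#' D = sum(ABBA - BABA) / sum(ABBA + BABA). The standard error comes from a
#' delete-one jackknife over contiguous genomic blocks of `block_size` bp
#' and Z = D / SE, significant when |Z| > 3 (two-tailed).
#'
#' @param freqs data.frame with chrom, pos and derived-allele frequency
#'   columns p1, p2, p3.
#' @param block_size Jackknife block size in bp (default 5e6).
#' @param z_threshold Significance threshold on |Z| (default 3).
#' @return list (class `DStatResult`) with abba, baba, D, se, Z,
#'   significant, n_blocks.
#' @export
d_statistic <- function(freqs, block_size = 5e6, z_threshold = 3) {
  stopifnot(all(c("chrom", "pos", "p1", "p2", "p3") %in% names(freqs)))
  abba <- (1 - freqs$p1) * freqs$p2 * freqs$p3
  baba <- freqs$p1 * (1 - freqs$p2) * freqs$p3
  tot <- sum(abba) + sum(baba)
  if (tot == 0) stop("sum(ABBA + BABA) = 0: D undefined")
  D <- (sum(abba) - sum(baba)) / tot
  block <- paste(freqs$chrom, floor((freqs$pos - 1) / block_size))
  blocks <- unique(block)
  if (length(blocks) < 20) {
    stop("need >= 20 jackknife blocks (got ", length(blocks),
         "); reduce block_size or add sites")
  }
  num_b <- vapply(blocks, function(b) sum(abba[block == b] - baba[block == b]), 0)
  den_b <- vapply(blocks, function(b) sum(abba[block == b] + baba[block == b]), 0)
  d_loo <- (sum(num_b) - num_b) / (sum(den_b) - den_b)
  nb <- length(blocks)
  se <- sqrt((nb - 1) / nb * sum((d_loo - mean(d_loo))^2))
  Z <- if (se > 0) D / se else if (D == 0) 0 else Inf * sign(D)
  structure(list(abba = sum(abba), baba = sum(baba), D = D, se = se, Z = Z,
                 significant = abs(Z) > z_threshold, n_blocks = nb),
            class = "DStatResult")
}

#' @export
print.DStatResult <- function(x, ...) {
  cat(sprintf("D = %.4f (SE %.4f, Z = %.2f, %d blocks)%s\n", x$D, x$se, x$Z,
              x$n_blocks, if (x$significant) " *" else ""))
  invisible(x)
}
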