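# TAD-constrained peak-gene correlation linkage with an empirical null,
# differential accessibility, DAR-DEG concordance ("common genes"), and
# genomic peak annotation.

#' Candidate peak-gene pairs within shared TADs
#'
#' A peak belongs to a TAD when its midpoint lies inside; a gene belongs
#' when its TSS lies inside (0-based half-open). Candidates are all
#' within-TAD peak x gene pairs; with overlapping TADs a peak or gene can
#' appear under several TADs, each processed independently.
#'
#' @param peaks An `IntervalSet` of peaks.
#' @param annotation A `GenomeAnnotation`.
#' @param tads An `IntervalSet` of TADs.
#' @return data.frame with tad_id, peak_id, gene_id.
#' @export
assign_to_tads <- function(peaks, annotation, tads) {
  stopifnot(inherits(annotation, "GenomeAnnotation"))
  genes <- annotation$genes
  mid <- floor((peaks$start + peaks$end) / 2)
  gr_tad <- GenomicRanges::GRanges(tads$chrom,
                                   IRanges::IRanges(tads$start + 1L, tads$end))
  gr_peak <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(mid + 1L, mid + 1L))
  gr_tss <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1L,
                                                    genes$tss + 1L))
  ph <- GenomicRanges::findOverlaps(gr_peak, gr_tad)
  gh <- GenomicRanges::findOverlaps(gr_tss, gr_tad)
  p_by_tad <- split(peaks$id[S4Vectors::queryHits(ph)],
                    S4Vectors::subjectHits(ph))
  g_by_tad <- split(genes$gene_id[S4Vectors::queryHits(gh)],
                    S4Vectors::subjectHits(gh))
  both <- intersect(names(p_by_tad), names(g_by_tad))
  message(sprintf("assign_to_tads: %d/%d peaks and %d/%d genes fall in a TAD",
                  length(unique(S4Vectors::queryHits(ph))), nrow(peaks),
                  length(unique(S4Vectors::queryHits(gh))), nrow(genes)))
  if (!length(both)) {
    return(data.frame(tad_id = character(0), peak_id = character(0),
                      gene_id = character(0)))
  }
  out <- do.call(rbind, lapply(both, function(ti) {
    expand.grid(peak_id = p_by_tad[[ti]], gene_id = g_by_tad[[ti]],
                stringsAsFactors = FALSE)
  }))
  tad_rep <- rep(tads$id[as.integer(both)],
                 vapply(both, function(ti)
                   length(p_by_tad[[ti]]) * length(g_by_tad[[ti]]), 0L))
  out <- data.frame(tad_id = tad_rep, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of candidate peak-gene pairs
#'
#' PCC is computed between log2(RPKM+1) accessibility and log2(TPM+1)
#' expression over the samples shared by the two matrices. Pairs with a
#' constant accessibility or expression vector are skipped (correlation
#' undefined).
#'
#' @param candidates data.frame from [assign_to_tads()].
#' @param access An `OmicsMatrix` of peak RPKM (or log2RPKM1).
#' @param expr An `OmicsMatrix` of gene TPM (or log2TPM1).
#' @return `candidates` with a `pcc` column, skipped pairs removed.
#' @export
link_correlation <- function(candidates, access, expr) {
  stopifnot(inherits(access, "OmicsMatrix"), inherits(expr, "OmicsMatrix"))
  shared <- intersect(colnames(access$values), colnames(expr$values))
  if (length(shared) < 10) stop("need >= 10 matched samples, got ",
                                length(shared))
  a <- access$values[, shared, drop = FALSE]
  if (access$unit == "RPKM") a <- log2(a + 1)
  e <- expr$values[, shared, drop = FALSE]
  if (expr$unit == "TPM") e <- log2(e + 1)
  cand <- candidates[candidates$peak_id %in% rownames(a) &
                       candidates$gene_id %in% rownames(e), , drop = FALSE]
  sda <- apply(a, 1, stats::sd)
  sde <- apply(e, 1, stats::sd)
  ok <- sda[cand$peak_id] > 0 & sde[cand$gene_id] > 0
  if (any(!ok)) {
    message(sprintf("link_correlation: %d pair(s) skipped (constant vector)",
                    sum(!ok)))
  }
  cand <- cand[ok, , drop = FALSE]
  az <- t(scale(t(a)))  # row-standardized: PCC is a scaled dot product
  ez <- t(scale(t(e)))
  n <- length(shared)
  cand$pcc <- rowSums(az[cand$peak_id, , drop = FALSE] *
                        ez[cand$gene_id, , drop = FALSE]) / (n - 1)
  rownames(cand) <- NULL
  cand
}

#' Empirical null p-values for peak-gene correlations
#'
#' Per chromosome, the null is the PCC distribution of TAD-assigned peaks
#' against all genes on that chromosome (uniformly subsampled to at most
#' `max_null` pairs, seeded); chromosomes with fewer than `min_null` null
#' pairs are pooled genome-wide. One-sided positive-tail p with the +1
#' correction, so p is monotone decreasing in pcc.
#'
#' @param links Output of [link_correlation()].
#' @param access,expr The matrices used for the link correlations.
#' @param peaks An `IntervalSet` of peaks (for chromosome lookup).
#' @param annotation A `GenomeAnnotation` (for gene chromosomes).
#' @param max_null Null-pair cap per chromosome (default 1e5).
#' @param min_null Minimum per-chromosome null size before pooling
#'   (default 200).
#' @param seed Seed for the subsampling.
#' @return `links` with an `empirical_p` column.
#' @export
empirical_null_p <- function(links, access, expr, peaks, annotation,
                             max_null = 1e5, min_null = 200, seed = 1L) {
  stopifnot(nrow(links) > 0)
  shared <- intersect(colnames(access$values), colnames(expr$values))
  a <- access$values[, shared, drop = FALSE]
  if (access$unit == "RPKM") a <- log2(a + 1)
  e <- expr$values[, shared, drop = FALSE]
  if (expr$unit == "TPM") e <- log2(e + 1)
  az <- t(scale(t(a)))
  ez <- t(scale(t(e)))
  n <- length(shared)
  peak_chrom <- stats::setNames(peaks$chrom, peaks$id)
  gene_chrom <- stats::setNames(annotation$genes$chrom,
                                annotation$genes$gene_id)
  set.seed(derive_seed(seed, "null"))
  null_for <- function(pk_ids, g_ids) {
    pk_ids <- pk_ids[!is.na(rowSums(az[pk_ids, , drop = FALSE]))]
    g_ids <- g_ids[!is.na(rowSums(ez[g_ids, , drop = FALSE]))]
    n_pairs <- length(pk_ids) * length(g_ids)
    if (n_pairs == 0) return(numeric(0))
    if (n_pairs <= max_null) {
      cc <- (az[pk_ids, , drop = FALSE] %*% t(ez[g_ids, , drop = FALSE])) / (n - 1)
      as.vector(cc)
    } else {
      take <- sample.int(n_pairs, max_null)
      pi <- (take - 1) %% length(pk_ids) + 1
      gi <- (take - 1) %/% length(pk_ids) + 1
      rowSums(az[pk_ids[pi], , drop = FALSE] *
                ez[g_ids[gi], , drop = FALSE]) / (n - 1)
    }
  }
  tad_peaks <- unique(links$peak_id)
  links$empirical_p <- NA_real_
  pooled <- NULL
  for (chrom in unique(peak_chrom[tad_peaks])) {
    pk <- tad_peaks[peak_chrom[tad_peaks] == chrom]
    gn <- names(gene_chrom)[gene_chrom == chrom]
    gn <- intersect(gn, rownames(ez))
    null_pcc <- null_for(pk, gn)
    rows <- peak_chrom[links$peak_id] == chrom
    if (length(null_pcc) < min_null) {
      message("empirical_null_p: pooling genome-wide null for ", chrom,
              " (only ", length(null_pcc), " null pairs)")
      if (is.null(pooled)) {
        pooled <- null_for(tad_peaks, intersect(names(gene_chrom),
                                                rownames(ez)))
      }
      null_pcc <- pooled
    }
    if (!length(null_pcc)) stop("no null pairs available")
    ord <- sort(null_pcc)
    n_ge <- length(ord) - findInterval(links$pcc[rows] - 1e-12, ord)
    links$empirical_p[rows] <- (1 + n_ge) / (1 + length(ord))
  }
  links
}

#' Flag significant peak-gene links
#'
#' significant = empirical p < `p_threshold` AND pcc >= `pcc_threshold`
#' (positive-tail gate: anticorrelated pairs are reported but never
#' significant).
#'
#' @param links Output of [empirical_null_p()].
#' @param p_threshold,pcc_threshold Gates (defaults 0.05 and 0.25).
#' @return `links` with a `significant` column.
#' @export
significant_links <- function(links, p_threshold = 0.05,
                              pcc_threshold = 0.25) {
  stopifnot("empirical_p" %in% names(links))
  links$significant <- links$empirical_p < p_threshold &
    links$pcc >= pcc_threshold
  links
}

#' Differential accessibility between two groups
#'
#' Same pluggable engine contract as [differential_expression()]; the DAR
#' gate follows raw p (not FDR): is_dar = p < `p_threshold` AND
#' |log2FC| > `lfc_threshold`. Set `use_fdr = TRUE` to gate on FDR instead.
#'
#' @param peak_counts An `OmicsMatrix` of peak counts (or RPKM rounded to
#'   counts upstream); ignored when `external_table` given.
#' @param group_a,group_b Sample ids of the contrast sides.
#' @param p_threshold,lfc_threshold DAR gates (defaults 0.05 and 0.5).
#' @param use_fdr Gate on FDR instead of raw p (default FALSE).
#' @param external_table Optional data.frame with peak_id, log2FC, p, FDR.
#' @return data.frame (class `DarResult`) with peak_id, log2FC, p, FDR,
#'   is_dar.
#' @export
differential_accessibility <- function(peak_counts = NULL, group_a = NULL,
                                       group_b = NULL, p_threshold = 0.05,
                                       lfc_threshold = 0.5, use_fdr = FALSE,
                                       external_table = NULL) {
  if (!is.null(external_table)) {
    need <- c("peak_id", "log2FC", "p", "FDR")
    miss <- setdiff(need, names(external_table))
    if (length(miss)) {
      stop("external DAR table missing column(s): ",
           paste(miss, collapse = ", "))
    }
    res <- external_table[, need]
  } else {
    de <- differential_expression(peak_counts, group_a, group_b,
                                  min_total = 0)
    res <- data.frame(peak_id = de$gene_id, log2FC = de$log2FC, p = de$p,
                      FDR = de$FDR, stringsAsFactors = FALSE)
  }
  gate_p <- if (use_fdr) res$FDR else res$p
  res$is_dar <- gate_p < p_threshold & abs(res$log2FC) > lfc_threshold
  rownames(res) <- NULL
  class(res) <- c("DarResult", "data.frame")
  res
}

#' Concordant DAR-DEG "common genes" through significant links
#'
#' For every significant link whose peak is a DAR and whose gene is a DEG in
#' the same contrast: concordant fold-change signs produce a common gene
#' with that direction; discordant pairs are dropped. Genes are counted once
#' per direction; the pair-level table is also returned.
#'
#' @param dars A `DarResult`.
#' @param degs A `DEResult`.
#' @param links Output of [significant_links()].
#' @return list with `genes` (gene_id, direction) and `pairs` (link-level
#'   support).
#' @export
common_genes <- function(dars, degs, links) {
  sig <- links[links$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(list(genes = data.frame(gene_id = character(0),
                                   direction = character(0)),
                pairs = data.frame()))
  }
  dar_fc <- stats::setNames(dars$log2FC, dars$peak_id)[sig$peak_id]
  dar_ok <- stats::setNames(dars$is_dar, dars$peak_id)[sig$peak_id]
  deg_fc <- stats::setNames(degs$log2FC, degs$gene_id)[sig$gene_id]
  deg_ok <- stats::setNames(degs$is_deg, degs$gene_id)[sig$gene_id]
  keep <- !is.na(dar_ok) & dar_ok & !is.na(deg_ok) & deg_ok &
    sign(dar_fc) == sign(deg_fc) & sign(dar_fc) != 0
  pairs <- data.frame(sig[keep, c("tad_id", "peak_id", "gene_id", "pcc")],
                      dar_log2FC = dar_fc[keep], deg_log2FC = deg_fc[keep],
                      direction = ifelse(dar_fc[keep] > 0, "up", "down"),
                      stringsAsFactors = FALSE)
  genes <- unique(pairs[, c("gene_id", "direction")])
  rownames(genes) <- rownames(pairs) <- NULL
  list(genes = genes, pairs = pairs)
}

#' Genomic annotation of peaks relative to genes
#'
#' Category by peak midpoint with precedence promoter > 5'UTR > 3'UTR >
#' exon > intron > downstream > distal_intergenic. The promoter is
#' TSS +/- `promoter_flank`; downstream extends `downstream_len` bp past the
#' gene 3' end; without sub-feature annotation, genic midpoints collapse to
#' intron. Distance to the nearest TSS is signed by that gene's strand
#' (positive downstream of the TSS).
#'
#' @param peaks An `IntervalSet` of peaks.
#' @param annotation A `GenomeAnnotation`; optional element `features`
#'   (data.frame chrom, start, end, type in 5UTR/3UTR/exon) refines genic
#'   categories.
#' @param promoter_flank Promoter half-width in bp (default 2000).
#' @param downstream_len Downstream window in bp (default 3000).
#' @return data.frame with peak_id, category, distance_to_tss.
#' @export
annotate_peaks <- function(peaks, annotation, promoter_flank = 2000,
                           downstream_len = 3000) {
  genes <- annotation$genes
  mid <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  category <- rep("distal_intergenic", n)
  dist_tss <- rep(NA_real_, n)
  feats <- annotation$features
  for (i in seq_len(n)) {
    g_chr <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(g_chr)) next
    d_signed <- ifelse(g_chr$strand == "+", mid[i] - g_chr$tss,
                       g_chr$tss - mid[i])
    nearest <- which.min(abs(d_signed))
    dist_tss[i] <- d_signed[nearest]
    in_promoter <- any(abs(d_signed) <= promoter_flank)
    in_gene <- g_chr$start <= mid[i] & mid[i] < g_chr$end
    tail3 <- ifelse(g_chr$strand == "+", g_chr$end, g_chr$start)
    in_down <- ifelse(g_chr$strand == "+",
                      mid[i] >= g_chr$end & mid[i] < g_chr$end + downstream_len,
                      mid[i] < g_chr$start & mid[i] >= g_chr$start - downstream_len)
    sub <- NA_character_
    if (!is.null(feats) && any(in_gene)) {
      f_chr <- feats[feats$chrom == peaks$chrom[i] &
                       feats$start <= mid[i] & mid[i] < feats$end, , drop = FALSE]
      if (nrow(f_chr)) {
        for (ty in c("5UTR", "3UTR", "exon")) {
          if (ty %in% f_chr$type) { sub <- ty; break }
        }
      }
    }
    category[i] <-
      if (in_promoter) "promoter"
      else if (!is.na(sub) && sub == "5UTR") "5'UTR"
      else if (!is.na(sub) && sub == "3UTR") "3'UTR"
      else if (!is.na(sub) && sub == "exon") "exon"
      else if (any(in_gene)) "intron"
      else if (any(in_down)) "downstream"
      else "distal_intergenic"
  }
  data.frame(peak_id = peaks$id, category = category,
             distance_to_tss = dist_tss, stringsAsFactors = FALSE)
}
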