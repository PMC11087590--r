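# Entropy-based chromatin tissue specificity and t-ranked tissue-specific
# expression.

#' Quantile-normalize a peak accessibility matrix
#'
#' Columns are quantile-normalized (tied values receive the mean of the tied
#' rank quantiles), so after normalization all samples share the same sorted
#' value vector.
#'
#' @param om An `OmicsMatrix` of RPKM values with >= 2 samples.
#' @return An `OmicsMatrix` with identically distributed columns.
#' @export
normalize_peak_matrix <- function(om) {
  stopifnot(inherits(om, "OmicsMatrix"))
  if (ncol(om$values) < 2) stop("quantile normalization needs >= 2 samples")
  zero <- colSums(om$values) == 0
  if (any(zero)) {
    stop("all-zero sample column(s): ",
         paste(colnames(om$values)[zero], collapse = ", "))
  }
  norm <- limma::normalizeQuantiles(om$values, ties = TRUE)
  dimnames(norm) <- dimnames(om$values)
  omics_matrix(norm, om$unit, om$meta)
}

#' Relative accessibility Ri = Ei / sum(Ei)
#'
#' @param E Non-negative vector of per-tissue normalized median RPKM values.
#' @return Vector R summing to 1.
#' @export
relative_accessibility <- function(E) {
  if (any(E < 0)) stop("Ei must be non-negative")
  s <- sum(E)
  if (s == 0) stop("sum(Ei) = 0: peak is unscorable")
  E / s
}

#' Shannon entropy of a relative-accessibility vector, in bits
#'
#' H = sum(-Ri * log2(Ri)) with 0 * log2(0) taken as 0. H is 0 for a peak
#' confined to one tissue and log2(N) for a uniformly accessible peak.
#'
#' @param R Relative-accessibility vector (non-negative, summing to 1).
#' @return Entropy in bits.
#' @export
peak_entropy <- function(R) {
  if (any(R < 0) || abs(sum(R) - 1) > 1e-8) {
    stop("R must be non-negative and sum to 1")
  }
  nz <- R > 0
  -sum(R[nz] * log2(R[nz]))
}

#' Classify peaks as tissue-restricted / conserved / other by entropy
#'
#' Per peak: E = per-tissue median of the (already normalized) accessibility,
#' R = E/sum(E), H = Shannon entropy in bits. Peaks with H below
#' `entropy_threshold` are tissue-restricted and assigned to the tissue with
#' maximal E; the `conserved_top` highest-entropy peaks are conserved.
#' Classes are disjoint (restricted takes precedence). Peaks with sum(E) = 0
#' are unscorable and excluded (reported via `message`).
#'
#' @param om A normalized `OmicsMatrix` whose metadata carries `tissue`.
#' @param entropy_threshold Restricted cutoff in bits (default 2.5).
#' @param conserved_top Number of top-entropy peaks called conserved
#'   (default 500).
#' @return data.frame with peak_id, per-tissue E columns, H, assigned_tissue,
#'   class.
#' @export
classify_peaks <- function(om, entropy_threshold = 2.5, conserved_top = 500) {
  stopifnot(inherits(om, "OmicsMatrix"), "tissue" %in% names(om$meta))
  tissues <- unique(om$meta$tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues")
  E <- vapply(tissues, function(ts) {
    cols <- om$meta$tissue == ts
    apply(om$values[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(om$values)))
  scorable <- rowSums(E) > 0
  if (any(!scorable)) {
    message(sprintf("classify_peaks: %d unscorable peak(s) excluded (sum E = 0)",
                    sum(!scorable)))
  }
  E <- E[scorable, , drop = FALSE]
  R <- E / rowSums(E)
  H <- apply(R, 1, peak_entropy)
  assigned <- tissues[max.col(E, ties.method = "first")]
  cls <- rep("other", nrow(E))
  cls[H < entropy_threshold] <- "restricted"
  if (conserved_top > nrow(E)) {
    warning("conserved_top exceeds peak count; all remaining peaks eligible")
  }
  n_cons <- min(conserved_top, nrow(E))
  cons_idx <- order(H, decreasing = TRUE)[seq_len(n_cons)]
  cls[cons_idx][cls[cons_idx] != "restricted"] <- "conserved"
  res <- data.frame(peak_id = rownames(E), E, H = H,
                    assigned_tissue = ifelse(cls == "restricted", assigned,
                                             NA_character_),
                    class = cls, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(res) <- NULL
  res
}

#' Tissue-specific genes by Welch t on log2(TPM+1)
#'
#' For each target tissue, every gene is tested (Welch t) against samples
#' from the other tissue categories; log2FC is the difference of group mean
#' log2(TPM+1); FDR is Benjamini-Hochberg within tissue. A gene is a TSG
#' when it sits in the top 5% by |t| (ties at the boundary included), has
#' |log2FC| > 1 and FDR < 0.01.
#'
#' @param tpm An `OmicsMatrix` of TPM values with `tissue` metadata.
#' @param tissue_categories Named character vector mapping each tissue to a
#'   broad category; the comparison group for a tissue excludes its own
#'   category.
#' @param top_fraction Fraction of genes ranked by |t| eligible (default
#'   0.05).
#' @param lfc_threshold,fdr_threshold TSG gates (defaults 1 and 0.01).
#' @return data.frame with tissue, gene_id, t_statistic, log2FC, FDR, is_tsg.
#' @export
tissue_specific_genes <- function(tpm, tissue_categories,
                                  top_fraction = 0.05, lfc_threshold = 1,
                                  fdr_threshold = 0.01) {
  stopifnot(inherits(tpm, "OmicsMatrix"))
  tissues <- unique(tpm$meta$tissue)
  miss <- setdiff(tissues, names(tissue_categories))
  if (length(miss)) stop("tissues without category: ", paste(miss, collapse = ", "))
  x <- log2(tpm$values + 1)
  out <- lapply(tissues, function(ts) {
    in_cols <- tpm$meta$tissue == ts
    other <- tissue_categories[tpm$meta$tissue] !=
      tissue_categories[[ts]]
    if (sum(in_cols) < 2 || sum(other) < 2) {
      stop("tissue '", ts, "' needs >= 2 samples in both groups")
    }
    wt <- welch_rows(x[, in_cols, drop = FALSE], x[, other, drop = FALSE])
    keep <- !is.na(wt$t)
    fdr <- rep(NA_real_, nrow(x))
    fdr[keep] <- stats::p.adjust(wt$p[keep], method = "BH")
    res <- data.frame(tissue = ts, gene_id = rownames(x),
                      t_statistic = wt$t, log2FC = wt$lfc, FDR = fdr,
                      stringsAsFactors = FALSE)
    res <- res[keep, , drop = FALSE]
    cut <- stats::quantile(abs(res$t_statistic), 1 - top_fraction,
                           names = FALSE, na.rm = TRUE)
    res$is_tsg <- abs(res$t_statistic) >= cut &
      abs(res$log2FC) > lfc_threshold & res$FDR < fdr_threshold
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Vectorized Welch two-sample t over matrix rows. Rows with zero variance in
# both groups give t = NA (undefined, excluded by callers).
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / (ifelse(v1 > 0, (v1 / n1)^2 / (n1 - 1), 0) +
                        ifelse(v2 > 0, (v2 / n2)^2 / (n2 - 1), 0)),
               NA_real_)
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, p = p, lfc = m1 - m2)
}
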