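# Differential expression with the study thresholds, shared/specific DEG
# classification, multi-tissue log2FC k-means, polynomial time-series DCG
# detection, and fuzzy c-means trajectory clustering.

#' Differential expression between two groups
#'
#' Default engine: genes with total count >= `min_total` are tested with a
#' Welch t on log2(CPM+1); log2FC is the difference of group mean
#' log2(CPM+1) (B vs A); FDR is Benjamini-Hochberg. A precomputed external
#' DE table (columns gene_id, log2FC, p, FDR) is accepted verbatim through
#' `external_table`, in which case only the threshold flags are applied.
#'
#' @param counts An `OmicsMatrix` of counts (ignored when `external_table`
#'   is given).
#' @param group_a,group_b Character vectors of sample ids for the two sides
#'   of the contrast (log2FC is B relative to A).
#' @param fdr_threshold,lfc_threshold DEG gates; defaults FDR < 0.05 and
#'   |log2FC| > 0.75.
#' @param min_total Total-count pre-filter (default 10).
#' @param external_table Optional data.frame with gene_id, log2FC, p, FDR.
#' @return data.frame (class `DEResult`) with gene_id, log2FC, p, FDR,
#'   is_deg.
#' @export
differential_expression <- function(counts = NULL, group_a = NULL,
                                    group_b = NULL,
                                    fdr_threshold = 0.05,
                                    lfc_threshold = 0.75,
                                    min_total = 10,
                                    external_table = NULL) {
  if (!is.null(external_table)) {
    need <- c("gene_id", "log2FC", "p", "FDR")
    miss <- setdiff(need, names(external_table))
    if (length(miss)) {
      stop("external DE table missing column(s): ", paste(miss, collapse = ", "))
    }
    res <- external_table[, need]
  } else {
    stopifnot(inherits(counts, "OmicsMatrix"), counts$unit == "count")
    if (length(group_a) < 2 || length(group_b) < 2) {
      stop("each group needs >= 2 replicates")
    }
    sub <- om_subset(counts, samples = c(group_a, group_b))
    keep <- rowSums(sub$values) >= min_total
    x <- om_log2cpm(sub)$values[keep, , drop = FALSE]
    wt <- welch_rows(x[, group_b, drop = FALSE], x[, group_a, drop = FALSE])
    ok <- !is.na(wt$t)
    res <- data.frame(gene_id = rownames(x)[ok], log2FC = wt$lfc[ok],
                      p = wt$p[ok],
                      FDR = stats::p.adjust(wt$p[ok], method = "BH"),
                      stringsAsFactors = FALSE)
  }
  res$is_deg <- res$FDR < fdr_threshold & abs(res$log2FC) > lfc_threshold
  rownames(res) <- NULL
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Tissue-shared and tissue-specific DEG classification
#'
#' Shared = DEG in at least `min_shared` tissues; specific = DEG in exactly
#' one tissue.
#'
#' @param deg_sets Named list (per tissue) of DEG gene-id vectors.
#' @param min_shared Minimum tissue count for "shared" (default 5).
#' @return list with `shared` (character) and `specific` (named list per
#'   tissue) plus a `counts` data.frame.
#' @export
classify_shared_specific <- function(deg_sets, min_shared = 5) {
  if (length(deg_sets) < 2) stop("need DEG sets from >= 2 tissues")
  all_genes <- unique(unlist(deg_sets))
  if (!length(all_genes)) {
    warning("no DEGs in any tissue")
    return(list(shared = character(0),
                specific = stats::setNames(
                  rep(list(character(0)), length(deg_sets)), names(deg_sets)),
                counts = data.frame(tissue = names(deg_sets), n_deg = 0L,
                                    n_specific = 0L)))
  }
  tally <- vapply(all_genes, function(g)
    sum(vapply(deg_sets, function(s) g %in% s, TRUE)), 0L)
  shared <- all_genes[tally >= min_shared]
  specific <- lapply(names(deg_sets), function(ts) {
    s <- deg_sets[[ts]]
    s[tally[match(s, all_genes)] == 1L]
  })
  names(specific) <- names(deg_sets)
  counts <- data.frame(tissue = names(deg_sets),
                       n_deg = lengths(deg_sets),
                       n_specific = lengths(specific))
  rownames(counts) <- NULL
  list(shared = shared, specific = specific, counts = counts)
}

#' Multi-tissue k-means on a genes x tissues log2FC matrix
#'
#' k is chosen by maximum mean silhouette width (Euclidean distance) over
#' `k_range`; the chosen k-means run uses `nstart` restarts under a fixed
#' seed.
#'
#' @param fc_matrix Numeric matrix, genes x tissues, no missing values.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param nstart Random restarts per k (default 25).
#' @param seed Seed for the restarts.
#' @return list (class `ClusterAssignment`) with method, k, cluster (hard
#'   labels), centers, withinss, silhouette (mean width per candidate k).
#' @export
multi_tissue_kmeans <- function(fc_matrix, k_range = 2:10, nstart = 25,
                                seed = 1L) {
  stopifnot(is.matrix(fc_matrix))
  if (anyNA(fc_matrix)) stop("log2FC matrix must not contain missing values")
  k_range <- k_range[k_range < nrow(fc_matrix)]
  if (!length(k_range)) stop("fewer genes than the smallest k")
  d <- stats::dist(fc_matrix)
  sil <- vapply(k_range, function(k) {
    set.seed(derive_seed(seed, "null") + k)
    km <- stats::kmeans(fc_matrix, centers = k, nstart = nstart)
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, 0)
  k_best <- k_range[which.max(sil)]
  set.seed(derive_seed(seed, "null") + k_best)
  km <- stats::kmeans(fc_matrix, centers = k_best, nstart = nstart)
  structure(list(method = "kmeans", k = k_best,
                 cluster = stats::setNames(km$cluster, rownames(fc_matrix)),
                 centers = km$centers, withinss = km$withinss,
                 silhouette = stats::setNames(sil, k_range)),
            class = "ClusterAssignment")
}

#' Detect dynamically changed genes by polynomial time regression
#'
#' Per gene, a degree-`degree` polynomial in time is fit by least squares to
#' variance-stabilized expression (log2(CPM+1) by default); the overall
#' regression F test against the intercept-only model gives p, BH-adjusted
#' to FDR; R2 is the model goodness of fit. A gene is a DCG when
#' FDR < `fdr_threshold` and R2 >= `r2_threshold`.
#'
#' @param x Numeric matrix of variance-stabilized expression, genes x
#'   samples, or an `OmicsMatrix` of counts (then log2(CPM+1) is taken).
#' @param time Numeric vector of sample times, parallel to columns.
#' @param degree Polynomial degree (default 4).
#' @param r2_threshold,fdr_threshold DCG gates (defaults 0.4 and 0.05).
#' @return data.frame (class `DcgResult`) with gene_id, R2, F_p, FDR,
#'   is_dcg.
#' @export
detect_dcgs <- function(x, time, degree = 4, r2_threshold = 0.4,
                        fdr_threshold = 0.05) {
  if (inherits(x, "OmicsMatrix")) {
    if (x$unit == "count") x <- om_log2cpm(x)
    time <- if (missing(time)) x$meta$time_point else time
    x <- x$values
  }
  stopifnot(is.matrix(x), length(time) == ncol(x))
  n_t <- length(unique(time))
  if (n_t <= degree) {
    stop("need more distinct time points (", n_t, ") than the polynomial ",
         "degree (", degree, "): model would be saturated")
  }
  X <- stats::poly(time, degree = degree, raw = FALSE)
  qr_x <- qr(cbind(1, X))
  n <- ncol(x); d <- degree
  ctr <- x - rowMeans(x)
  tss <- rowSums(ctr^2)
  # residuals of every gene against the common design in one pass
  res <- t(qr.resid(qr_x, t(x)))
  rss <- rowSums(res^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  f <- (r2 / d) / ((1 - r2) / (n - d - 1))
  p <- stats::pf(f, d, n - d - 1, lower.tail = FALSE)
  ok <- !is.na(r2)
  out <- data.frame(gene_id = rownames(x)[ok], R2 = r2[ok], F_p = p[ok],
                    FDR = stats::p.adjust(p[ok], method = "BH"),
                    stringsAsFactors = FALSE)
  out$is_dcg <- out$FDR < fdr_threshold & out$R2 >= r2_threshold
  rownames(out) <- NULL
  class(out) <- c("DcgResult", "data.frame")
  out
}

#' Standardize trajectory rows to mean 0, SD 1
#'
#' Zero-variance rows are dropped (reported via `message`).
#'
#' @param x Numeric matrix, genes x time points.
#' @return Standardized matrix, possibly with fewer rows.
#' @export
standardize_rows <- function(x) {
  stopifnot(is.matrix(x))
  s <- apply(x, 1, stats::sd)
  if (any(s == 0)) {
    message(sprintf("standardize_rows: %d zero-variance row(s) excluded",
                    sum(s == 0)))
  }
  x <- x[s > 0, , drop = FALSE]
  t(scale(t(x)))[, , drop = FALSE]
}

#' Fuzzy c-means clustering of standardized trajectories
#'
#' Bezdek alternating optimization: memberships
#' u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)), centers are u^m-weighted means;
#' iteration stops when the maximum membership change falls below `tol` or
#' after `max_iter` iterations. The objective J = sum u^m d^2 is recorded
#' every iteration and asserted non-increasing.
#'
#' @param x Numeric matrix of row-standardized trajectories (genes x time).
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1, default 2).
#' @param tol Membership-change tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 300).
#' @param seed Seed for center initialization.
#' @return list (class `ClusterAssignment`) with method, k, membership,
#'   cluster (hard labels), centers, objective (per iteration).
#' @export
fuzzy_cmeans <- function(x, c, m = 2, tol = 1e-6, max_iter = 300, seed = 1L) {
  stopifnot(is.matrix(x), c >= 2, m > 1)
  if (nrow(x) <= c) stop("fewer trajectories than clusters")
  set.seed(derive_seed(seed, "null") + c)
  centers <- x[sample.int(nrow(x), c), , drop = FALSE]
  u_old <- matrix(1 / c, nrow(x), c)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    u <- memberships_from_d2(d2, m)
    um <- u^m
    objective <- c(objective, sum(um * d2))
    centers <- (t(um) %*% x) / colSums(um)
    delta <- max(abs(u - u_old))
    u_old <- u
    if (delta < tol) break
  }
  if (any(diff(objective) > 1e-8 * pmax(1, objective[-length(objective)]))) {
    stop("fuzzy c-means objective increased between iterations")
  }
  rownames(u) <- rownames(x)
  structure(list(method = "cmeans", k = c, membership = u,
                 cluster = stats::setNames(max.col(u, ties.method = "first"),
                                           rownames(x)),
                 centers = centers, objective = objective),
            class = "ClusterAssignment")
}

memberships_from_d2 <- function(d2, m) {
  pow <- 1 / (m - 1)
  u <- matrix(0, nrow(d2), ncol(d2))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {  # point on a center: full membership there (formula limit)
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  if (any(!hit)) {
    inv <- (1 / d2[!hit, , drop = FALSE])^pow
    u[!hit, ] <- inv / rowSums(inv)
  }
  u
}

#' Choose the fuzzy cluster count by the center-splitting rule
#'
#' Returns the smallest c in `c_range` such that moving to c+1 clusters no
#' longer adds a genuinely new expression profile but splits an existing
#' one. A split is detected on the *shape* of the centers: after
#' standardizing each center to mean 0, SD 1 (trajectories are compared by
#' profile, not amplitude), two centers closer than
#' `theta_split * sqrt(2 * (T - 1))` -- the distance scale of two
#' uncorrelated standardized profiles over T time points -- are duplicates
#' of one profile rather than distinct clusters.
#'
#' @param x Row-standardized trajectory matrix (genes x T time points).
#' @param c_range Candidate counts (default 2:12).
#' @param theta_split Split-detection factor in (0, 1) (default 0.3,
#'   equivalent to flagging center pairs correlated above 1 - theta^2).
#' @param ... Passed to [fuzzy_cmeans()].
#' @return Chosen cluster count (with a warning if the rule never triggers).
#' @export
choose_cluster_number <- function(x, c_range = 2:12, theta_split = 0.3, ...) {
  c_range <- sort(c_range)
  scale_ref <- sqrt(2 * (ncol(x) - 1))
  for (cc in c_range) {
    fit_next <- fuzzy_cmeans(x, cc + 1, ...)
    ctr <- t(scale(t(fit_next$centers)))
    if (min(stats::dist(ctr)) < theta_split * scale_ref) return(cc)
  }
  warning("cluster-splitting rule never triggered; returning max of c_range")
  max(c_range)
}
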