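# Synthetic-data generator: every pipeline input with known planted truth.
# The defaults emulate the study design the package targets: 8 tissues
# profiled for chromatin accessibility, 5 acclimatization time points
# (0, 7, 14, 21, ~245 days), 10 RNA replicates per tissue/time cell,
# negative-binomial counts, Balding-Nichols two-population genotypes.

#' Simulation configuration
#'
#' Central parameter object for the synthetic-data generator. Defaults are
#' the study conditions the package emulates; every downstream test and the
#' demo pipeline read their problem sizes from here.
#'
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_chromosomes,chrom_length Genome shape for genes/TADs/peaks.
#' @param n_genes,n_peaks,n_tads Feature counts. All gene TSSs are placed
#'   inside TADs (TADs are non-overlapping by construction).
#' @param tissues Character vector of tissue names.
#' @param time_points Numeric days; default `c(0, 7, 14, 21, 245)`.
#' @param replicates RNA replicates per tissue x time cell (>= 2).
#' @param access_replicates ATAC replicates per tissue x time cell.
#' @param nb_mean_range,nb_dispersion_range Negative-binomial baseline mean
#'   (log-uniform) and gene-wise dispersion (uniform) ranges.
#' @param deg_fraction,deg_log2fc Fraction of genes planted as differentially
#'   expressed after ascent, and their |log2 fold change|.
#' @param dcg_fraction,dcg_var_frac Fraction of genes planted with a smooth
#'   time trend, and the fraction of log-scale variance the trend explains.
#' @param restricted_peak_fraction Fraction of decoy peaks restricted to one
#'   tissue (the rest are ubiquitous).
#' @param n_links,r_true Number of planted peak-gene links and their true
#'   log-scale Pearson correlation.
#' @param access_noise_sd,restricted_signal Accessibility noise SD and
#'   restricted-peak signal, both on the log2(RPKM+1) scale.
#' @param pop_sizes Named diploid sample sizes for the two populations.
#' @param f_background,f_high Balding-Nichols F outside/inside planted
#'   windows.
#' @param n_snps,geno_chrom_length,fst_window,n_planted_windows Genotype
#'   genome shape for the windowed scan.
#' @param geno_missing_rate Per-call missing-genotype probability.
#' @param d_n_sites,d_chrom_length,d_block_size,d_drift_f,d_pop_size
#'   Four-taxon simulation shape (sites, genome length, jackknife block size,
#'   per-branch drift F, diploids per taxon).
#' @param introgression_f,d_intro_block_frac Fraction of donor (H3) ancestry
#'   entering H2 inside introgressed blocks, and the genome fraction those
#'   blocks cover.
#' @return A validated `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L, chrom_length = 5e6,
                       n_genes = 2000L, n_peaks = 1000L, n_tads = 50L,
                       tissues = c("heart", "artery", "lung", "liver",
                                   "hypothalamus", "rumen", "duodenum",
                                   "adipose"),
                       time_points = c(0, 7, 14, 21, 245),
                       replicates = 10L, access_replicates = 2L,
                       nb_mean_range = c(20, 2000),
                       nb_dispersion_range = c(0.05, 0.5),
                       deg_fraction = 0.1, deg_log2fc = 2,
                       dcg_fraction = 0.05, dcg_var_frac = 0.6,
                       restricted_peak_fraction = 0.2,
                       n_links = 100L, r_true = 0.7,
                       access_noise_sd = 0.5, restricted_signal = 5,
                       pop_sizes = c(lowland = 100L, highland = 100L),
                       f_background = 0.02, f_high = 0.3,
                       n_snps = 2000L, geno_chrom_length = 1e6,
                       fst_window = 1e4, n_planted_windows = 5L,
                       geno_missing_rate = 0.02,
                       d_n_sites = 5000L, d_chrom_length = 1e8,
                       d_block_size = 5e6, d_drift_f = 0.1,
                       d_pop_size = 20L,
                       introgression_f = 0, d_intro_block_frac = 0.2) {
  cfg <- as.list(environment())
  fracs <- c(deg_fraction, dcg_fraction, dcg_var_frac,
             restricted_peak_fraction, introgression_f, d_intro_block_frac,
             geno_missing_rate)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(r_true) >= 1) stop("r_true must lie in (-1, 1)")
  if (any(c(f_background, f_high, d_drift_f) <= 0) ||
      any(c(f_background, f_high, d_drift_f) >= 1)) {
    stop("Balding-Nichols F parameters must lie in (0, 1)")
  }
  if (n_genes < 1) stop("n_genes must be positive")
  if (replicates < 2) stop("at least 2 replicates per design cell are required")
  if (length(tissues) < 2) stop("at least 2 tissues are required")
  structure(cfg, class = "SimulationConfig")
}

# Deterministic per-stage seed derivation from the master seed (kept < 2^31).
derive_seed <- function(seed, stage) {
  offsets <- c(genome = 101L, expression = 211L, accessibility = 307L,
               genotypes = 401L, dstat = 503L, pipeline = 601L,
               null = 701L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Simulate a genome: gene annotation plus non-overlapping TADs
#'
#' TADs (30-60 kb) are packed into each chromosome with random gaps; every
#' gene TSS falls inside exactly one TAD and every TAD receives at least one
#' gene. Gene bodies (1-5 kb) may spill past a TAD edge; domain membership
#' downstream is decided by TSS/midpoint, not by the body.
#'
#' @param config A `SimulationConfig`.
#' @return list with `annotation` (`GenomeAnnotation`) and `tads`
#'   (`IntervalSet`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "genome"))
  chroms <- stats::setNames(rep(config$chrom_length, config$n_chromosomes),
                            sprintf("chr%d", seq_len(config$n_chromosomes)))
  per_chrom <- diff(floor(seq(0, config$n_tads, length.out =
                                config$n_chromosomes + 1)))
  tad_list <- list()
  for (ci in seq_along(chroms)) {
    n_t <- per_chrom[ci]
    if (n_t == 0) next
    lens <- round(stats::runif(n_t, 30e3, 60e3))
    slack <- chroms[ci] - sum(lens)
    if (slack < 0) {
      stop("infeasible TAD packing on ", names(chroms)[ci],
           ": increase chrom_length or reduce n_tads")
    }
    cuts <- sort(stats::runif(n_t, 0, slack))
    starts <- round(cuts) + cumsum(c(0, lens[-n_t]))
    tad_list[[ci]] <- data.frame(chrom = names(chroms)[ci],
                                 start = starts, end = starts + lens,
                                 stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, tad_list)
  tads$id <- sprintf("tad%03d", seq_len(nrow(tads)))
  tads <- interval_set(tads, role = "TAD", chromosomes = chroms)

  # one guaranteed gene per TAD, remainder spread over random TADs
  tad_of_gene <- c(seq_len(nrow(tads)),
                   sample.int(nrow(tads), max(0, config$n_genes - nrow(tads)),
                              replace = TRUE))[seq_len(config$n_genes)]
  glen <- round(stats::runif(config$n_genes, 1e3, 5e3))
  margin <- 500
  tss <- round(stats::runif(config$n_genes,
                            tads$start[tad_of_gene] + margin,
                            tads$end[tad_of_gene] - margin - 1))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(0, tss - glen + 1))
  end <- ifelse(strand == "+", pmin(config$chrom_length, tss + glen), tss + 1)
  genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
                      chrom = tads$chrom[tad_of_gene], strand = strand,
                      start = as.integer(start), end = as.integer(end),
                      tss = as.integer(tss), stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), ]
  genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))  # keep ids ordered
  list(annotation = genome_annotation(chroms, genes), tads = tads)
}

# Trajectory archetypes for planted dynamic genes, standardized over the
# design time points (mean 0, SD 1).
dcg_archetypes <- function(time_points) {
  u <- (time_points - min(time_points)) / diff(range(time_points))
  shapes <- cbind(rise = u,
                  fall = -u,
                  pulse = exp(-((u - 0.35) / 0.22)^2),
                  dip = -exp(-((u - 0.35) / 0.22)^2))
  apply(shapes, 2, function(s) (s - mean(s)) / stats::sd(s))
}

#' Simulate the expression compartment (counts, TPM, truth)
#'
#' Counts are negative-binomial with gene-wise baseline mean and dispersion.
#' Planted DEGs receive a multiplicative shift 2^(+/- log2FC) at all
#' post-ascent time points in a random tissue subset; planted DCGs receive a
#' smooth standardized trajectory whose amplitude is calibrated (delta
#' method) so the trend explains `dcg_var_frac` of the log2-scale variance.
#'
#' @param config A `SimulationConfig`.
#' @param annotation A `GenomeAnnotation` from [simulate_genome()].
#' @return list with `counts` and `tpm` (`OmicsMatrix`) and `truth`
#'   (`TruthTable` with `degs` and `dcgs` tables).
#' @export
simulate_expression <- function(config, annotation) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(annotation, "GenomeAnnotation"))
  if (config$replicates < 2) stop("replicates < 2 in a design cell")
  set.seed(derive_seed(config$seed, "expression"))
  genes <- annotation$genes
  n_genes <- nrow(genes)
  design <- expand.grid(rep = seq_len(config$replicates),
                        time_point = config$time_points,
                        tissue = config$tissues,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_t%g_r%d", design$tissue, design$time_point,
                              design$rep)
  meta <- data.frame(sample_id = design$sample_id, tissue = design$tissue,
                     time_point = design$time_point,
                     group = sprintf("t%g", design$time_point),
                     animal_id = sprintf("a%02d", design$rep),
                     stringsAsFactors = FALSE)
  mu <- exp(stats::runif(n_genes, log(config$nb_mean_range[1]),
                         log(config$nb_mean_range[2])))
  disp <- stats::runif(n_genes, config$nb_dispersion_range[1],
                       config$nb_dispersion_range[2])

  n_deg <- round(config$deg_fraction * n_genes)
  deg_idx <- sample.int(n_genes, n_deg)
  degs <- NULL
  if (n_deg > 0) {
    deg_rows <- lapply(seq_len(n_deg), function(i) {
      k <- sample.int(length(config$tissues), 1)
      data.frame(gene_id = genes$gene_id[deg_idx[i]],
                 tissue = sample(config$tissues, k),
                 log2fc = sample(c(-1, 1), 1) * config$deg_log2fc,
                 stringsAsFactors = FALSE)
    })
    degs <- do.call(rbind, deg_rows)
  }

  pool <- setdiff(seq_len(n_genes), deg_idx)
  n_dcg <- min(round(config$dcg_fraction * n_genes), length(pool))
  dcg_idx <- sample(pool, n_dcg)
  arch <- dcg_archetypes(config$time_points)
  dcgs <- NULL
  if (n_dcg > 0) {
    dcg_rows <- lapply(seq_len(n_dcg), function(i) {
      k <- sample.int(length(config$tissues), 1)
      data.frame(gene_id = genes$gene_id[dcg_idx[i]],
                 tissue = sample(config$tissues, k),
                 archetype = sample(colnames(arch), 1),
                 stringsAsFactors = FALSE)
    })
    dcgs <- do.call(rbind, dcg_rows)
  }

  # per-gene log2-scale noise SD (delta method for NB counts)
  sigma_log2 <- sqrt(1 / mu + disp) / log(2)
  v <- config$dcg_var_frac
  amp <- if (v > 0 && v < 1) sigma_log2 * sqrt(v / (1 - v)) else sigma_log2

  log2shift <- matrix(0, n_genes, nrow(meta),
                      dimnames = list(genes$gene_id, meta$sample_id))
  if (!is.null(degs)) {
    post <- meta$time_point > min(config$time_points)
    for (r in seq_len(nrow(degs))) {
      cols <- post & meta$tissue == degs$tissue[r]
      log2shift[degs$gene_id[r], cols] <-
        log2shift[degs$gene_id[r], cols] + degs$log2fc[r]
    }
  }
  if (!is.null(dcgs)) {
    t_idx <- match(meta$time_point, config$time_points)
    for (r in seq_len(nrow(dcgs))) {
      g <- dcgs$gene_id[r]
      cols <- meta$tissue == dcgs$tissue[r]
      log2shift[g, cols] <- log2shift[g, cols] +
        amp[match(g, genes$gene_id)] * arch[t_idx[cols], dcgs$archetype[r]]
    }
  }
  mu_mat <- mu * 2^log2shift
  counts <- matrix(stats::rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                                  size = rep(1 / disp, ncol(mu_mat))),
                   n_genes, ncol(mu_mat), dimnames = dimnames(mu_mat))
  counts_om <- omics_matrix(counts, "count", meta)
  lens <- stats::setNames(genes$end - genes$start, genes$gene_id)
  truth <- structure(list(degs = degs, dcgs = dcgs), class = "TruthTable")
  list(counts = counts_om, tpm = om_tpm(counts_om, lens), truth = truth)
}

#' Simulate the accessibility compartment (peak RPKM, peak intervals, truth)
#'
#' Planted links: peak log2(RPKM+1) = a + log2(TPM+1) of the target gene plus
#' Gaussian noise whose SD is solved so the construction correlation equals
#' `r_true`; linked peaks are placed inside the target gene's TAD. Decoy
#' peaks are placed uniformly over the genome (inside and outside TADs) and
#' are either tissue-restricted (signal in exactly one tissue, zero RPKM
#' elsewhere) or ubiquitous. Accessibility samples are the first
#' `access_replicates` replicates of every tissue x time cell, so their ids
#' match the expression samples.
#'
#' @param config A `SimulationConfig`.
#' @param genome Output of [simulate_genome()].
#' @param tpm The TPM `OmicsMatrix` from [simulate_expression()].
#' @param truth The `TruthTable` to extend.
#' @return list with `rpkm` (`OmicsMatrix`), `peaks` (`IntervalSet`) and the
#'   extended `truth` (`links`, `peak_classes` tables).
#' @export
simulate_accessibility <- function(config, genome, tpm, truth) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(tpm, "OmicsMatrix"), inherits(truth, "TruthTable"))
  set.seed(derive_seed(config$seed, "accessibility"))
  ann <- genome$annotation
  tads <- genome$tads
  keep <- tpm$meta$animal_id %in% sprintf("a%02d",
                                          seq_len(config$access_replicates))
  samp <- tpm$meta$sample_id[keep]
  if (length(samp) < 10) stop("fewer than 10 accessibility samples in design")
  meta <- tpm$meta[keep, , drop = FALSE]
  expr_log <- log2(tpm$values[, samp, drop = FALSE] + 1)

  n_links <- min(config$n_links, nrow(ann$genes))
  target <- sample(ann$genes$gene_id, n_links)
  g_rows <- ann$genes[match(target, ann$genes$gene_id), ]
  tad_of <- locate_in_intervals(g_rows$chrom, g_rows$tss, tads)
  if (anyNA(tad_of)) stop("internal: target gene TSS outside every TAD")

  width <- 500
  link_start <- round(stats::runif(n_links, tads$start[tad_of],
                                   tads$end[tad_of] - width - 1))
  n_decoy <- config$n_peaks - n_links
  decoy_chrom <- sample(names(ann$chromosomes), n_decoy, replace = TRUE)
  decoy_start <- round(stats::runif(n_decoy, 0,
                                    ann$chromosomes[decoy_chrom] - width - 1))
  peaks <- data.frame(
    chrom = c(tads$chrom[tad_of], decoy_chrom),
    start = as.integer(c(link_start, decoy_start)),
    stringsAsFactors = FALSE)
  peaks$end <- peaks$start + as.integer(width)
  peaks$id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$score <- NA_real_
  linked_ids <- peaks$id[seq_len(n_links)]
  decoy_ids <- setdiff(peaks$id, linked_ids)

  n_restricted <- round(config$restricted_peak_fraction * n_decoy)
  restricted_ids <- sample(decoy_ids, n_restricted)
  assigned <- sample(config$tissues, n_restricted, replace = TRUE)

  y <- matrix(0, nrow(peaks), length(samp),
              dimnames = list(peaks$id, samp))
  # planted links on the log2(x+1) scale
  for (i in seq_len(n_links)) {
    g <- expr_log[target[i], ]
    sdg <- stats::sd(g)
    if (sdg == 0) stop("r_true incompatible with noise floor: target gene '",
                       target[i], "' has constant expression")
    noise_sd <- sdg * sqrt(1 / config$r_true^2 - 1)
    y[linked_ids[i], ] <- stats::runif(1, 2, 5) + (g - mean(g)) +
      stats::rnorm(length(g), 0, noise_sd)
  }
  ubiq_ids <- setdiff(decoy_ids, restricted_ids)
  base <- stats::runif(length(ubiq_ids), 2, 6)
  y[ubiq_ids, ] <- base +
    matrix(stats::rnorm(length(ubiq_ids) * length(samp), 0,
                        config$access_noise_sd),
           length(ubiq_ids), length(samp))
  for (i in seq_along(restricted_ids)) {
    cols <- meta$tissue == assigned[i]
    y[restricted_ids[i], cols] <- config$restricted_signal +
      stats::rnorm(sum(cols), 0, config$access_noise_sd)
    # stays exactly zero outside the assigned tissue
  }
  # off-tissue entries of restricted peaks stay y = 0, hence RPKM exactly 0
  rpkm <- pmax(2^y - 1, 0)
  classes <- data.frame(peak_id = peaks$id,
                        class = "linked", assigned_tissue = NA_character_,
                        stringsAsFactors = FALSE)
  classes$class[classes$peak_id %in% ubiq_ids] <- "ubiquitous"
  classes$class[classes$peak_id %in% restricted_ids] <- "restricted"
  classes$assigned_tissue[match(restricted_ids, classes$peak_id)] <- assigned

  truth$links <- data.frame(peak_id = linked_ids, gene_id = target,
                            tad_id = tads$id[tad_of],
                            r_true = rep(config$r_true, n_links),
                            stringsAsFactors = FALSE)
  truth$peak_classes <- classes
  list(rpkm = omics_matrix(rpkm, "RPKM", meta),
       peaks = interval_set(peaks, role = "peak",
                            chromosomes = ann$chromosomes),
       truth = truth)
}

# index of the (first) containing interval for each (chrom, pos); NA if none
locate_in_intervals <- function(chrom, pos, intervals) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L,
                                               intervals$end))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  as.integer(hits)
}

#' Simulate two-population genotypes with planted high-FST windows
#'
#' Balding-Nichols model: per-SNP ancestral frequency p ~ U(0.05, 0.95);
#' each population's frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = `f_background` everywhere except the planted windows, where
#' F = `f_high`; genotypes are Binomial(2, freq) with a small missing-call
#' rate.
#'
#' @param config A `SimulationConfig`.
#' @return list with `genotypes` (`GenotypeMatrix` with population labels)
#'   and `truth` (`TruthTable` with a `selected_windows` table).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(config$pop_sizes) < 2) stop("at least 2 populations required")
  set.seed(derive_seed(config$seed, "genotypes"))
  L <- config$geno_chrom_length
  w <- config$fst_window
  n_windows <- floor(L / w)
  planted <- sort(sample.int(n_windows, config$n_planted_windows))
  win_start <- (planted - 1) * w
  pos <- sort(sample.int(L, config$n_snps))
  site_window <- floor((pos - 1) / w) + 1
  f_site <- ifelse(site_window %in% planted, config$f_high,
                   config$f_background)
  p_anc <- stats::runif(config$n_snps, 0.05, 0.95)
  geno_cols <- list()
  for (pop in names(config$pop_sizes)) {
    a <- p_anc * (1 - f_site) / f_site
    b <- (1 - p_anc) * (1 - f_site) / f_site
    p_pop <- stats::rbeta(config$n_snps, a, b)
    n_s <- config$pop_sizes[[pop]]
    g <- matrix(stats::rbinom(config$n_snps * n_s, 2, rep(p_pop, n_s)),
                config$n_snps, n_s)
    colnames(g) <- sprintf("%s_%03d", pop, seq_len(n_s))
    geno_cols[[pop]] <- g
  }
  geno <- do.call(cbind, geno_cols)
  if (config$geno_missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$geno_missing_rate] <- NA
  }
  variants <- data.frame(chrom = "chr1", pos = pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  pops <- stats::setNames(rep(names(config$pop_sizes), config$pop_sizes),
                          colnames(geno))
  truth <- structure(
    list(selected_windows = data.frame(chrom = "chr1", start = win_start,
                                       end = win_start + w,
                                       f_high = config$f_high)),
    class = "TruthTable")
  list(genotypes = genotype_matrix(variants, geno, pops), truth = truth)
}

#' Simulate four-taxon derived-allele frequencies for the D-statistic
#'
#' Three ingroup taxa (H1, H2, H3) drift independently from a shared
#' ancestral derived-allele frequency under the Balding-Nichols model; the
#' outgroup (H4) carries the ancestral allele, so frequencies are already
#' polarized. Optional gene flow copies a fraction `introgression_f` of H3
#' ancestry into H2 within contiguous blocks covering
#' `d_intro_block_frac` of the genome (frequency-level mixing,
#' p2' = (1-f) p2 + f p3). Reported frequencies are sample frequencies from
#' Binomial(2N) draws.
#'
#' @param config A `SimulationConfig`.
#' @return list with `freqs` (data.frame chrom, pos, p1, p2, p3) and `truth`
#'   (`TruthTable` with the introgression flag and blocks).
#' @export
simulate_four_taxon <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "dstat"))
  n <- config$d_n_sites
  pos <- sort(sample.int(config$d_chrom_length, n))
  p0 <- stats::runif(n, 0.05, 0.95)
  f <- config$d_drift_f
  draw <- function() stats::rbeta(n, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  p1 <- draw(); p2 <- draw(); p3 <- draw()
  intro_blocks <- NULL
  if (config$introgression_f > 0) {
    blk_len <- config$d_chrom_length * config$d_intro_block_frac
    blk_start <- round(stats::runif(1, 0, config$d_chrom_length - blk_len))
    in_blk <- pos > blk_start & pos <= blk_start + blk_len
    p2[in_blk] <- (1 - config$introgression_f) * p2[in_blk] +
      config$introgression_f * p3[in_blk]
    intro_blocks <- data.frame(chrom = "chr1", start = blk_start,
                               end = blk_start + blk_len)
  }
  m <- 2 * config$d_pop_size
  sample_freq <- function(p) stats::rbinom(n, m, p) / m
  freqs <- data.frame(chrom = "chr1", pos = pos,
                      p1 = sample_freq(p1), p2 = sample_freq(p2),
                      p3 = sample_freq(p3))
  truth <- structure(list(introgressed = config$introgression_f > 0,
                          intro_blocks = intro_blocks),
                     class = "TruthTable")
  list(freqs = freqs, truth = truth)
}
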