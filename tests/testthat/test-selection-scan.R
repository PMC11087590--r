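test_that("SNP QC filter matches a hand-filtered oracle with strict thresholds", {
  variants <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                         ref = "A", alt = "G")
  geno <- rbind(
    c(0, 1, 1, 0, 2, 0, 1, 0, 1, 0),     # keep: cr 1.0, maf 0.3
    c(0, 1, NA, NA, 0, 0, 0, 0, 0, 1),   # drop: call rate 0.8
    c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0),     # drop: maf exactly 0.05
    c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2),     # drop: monomorphic
    c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0))     # keep: maf 0.10
  colnames(geno) <- paste0("s", 1:10)
  g <- genotype_matrix(variants, geno)
  kept <- suppressMessages(filter_snps(g))
  expect_equal(kept$variants$pos, c(10L, 50L))
})

test_that("Hudson per-site components follow the estimator algebra", {
  fixed <- hudson_fst_site(1, 10, 0, 10)
  expect_equal(fixed$num, 1)
  expect_equal(fixed$den, 1)

  same <- hudson_fst_site(0.5, 10, 0.5, 10)
  expect_equal(same$num, -1 / 18)
  expect_equal(same$den, 0.5)
  expect_equal(same$num / same$den, -1 / 9)

  # p1 = p2 = p generally: num = -2 p(1-p)/(n-1), den = 2 p(1-p)
  p <- 0.3; n <- 20
  r <- hudson_fst_site(p, n, p, n)
  expect_equal(r$num, -2 * p * (1 - p) / (n - 1))
  expect_equal(r$den, 2 * p * (1 - p))

  # both fixed for the same allele: excluded as (0, 0)
  z <- hudson_fst_site(0, 10, 0, 10)
  expect_equal(c(z$num, z$den), c(0, 0))
})

test_that("windowed FST is a ratio of sums and matches the brute-force oracle", {
  cfg <- sim_config(seed = 19, n_snps = 800L, geno_chrom_length = 2e5,
                    pop_sizes = c(lowland = 30L, highland = 30L),
                    n_planted_windows = 2L)
  gen <- simulate_genotypes(cfg)
  filt <- suppressMessages(filter_snps(gen$genotypes))
  w <- windowed_fst(filt, c("lowland", "highland"),
                    chrom_lengths = c(chr1 = 2e5))
  oracle <- windowed_fst_oracle(filt, c("lowland", "highland"), 1e4)
  key <- paste(w$chrom, floor(w$start / 1e4))
  expect_equal(w$fst, unname(oracle[key]))

  # single fixed-difference SNP in a window gives FST = 1
  g1 <- genotype_matrix(
    data.frame(chrom = "chr1", pos = 5000L, ref = "A", alt = "G"),
    matrix(c(rep(2, 4), rep(0, 4)), 1,
           dimnames = list(NULL, paste0("s", 1:8))),
    stats::setNames(rep(c("p1", "p2"), each = 4), paste0("s", 1:8)))
  w1 <- windowed_fst(g1, c("p1", "p2"), min_snps = 1)
  expect_equal(w1$fst, 1)

  # concatenating windows combines sums, not window means
  two <- w[w$eligible, ][1:2, ]
  combined <- sum(two$numerator_sum) / sum(two$denominator_sum)
  expect_false(isTRUE(all.equal(combined, mean(two$fst))))
  expect_equal(combined,
               (two$numerator_sum[1] + two$numerator_sum[2]) /
                 (two$denominator_sum[1] + two$denominator_sum[2]))
})

test_that("top-window calling selects the exact upper tail and merges neighbors", {
  set.seed(3)
  w <- data.frame(chrom = "chr1", start = seq(0, 99e4, 1e4),
                  end = seq(1e4, 1e6, 1e4), n_snps = 10,
                  numerator_sum = 1, denominator_sum = 1,
                  fst = sample(seq(0.01, 1, length.out = 100)),
                  eligible = TRUE)
  class(w) <- c("FstWindow", "data.frame")
  top <- suppressMessages(top_windows(w, top_fraction = 0.05))
  n_selected <- sum(top$end - top$start) / 1e4
  expect_equal(n_selected, 5)

  # two adjacent selected windows merge into one region
  w2 <- w
  w2$fst <- c(rep(0.1, 98), 0.9, 0.95)  # last two windows adjacent
  top2 <- top_windows(w2, top_fraction = 0.02)
  expect_equal(nrow(top2), 1)
  expect_equal(c(top2$start, top2$end), c(98e4, 1e6))
  expect_error(top_windows(w[1:10, ]), ">= 20 eligible")
})

test_that("region-to-gene annotation respects half-open overlap and the oracle", {
  ann <- toy_annotation()
  regions <- interval_set(data.frame(chrom = "chr1", start = 0L,
                                     end = 10000L, id = "r1"),
                          role = "region")
  expect_equal(annotate_regions_to_genes(regions, ann), "gA")  # 1 bp overlap
  regions2 <- interval_set(data.frame(chrom = "chr1", start = 0L,
                                      end = 9999L, id = "r1"),
                           role = "region")
  expect_equal(annotate_regions_to_genes(regions2, ann), character(0))

  set.seed(6)
  rnd <- interval_set(data.frame(chrom = sample(c("chr1", "chr2"), 20,
                                                replace = TRUE),
                                 start = s <- sample.int(15000, 20),
                                 end = s + 3000L,
                                 id = sprintf("r%02d", 1:20)),
                      role = "region")
  expect_equal(annotate_regions_to_genes(rnd, ann, flank = 500),
               region_gene_overlap_oracle(rnd, ann$genes, flank = 500))
})

test_that("multi-tissue intersection applies both membership gates", {
  sets <- stats::setNames(
    c(rep(list(c("gFst5", "gOther10")), 10),
      rep(list("gFst4"), 4), rep(list(character(0)), 5)),
    paste0("t", 1:19))
  res <- multi_tissue_intersection(c("gFst5", "gFst4"), sets,
                                   min_tissues = 5)
  expect_equal(res$gene_id, "gFst5")
  expect_equal(res$n_tissues, 10L)
  expect_error(multi_tissue_intersection("g", sets[1:3], min_tissues = 5),
               "fewer tissues")
})

test_that("overlap permutation test matches the hypergeometric truth", {
  universe <- sprintf("g%02d", 1:20)
  A <- universe[1:5]; B <- universe[1:8]
  res <- overlap_permutation_test(A, B, universe, n_perm = 10000, seed = 2)
  expect_equal(res$observed, 5L)
  # exhaustive: P(X >= 5) = C(8,5)/C(20,5) = 56/15504
  p_exact <- 56 / 15504
  expect_lt(abs(res$p - p_exact), 3 * sqrt(p_exact / 10000))
  expect_lt(abs(res$null_mean - 2), 3 * res$null_sd / sqrt(10000))

  degenerate <- overlap_permutation_test(universe, universe, universe,
                                         n_perm = 100, seed = 1)
  expect_equal(degenerate$observed, 20L)
  expect_equal(degenerate$p, 1)
  expect_error(overlap_permutation_test(c(A, "not_there"), B, universe),
               "outside the universe")
})

test_that("D-statistic reproduces direct counts and its symmetries", {
  # haploid-style site patterns over >= 20 jackknife blocks:
  # 30 pure-ABBA sites and 10 pure-BABA sites -> D = 0.5
  pos <- seq(1e5, by = 5e6, length.out = 40)
  freqs <- data.frame(chrom = "chr1", pos = pos,
                      p1 = c(rep(0, 30), rep(1, 10)),
                      p2 = c(rep(1, 30), rep(0, 10)),
                      p3 = 1)
  res <- d_statistic(freqs, block_size = 5e6)
  expect_equal(res$abba, 30)
  expect_equal(res$baba, 10)
  expect_equal(res$D, 0.5)

  # p1 = p2 everywhere: D = 0 exactly
  set.seed(9)
  p <- stats::runif(200)
  sym <- data.frame(chrom = "chr1", pos = seq(1, 1e8, length.out = 200),
                    p1 = p, p2 = p, p3 = stats::runif(200))
  expect_identical(d_statistic(sym, block_size = 5e6)$D, 0)

  # antisymmetry under swapping the first two taxa
  ft <- simulate_four_taxon(sim_config(seed = 23, d_n_sites = 1500L))
  d_fwd <- d_statistic(ft$freqs)
  swapped <- ft$freqs
  names(swapped)[names(swapped) %in% c("p1", "p2")] <- c("p2", "p1")
  expect_equal(d_statistic(swapped)$D, -d_fwd$D)

  none <- data.frame(chrom = "chr1", pos = pos, p1 = 1, p2 = 1, p3 = 0)
  expect_error(d_statistic(none), "undefined")
})
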