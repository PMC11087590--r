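test_that("DEG thresholds apply exactly to external tables", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    log2FC = c(1.0, 2.0, 0.5),
                    p = c(0.001, 0.05, 0.001),
                    FDR = c(0.01, 0.2, 0.01))
  res <- differential_expression(external_table = tab)
  expect_equal(sum(res$is_deg), 1L)
  expect_equal(res$gene_id[res$is_deg], "g1")
  expect_error(differential_expression(external_table = tab[, 1:3]),
               "missing column")
  # relaxing both gates makes every tested gene a DEG
  relaxed <- differential_expression(external_table = tab,
                                     fdr_threshold = 1 + 1e-9,
                                     lfc_threshold = 0)
  expect_true(all(relaxed$is_deg))
})

test_that("default DE engine is calibrated on nulls and powered on planted effects", {
  om0 <- nb_two_group(2000, 10, dispersion = 0.2, seed = 101)
  res0 <- differential_expression(om0, colnames(om0$values)[1:10],
                                  colnames(om0$values)[11:20])
  expect_lte(sum(res0$is_deg), 0.01 * nrow(res0))

  lfc <- c(rep(2, 100), rep(0, 900))
  om1 <- nb_two_group(1000, 10, dispersion = 0.1, lfc = lfc, seed = 102)
  res1 <- differential_expression(om1, colnames(om1$values)[1:10],
                                  colnames(om1$values)[11:20])
  planted <- sprintf("g%04d", 1:100)
  expect_gte(mean(planted %in% res1$gene_id[res1$is_deg]), 0.9)
  expect_error(differential_expression(om1, colnames(om1$values)[1],
                                       colnames(om1$values)[11:20]),
               ">= 2 replicates")
})

test_that("DEG flags are invariant to gene and sample ordering", {
  om <- nb_two_group(200, 5, lfc = c(rep(1.5, 20), rep(0, 180)), seed = 103)
  a <- colnames(om$values)[1:5]; b <- colnames(om$values)[6:10]
  res <- differential_expression(om, a, b)
  perm_g <- sample(rownames(om$values))
  perm_s <- sample(colnames(om$values))
  om2 <- om_subset(om, samples = perm_s, features = perm_g)
  res2 <- differential_expression(om2, a, b)
  m <- match(res$gene_id, res2$gene_id)
  expect_equal(res$is_deg, res2$is_deg[m])
  expect_equal(res$log2FC, res2$log2FC[m])
})

test_that("shared/specific classification follows the tissue-count rule", {
  sets <- c(list(t1 = c("shared5", "spec1", "three"),
                 t2 = c("shared5", "three"),
                 t3 = c("shared5", "three"),
                 t4 = c("shared5"), t5 = c("shared5")),
            stats::setNames(rep(list(character(0)), 14), paste0("t", 6:19)))
  res <- classify_shared_specific(sets, min_shared = 5)
  expect_equal(res$shared, "shared5")
  expect_equal(res$specific$t1, "spec1")
  expect_false("three" %in% c(res$shared, unlist(res$specific)))
  expect_warning(classify_shared_specific(list(a = character(0),
                                               b = character(0))),
                 "no DEGs")
})

test_that("multi-tissue k-means recovers planted archetypes", {
  set.seed(5)
  centers <- matrix(stats::rnorm(5 * 8, sd = 4), 5, 8)
  truth <- rep(1:5, each = 60)
  fc <- centers[truth, ] + matrix(stats::rnorm(300 * 8, sd = 0.5), 300, 8)
  rownames(fc) <- sprintf("g%03d", 1:300)
  km <- multi_tissue_kmeans(fc, k_range = 2:8, seed = 3)
  expect_equal(km$k, 5)
  expect_gte(adjusted_rand_index(km$cluster, truth), 0.9)
  # centers are the means of their members (k-means fixed point)
  for (k in seq_len(km$k)) {
    expect_equal(unname(km$centers[k, ]),
                 unname(colMeans(fc[km$cluster == k, , drop = FALSE])),
                 tolerance = 1e-8)
  }
  # two well-separated archetypes: k = 2 and a perfect split
  fc2 <- rbind(matrix(3, 40, 8), matrix(-3, 40, 8)) +
    matrix(stats::rnorm(80 * 8, sd = 0.3), 80, 8)
  rownames(fc2) <- sprintf("h%02d", 1:80)
  km2 <- multi_tissue_kmeans(fc2, k_range = 2:6, seed = 3)
  expect_equal(km2$k, 2)
  expect_equal(adjusted_rand_index(km2$cluster, rep(1:2, each = 40)), 1)
  expect_error(multi_tissue_kmeans(fc2[1:3, ], k_range = 5:6), "fewer genes")
})

test_that("ARI helper agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("DCG detection: exact interpolation, ANOVA identity, null tail", {
  # 5 time points x 2 reps, zero within-time noise: degree-4 fit is exact
  time <- rep(c(0, 7, 14, 21, 245), each = 2)
  x <- matrix(rep(c(0, 0, 0, 0, 10), each = 2), 1, 10, byrow = TRUE,
              dimnames = list("step", paste0("s", 1:10)))
  res <- detect_dcgs(x, time)
  expect_identical(res$R2, 1)
  expect_true(res$is_dcg)

  # balanced design: R2 equals between-time SS / total SS
  set.seed(30)
  xb <- matrix(stats::rnorm(50 * 10, mean = rep(time, each = 50) / 50),
               50, 10, dimnames = list(sprintf("g%02d", 1:50), NULL))
  resb <- detect_dcgs(xb, time)
  r2_oracle <- apply(xb, 1, function(y) {
    fit <- stats::aov(y ~ factor(time))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    ss[1] / sum(ss)
  })
  expect_equal(resb$R2, unname(r2_oracle), tolerance = 1e-10)

  # pure-noise genes essentially never pass the R2 >= 0.4 + FDR gate
  set.seed(31)
  tn <- rep(c(0, 7, 14, 21, 245), each = 10)
  xn <- matrix(stats::rnorm(2000 * 50), 2000, 50,
               dimnames = list(sprintf("n%04d", 1:2000), NULL))
  resn <- detect_dcgs(xn, tn)
  expect_lt(mean(resn$is_dcg), 0.001)
  # analytic null: R2 ~ Beta(d/2, (n-d-1)/2), tail below 1 in 1000 per gene
  expect_lt(stats::pbeta(0.4, 2, 22.5, lower.tail = FALSE), 0.001)

  expect_error(detect_dcgs(x, rep(c(0, 7), each = 5)), "distinct time")
})

test_that("DCG R2 is invariant under affine rescaling of the time axis", {
  set.seed(33)
  time <- rep(c(0, 7, 14, 21, 245), each = 4)
  x <- matrix(stats::rnorm(100 * 20, mean = rep(sqrt(time), each = 100)),
              100, 20, dimnames = list(sprintf("g%03d", 1:100), NULL))
  r1 <- detect_dcgs(x, time)
  r2 <- detect_dcgs(x, time * 3.7 - 12)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-10)
})

test_that("fuzzy c-means obeys its membership and objective contracts", {
  set.seed(4)
  arch <- rbind(c(-1, -0.5, 0, 0.5, 1), c(1, 0.5, 0, -0.5, -1))
  truth <- rep(1:2, each = 100)
  x <- arch[truth, ] + matrix(stats::rnorm(200 * 5, sd = 0.3), 200, 5)
  x <- standardize_rows(x)
  rownames(x) <- sprintf("g%03d", 1:200)
  fit <- fuzzy_cmeans(x, c = 2, seed = 6)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 200),
               tolerance = 1e-12)
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_gte(max(adjusted_rand_index(fit$cluster, truth),
                 mean(fit$cluster == truth),
                 mean(fit$cluster != truth)), 0.95)

  # a point at zero distance from a center gets full membership there
  u <- hypoxlink:::memberships_from_d2(matrix(c(0, 2.3), 1, 2), m = 2)
  expect_equal(as.vector(u), c(1, 0))
})

test_that("fuzzy c-means agrees with the e1071 reference on separated data", {
  skip_if_not_installed("e1071")
  set.seed(12)
  arch <- rbind(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2), c(0, 2, 0, 2, 0))
  truth <- rep(1:3, each = 50)
  x <- standardize_rows(arch[truth, ] +
                          matrix(stats::rnorm(150 * 5, sd = 0.2), 150, 5))
  rownames(x) <- sprintf("g%03d", 1:150)
  ours <- fuzzy_cmeans(x, c = 3, seed = 2)
  ref <- e1071::cmeans(x, centers = 3, m = 2)
  expect_equal(adjusted_rand_index(ours$cluster, ref$cluster), 1)
})

test_that("cluster-number rule returns planted counts and degenerate minima", {
  set.seed(14)
  arch <- rbind(c(2, 1, 0, -1, -2), c(-2, -1, 0, 1, 2),
                c(0, 2, 0, 2, 0), c(2, -2, 2, -2, 2))
  truth <- rep(1:4, each = 60)
  x <- standardize_rows(arch[truth, ] +
                          matrix(stats::rnorm(240 * 5, sd = 0.25), 240, 5))
  rownames(x) <- sprintf("g%03d", 1:240)
  expect_equal(choose_cluster_number(x, c_range = 2:6, seed = 9), 4)

  # one archetype plus noise: no second profile exists, so the minimum wins
  one <- standardize_rows(matrix(rep(c(2, 1, 0, -1, -2), each = 150),
                                 150, 5) +
                            matrix(stats::rnorm(750, sd = 0.4), 150, 5))
  rownames(one) <- sprintf("n%03d", 1:150)
  expect_equal(choose_cluster_number(one, c_range = 2:5, seed = 9), 2)

  # duplicated archetypes make the split criterion trigger immediately
  dup <- standardize_rows(rbind(arch[c(1, 1, 2), ])[rep(1:3, each = 50), ] +
                            matrix(stats::rnorm(750, sd = 0.15), 150, 5))
  rownames(dup) <- sprintf("d%03d", 1:150)
  expect_equal(choose_cluster_number(dup, c_range = 2:5, seed = 9), 2)
})
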