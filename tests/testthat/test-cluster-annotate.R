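# HVG selection, clustering, marker testing, cell typing, frequency tests.

test_that("variable-gene selection excludes constants and off-window means, finds planted", {
  set.seed(1)
  n <- 300; g_null <- 1000; g_pl <- 30
  G <- 3 + g_null + g_pl
  feats <- data.frame(id = paste0("g", 1:G), symbol = paste0("G", 1:G),
                      chromosome = "chr1", start = 1:G,
                      mito = FALSE, hemoglobin = FALSE)
  m <- matrix(0L, n, G)
  m[, 1] <- 7L                                   # constant: variance 0
  m[, 2] <- rbinom(n, 1, 0.002)                  # mean below 0.0125
  m[, 3] <- rnbinom(n, size = 0.3, mu = 40)      # mean above 6: excluded
  for (j in 4:(3 + g_null)) m[, j] <- rpois(n, runif(1, 1, 5))
  planted <- (4 + g_null):G
  for (j in planted) m[, j] <- rnbinom(n, size = 0.3, mu = runif(1, 1, 5))
  norm <- normalize_log(count_matrix(Matrix::Matrix(m, sparse = TRUE), feats),
                        scale_factor = mean(rowSums(m)))
  hvg <- select_hvg(norm)
  expect_false("G1" %in% hvg)
  expect_false("G2" %in% hvg)
  expect_false("G3" %in% hvg)
  sens <- mean(paste0("G", planted) %in% hvg)
  expect_gt(sens, 0.9)
  # Poisson background stays mostly unselected
  fp <- mean(paste0("G", 4:(3 + g_null)) %in% hvg)
  expect_lt(fp, 0.1)
})

test_that("clustering recovers planted types and is deterministic", {
  fx <- fx_atlas()
  hvg <- select_hvg(fx$norm)
  cl <- embed_and_cluster(fx$norm, hvg)
  ari <- adjusted_rand(cl$clusters, fx$truth_kept$true_type)
  expect_gt(ari, 0.95)
  # labels are dense 0..K-1 ordered by size
  sizes <- table(cl$clusters)
  expect_identical(sort(unique(cl$clusters)), 0:(length(sizes) - 1L))
  expect_true(all(diff(as.integer(sizes)) <= 0))
  cl2 <- embed_and_cluster(fx$norm, hvg)
  expect_identical(cl$clusters, cl2$clusters)
  expect_error(embed_and_cluster(fx$norm, hvg, cluster_config(knn_k = 10000L)),
               "knn_k")
})

test_that("marker testing matches the exact rank-permutation oracle", {
  # 4-vs-4 toy: package Wilcoxon p equals full enumeration
  x <- c(1.1, 2.3, 3.1, 4.7); y <- c(5.2, 6.1, 7.9, 8.4)
  expect_equal(suppressWarnings(wilcox.test(x, y))$p.value,
               wilcox_oracle_p(x, y))
  x2 <- c(1.1, 6.5, 3.1, 4.7); y2 <- c(5.2, 2.2, 7.9, 8.4)
  expect_equal(suppressWarnings(wilcox.test(x2, y2))$p.value,
               wilcox_oracle_p(x2, y2))
})

test_that("marker table reports sound statistics on planted structure", {
  fx <- fx_atlas()
  truth <- fx$truth_kept
  degs <- find_markers(fx$norm, truth$true_type)
  expect_true(all(degs$p_bonferroni >= degs$p_raw - 1e-12))
  expect_true(all(degs$fdr >= degs$p_raw - 1e-12))
  expect_equal(degs$p_bonferroni,
               pmin(1, degs$p_raw * ncol(fx$norm$values)))
  expect_true(all(degs$fraction_in >= 0 & degs$fraction_in <= 1))
  # each type's planted markers surface as markers of that type
  mk <- fx$cfg$marker_assignments
  tum <- degs[degs$cluster == "tumor" & degs$is_marker, "gene"]
  expect_true(all(mk$tumor %in% tum))
  # a gene exclusive to one cluster is its marker with positive lfc
  exc <- degs[degs$cluster == "EC" & degs$gene == "PLVAP", ]
  expect_true(nrow(exc) == 1 && exc$log_fold_change > 0 && exc$is_marker)
})

test_that("cell-type assignment is exact on planted types", {
  fx <- fx_atlas()
  truth <- fx$truth_kept
  hvg <- select_hvg(fx$norm)
  cl <- embed_and_cluster(fx$norm, hvg)
  ann <- assign_cell_types(fx$norm, cl$clusters, fx$cfg$marker_assignments)
  # majority-truth label of each cluster matches the assignment
  for (g in names(ann$cluster_type)) {
    maj <- names(sort(table(truth$true_type[cl$clusters == as.integer(g)]),
                      decreasing = TRUE))[1]
    expect_identical(ann$cluster_type[[g]], maj)
  }
  # all-zero marker expression -> unassigned
  feats <- data.frame(id = paste0("g", 1:30), symbol = paste0("G", 1:30),
                      chromosome = "chr1", start = 1:30,
                      mito = FALSE, hemoglobin = FALSE)
  m <- Matrix::Matrix(matrix(rpois(20 * 30, 4), 20, 30), sparse = TRUE)
  norm0 <- normalize_log(count_matrix(m, feats))
  ann0 <- assign_cell_types(norm0, rep(0L, 20),
                            markers = list(tumor = c("EPCAM", "CDH17")))
  expect_identical(unname(ann0$cluster_type), "unassigned")
})

test_that("frequency tests: trivial equality, planted shift power, normalization", {
  # identical frequencies in both groups -> p = 1, diff 0
  ct <- rep(c("A", "B"), 60)
  smp <- rep(paste0("s", 1:12), each = 10)
  grp <- rep(c("adjacent", "cancer"), each = 60)
  r <- celltype_frequency_test(ct, smp, grp)
  expect_true(all(abs(rowSums(r$frequencies) - 1) < 1e-12))
  expect_equal(r$t_tests$p, rep(1, 2))
  expect_equal(r$t_tests$diff, rep(0, 2))
  # planted 3x shift, n = 12 per group: significant in most replicates
  set.seed(99)
  hits <- replicate(40, {
    fa <- pmin(pmax(rnorm(12, 0.10, 0.03), 0.01), 1)
    fb <- pmin(pmax(rnorm(12, 0.30, 0.03), 0.01), 1)
    cells <- do.call(rbind, lapply(1:24, function(i) {
      f <- if (i <= 12) fa[i] else fb[i - 12]
      n_a <- rbinom(1, 100, f)
      data.frame(ct = c(rep("A", n_a), rep("B", 100 - n_a)),
                 smp = paste0("s", i),
                 grp = if (i <= 12) "g1" else "g2")
    }))
    rr <- celltype_frequency_test(cells$ct, cells$smp, cells$grp)
    rr$t_tests$p[rr$t_tests$type == "A"] < 0.05
  })
  expect_gt(mean(hits), 0.9)
  # under-filled group is skipped with notice
  ct3 <- rep(c("A", "B"), 15)
  smp3 <- rep(paste0("s", 1:3), each = 10)
  grp3 <- rep(c("adjacent", "adjacent", "cancer"), each = 10)
  r2 <- celltype_frequency_test(ct3, smp3, grp3)
  expect_null(r2$t_tests)
  expect_match(r2$skipped, "< 2 samples")
})
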