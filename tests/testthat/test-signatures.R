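# Gene-set scoring, subtype deconvolution, tumor grouping, enrichment,
# ANOVA.

test_that("gene-set score follows the z-score definition", {
  set.seed(3)
  x <- matrix(rnorm(50 * 10, 5), 50, 10,
              dimnames = list(NULL, paste0("G", 1:10)))
  # a sample at the global mean of every gene scores 0
  x[1, ] <- colMeans(x[-1, ])
  x1 <- rbind(x[-1, ], x[1, ])
  sc <- score_gene_set(x1, paste0("G", 1:5))
  mu <- colMeans(x1); sdv <- apply(x1, 2, sd)
  expect_equal(unname(sc),
               unname(rowMeans(sweep(sweep(x1[, 1:5], 2, mu[1:5]), 2,
                                     sdv[1:5], "/"))),
               ignore_attr = TRUE)
  # single-gene set equals that gene's z-score
  sc1 <- score_gene_set(x, "G1")
  expect_equal(unname(sc1), unname((x[, "G1"] - mean(x[, "G1"])) / sd(x[, "G1"])),
               ignore_attr = TRUE)
  # invariant to genes outside the set
  x_noise <- cbind(x, H1 = rnorm(50))
  expect_equal(unname(score_gene_set(x_noise, paste0("G", 1:5))),
               unname(score_gene_set(x, paste0("G", 1:5))))
  expect_error(score_gene_set(x, c("ZZZ"), "EmyoT"), "EmyoT")
})

test_that("deconvolution recovers pure columns and mixtures", {
  fx <- fx_atlas()
  sig <- fx$cfg$programs[, c("GMC", "MSC", "tumor", "fibroblast")] * 1e4
  # pure column: weight 1 on that subtype
  dc <- deconvolve_subtypes(rbind(p = sig[, "tumor"]), sig)
  expect_equal(unname(dc$weights[1, "tumor"]), 1, tolerance = 1e-8)
  expect_identical(dc$label[1], "tumor")
  # noiseless 50/50 mixtures: weights within 0.05 L1
  pairs <- utils::combn(colnames(sig), 2)
  for (j in seq_len(ncol(pairs))) {
    mix <- 0.5 * sig[, pairs[1, j]] + 0.5 * sig[, pairs[2, j]]
    w <- deconvolve_subtypes(rbind(m = mix), sig)$weights[1, ]
    want <- setNames(rep(0, ncol(sig)), colnames(sig))
    want[pairs[, j]] <- 0.5
    expect_lt(sum(abs(w - want)), 0.05)
  }
  # weights never negative; all-zero input flagged
  set.seed(9)
  noisy <- rbind(a = pmax(sig[, 1] + rnorm(nrow(sig), 0, 0.1), 0),
                 z = rep(0, nrow(sig)))
  dcn <- deconvolve_subtypes(noisy, sig)
  expect_true(all(dcn$weights >= 0))
  expect_true(dcn$flagged[2])
  expect_true(is.na(dcn$label[2]))
})

test_that("tumor grouping separates planted intestinal / EMT / EmyoT programs", {
  sets <- default_gene_sets()
  markers <- list(intestinal = sets$intestinal, EMT = sets$EMT,
                  EmyoT = sets$EmyoT)
  # EmyoT is a rare subpopulation, as in real tumors
  cfg <- sim_config(n_cells_per_type = c(intestinal = 110L, EMT = 110L,
                                         EmyoT = 20L),
                    marker_assignments = markers, seed = 55L)
  sim <- simulate_cells(cfg)
  norm <- normalize_log(filter_cells(sim$counts)$kept)
  truth <- sim$truth[filter_cells(sim$counts)$report$kept, ]
  sc <- sapply(names(markers), function(nm) score_gene_set(norm, sets[[nm]], nm))
  grp <- classify_tumor_groups(sc)
  expect_gt(mean(grp$label == truth$true_type), 0.95)
  # planted EmyoT cells land in the top decile of the EmyoT score
  emyot_rank <- rank(sc[, "EmyoT"]) / nrow(sc)
  expect_gt(median(emyot_rank[truth$true_type == "EmyoT"]), 0.9)
  # EmyoT-like cells (myofibroblast high, EMT low) are never labeled EMT
  expect_false(any(grp$label[truth$true_type == "EmyoT"] == "EMT"))
  # exact tie resolves by priority with a flag
  tie <- classify_tumor_groups(
    matrix(c(1, 2, 1, 2, 1, 2), 2,
           dimnames = list(NULL, c("intestinal", "EMT", "EmyoT"))))
  expect_true(all(tie$tie))
  expect_true(all(tie$label == "EmyoT"))
  expect_error(classify_tumor_groups(sc[, 1:2]), "EmyoT")
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- paste0("G", 1:1000)
  deg <- paste0("G", 1:40)
  pw <- list(hit = paste0("G", 1:50), all = universe,
             off = paste0("H", 1:10))
  r <- hypergeometric_enrichment(deg, pw, universe)
  expect_equal(r$p[r$pathway == "hit"],
               phyper(39, 50, 950, 40, lower.tail = FALSE))
  expect_equal(r$p[r$pathway == "all"], 1)
  expect_identical(attr(r, "skipped"), "off")
  # disjoint large pathway: p ~ 1
  pw2 <- list(big = paste0("G", 500:900))
  expect_gt(hypergeometric_enrichment(deg, pw2, universe)$p, 0.99)
  expect_error(hypergeometric_enrichment("H1", pw, universe), "subset")
})

test_that("ANOVA matches direct sum-of-squares and has power on planted shifts", {
  # 3 x 5 toy against the direct SS computation
  y <- c(1.2, 2.1, 1.8, 2.4, 1.9,
         3.1, 2.8, 3.3, 3.0, 2.6,
         4.2, 3.9, 4.4, 4.1, 3.8)
  g <- rep(c("a", "b", "c"), each = 5)
  r <- compare_scores_anova(y, g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(r$F, f_oracle, tolerance = 1e-10)
  expect_equal(r$p, pf(f_oracle, 2, 12, lower.tail = FALSE))
  # identical group means: F = 0, p = 1
  r0 <- compare_scores_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # planted 1-sigma shift, n = 100 per group: power > 0.9 at alpha 0.01
  set.seed(17)
  hits <- replicate(60, {
    compare_scores_anova(c(rnorm(100), rnorm(100, 1)),
                         rep(c("a", "b"), each = 100))$p < 0.01
  })
  expect_gt(mean(hits), 0.9)
  expect_error(compare_scores_anova(1:4, c("a", "a", "a", "b")), "singleton")
})
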