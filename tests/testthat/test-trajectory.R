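# Pseudotime construction, progression states, pseudotime DEG test,
# cross-lineage overlap.

test_that("three collinear planted clusters order correctly from the root", {
  set.seed(7)
  n <- 60
  feats <- data.frame(id = paste0("g", 1:40), symbol = paste0("G", 1:40),
                      chromosome = "chr1", start = 1:40,
                      mito = FALSE, hemoglobin = FALSE)
  shift <- rep(c(0, 4, 8), each = n)  # A -> B -> C along genes 1:20
  m <- matrix(rpois(3 * n * 40, 5), 3 * n, 40)
  m[, 1:20] <- m[, 1:20] + shift
  types <- rep(c("A", "B", "C"), each = n)
  norm <- normalize_log(count_matrix(Matrix::Matrix(m, sparse = TRUE), feats))
  tr <- build_trajectory(norm, paste0("G", 1:40), root_types = "A",
                         annotations = types, k_medoids = 6L)
  mean_pt <- tapply(tr$pseudotime, types, mean)
  expect_true(mean_pt[["A"]] < mean_pt[["B"]])
  expect_true(mean_pt[["B"]] < mean_pt[["C"]])
  # the root medoid cell sits at pseudotime 0, all others non-negative
  expect_equal(min(tr$pseudotime), 0)
  expect_true(all(tr$pseudotime >= 0))
})

test_that("pseudotime recovers the planted latent time", {
  fx <- fx_lineage()
  truth <- fx$truth
  hvg <- select_hvg(fx$norm)
  tr <- build_trajectory(fx$norm, hvg, root_types = "GMC",
                         annotations = truth$true_type)
  lin <- !is.na(truth$true_latent_time)
  sp <- cor(tr$pseudotime[lin], truth$true_latent_time[lin],
            method = "spearman")
  expect_gte(sp, 0.8)
  # invariance to cell input order at fixed seed
  perm <- sample(nrow(fx$norm$values))
  norm_p <- structure(list(values = fx$norm$values[perm, ],
                           scale_factor = fx$norm$scale_factor,
                           features = fx$norm$features),
                      class = "normalized_matrix")
  tr_p <- build_trajectory(norm_p, hvg, root_types = "GMC",
                           annotations = truth$true_type[perm])
  sp_pair <- cor(tr$pseudotime[rownames(norm_p$values)], tr_p$pseudotime,
                 method = "spearman")
  expect_gt(sp_pair, 0.99)
})

test_that("progression states split by pseudotime and respect exclusions", {
  fx <- fx_lineage()
  truth <- fx$truth
  hvg <- select_hvg(fx$norm)
  tr <- build_trajectory(fx$norm, hvg, root_types = "GMC",
                         annotations = truth$true_type)
  st <- assign_progression_states(tr, truth$true_type, n_states = 3,
                                  prefix = "I")
  # excluded types carry their own labels
  excl <- truth$true_type %in% c("fibroblast", "EC")
  expect_true(all(grepl("^excluded_", st$state[excl])))
  expect_true(all(grepl("^I[123]$", st$state[!excl])))
  # tertile split: equal counts up to rounding
  cnt <- table(st$state[!excl])
  expect_lt(diff(range(cnt)), 3)
  # state means are ordered in pseudotime
  mp <- tapply(tr$pseudotime[!excl], st$state[!excl], mean)
  expect_identical(names(sort(mp)), st$state_order)
  # planted stage recovery
  lin <- !is.na(truth$true_latent_time)
  acc <- mean(match(st$state[lin], st$state_order) == truth$true_stage[lin])
  expect_gte(acc, 0.8)
  # stage medians align monotonically with states (perfect rank agreement)
  med <- tapply(truth$true_stage[lin], st$state[lin], median)
  expect_identical(order(med[st$state_order]), seq_along(st$state_order))
})

test_that("all-excluded input yields only excluded labels", {
  fx <- fx_lineage()
  truth <- fx$truth
  hvg <- select_hvg(fx$norm)
  tr <- build_trajectory(fx$norm, hvg, root_types = "GMC",
                         annotations = truth$true_type)
  st <- assign_progression_states(tr, rep("EC", length(tr$pseudotime)),
                                  n_states = 3, exclude_types = "EC")
  expect_true(all(grepl("^excluded_EC$", st$state)))
})

test_that("pseudotime LRT is calibrated and detects planted dependence", {
  set.seed(2)
  n <- 300
  pt <- runif(n)
  n_genes <- 500
  y <- matrix(rnorm(n * n_genes), n, n_genes)      # null genes
  y[, 1] <- 2 * pt + rnorm(n, 0, 0.1)              # planted signal
  y[, 2] <- 1.5                                    # constant
  feats <- data.frame(id = paste0("g", 1:n_genes),
                      symbol = paste0("G", 1:n_genes),
                      chromosome = "chr1", start = 1:n_genes,
                      mito = FALSE, hemoglobin = FALSE)
  norm <- structure(list(values = Matrix::Matrix(pmax(y, 0), sparse = TRUE),
                         scale_factor = 1, features = feats),
                    class = "normalized_matrix")
  res <- pseudotime_deg_lrt(norm, pt)
  expect_lt(res$p[1], 1e-5)
  expect_equal(res$p[2], 1)
  ks <- ks.test(res$p[3:n_genes], "punif")$p.value
  expect_gt(ks, 0.01)
})

test_that("DEG overlap follows its definition", {
  a <- paste0("G", 1:100)
  expect_equal(state_overlap(a, a)$percent, 100)
  expect_equal(state_overlap(a, paste0("H", 1:50))$percent, 0)
  b <- c(paste0("G", 1:84), paste0("X", 1:30))
  r <- state_overlap(a, b)
  expect_equal(r$percent, 84.0)
  expect_length(r$intersection, 84L)
  expect_error(state_overlap(character(0), a), "empty")
})
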