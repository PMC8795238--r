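# The generator must be deterministic, plant exactly what it is told to,
# and converge to its programs in the mean.

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 30L, tumor = 30L), seed = 5L)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_identical(a$truth, b$truth)
})

test_that("clean config passes all four QC rules by brute force", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 50L, MSC = 50L, tumor = 50L),
                    seed = 8L)
  sim <- simulate_cells(cfg)
  dense <- as.matrix(sim$counts$values)
  mh <- sim$counts$features$mito | sim$counts$features$hemoglobin
  expect_equal(nrow(dense), 150L)
  expect_true(all(qc_oracle_keep(dense, mh)))
})

test_that("planted low-UMI cells are exactly the UMI-floor failures", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 40L),
                    qc_violation_counts = c(low_umi = 5L), seed = 13L)
  sim <- simulate_cells(cfg)
  total <- Matrix::rowSums(sim$counts$values)
  below <- unname(which(total < 100))
  planted <- which(sim$truth$true_qc_fail == "low_umi")
  expect_identical(below, planted)
  expect_length(below, 5L)
})

test_that("planted truth is recoverable by direct lookup", {
  fx <- fx_atlas()
  truth <- fx$sim$truth
  # every planted violation really violates its rule (brute force)
  dense <- as.matrix(fx$sim$counts$values)
  mh <- fx$sim$counts$features$mito | fx$sim$counts$features$hemoglobin
  keep <- qc_oracle_keep(dense, mh)
  expect_true(all(!keep[truth$true_qc_fail != ""]))
  # CNV carriers are exactly the tumor cells
  cnv_flag <- attr(truth, "true_cnv")[, 1]
  expect_identical(cnv_flag, truth$true_type == "tumor")
  # carriers only among configured carrier types
  carrier <- attr(truth, "true_carrier")
  expect_true(all(truth$true_type[carrier[, "CCND1_T286"]] %in% c("MSC", "tumor")))
})

test_that("type mean expression converges to its program", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 2000L), seed = 21L,
                    libsize_sdlog = 0)
  sim <- simulate_cells(cfg)
  dense <- as.matrix(sim$counts$values)
  prog <- cfg$programs[, "GMC"] * cfg$mean_umi
  emp <- colMeans(dense)
  se <- apply(dense, 2, sd) / sqrt(nrow(dense))
  frac_within <- mean(abs(emp - prog) <= 3 * pmax(se, 1e-8))
  expect_gt(frac_within, 0.98)
})

test_that("program override shares biology across simulations", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 20L, tumor = 20L), seed = 5L)
  cfg2 <- sim_config(n_cells_per_type = c(GMC = 20L, tumor = 20L),
                     cell_type_programs = cfg$programs, seed = 6L)
  expect_equal(cfg2$programs, cfg$programs)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg2)
  # same biology, different noise draw
  expect_false(identical(as.matrix(a$counts$values),
                         as.matrix(b$counts$values)))
  expect_error(sim_config(n_cells_per_type = c(GMC = 5L),
                          cell_type_programs = cfg$programs[1:10, ]),
               "genes x types")
})

test_that("configuration errors are caught", {
  expect_error(sim_config(n_cells_per_type = c(ghost = 10L)), "marker")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(cnv_block(1:10, 0, "tumor"), "multiplier")
  expect_error(sim_config(n_cells_per_type = c(GMC = 10L),
                          cnv_blocks = list(cnv_block(10^6, 2, "GMC"))),
               "range")
  ms <- default_mutation_spec()
  ms$carrier_prob[1] <- 2
  expect_error(sim_config(mutation_spec = ms), "carrier_prob")
})

test_that("allele counts follow carrier status and depth model", {
  cfg <- sim_config(n_cells_per_type = c(MSC = 150L, GMC = 150L),
                    mutation_spec = data.frame(
                      variant_id = "V1", gene = "CCND1", position = 100,
                      protein_change = "T286", carrier_types = "MSC",
                      carrier_prob = 1, vaf = 1, mean_depth = 20),
                    seed = 33L)
  sim <- simulate_cells(cfg)
  ac <- simulate_allele_counts(sim$truth, cfg)
  carrier <- attr(sim$truth, "true_carrier")[, 1]
  vv <- tabulate_vaf(ac)
  # expected VAF 1: every covered carrier is fully alt
  expect_true(all(ac$alt[carrier, 1] + ac$ref[carrier, 1] > 0))
  expect_equal(mean(vv$vaf[carrier, 1], na.rm = TRUE), 1)
  # non-carriers have no alt reads, VAF 0 where covered
  expect_equal(sum(ac$alt[!carrier, 1]), 0)
  covered_nc <- !carrier & (ac$ref[, 1] > 0)
  expect_true(all(vv$vaf[covered_nc, 1] == 0))
  # intermediate VAF: binomial expectation within 3 SE
  cfg2 <- sim_config(n_cells_per_type = c(MSC = 400L),
                     mutation_spec = data.frame(
                       variant_id = "V1", gene = "CCND1", position = 100,
                       protein_change = "T286", carrier_types = "MSC",
                       carrier_prob = 1, vaf = 0.4, mean_depth = 30),
                     seed = 34L)
  sim2 <- simulate_cells(cfg2)
  ac2 <- simulate_allele_counts(sim2$truth, cfg2)
  vaf_hat <- sum(ac2$alt[, 1]) / sum(ac2$alt[, 1] + ac2$ref[, 1])
  se <- sqrt(0.4 * 0.6 / sum(ac2$alt[, 1] + ac2$ref[, 1]))
  expect_lt(abs(vaf_hat - 0.4), 3 * se)
  # zero mean depth: no entries at all
  cfg3 <- sim_config(n_cells_per_type = c(MSC = 50L),
                     mutation_spec = data.frame(
                       variant_id = "V1", gene = "CCND1", position = 100,
                       protein_change = "T286", carrier_types = "MSC",
                       carrier_prob = 1, vaf = 0.5, mean_depth = 0),
                     seed = 35L)
  sim3 <- simulate_cells(cfg3)
  ac3 <- simulate_allele_counts(sim3$truth, cfg3)
  expect_equal(sum(ac3$ref[, 1] + ac3$alt[, 1]), 0)
})

test_that("bulk cohort reproduces hazard ratio, batches and censoring", {
  cfg <- sim_config(n_cells_per_type = c(GMC = 20L, tumor = 20L), seed = 40L)
  bulk <- simulate_bulk_cohort(cfg, groups = list(A = c(GMC = 1), B = c(tumor = 1)),
                               n_per_group = c(A = 1000L, B = 1000L),
                               hazards = c(A = 0.01, B = 0.02),
                               censor_hazard = 0)
  s <- bulk$samples
  # exponential MLE d/T per group
  rate <- tapply(s$event, s$group, sum) / tapply(s$time, s$group, sum)
  expect_equal(unname(rate["B"] / rate["A"]), 2, tolerance = 0.15)
  expect_true(all(s$event == 1))
  # overwhelming censoring: no events
  bulk2 <- simulate_bulk_cohort(cfg, groups = list(A = c(GMC = 1), B = c(tumor = 1)),
                                n_per_group = c(A = 50L, B = 50L),
                                hazards = c(A = 0.01, B = 0.02),
                                censor_hazard = 1e9)
  expect_true(all(bulk2$samples$event == 0))
  expect_error(simulate_bulk_cohort(cfg, groups = list(A = c(GMC = 1)),
                                    n_per_group = c(A = 10L),
                                    hazards = c(A = 0)), "hazard")
})

test_that("stain simulation plants exactly the configured tiles", {
  blank <- simulate_ihc(width = 90, height = 68, n_cols = 9, n_rows = 4,
                        regions = list(), seed = 2L)
  expect_false(any(blank$truth))
  ih <- simulate_ihc(width = 90, height = 68, n_cols = 9, n_rows = 4,
                     regions = list(list(channels = c("MRTFA", "SRF"),
                                         cols = 2:3, rows = 1:2)), seed = 2L)
  expect_equal(sum(ih$truth[, "MRTFA"] & ih$truth[, "SRF"]), 4L)
  expect_equal(sum(ih$truth[, "IGFBP5"]), 0L)
  ih2 <- simulate_ihc(width = 90, height = 68, n_cols = 9, n_rows = 4,
                      regions = list(list(channels = c("MRTFA", "SRF"),
                                          cols = 2:3, rows = 1:2)), seed = 2L)
  expect_identical(ih$images, ih2$images)
  expect_error(simulate_ihc(n_cols = 5, n_rows = 5, width = 50, height = 50,
                            regions = list(list(channels = "MRTFA",
                                                cols = 6, rows = 1))),
               "outside")
})
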