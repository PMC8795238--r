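# Shared synthetic fixtures, built once per test run and cached.

.fx <- new.env()

# Small three-type atlas with planted QC violations and mutations.
fx_atlas <- function() {
  if (is.null(.fx$atlas)) {
    cfg <- sim_config(
      n_cells_per_type = c(GMC = 80L, MSC = 80L, tumor = 80L,
                           fibroblast = 50L, EC = 40L, immune = 60L),
      qc_violation_counts = c(low_sd = 3L, high_zero = 3L, high_mito = 3L,
                              low_umi = 5L, high_umi = 2L),
      mutation_spec = default_mutation_spec(),
      cnv_blocks = list(cnv_block(301:500, 2, "tumor")),
      seed = 424242L)
    sim <- simulate_cells(cfg)
    qc <- filter_cells(sim$counts)
    norm <- normalize_log(qc$kept)
    .fx$atlas <- list(cfg = cfg, sim = sim, qc = qc, norm = norm,
                      truth_kept = sim$truth[qc$report$kept, ])
  }
  .fx$atlas
}

# Benign -> premalignant -> malignant lineage with stromal bystanders.
fx_lineage <- function() {
  if (is.null(.fx$lineage)) {
    cfg <- sim_config(
      n_cells_per_type = c(fibroblast = 50L, EC = 40L),
      lineage_spec = list(types = c("GMC", "MSC", "tumor"), n_cells = 600L),
      seed = 31L)
    sim <- simulate_cells(cfg)
    qc <- filter_cells(sim$counts)
    norm <- normalize_log(qc$kept)
    .fx$lineage <- list(cfg = cfg, sim = sim, norm = norm,
                        truth = sim$truth[qc$report$kept, ])
  }
  .fx$lineage
}
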