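# Shared configuration for the analysis scripts. Sourced by each numbered
# driver so every step regenerates identical inputs from one seed instead
# of passing binary intermediates around.

library(gcatlas)

ATLAS_SEED <- 20260927L %% 100000L

atlas_config <- function() {
  sim_config(
    n_cells_per_type = c(GMC = 150L, PMC = 100L, MSC = 120L, tumor = 120L,
                         fibroblast = 80L, EC = 60L, enteroendocrine = 40L,
                         IM = 80L, immune = 120L),
    qc_violation_counts = c(low_sd = 5L, high_zero = 5L, high_mito = 5L,
                            low_umi = 8L, high_umi = 3L),
    cnv_blocks = list(cnv_block(301:500, 2, "tumor")),
    mutation_spec = default_mutation_spec(),
    seed = ATLAS_SEED)
}

lineage_config <- function() {
  sim_config(
    n_cells_per_type = c(fibroblast = 60L, EC = 50L),
    lineage_spec = list(types = c("GMC", "MSC", "tumor"), n_cells = 600L),
    seed = ATLAS_SEED + 1L)
}

# atlas after QC + normalization, with truth aligned to kept cells
atlas_prepared <- function(cfg = atlas_config()) {
  sim <- simulate_cells(cfg)
  qc <- filter_cells(sim$counts)
  norm <- normalize_log(qc$kept)
  list(cfg = cfg, sim = sim, qc = qc, norm = norm,
       truth = sim$truth[qc$report$kept, ])
}

dir.create("results", showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path("results", f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
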