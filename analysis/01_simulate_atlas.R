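#!/usr/bin/env Rscript
# Generate the synthetic gastric atlas: a 10x-style count matrix over nine
# cell types with planted low-quality cells, a CCND1-hotspot mutation
# catalog carried by the MSC/tumor lineage, and a 2x copy-number gain in
# tumor cells. Writes the Matrix Market triplet and the ground truth.

source("analysis/00_config.R")

cfg <- atlas_config()
sim <- simulate_cells(cfg)
message(sprintf("simulated %d cells x %d genes (%d planted QC violations)",
                nrow(sim$counts$values), ncol(sim$counts$values),
                sum(sim$truth$true_qc_fail != "")))

write_count_matrix(sim$counts, "results/atlas_counts")
tsv(sim$truth, "atlas_truth.tsv")
tsv(cfg$mutation_spec, "hotspot_catalog.tsv")
write_gmt(default_gene_sets(), "results/gene_sets.gmt")
message("wrote results/atlas_counts/, atlas_truth.tsv, hotspot_catalog.tsv, gene_sets.gmt")
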