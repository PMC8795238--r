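#!/usr/bin/env Rscript
# Quality control, depth normalization, immune split, clustering and
# marker-based cell typing of the synthetic atlas, plus per-sample
# frequency tests between lesions.

source("analysis/00_config.R")

prep <- atlas_prepared()
rep <- prep$qc$report
message(sprintf("QC: %d of %d cells kept; removed by rule: %s",
                sum(rep$kept), nrow(rep),
                paste(capture.output(print(table(
                  rep$rules_violated[!rep$kept]))), collapse = " ")))
tsv(rep, "qc_report.tsv")

hvg <- select_hvg(prep$norm)
cl <- embed_and_cluster(prep$norm, hvg)
ann <- assign_cell_types(prep$norm, cl$clusters, prep$cfg$marker_assignments)
imm <- split_immune(prep$norm, cl$clusters)
acc <- mean(ann$cell_type == prep$truth$true_type)
message(sprintf("%d variable genes; %d clusters; cell-type accuracy vs truth %.3f",
                length(hvg), length(unique(cl$clusters)), acc))

degs <- find_markers(prep$norm, cl$clusters)
tsv(degs, "cluster_markers.tsv")
tsv(data.frame(cell = rownames(prep$norm$values), cluster = cl$clusters,
               cell_type = ann$cell_type, immune = imm$cell_class,
               true_type = prep$truth$true_type), "annotation.tsv")

# synthetic lesion assignment: odd/even patients, tumor-bearing = cancer
set.seed(ATLAS_SEED)
patient <- sample(paste0("P", 1:8), nrow(prep$norm$values), replace = TRUE)
lesion <- ifelse(prep$truth$true_type %in% c("tumor", "MSC"),
                 "cancer", sample(c("adjacent", "cancer"),
                                  nrow(prep$norm$values), replace = TRUE))
freq <- celltype_frequency_test(ann$cell_type, patient, lesion)
tsv(freq$t_tests, "celltype_frequency_tests.tsv")
message("frequency t-tests written; smallest p = ",
        signif(min(freq$t_tests$p), 3))
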