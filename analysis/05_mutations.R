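#!/usr/bin/env Rscript
# Per-cell hotspot allele counts -> VAF, catalog filtering, mutated-cell
# tabulation by cell type, and the cell-cycle G1/S score contrast between
# CCND1-mutant and wild-type cells.

source("analysis/00_config.R")

prep <- atlas_prepared()
ac_all <- simulate_allele_counts(prep$sim$truth, prep$cfg)
kept <- prep$qc$report$kept
ac <- allele_counts(ac_all$ref[kept, , drop = FALSE],
                    ac_all$alt[kept, , drop = FALSE], ac_all$catalog)

flt <- filter_hotspot_variants(ac, annotations = prep$truth$true_type)
message(sprintf("%d of %d catalog variants carry alt reads outside immune cells",
                ncol(flt$alt), ncol(ac$alt)))

vv <- tabulate_vaf(flt)
ann_ni <- prep$truth$true_type[!(prep$truth$true_type %in% "immune")]
tab <- mutation_by_celltype(flt, ann_ni)
tsv(as.data.frame.table(tab$by_celltype,
                        responseName = "mutated_cells"),
    "mutation_by_celltype.tsv")
message("CCND1 mutated cells by type: ",
        paste(colnames(tab$by_celltype), tab$by_celltype["CCND1", ],
              collapse = ", "))

# enrichment of CCND1 mutation in the MSC/tumor lineage (Fisher)
is_lineage <- ann_ni %in% c("MSC", "tumor")
ccnd1_mut <- rowSums(as.matrix(flt$alt[, flt$catalog$gene == "CCND1",
                                       drop = FALSE]) >= 1) > 0
fis <- enrichment_fisher(table(factor(ccnd1_mut, c(TRUE, FALSE)),
                               factor(is_lineage, c(TRUE, FALSE))))
message(sprintf("CCND1-mut enrichment in MSC/tumor: OR %.1f, P = %.3g",
                fis$odds_ratio, fis$p))

# G1/S pathway score in CCND1-mutant vs wild-type premalignant/tumor cells
sets <- default_gene_sets()
g1s <- score_gene_set(prep$norm, sets$G1S, "G1S")
g1s_ni <- g1s[!(prep$truth$true_type %in% "immune")]
sub <- is_lineage
an <- compare_scores_anova(g1s_ni[sub],
                           ifelse(ccnd1_mut[sub], "CCND1_mut", "WT"))
message(sprintf("G1/S score CCND1-mut vs WT (MSC/tumor): F = %.2f, P = %.3g",
                an$F, an$p))
tsv(data.frame(cell = names(g1s_ni)[sub], g1s_score = g1s_ni[sub],
               ccnd1_mutant = ccnd1_mut[sub]), "g1s_scores.tsv")
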