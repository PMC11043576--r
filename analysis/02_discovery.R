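#!/usr/bin/env Rscript
# Stage 2 -- discovery-phase qPCR statistics: collapse technical duplicates,
# flag outliers, apply the Ct > 34 exclusion, impute, globally normalize,
# pick Normfinder references, run hormone-stratified t-tests and the
# dual-threshold candidate rule, then assemble the replication probe panel.

suppressPackageStartupMessages(library(endomiR))

cohort <- read_sample_sheet("results/data/discovery_samples.csv",
                            phase = "discovery")
ct <- read_expr_tsv("results/data/discovery_ct.tsv", type = "ct")

collapsed <- collapse_duplicates(ct, max_discordance = 1.0)
groups <- cohort$group[match(colnames(collapsed$values), cohort$sample_id)]
collapsed <- flag_outliers(collapsed, groups)
qc <- qc_filter(collapsed, ct_max = 34, max_missing_fraction = 0.5)
cat(sprintf("QC: dropped %d of %d miRNAs\n", length(qc$report$dropped),
            nrow(ct$values)))

expr <- global_normalize(impute_missing(qc$ct, cohort))
ranking <- normfinder_stability(expr, groups)
expr$reference_set <- select_references(ranking, 5L)
cat("reference miRNAs:", paste(expr$reference_set, collapse = ", "), "\n")

tests <- stratified_ttests(expr, cohort)
rule <- discovery_selection_rule(tests$p_hormone, tests$p_nonhormone)
selection <- cbind(tests, rule)
selected <- selection$mirna_id[selection$included]
cat(sprintf("candidates: %d (%d by a p<0.005 stratum, %d by both strata p<=0.05)\n",
            length(selected),
            sum(rule$inclusion_reason == "either_stratum_p005"),
            sum(rule$inclusion_reason == "both_strata_p05")))

panel <- assemble_panel(selected,
                        literature_additions = sprintf("miR-lit-%02d", 1:8),
                        positive_controls = sprintf("posctrl-%02d", 1:3),
                        negative_controls = sprintf("negctrl-%02d", 1:3))
cat(sprintf("replication panel: %d probes\n", nrow(panel)))

write.table(selection, "results/discovery_selection.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(panel, "results/panel.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
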