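#!/usr/bin/env Rscript
# Stage 3 -- replication-phase preprocessing and feature selection: simulate
# the bead-array readout for the assembled panel, split 2:1, log10-transform
# (negatives shifted to 0.001), run the univariate screen with Holm-Sidak
# correction, check PCA separation, and select features by CFS with the
# hormone covariate forced in.

suppressPackageStartupMessages(library(endomiR))

cohort <- read_sample_sheet("results/data/replication_samples.csv",
                            phase = "replication")
panel <- read.delim("results/panel.tsv", stringsAsFactors = FALSE)
meta <- jsonlite::fromJSON("results/data/truth.json")
truth <- simulation_truth(
  effects = effect_spec(meta$truth$effects$mirna_id,
                        meta$truth$effects$stratum,
                        meta$truth$effects$log2_effect),
  reference_mirnas = meta$truth$reference_mirnas)

set.seed(meta$seed)
seeds <- sample.int(2^31 - 2, 4)

cohort <- stratified_split(cohort, 2 / 3, c("group", "hormone_use"),
                           seed = seeds[1])
mfi <- simulate_mfi_matrix(cohort, truth, panel$probe_id,
                           background_probes =
                             panel$probe_id[panel$category == "negative_control"],
                           seed = meta$mfi_seed)
write_expr_tsv(mfi, "results/data/replication_mfi.tsv")
write_sample_sheet(cohort, "results/data/replication_samples_split.csv")

features <- preprocess_mfi(mfi, cohort)
uni <- univariate_tests(features, training_only = TRUE)
cat(sprintf("univariate screen (training): %d of %d probes at raw p<0.05, %d after Holm-Sidak\n",
            sum(uni$p_raw < 0.05, na.rm = TRUE), nrow(uni),
            sum(uni$p_adj < 0.05, na.rm = TRUE)))

pca <- pca_separation(features)
cat(sprintf("PCA: PC1 AUC %.2f, 2-means agreement %.2f (chance ~ 0.5)\n",
            pca$pc1_auc, pca$cluster_agreement))

candidates <- uni$probe_id[uni$probe_id %in%
                             panel$probe_id[panel$category %in%
                                              c("discovery", "literature")] &
                             !is.na(uni$p_raw) & uni$p_raw <= 0.15]
fs <- cfs_select(features, candidates, forced = "hormone_use", folds = 10L,
                 seed = seeds[2])
cat(sprintf("CFS: %d candidates passed the p<=0.15 gate; selected %s\n",
            length(candidates),
            paste(fs$selected, collapse = ", ")))

write.table(uni, "results/replication_univariate.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(selected = fs$selected, forced = fs$forced,
                          fold_frequency = fs$fold_frequency,
                          per_fold = fs$per_fold,
                          cfs_seed = seeds[2], ensemble_seed = seeds[3]),
                     "results/feature_set.json", auto_unbox = TRUE,
                     digits = NA)
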