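#!/usr/bin/env Rscript
# Stage 5 -- evaluation: ROC with Hanley-McNeil inference against chance on
# the testing split, confusion matrices at the 0.5 cutoff with exact binomial
# intervals, and recovery of the planted simulation truth.

suppressPackageStartupMessages(library(endomiR))

cohort <- read_sample_sheet("results/data/replication_samples_split.csv",
                            phase = "replication")
mfi <- read_expr_tsv("results/data/replication_mfi.tsv", type = "mfi")
fs <- jsonlite::fromJSON("results/feature_set.json")
model <- mlp_from_json("results/final_model.json")
meta <- jsonlite::fromJSON("results/data/truth.json")

features <- preprocess_mfi(mfi, cohort)
df <- as.data.frame(features)
x <- as.matrix(df[, c(fs$selected, fs$forced), drop = FALSE])
storage.mode(x) <- "double"
y <- as.integer(df$group == "case")
tr <- df$split == "train"

prob_tr <- predict_proba(model, x[tr, , drop = FALSE])
prob_te <- predict_proba(model, x[!tr, , drop = FALSE])

roc <- roc_report(prob_te[y[!tr] == 1], prob_te[y[!tr] == 0])
cat("testing set: "); print(roc)
conf_tr <- confusion_at_threshold(prob_tr, y[tr])
conf_te <- confusion_at_threshold(prob_te, y[!tr])
cat("training confusion: "); print(conf_tr)
cat("testing confusion:  "); print(conf_te)

planted <- effect_spec(meta$truth$effects$mirna_id,
                       meta$truth$effects$stratum,
                       meta$truth$effects$log2_effect)
rec <- recovery_report(fs$selected, planted)
cat(sprintf("planted-effect recovery through discovery + CFS: %.0f%% (%d false)\n",
            100 * rec$recall, rec$n_false))

write.table(roc$points, "results/roc_points_test.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
jsonlite::write_json(
  list(test_auc = roc$auc, se = roc$se, z = roc$z, p = roc$p_two_sided,
       ci = roc$ci,
       confusion_train = unclass(conf_tr), confusion_test = unclass(conf_te),
       recovery = rec),
  "results/evaluation.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/evaluation.json\n")
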