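#!/usr/bin/env Rscript
# Stage 4 -- model construction: sweep random single-hidden-layer perceptron
# architectures (hidden size n/3 .. 1.5n, four activation families), train
# each by BFGS on the training split, keep the 50 best by training AUC and
# pick the final model on the testing split. Pass the network count as the
# first argument (default 2000; the study-scale sweep is 15000).

suppressPackageStartupMessages(library(endomiR))

args <- commandArgs(trailingOnly = TRUE)
n_networks <- if (length(args)) as.integer(args[1]) else 2000L

cohort <- read_sample_sheet("results/data/replication_samples_split.csv",
                            phase = "replication")
mfi <- read_expr_tsv("results/data/replication_mfi.tsv", type = "mfi")
fs <- jsonlite::fromJSON("results/feature_set.json")

features <- preprocess_mfi(mfi, cohort)
df <- as.data.frame(features)
cols <- c(fs$selected, fs$forced)
x <- as.matrix(df[, cols, drop = FALSE])
storage.mode(x) <- "double"
y <- as.integer(df$group == "case")
tr <- df$split == "train"

cat(sprintf("training %d networks on %d features x %d training samples\n",
            n_networks, ncol(x), sum(tr)))
ens <- ensemble_search(x[tr, , drop = FALSE], y[tr],
                       n_networks = n_networks, top_k = 50L,
                       seed = fs$ensemble_seed)
cat(sprintf("best training AUC %.3f (%d failed networks)\n",
            max(ens$manifest$train_auc, na.rm = TRUE), ens$n_failed))

final <- select_final(ens, x[!tr, , drop = FALSE], y[!tr])
cat(sprintf("final model: network %d (%s, %d hidden), testing AUC %.3f\n",
            final$network,
            final$model$architecture$hidden_activation,
            final$model$architecture$n_hidden, final$test_auc))

write.table(cbind(utils::head(ens$manifest, 50),
                  test_auc = final$candidates$test_auc),
            "results/ensemble_manifest.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
mlp_to_json(final$model, "results/final_model.json")
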