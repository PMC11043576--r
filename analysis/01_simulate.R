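#!/usr/bin/env Rscript
# Stage 1 -- simulate the study: a discovery qPCR cohort (10 cases, 10
# controls, 754 miRNAs in technical duplicate) and a replication bead-array
# cohort (54 cases, 108 controls) with five planted hormone-stratum-specific
# effects. Writes the sample sheets, expression matrices and ground truth
# under results/data/.

suppressPackageStartupMessages(library(endomiR))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20260927L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

truth <- simulation_truth()   # default: 5 planted effects, |log2 FC| = 1
set.seed(seed)
seeds <- sample.int(2^31 - 2, 4)

disc <- simulate_cohort(10L, 1L, hormone_fraction = 0.5,
                        age_range = c(15L, 19L), seed = seeds[1],
                        phase = "discovery")
ct <- simulate_ct_matrix(disc, truth, n_mirnas = 754L, seed = seeds[2])

repl <- simulate_cohort(54L, 2L, hormone_fraction = 0.78,
                        age_range = c(13L, 25L), seed = seeds[3])

write_sample_sheet(disc, "results/data/discovery_samples.csv")
write_sample_sheet(repl, "results/data/replication_samples.csv")
write_expr_tsv(ct, "results/data/discovery_ct.tsv")
jsonlite::write_json(list(truth = unclass(truth), seed = seed,
                          mfi_seed = seeds[4]),
                     "results/data/truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d discovery samples x %d miRNAs and %d replication samples\n",
            nrow(disc), nrow(ct$values), nrow(repl)))
cat(sprintf("planted effects: %s\n",
            paste(truth$effects$mirna_id, collapse = ", ")))
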