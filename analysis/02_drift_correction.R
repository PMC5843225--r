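#!/usr/bin/env Rscript
# Step 2 — Why the drift correction matters.
#
# Serial-founder drift makes neighbouring populations' allele
# frequencies correlated, and migratory distance is by construction
# monotone along the founder chain, so a naive regression finds
# spurious clines. This simulation measures the type-I error of the
# no-cline world with and without the drift structure in the GLS.

suppressPackageStartupMessages(library(ooadrift))
dir.create("results", showWarnings = FALSE)

n_rep <- 200
rej <- data.frame(replicate = seq_len(n_rep), identity = NA, true_R = NA)
for (r in seq_len(n_rep)) {
  s <- simulate_drift_frequencies(beta_true = 0, seed = 1000 + r)
  rej$identity[r] <- fit_cline_model(s$table, "m1")$p_value[2] < 0.05
  rej$true_R[r] <-
    fit_cline_model(s$table, "m1", R = s$R_true)$p_value[2] < 0.05
}
summary_tab <- data.frame(
  correlation = c("identity (no adjustment)", "true drift structure"),
  rejection_rate = c(mean(rej$identity), mean(rej$true_R)),
  n_replicates = n_rep)
print(summary_tab, row.names = FALSE)
write.table(summary_tab, "results/drift_typeI.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nAt nominal alpha = 0.05, ignoring drift rejects %.0f%% of\n",
            100 * mean(rej$identity)))
cat(sprintf("pure-drift replicates; the drift-aware GLS rejects %.1f%%.\n",
            100 * mean(rej$true_R)))
cat("This mirrors the attenuation from the unadjusted to the adjusted\n")
cat("column of the published association table. Written to\n")
cat("results/drift_typeI.tsv\n")
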