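#!/usr/bin/env Rscript
# Step 4: isoform-level PSI and differential splicing between the crosses.
#
# Computes percent spliced-in per isoform and sample from the quant.sf-style
# tables, the average PSI difference between the two cross directions, an
# abundance-binned empirical p-value per isoform, and the differential
# splicing calls (|dPSI| > 0.1, FDR < 0.05); finishes with the
# Kolmogorov-Smirnov comparison of the pooled PSI distributions.

suppressPackageStartupMessages(library(reciprocross))

simdir <- "results/simdata"
truth <- readr::read_tsv(file.path(simdir, "truth_isoforms.tsv"),
                         show_col_types = FALSE)
quant_files <- list.files(simdir, pattern = "^quant_.*\\.sf$", full.names = TRUE)
quant <- dplyr::bind_rows(lapply(quant_files, function(f) {
  read_transcript_quant(f, file.path(simdir, "tx2gene.tsv"),
                        sub("^quant_(.*)\\.sf$", "\\1", basename(f)))
}))
crosses <- unique(sub("_r[0-9]+$", "", quant$sample_id))

psi <- psi_per_isoform(quant, floor = 1)
readr::write_tsv(psi, "results/psi.tsv")
g1 <- psi[startsWith(psi$sample_id, crosses[1]), ]
g2 <- psi[startsWith(psi$sample_id, crosses[2]), ]

n_alt <- sum(alternative_flag(psi$psi), na.rm = TRUE)
cat(sprintf("PSI computed for %d isoforms x %d samples; %d records in the alternative band [0.05, 0.95]\n",
            length(unique(psi$isoform_id)), length(unique(psi$sample_id)),
            n_alt))

sig <- empirical_significance(g1, g2, n_null = 1000, seed = 11)
das <- das_call(sig, dpsi_threshold = 0.1, fdr = 0.05)
readr::write_tsv(das, "results/das_calls.tsv")
updown <- das_summary(das)
cat(sprintf("Differential splicing %s vs %s: %d significant isoforms (%s)\n",
            crosses[2], crosses[1], sum(das$significant),
            paste(sprintf("%s %d", updown$direction, updown$n), collapse = ", ")))

m <- match(das$isoform_id, truth$isoform_id)
sens <- mean(das$significant[truth$is_target[m]], na.rm = TRUE)
fpr <- mean(das$significant[truth$planted_delta[m] == 0], na.rm = TRUE)
cat(sprintf("  planted-shift recovery %.0f%%; false positives %.2f%%\n",
            100 * sens, 100 * fpr))

ks <- psi_distribution_compare(g1, g2)
cat(sprintf("KS comparison of pooled PSI distributions: D = %.4f, p = %.3g\n",
            ks$D, ks$p_value))
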