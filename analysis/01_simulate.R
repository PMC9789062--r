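#!/usr/bin/env Rscript
# Step 1: generate the synthetic study tables.
#
# Emulates a reciprocal interploidy cross pair (hexaploid mother x tetraploid
# father, and its reciprocal) with two biological replicates: a triad
# expression matrix with planted bias categories, allele-specific counts
# for one embryo stage (E3) and one endosperm stage (E8) with planted MEGs
# and PEGs, and isoform quantifications with planted PSI shifts. All tables
# land in results/simdata/ in the package's TSV dialects, alongside
# truth_*.tsv ground-truth tables used by the downstream steps.

suppressPackageStartupMessages(library(reciprocross))

outdir <- "results/simdata"
cfg <- simulation_config(seed = 20260924L, stages = c("E3", "E8"))
sim <- simulate_all_tables(cfg, outdir)

cat("Simulated study tables written to", outdir, "\n")
cat(sprintf("  triads:   %d (categories: %s)\n", cfg$n_triads,
            paste(names(cfg$category_proportions), collapse = ", ")))
cat(sprintf("  samples:  %d (%s x %s x %d replicates)\n",
            nrow(sim$triads$expr$meta),
            paste(cfg$cross_pair, collapse = "/"),
            paste(cfg$stages, collapse = "/"), cfg$n_replicates))
cat(sprintf("  ASE genes: %d (%d planted MEGs, %d planted PEGs at strength %.2f)\n",
            cfg$n_genes_ase, sum(sim$allele$truth$status == "MEG"),
            sum(sim$allele$truth$status == "PEG"), cfg$imprint_strength))
cat(sprintf("  isoforms: %d (%d with a planted PSI shift of %.1f)\n",
            nrow(sim$isoforms$truth), sum(sim$isoforms$truth$is_target),
            cfg$delta_psi_planted))
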