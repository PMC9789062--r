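# reciprocross

Transcriptome analysis of grain development in reciprocal crosses between
tetraploid (AABB) and hexaploid (AABBDD) wheats. Crossing the two species in
both directions yields genetically identical pentaploid (AABBD) embryos whose
endosperm differs in D-genome dosage, which makes the cross pair a natural
experiment for three questions this package answers from expression tables
alone:

1. **Homoeolog expression bias** — within each 1:1:1 A/B/D gene triad, which
   subgenome carries the expression, and how does a triad's bias category
   shift between the two cross directions?
2. **Genomic imprinting** — which genes are expressed predominantly from the
   maternal (MEG) or paternal (PEG) allele, once the parental genome dosage
   of the tissue is accounted for?
3. **Differential alternative splicing** — which transcript isoforms change
   their inclusion level (PSI) between the reciprocal crosses?

The package is organised as an analysis workflow: every computation lives in
exported functions, and the numbered scripts under `analysis/` run the
pipeline end to end on synthetic data with planted ground truth, so no
sequencing data is required.

## Methods at a glance

**Triad bias.** For a triad with homoeolog TPMs
(x_A, x_B, x_D), the composition f = x / sum(x) lives on the 2-simplex. Each
triad is assigned to the bias category whose centroid minimises the
Euclidean distance ||f − c||: Balanced (1/3, 1/3, 1/3), A/B/D dominant
((1,0,0) etc.), and A/B/D suppressed ((0, 1/2, 1/2) etc.). Ties resolve to
the earliest category in that canonical order. Triads with total TPM below a
floor (default 0.5) are undefined. Category switches between samples are
cross-tabulated over triads defined in both.

**Imprinting.** Replicates are pooled within each cross direction. For a
gene with m maternal and p paternal SNP-informative reads, the maternal
fraction m/(m+p) is tested against the dosage expectation E[m/(m+p)] = 1/2
in embryo (1m:1p genomes) and 2/3 in endosperm (2m:1p) with a one-degree
Pearson chi-square goodness-of-fit test; p-values are Benjamini–Hochberg
adjusted over all (gene × direction) tests. A gene is a MEG when both
directions have q < 0.01 and maternal fraction ≥ 0.7 (embryo) / 0.85
(endosperm); a PEG when both paternal fractions reach 0.7 (embryo) / 0.6
(endosperm). Genes with fewer than 10 reads in either direction are
`insufficient_data`.

**Splicing.** PSI of an isoform is its TPM share of the gene's summed
isoform TPM (undefined below 1 gene TPM). ΔPSI is the difference of group
mean PSI. Significance is empirical: within-group between-replicate |ΔPSI|
values, pooled in three log10-abundance bins, form the null; the p-value is
the add-one-smoothed fraction of 1000 null draws reaching the observed
|ΔPSI|. Calls require |ΔPSI| > 0.1 and BH FDR < 0.05. PSI distributions of
two groups are compared with the two-sample Kolmogorov–Smirnov test, and an
isoform is "alternative" when 0.05 ≤ PSI ≤ 0.95.

**Synthetic data.** `simulation_config()` + `simulate_triads()` /
`simulate_allele_counts()` / `simulate_isoform_quants()` generate all input
tables with planted truth: negative-binomial triad counts (variance
μ + 0.05 μ²) around category centroids, Poisson/binomial allele counts at
the tissue dosage with planted MEGs/PEGs, and Dirichlet-based isoform PSIs
with planted shifts — two biological replicates per sample by default.

## Worked example

```r
library(reciprocross)

# A triad expressing 72/18/10 percent from A/B/D is A-dominant:
classify_triad(c(0.72, 0.18, 0.10))
#> [1] "A_dominant"

# Imprinting calls on a simulated endosperm stage with 20 planted MEGs
# and 10 planted PEGs among 1000 genes:
cfg <- simulation_config(seed = 42, n_genes_ase = 1000, frac_meg = 0.02,
                         frac_peg = 0.01, stages = "E8")
sim <- simulate_allele_counts(cfg)
calls <- call_imprinted(sim$counts, "E8", "endosperm", cfg$cross_pair)
table(calls$status)
#>           MEG not_imprinted           PEG
#>            20           970            10

subset(calls, status == "MEG")[1:3, c("gene_id", "maternal_fraction_forward",
                                      "maternal_fraction_reverse", "q")]
#>   gene_id   maternal_fraction_forward maternal_fraction_reverse        q
#> 1 aseg00010                     0.977                     0.973 2.18e-16
#> 2 aseg00040                     0.956                     0.943 1.20e-14
#> 3 aseg00071                     0.947                     0.985 7.97e-16
```

All 30 planted imprinted genes are recovered, none of the 970 unimprinted
genes is called, and the recovered maternal fractions sit near the planted
imprint strength of 0.95 in **both** cross directions — the reciprocal
concordance that separates imprinting from genotype effects.

The full workflow runs as:

```sh
Rscript analysis/01_simulate.R     # synthetic study tables -> results/simdata/
Rscript analysis/02_triad_bias.R   # bias categories, transitions, contributions
Rscript analysis/03_imprinting.R   # MEG/PEG calls per stage
Rscript analysis/04_splicing.R     # PSI, differential splicing, KS comparison
```

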