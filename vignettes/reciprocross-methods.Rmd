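---
title: "Models and design decisions behind reciprocross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions behind reciprocross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciprocross)
```

# Scope

reciprocross analyses transcriptomes of developing grain from reciprocal
crosses between tetraploid (AABB) and hexaploid (AABBDD) wheat. It starts
from quantified expression tables — gene-level TPM, per-gene maternal and
paternal allele counts, and transcript-level quantifications — and stops at
three kinds of biological calls: homoeolog-triad expression-bias categories,
maternally/paternally expressed genes (MEGs/PEGs), and differential isoform
splicing. Read processing, alignment, SNP calling and transcript assembly
are upstream of this package and out of its scope.

# Triad bias classification

## Model

A homoeolog triad is a 1:1:1 set of genes on the A, B and D subgenomes. Its
expression state in a sample is summarised by the composition
$f = (x_A, x_B, x_D) / (x_A + x_B + x_D)$ of the three homoeolog TPMs, a
point on the 2-simplex. Seven idealised states serve as centroids: balanced
$(1/3, 1/3, 1/3)$; A, B or D dominant (all expression from one subgenome);
and A, B or D suppressed (the named subgenome silent, the other two equal).
A triad is assigned to the category whose centroid is nearest in Euclidean
distance. For tetraploid crosses, which lack the D genome, a two-genome
centroid set is used: balanced $(1/2, 1/2)$, A dominant $(1, 0)$, B dominant
$(0, 1)$.

The centroid geometry partitions the simplex into seven cells, so the
classifier is equivalent to a fixed Voronoi tessellation; no training is
involved. The assumption worth stating is that *relative* expression within
a triad is comparable across samples — which holds for within-sample
normalised units such as TPM, and is why the package never classifies raw
counts.

## Numerical choices

* The balanced centroid uses exact thirds. The commonly printed rounded form
  $(0.33, 0.33, 0.33)$ does not sum to one and sits off the simplex; the
  difference moves no decision boundary by more than ~0.006, but exactness
  costs nothing.
* Compositions must sum to 1 within $10^{-6}$; anything else is a validation
  error rather than a silent renormalisation, since it indicates an upstream
  bug.
* Exact distance ties are geometrically possible (e.g. $(0.75, 0.25, 0)$ is
  equidistant to A dominant and D suppressed, and grid points such as
  $(0.23, 0.04, 0.73)$ tie D dominant with B suppressed). Ties are detected
  with a tolerance of $10^{-9}$ on squared distance and resolved to the
  earliest category in the canonical order (balanced, then dominants, then
  suppressed), so results do not depend on floating-point summation order.
* A triad whose total TPM falls below a floor (default 0.5 TPM) is
  *undefined* in that sample: the composition of a silent triad is dominated
  by noise. The floor is a free parameter (`floor` in `triad_fractions()`);
  0.5 total TPM was chosen as half of the conventional 1-TPM expressed-gene
  threshold, since triad totals pool three genes.
* Replicate fractions are averaged *as compositions* before classification
  (`average_replicate_fractions()`), the mean of points on the simplex being
  itself on the simplex. Per-replicate classification remains available by
  classifying the un-averaged fractions; averaging first was preferred as
  the default because category calls near a boundary otherwise flip between
  replicates with no biological meaning.

Category transitions between two samples (typically the two directions of a
reciprocal cross) are counted only over triads defined in both samples;
triads undefined in either are tallied separately rather than forced into a
pseudo-category.

# Imprinting calls

## Model

In the embryo each parent contributes one genome copy, so an unimprinted
gene is expected to show a maternal read fraction of $1/2$; the triploid
endosperm carries two maternal and one paternal copy, shifting the
expectation to $2/3$. Observed maternal/paternal allele counts $(m, p)$ are
tested against this dosage expectation with a one-degree-of-freedom Pearson
goodness-of-fit statistic on the two cells $(m, p)$ versus
$((m+p)f, (m+p)(1-f))$. No continuity correction is applied by default (the
`continuity_correction` flag exists); with the 10-read minimum below, cell
expectations are large enough that the uncorrected statistic is the
standard choice.

A gene is called imprinted only when **both** cross directions agree: the
parental bias must follow the parent-of-origin role, not the genotype —
otherwise strain-specific cis effects masquerade as imprinting. Calls
require, in both directions, a BH-adjusted chi-square q-value below 0.01
and a read-fraction beyond the tissue threshold: maternal fraction ≥ 0.7
(embryo MEG), ≥ 0.85 (endosperm MEG), paternal fraction ≥ 0.7 (embryo PEG),
≥ 0.6 (endosperm PEG). The endosperm thresholds are asymmetric because the
2:1 dosage already places unimprinted genes at 2/3 maternal; 0.85 maternal
demands bias beyond dosage, while 0.6 paternal is far below the dosage
expectation of 1/3 paternal. The embryo thresholds are symmetric because
the dosage is.

## Decisions a reader should know about

* **Replicates are pooled** within each cross direction before testing.
  Requiring both replicates' support is read as pooling their evidence; a
  stricter mode (`require_each_replicate = TRUE`) additionally demands that
  every replicate individually clear the fraction threshold. Pooling makes
  calls invariant to how reads are split across replicates, which is tested
  as a property.
* **The BH family** is all (gene × direction) tests within one stage and
  tissue. Correcting each direction separately, or pooling stages, are
  defensible alternatives; the per-stage, both-directions family was chosen
  because the two directions are part of one decision per gene and stage.
* **Genes below 10 pooled reads in either direction** are reported as
  `insufficient_data`, never silently dropped, so downstream tallies can
  distinguish "not imprinted" from "not testable".
* **Endosperm expectation is 2/3 for every gene**, including D-subgenome
  genes in pentaploid endosperm whose true dosage differs between the cross
  directions (AAABBBDD vs AAABBBD). A single reference line matching the
  bulk of the genome was preferred over per-gene dosage bookkeeping; for
  D-genome genes in interploidy endosperm the test is therefore
  approximate, a documented caveat rather than a hidden one.
* Fractions of exactly 0 or 1 at high depth are legal and intended: complete
  uniparental expression is the textbook imprinting signal, not a special
  case.

# Differential splicing

## Model

PSI (percent spliced-in) of an isoform in a sample is its TPM divided by the
summed TPM of its gene's isoforms; PSI is undefined when the gene total
falls below 1 TPM (the conventional expressed-gene floor — inclusion ratios
of unexpressed genes are noise). ΔPSI between two sample groups is the
difference of group mean PSIs over defined values. An isoform is
*alternative* when $0.05 \le PSI \le 0.95$, boundaries included.

Significance is empirical rather than parametric, in the spirit of
transcript-quantification splicing tools: the distribution of |ΔPSI| under
no change is estimated from between-replicate, within-group PSI
differences — the natural measurement-noise scale — pooled across isoforms
within three log10 gene-TPM abundance bins (quantification noise shrinks
with abundance, so pooling across all abundances would be anticonservative
for highly expressed genes). Each isoform's p-value is the add-one-smoothed
exceedance fraction of `n_null = 1000` draws from its bin's pool:
$p = (1 + \#\{d_{null} \ge |\Delta PSI|\}) / (n_{null} + 1)$. Because the
within-group replicate difference has variance at least as large as the
between-group difference of replicate means under the null, these p-values
are conservative, which the test suite asserts on null simulations. Calls
require $|\Delta PSI| > 0.1$ (strict) and BH FDR < 0.05.

With a single replicate per group the empirical null is undefined and the
function refuses to guess; this is an error by design.

# The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, plus planted ground truth, so that recovery is measurable:

* **Triads** — a category per triad from configurable proportions, total
  expression from a Gamma distribution (shape 2, default mean 300 TPM per
  triad), homoeolog means at the category centroid, negative-binomial counts
  (variance $\mu + \alpha\mu^2$, default $\alpha = 0.05$, typical bulk
  RNA-seq overdispersion) converted to TPM. The default category mixture —
  50% balanced, 28% D suppressed, the rest spread over the other
  categories — imitates a pentaploid embryo with its univalent, suppressed D
  genome; its closed-form mixture mean puts the A and B subgenomes near 40%
  and D near 20% of triad expression, which the tests verify against the
  simulated contributions.
* **Allele counts** — per gene, direction and replicate, total reads are
  Poisson (default mean 100) and maternal reads binomial with maternal
  probability 0.5 (embryo) or 2/3 (endosperm) for unimprinted genes, and
  `imprint_strength` (default 0.95) or its complement for planted MEGs and
  PEGs. The probability is defined relative to the maternal *role*, so a
  planted MEG is maternal-biased in both cross directions, exactly the
  concordance the caller requires.
* **Isoforms** — genes of 2–4 isoforms with baseline PSI from a symmetric
  Dirichlet (concentration 1.5); planted shifts of `delta_psi_planted`
  (default 0.3) are applied upward when there is headroom and downward
  otherwise (for shifts ≤ 0.5 one direction always fits, so no clipping
  occurs), with the gene's other isoforms renormalised and their induced
  shifts recorded in the truth table too. Replicate TPMs get multiplicative
  lognormal noise (sdlog 0.15).

Each sub-simulation seeds its own stream (config seed plus a fixed offset:
+101 triads, +202 allele counts, +303 isoforms), so running one simulator
never perturbs another — a determinism property the tests check.

Two biological replicates per sample is the default throughout, matching the
design of the reciprocal-cross experiments this emulates.

**What the generator does not emulate.** Stages are exchangeable — no
developmental trajectory links E1 to E7; there is no differential gene
expression between crosses, no correlation between a triad's bias and its
expression level, no mapping bias or reference bias in allele counts, no
SNP-density variation between genes, and isoform noise is independent
across isoforms rather than negatively correlated within a gene. Passing
recovery tests on these simulations therefore demonstrates that the
*inference machinery* is correct and calibrated under its own assumptions,
not that real tissue data will be as clean; on real data, mapping bias and
maternal RNA carry-over in early embryos are the first things to worry
about.

# Problem sizes and runtime

The test suite and the acceptance script run the simulations at the sizes
the recovery properties are stated for: 2,000 triads, 5,000
allele-specific genes at 100× depth per direction, 2,000 isoforms with 100
planted shifts, 1,000 null draws per isoform, and a 5,151-point simplex
grid for the classifier oracle. These sizes keep the whole suite under a
minute on a single CPU while leaving the Monte-Carlo margins of the
recovery thresholds (≥ 90% triad recovery, ≤ 1% imprinting false calls,
≥ 80% splicing sensitivity) wide.

# Known limitations

* The nearest-centroid categories are hard assignments; triads near cell
  boundaries carry no uncertainty measure. A distance-to-second-best margin
  could be added without changing the interface.
* The chi-square test treats allele counts as binomial given the total;
  overdispersion between replicates (common in allele-specific data) is not
  modelled. Pooling replicates partially hides this; the
  `require_each_replicate` mode is the pragmatic guard.
* The empirical splicing null draws with replacement from a finite pool of
  within-group differences; with two replicates per group the pool has one
  difference per isoform per group, so per-bin pools must span many isoforms
  to be smooth. Fewer than ~100 isoforms per bin makes the p-values coarse.
* Endosperm D-genome dosage in interploidy crosses is approximated by the
  genome-wide 2:1 expectation, as discussed above.
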