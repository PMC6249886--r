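---
title: "Methods: calling cis lncRNA-PCG pairs and screening their interactions"
author: "lncpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling cis lncRNA-PCG pairs and screening their interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpair)
```

## The analysis

Long non-coding RNAs are frequently transcribed from the immediate
neighborhood of protein-coding genes, and when a lncRNA and its neighbor
respond to the same perturbation in the same direction, the parsimonious
reading is shared transcriptional machinery acting in *cis*. `lncpair`
formalizes a tissue-level version of that argument for a two-condition
design (conventional vs germ-free mice, here called the CV and GF
*enterotypes*, with organs as strata): filter genes by expression and
differential regulation, relate lncRNA loci to coding-gene structure,
call proximity pairs, tally co-regulation directions, and screen the
paired transcripts for direct hybridization potential.

This vignette records the model choices, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
conventions — the things a maintainer would otherwise have to reverse
engineer from the code.

## Thresholds and the differential test

Two filters define the analysis population per organ:

* **expressed**: mean FPKM over the CV replicates or over the GF
  replicates strictly above 1. The mean is the plain arithmetic mean over
  all replicates, zeros included.
* **differentially regulated**: expressed, and Benjamini–Hochberg
  q-value strictly below 0.05. Both inequalities are strict because the
  thresholds are phrased as "above 1" and "< 0.05"; the boundary cases
  (`mean == 1`, `q == 0.05`) fail the filters, and tests pin this down.

BH adjustment is applied per organ and per gene class — the lncRNA set
and the PCG set separately — mirroring differential runs against separate
reference annotations. The step-up definition
(`q_(i) = min_{j>=i} p_(j) * m / j`, capped at 1) is implemented directly
and cross-checked in the test suite against both a brute-force evaluation
of that definition and `stats::p.adjust`.

When no precomputed differential table is available, `fallback_de_test()`
tests `log2(FPKM + 0.01)` between enterotypes. The pseudocount (default
0.01, configurable) keeps zeros finite and barely perturbs expressed
genes, and the reported effect size is always
`log2((mean_GF + eps) / (mean_CV + eps))`. The test statistic is a
**moderated t** (limma): with three replicates per group a per-gene
variance estimate has four degrees of freedom, and a power analysis of
the per-gene Welch test under the generator's own noise model showed it
cannot reliably recover effects near |log2FC| = 1 after FDR control —
its per-gene sensitivity plateaus well below what end-to-end pair
recovery requires, because a pair needs *both* members to survive the
filter. Shrinking gene-wise variances toward a common prior is the
standard remedy in this field (count-based tools pool dispersion across
genes for the same reason) and restores near-complete power at the
planted effect sizes while keeping the null calibrated; the test suite
verifies a type-I error within [0.03, 0.07] at p < 0.05 on a 5,000-gene
null cohort.

Degenerate inputs are reachable on synthetic data and handled
deterministically: if both groups have zero variance, p = 1 when the
group means are equal and the smallest representable positive double when
they differ. Genes failing the expression filter are never tested
(p and q are `NA`), so the FDR denominator is the organ's expressed set.

## Gene models and coordinates

All coordinates are 0-based half-open internally; GTF's 1-based closed
convention exists only at the I/O boundary (`to_zero_based()` /
`to_one_based()` are exact inverses). Multi-isoform genes collapse to the
exon union with the widest span, because pairing and FPKM operate at gene
level; adjacent exons (gap 0) merge, a gap of one base is an intron. UTRs
come from explicit UTR features when present, otherwise they are derived
from the CDS extent strand-aware (exonic sequence 5′ of the 5′-most CDS
base is 5′UTR, and symmetrically). Non-coding dialects without CDS simply
produce non-coding models. TSS/TTS windows are computed per collapsed
gene, not per transcript.

The overlap index wraps an IRanges interval query; the strand-aware
window extension (upstream bases 5′ of the TSS, downstream bases 3′ of
the TTS) is applied to the gene spans at query time. The test suite holds
the index to exact set equality with an independent linear scan on
randomized genomes.

## Region classification

Each lncRNA receives exactly one class relative to the coding genes:
`upstream`, `five_prime_utr`, `exonic`, `intronic`, `three_prime_utr`,
`downstream`, or `intergenic`. The classification anchor is the locus
**midpoint** (integer floor). A single anchor point guarantees a single
class; the midpoint is stable for long loci, and a 5′-end anchor is
available as an option. Candidates are the genes whose span or extended
window (defaults 5 kb upstream, 1 kb downstream) contains the anchor; the
nearest candidate wins, with distance measured from the anchor to the
gene span and ties broken by lexicographic gene id so output is
deterministic and insertion-order independent. Inside a gene body the
feature precedence is 5′UTR > 3′UTR > exonic > intronic, matching
annotation tools that report UTRs separately from "exonic". Classification
is validated against a per-definition brute-force oracle on ≥ 1,000
randomized loci across five seeds.

## Pair calling

Pairing deliberately uses a *different* geometric rule than
classification: criterion 1 is interval overlap between the lncRNA locus
and the PCG's extended interval [TSS − 5 kb, TTS + 1 kb], at least one
base, where "coding region" is read as the whole gene span rather than
the CDS — the motivating examples include intron- and 3′UTR-resident
lncRNAs. Overlap is the more inclusive rule and admits many-to-many
pairings (one PCG may pair with several lncRNAs and vice versa); no
strand filter is applied, since co-regulated pairs occur on both same and
opposite strands. Criteria 2 and 3 are the expression and differential
filters above, evaluated per organ for both members.

The direction category is a deterministic function of the two signs
(positive log2FC = higher in GF = up-regulated by absence of the
microbiome), and per-organ summaries always satisfy
`total = both_up + both_down + discordant counts` — an arithmetic
invariant the tests assert on random inputs and the acceptance suite
verifies against the published per-organ tallies.

## Tissue overlaps

`venn_partition()` assigns every id in the union its exact membership
signature over up to eight tissue sets, so "commonly expressed" is the
full-intersection signature and "uniquely expressed in T" the singleton.
Ids are compared as exact strings after whitespace trimming; version
suffixes are significant and never normalized. The partition is
permutation-invariant and reconstructs every input set size, both checked
property-style.

## The interaction screen

The hybridization model is a deliberately simple stacked-pair scheme, not
a nearest-neighbor thermodynamic table: per complementary pair G:C
contributes −3, A:U −2 and G:U (wobble) −1 kcal/mol, configurable. The
scan considers every ungapped antiparallel offset of the two sequences
and defines `dG` as the energy of the single most stable **maximal
complementary run** of length ≥ `min_run` (default 2), with no bulges or
internal loops. Summing all chance runs in an offset would make `dG` grow
linearly with sequence length for random transcripts and saturate the
binding rule, so the screen scores the best contiguous duplex segment —
the quantity the planted-window calibration and the non-binder
specificity requirement both measure. The inner scan is a short C++
kernel (an alignment-style anti-diagonal walk); the test suite holds it
to exact equality with a quadratic R scorer that enumerates every offset
and run explicitly.

`ndG` normalizes by the *shorter* transcript's length — the published
screen reports a "normalized" free energy without a formula, and
min-length normalization makes a perfect duplex of the shorter molecule
scale-free. Binding is declared at `ndG < −0.08` strictly, the lowest
recommended screening threshold; exact published `dG`/`ndG` values are
not a reproduction target (the energy model differs), only the
thresholding logic and qualitative ranking are.

## The synthetic cohort

The generator emulates the study conditions, not real genomes:

* **Design**: 8 organs, 3 replicates per enterotype, 200 coding genes and
  300 lncRNAs on 2 × 2 Mb chromosomes by default.
* **Region classes**: planted with the aggregate annotation proportions
  (intronic 0.354, intergenic 0.244, 3′UTR 0.160, exonic 0.103, upstream
  0.068, downstream 0.061, 5′UTR 0.011). The printed percentages sum to
  100.1% from rounding, so the defaults are normalized by their sum.
  Placement is rejection-sampled until the package's own classifier
  returns the planted class, making truth consistent with the pipeline's
  definitions by construction; inter-gene gaps (12–14 kb) are wide enough
  that proximity windows never overlap, and intergenic loci (capped at
  1 kb) sit entirely outside every window so they can never create pairs.
* **Expression**: FPKM = baseline × 2^(Δ·[GF]) × 2^N(0, σ_rep), with
  log-normal baselines (meanlog 1, sdlog 1; a 20% fraction drawn low to
  exercise the expression filter) and σ_rep = 0.2 on the log2 scale — the
  same scale as the planted effects Δ, whose magnitudes are
  Uniform(1, 3). Per organ, 15% of eligible neighbor pairs are planted
  differentially regulated with a common sign for both members; 1% of
  planted pairs are discordant (opposite signs), so the rare direction
  category is covered deterministically. Planted members' baselines are
  floored at 1.5 so planted pairs pass the expression filter by
  construction; a host PCG reused by two planted lncRNAs keeps one
  effect, and the lncRNAs follow its sign.
* **Sequences**: random-composition transcripts of 500–3,000 nt. Each
  planted binder receives a reverse-complement window copied from its
  mRNA into the lncRNA; the window is
  `max(50, ceil(0.06 × min(lengths)))` nt because a fixed 50-nt window
  cannot clear the `ndG < −0.08` rule once the shorter transcript exceeds
  ~1.5 kb, whereas 0.06·L of pairs at ≤ −2 kcal/mol each guarantees
  `|dG| ≥ 0.12·L` — bound with a safety factor, for any composition.
* **Determinism**: each generator seeds its own RNG stream
  (`seed`, `seed + 1`, `seed + 2` for genome, expression, sequences), so
  outputs are byte-identical across reruns and adding draws to one
  generator does not perturb the others.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: realistic transcriptome sequence
composition and repeat structure, overlapping or nested coding genes,
isoform-level variation, count-level sampling noise (FPKM noise is purely
log-normal), unbalanced designs, and batch effects. Recovery results on
the synthetic cohort demonstrate the pipeline's internal consistency, not
field performance on real references, whose headline counts additionally
depend on the actual reference databases and read data.

## Problem sizes and runtime choices

The default test and acceptance runs use cohorts of 200 + 300 genes over
8 organs, oracle-equivalence sweeps of 1,000 randomized instances per
operation across five seeds with small sequences (15–50 nt) and genomes
(25 coding genes), a 2,000-lncRNA cohort for proportion recovery, and a
5,000-gene null for calibration. These sizes keep the full suite around
three minutes on one CPU while leaving every randomized check with
comfortable statistical margin.

## Known limitations

* The classification anchor rule of the original web annotation tool is
  not recoverable; the midpoint convention here is a documented choice,
  so per-class percentages on real data may shift slightly relative to
  that tool even with identical windows.
* The duplex screen ignores secondary structure, bulges and loops; its
  energies rank complementarity, they are not physical free energies.
* The fallback differential test assumes approximately log-normal FPKM
  within groups; for strongly zero-inflated genes a count-based model
  would behave differently.
* Pair calling treats organs independently; no cross-organ borrowing of
  information is attempted.
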