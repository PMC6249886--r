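# lncpair

Tissue-level RNA-seq of conventional (CV) versus germ-free (GF) mice shows
that the gut microbiome reshapes the expression of long non-coding RNAs
(lncRNAs) alongside their neighboring protein-coding genes (PCGs),
suggesting shared transcriptional machinery acting in *cis*. `lncpair`
implements that analysis as a tested, reusable R pipeline for anyone who
has gene-level FPKM quantifications against a coding and a non-coding
reference and wants to call microbiota-responsive (or any two-condition)
lncRNA–PCG neighbor pairs.

## What it computes

Given gene models (GTF) and per-sample FPKM tables with a CV/GF design
(*n* replicates per enterotype per organ):

1. **Expression and differential filters.** A gene is *expressed* in an
   organ when its mean FPKM over either enterotype's replicates is
   strictly above 1, and *differentially regulated* when additionally its
   Benjamini–Hochberg q-value is strictly below 0.05. When no precomputed
   differential table (Cuffdiff `gene_exp.diff` dialect) is supplied, a
   moderated two-group t-test on log2(FPKM + 0.01) provides the p-values,
   with BH adjustment over the organ's expressed genes per gene class.
2. **Region annotation.** Each lncRNA is assigned one class relative to
   the nearest coding gene — upstream (≤ 5 kb 5′ of the TSS), 5′UTR,
   exonic, intronic, 3′UTR, or downstream (≤ 1 kb 3′ of the TTS) — or
   *intergenic* when its anchor lies outside every window.
3. **Pair calling.** A lncRNA–PCG pair is recorded in an organ iff
   (i) the lncRNA locus overlaps the PCG's strand-aware extended interval
   [TSS − 5 kb, TTS + 1 kb] by ≥ 1 base, and (ii)–(iii) both members are
   expressed and differentially regulated there. Pairs carry a
   co-regulation category (both up, both down, or discordant) and are
   tallied per organ.
4. **Tissue overlaps.** Exact membership-signature partitions (Venn
   counts) of expressed and differentially regulated sets across tissue
   groups.
5. **Interaction screen.** Each lncRNA–mRNA transcript pair gets a
   hybridization energy `dG` — the most stable ungapped antiparallel
   complementary run (G:C −3, A:U −2, G:U −1 kcal/mol per pair, runs of
   ≥ 2) — normalized as `ndG = dG / min(length_lnc, length_mRNA)`;
   binding is declared at `ndG < −0.08` (strict).

A synthetic-data module generates download-free cohorts with
machine-readable planted truth (region classes, differential neighbor
pairs with a rare discordant fraction, complementary sequence windows), so
the whole pipeline is exercised end-to-end without external references.

## Worked example

```r
library(lncpair)
cfg <- sim_config(seed = 42, n_pcg = 60, n_lnc = 90, n_chromosomes = 1,
                  chrom_length = 1.6e6,
                  organs = c("liver", "jejunum", "colon"), n_binders = 4)
cohort <- generate_cohort(cfg)
ann <- annotate_regions(cohort$genome$lnc_models, cohort$genome$pcg_index)
head(region_distribution(ann))
#>            region count   fraction
#> 1        upstream     9 0.10000000
#> 2  five_prime_utr     0 0.00000000
#> 3          exonic     8 0.08888889
#> 4        intronic    31 0.34444444
#> 5 three_prime_utr    18 0.20000000
#> 6      downstream     2 0.02222222

rec <- evaluate_planted_recovery(cohort, n_nonbinders = 20)
summarize_pairs(rec$pairs)
#>     organ total n_both_up n_both_down n_lnc_up_pcg_down n_lnc_down_pcg_up
#> 1   colon     6         3           3                 0                 0
#> 2 jejunum     6         1           5                 0                 0
#> 3   liver     6         4           2                 0                 0
```

The distribution mirrors the configured class proportions (intronic
placements dominate), each organ's pair total equals the sum of its
direction categories, and here all 18 planted pairs are recovered with no
false calls (sensitivity and precision 1.000). Scoring the four planted
binder transcript pairs:

```r
score_interactions(cohort$sequences$binders, cohort$sequences$lnc_seqs,
                   cohort$sequences$mrna_seqs)
#>   lncrna_transcript_id pcg_transcript_id   dG        ndG bound
#> 1            LNC0052.1         PCG0021.1 -122 -0.2440000  TRUE
#> 2            LNC0084.1         PCG0047.1 -134 -0.2100313  TRUE
#> 3            LNC0069.1         PCG0028.1 -121 -0.1964286  TRUE
#> 4            LNC0020.1         PCG0028.1 -142 -0.1569061  TRUE
```

Every planted complementary window yields a deeply negative run energy and
an `ndG` far below the −0.08 binding threshold.

`run_pipeline(pipeline_config(out_dir = "out", sim = cfg))` runs the same
stages end-to-end and writes per-organ differential tables, annotation and
pair TSVs, BED and gene-list exports, overlap counts, the interaction
table and a text report; `read_pipeline_config()` loads the equivalent
YAML description.

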