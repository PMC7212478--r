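---
title: "cloneDiverge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cloneDiverge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneDiverge)
```

This vignette is the package's own account of what it computes, which
assumptions each stage makes, and where genuinely open design choices were
resolved. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Analysis model

### Somatic SNVs and the clonal tree

Input is a table of candidate somatic variants with per-sample
strand-split variant read counts and total depth, plus variant reads in a
matched normal. A variant is *present* in a tumor sample when

* variant allele fraction (variant reads / total depth) `> min_vaf`
  (default 0.10),
* variant reads `> min_reads` (default 5), and
* at least one variant read on each strand (double-strand support;
  `per_strand_min` raises the per-strand floor for a stricter reading of
  the rule).

A variant is retained when present in at least one sample and absent (zero
variant reads) in the normal. "Mutation frequency" is interpreted as
variant reads over total site depth; the alternative reading — a per-strand
minimum of five — is available through `per_strand_min` but is not the
default.

Loss of heterozygosity can delete the mutant allele, turning a truly
inherited variant into an apparent absence and corrupting the binary coding
for the whole panel, so variants inside an LOH segment (B-allele copy
number 0) of *any* sample are masked before tree building. Per-sample
masking is available (`mask_loh(per_sample = TRUE)`) for sensitivity
analyses.

Tree reconstruction uses Wagner parsimony. On binary characters Wagner
parsimony coincides with Fitch small parsimony, and the panel is tiny, so
instead of heuristic search the package enumerates *all* unrooted binary
topologies over ingroup + outgroup (105 for five taxa; exact up to 12
ingroup taxa) and scores each character by the Fitch union count,
vectorized across characters. Branch change counts come from one
most-parsimonious refinement with ties resolved toward the ancestral state
0, which is the natural polarity here because the outgroup (matched normal)
carries no somatic variant. Equally parsimonious topologies are all
reported; the primary tree is the lexicographically smallest canonical
newick, which makes results order-independent (input-order tie behavior of
classic implementations is deliberately not reproduced).

### Expression

Raw counts are normalized so that each library's 75th percentile of
nonzero counts equals the across-library mean of those percentiles
(upper-quartile normalization); the procedure is idempotent and its scale
factors are logged. "Expressed" means mean normalized count > 1 in at
least one sample.

The pairwise differential test is a deliberate stand-in for
empirical-Bayes posterior machinery, which needs nothing re-implementing
here: with two replicates per condition, a pooled-dispersion
method-of-moments estimate and a normal approximation on log2 condition
means give a stable two-sided p per gene. The evidence score is defined as
1 − BH-adjusted p so that the conventional "posterior > 0.99" gate maps
onto "adjusted p < 0.01"; the decision surface (evidence gate AND
fold-change gate, FC > 1.5 on the ratio of normalized means) is preserved.
The score is frequentist and is documented as such — it is *not* a
posterior probability. A pseudo-mean of 0.25 stabilizes logs and variances
for genes with a zero mean on one side.

Sample-specific DEGs for a focal sample are the intersection of its three
pairwise DEG lists; genes whose direction disagrees across the three
comparisons are flagged and left unlabeled. Fold changes are oriented
focal/other throughout, and the per-gene `log2_fc` reported for
sample-specific DEGs is the mean over the three comparisons.

Divergence summaries use Spearman correlation (Pearson available) on
`log2(mean + 1)` profiles of expressed genes, and complete-linkage
clustering on Euclidean distances — the defaults of the heatmap tooling
this style of analysis conventionally uses. `log2(x + 1)` is used wherever
counts are logged; the offset is stated because the convention is often
left implicit.

### Methylation

Per-sample coverage files are position-level; opposite-strand records of
one CpG (adjacent positions) are merged before filtering, with a flag to
disable. Only sites with total reads strictly greater than `min_depth`
(default 10) in *every* sample are retained, so all comparisons share one
site universe.

* **Differentially methylated sites (DMS):** per site, a two-sided Fisher
  exact test on methylated/unmethylated counts between two samples,
  BH-adjusted across all retained sites of that comparison (global, not
  per-chromosome), called at adjusted p < 0.05. Because millions of small
  tables arise, the package evaluates the exact test directly by
  hypergeometric summation (`fisher_exact_2x2`), de-duplicated across
  repeated count configurations; it is tested for exact agreement with
  `stats::fisher.test`.
* **Region levels:** the unweighted mean of site levels inside a region
  (promoter TSS−1500..TSS+500, strand-aware and clipped; gene body
  TSS..TES; CGI shores/shelves as 2-kb flanks with island > shore > shelf
  precedence). Regions need `min_sites` (default 3) retained sites: a mean
  over fewer sites at 10–30× coverage is noise-dominated.
* **Differentially methylated regions (DMF; DMP/DMGB when restricted to
  promoters/gene bodies):** |ΔML| > 0.20 *and* a two-sided Fisher test on
  counts pooled over the region's sites at unadjusted p < 0.05. Pooling is
  the one construction that yields a 2×2 table from a region; comparing
  site-level distributions instead would be a different (and unstated)
  test.
* **Global comparisons:** paired Wilcoxon signed-rank on per-site levels
  (zero differences dropped; identical samples are reported as p = 1 with
  a degeneracy flag), and the genome mean as the unweighted mean of site
  levels. Equal-site weighting (not equal-region weighting) is used for
  category means; this matters when regions differ greatly in site count.

### Integration

Each gene takes the copy number of the segment containing its TSS; genes
whose body straddles a segment boundary are flagged and excluded from
dosage tests, because they have no single copy number. Dosage classes are
relative to the baseline ploidy (default 3, the panel being triploid).
The dosage test compares expression changes (focal − other, log2 means,
genes with mean count < 1 in either sample excluded) of gain and loss
genes against *neutral* genes of the same pair, with one-sided
Kolmogorov–Smirnov alternatives "shifted up" and "shifted down"
respectively; neutral genes are the natural reference distribution and are
stated explicitly because figure-level descriptions usually leave the
reference implicit.

A *focal-specific CNA gene* has a focal copy number differing from every
other sample while the other samples agree (a relaxed modal-copy-number
mode exists). A *driven gene* is a focal-specific DEG whose direction
matches its focal-specific CNA (gain→up, loss→down) or gene-body
methylation change (hyper→up, hypo→down; gene-body methylation couples
positively to transcription, unlike promoter methylation); genes
satisfying both are "both", and the union accounting identity
`n_union = n_cna_consistent + n_dmgb_consistent − n_both` is asserted on
every run.

The mutated-gene/DEG overlap test is an exact binomial with
`p0 = |DEGs| / |universe|`; because a *lack* of overlap is the interesting
direction in this design, both tail probabilities are always reported and
the headline flag uses the depletion tail. Gene-set enrichment is a
one-sided hypergeometric over-representation test per set with BH across
sets — a generic stand-in for web-service enrichment tools, using
user-supplied GMT files.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Defaults (all in `sim_config()`):

| parameter | default | meaning |
|---|---|---|
| genome | 4 chromosomes × 5 Mb | desk-scale stand-in for a genome |
| `n_genes` | 2400 | non-overlapping genes, 2–6 kb |
| `n_cpg_sites` | 50,000 | 62% gene bodies, 30% promoters, 8% intergenic |
| `tree_topology` | `((Pa,Pb),(Ra,Rb))` + outgroup `TIL` | planted clonal tree |
| `branch_snv_counts` | trunk 40; internal clades 15; leaves 8 | perfect-phylogeny characters, no homoplasy |
| `baseline_ploidy` | 3 | triploid clones |
| CNA events | 2–6 per branch, 8–24 whole genes each | gains {4,5,6}, losses {1,2}; `loh_fraction` 0.5 of losses have B = 0 |
| `global_methylation_level` | Pa 0.460, Ra 0.409, Rb 0.407 | per-sample genome means |
| `cpg_coverage_mean` | 30 | Poisson site coverage |
| `snv_coverage_mean` | 60 | Poisson SNV depth; carrier VAF = 1/copy number |
| plantings | 150 DMGB, 200 DMP, 10 "both" genes | focal-sample (Ra) region shifts, magnitude 0.25–0.45 |
| `methylation_expression_coupling` | 3.5 | log2FC per unit gene-body ΔML |
| `dosage_coupling` | 1 | expression ∝ (CN/3) |
| `nb_dispersion` | 0.01 | negative-binomial replicate dispersion |
| `n_replicates` | 2 | RNA replicates per sample |

Rationale for the values that matter most:

* **Carrier VAF = mutant copies / total copies with one mutant copy**: in
  a triploid clone the natural clonal-heterozygous expectation is 1/3; at
  60× depth the read-support filter then passes carriers with probability
  > 0.999, so presence/absence coding is essentially noiseless — which is
  what makes topology recovery a sharp acceptance surface. Poisson
  coverage is the simplest model satisfying the filters' preconditions.
* **Perfect phylogeny by default**: every planted carrier set is a clade
  of the tree, so the planted topology is the unique optimum whenever
  ≥ 1 clean character per internal branch survives masking; defaults plant
  15 per internal branch. CNA placement covers whole genes only, so every
  gene has one unambiguous copy number.
* **Methylation model**: region base levels are Beta-distributed per
  region class (bodies high, promoters low), a shared per-site jitter
  preserves cross-sample site structure, and per-sample global offsets are
  calibrated in two passes so clamping to (0,1) does not bias the realized
  genome means; methylated counts are Binomial(coverage, target), i.e. a
  beta-binomial hierarchy across sites. Promoters get a larger per-bp CpG
  share than bodies (as CGI-dense promoters do), which keeps the null
  spread of promoter region ΔML well inside the 0.20 gate; body CpGs are
  placed beyond 600 bp downstream of the TSS so promoter and gene-body
  signals do not mix within a gene.
* **Couplings calibrated for recoverable truth**: the weakest planted
  gene-body shift (|ΔML| = 0.25) maps to FC `2^(3.5 × 0.25) ≈ 1.8`, and a
  single-copy gain at 2 replicates with dispersion 0.01 gives a log2-mean
  sampling sd ≈ 0.2, so planted effects at the stated evaluation sizes
  (|ΔML| ≥ 1/3, |ΔCN| ≥ 1, |log2FC| ≥ 1) clear the paper-style gates
  (score > 0.99, FC > 1.5) with margin rather than sitting on them. The
  tight dispersion reflects replicates of a homogeneous cultured clone.
  Methylation and "both" plantings (and the recoverability evaluation) are
  restricted to genes with baseline mean ≥ 100 counts: gene-body
  methylation tracks active transcription, and no method recovers
  expression effects from near-silent genes at n = 2.
* **One divergent sample**: all sample-specific plantings (strong CNAs,
  DMGB shifts, hence DEGs) go to Ra, which reproduces the qualitative
  discordance this analysis is about: the tree groups (Ra,Rb) while
  expression and methylome clusterings isolate Ra.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing error and mapping artifacts (counts
are drawn from the model, not from reads), subclonal mixtures or impurity
within a sample (each sample is one pure clone, as cultured populations
are treated), homoplasy and back-mutation (available only as an explicit
stress option), chromosome-scale CNA structure and interactions between
overlapping events, distance decay of methylation correlation, and any
trans-acting regulation: expression couples only to the gene's own copy
number and gene-body methylation. Tumor purity of the cultures is treated
as 1; no contamination model is attempted.

## Numerical and convention choices

* Coordinates are 1-based inclusive internally; BED input/output (0-based
  half-open) is converted exactly at the reader/writer boundary.
* The promoter is 2,001 bp before clipping: "1500 upstream to 500
  downstream" is read as including the TSS base.
* One representative record per gene is assumed in the annotation tables
  the generator writes; with real multi-transcript annotation, callers
  pass one row per transcript and aggregate as they see fit.
* `fisher_exact_2x2` reproduces the standard two-sided convention (sum of
  point probabilities ≤ observed × (1 + 1e-7)).
* The one-sided KS wrapper maps shift language ("x shifted up") onto the
  CDF language of `stats::ks.test`, which is the opposite orientation — a
  classic foot-gun, hence the wrapper.
* Degenerate inputs are reported, not errored, where a defined value
  exists: identical samples give Wilcoxon p = 1 with a flag; zero-variance
  correlation inputs give `r = NA` with a flag; zero-length gene bodies
  are kept as single-position intervals and logged.
* Determinism: the truth set is a pure function of the configuration
  (including its seed); the three count simulators re-seed from fixed
  offsets of the config seed so any subset of the bundle can be
  regenerated independently and the full bundle is hash-stable.

## Problem sizes used in validation

The test suite and acceptance script run at the generator's default scale
(2400 genes, 50,000 CpGs, ~100 SNVs) and use 100 independent seeds for the
topology-recovery and clustering-discordance rates, 200 × 10,000 null sites
for false-discovery control of the site test, 500 random instances for the
parsimony oracle, and single-seed full-pipeline runs for the coupling and
classification recoveries. These sizes were chosen so the whole validation
runs comfortably on a laptop while leaving the Monte-Carlo margins (e.g.
±0.02 on genome means at 50,000 sites) far from their thresholds.

## Known limitations

* The DEG score is a frequentist stand-in with matched decision surface,
  not the empirical-Bayes posterior of the tool it replaces; numerical
  score values are not comparable between the two, only the calls are
  designed to be.
* Exhaustive parsimony is exact but exponential: panels beyond 12 ingroup
  taxa are refused rather than approximated.
* The binomial overlap test's universe and direction are analysis choices;
  both tails are reported precisely because the construction is not
  uniquely determined.
* Strand merging of coverage files is positional (adjacent records) and
  can be disabled; with a reference genome one would merge by actual CpG
  dyads.
* Realized genome means can drift a few thousandths above the configured
  target for the focal sample because planted region shifts are signed by
  available headroom; the ±0.02 validation margin absorbs this.
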