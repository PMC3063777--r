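---
title: "Methods: cross-strain digital expression, allele-mapping bias, and array concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-strain digital expression, allele-mapping bias, and array concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strainseq` analyses differential gene expression between the C57BL/6J (B6)
and DBA/2J (D2) inbred mouse strains by digital mRNA counting, with two
distinctive concerns: the allele-specific mapping bias that strain SNPs
create when D2 reads are aligned to the B6-derived reference, and the
concordance of sequencing-based calls with two oligonucleotide microarray
platforms.  This vignette is the package's own account of the statistical
model, the algorithmic conventions, the synthetic-data generator, and the
design choices that were genuinely open.

## Gene models and counting

Expression is summarized at the gene level over *union exons*: for each
gene the exon intervals of all its transcripts are merged (overlapping or
book-ended intervals coalesce), and any genomic interval covered by the
union exons of two or more genes is excised from *all* of them, so that a
read start identifies at most one gene.  Two conventions matter:

* **Strand is ignored for overlap removal and counting.**  The protocol is
  unstranded, so a read cannot be attributed between opposite-strand
  overlapping genes any better than between same-strand ones.
* **Book-ended intervals merge.**  "Non-redundant exons" are maximal
  merged runs; counting by start position is insensitive to the choice.

Genes reduced to zero length by overlap removal are retained with an empty
model (they report zero counts and fall to the count filter) rather than
silently dropped, for auditability.  Gene length, wherever it is used
downstream (length-bias quartiles, SNPs per kilobase), is the length of the
*final* model, after overlap removal — the removed intervals can contribute
neither counts nor mappable SNP positions, so including them would dilute
both diagnostics.

Internally, intervals are carried as `IRanges`/`GRanges` (1-based, closed),
the Bioconductor convention; annotation input is 1-based inclusive (GTF)
and BED output is 0-based half-open, with conversion only at the IO
boundary.

## The toy seeded aligner

The original analysis used a production short-read aligner whose
quality-aware backtracking is not reproducible from its printed settings.
What *is* reproducible — and what creates allele-mapping bias — is the
mismatch economy: reads trimmed to 43 bases, a seed of the first 32 bases
allowing at most 2 mismatches, and a unique-best-locus policy.  The package
therefore defines a deterministic aligner with exactly those parameters:

* candidate loci are all positions (either strand) where the seed matches
  with ≤ 2 mismatches and the full 43 bases fit in one chromosome;
* candidates are ranked by total mismatches over 43 bases, ties broken by
  seed mismatches; a read is `unique` only when a single best locus
  remains, `multi` when several tie (never resolved by random choice),
  `unmapped` otherwise;
* `N` never matches anything, in read or genome, and counts as a mismatch;
* the reverse strand is handled by aligning the read's reverse complement
  to the forward genome; the reported position is the leftmost
  forward-strand base, and counting uses that leftmost base for both
  strands (a single convention shared with the test oracles).

The implementation indexes the genome by exact 10-mers at three fixed probe
offsets partitioning the 32-base seed (11 + 11 + 10): any seed hit with
≤ 2 mismatches leaves at least one partition class exact, so probing three
10-mers per read and strand yields a candidate superset, verified
base-by-base.  The unit and acceptance tests compare it against an
exhaustive per-offset scan.

With a SNP roughly every 9 bases — the density the generator plants in its
"SNP-dense" genes — every 32-base window of a D2 read carries at least 3
reference mismatches, exhausting the seed budget: D2 reads from such genes
go unmapped against the B6 reference and return only when the D2 alleles
are substituted into it.  This is the mechanism the allele-bias module
measures.

## Normalization and the exact test

Let `y_gj` be the count for gene `g` in sample `j`, `N_j` the sample's
total unique mapped reads.  The upper-quartile factor is
`f_j ∝ u_j / N_j`, with `u_j` the 75th percentile (linear interpolation) of
the *nonzero* counts in sample `j` — zero-heavy count matrices make the raw
75th percentile degenerate — normalized so that the factors have geometric
mean 1.  Effective library sizes are `M_j = f_j N_j`.  Total-count scaling
(`y / (N/10^6)`) is kept only as a diagnostic.

Counts are modeled as negative binomial with a single common dispersion
`φ` (variance `μ + φμ²`).  The exact test conditions on the two group sums,
which requires equal library sizes, so observed counts are first mapped to
*pseudocounts* at the common size `M* = geomean(M_j)` by quantile matching:
the pseudocount is the value whose NB cumulative probability at `M*`
matches the observed count's cumulative probability at its own `M_j`,
using the mid-probability transform interpolated linearly between integer
support points.  This makes the adjustment exactly the identity when all
`M_j` are equal, and reduces to Poisson matching at `φ = 0`.

`φ` is estimated by maximizing the conditional (Dirichlet-multinomial)
log-likelihood of the pseudocounts given their group sums, summed over
genes and groups, parameterized as `δ = φ/(1+φ)` on `[0.001, 0.95]` with a
coarse grid and golden-section refinement.  Adjustment and estimation are
iterated twice (starting from `φ = 0`), then pseudocounts are recomputed at
the final estimate; a third iteration changes `φ̂` by less than the
optimizer tolerance at the design sizes used here.  The estimate reproduces
edgeR's conditional MLE to within a few percent on shared inputs (checked
in the test suite, where edgeR serves only as an independent cross-check).

For each gene the exact two-sided p-value treats the rounded pseudocount
group sums `(s_A, s_B)` conditional on `S = s_A + s_B`: the probability of
a split `s` is proportional to
`NB(s; n_A μ̂, n_A/φ) · NB(S−s; n_B μ̂, n_B/φ)` with `μ̂ = S/(n_A+n_B)`, and
the p-value sums all outcomes whose probability does not exceed the
observed one.  Numerical conventions:

* group sums are rounded half to even (deterministic, unbiased);
* probabilities are normalized on the log scale; ties are detected with a
  relative tolerance of `1e-8` so analytically equal probabilities
  computed by different routes still count as ties;
* `S = 0` returns p = 1 by convention;
* `φ = 0` reduces exactly to the conditional binomial test.

The single-factor Poisson likelihood-ratio test (closed-form MLEs with
`M_j` offsets, chi-square(1) reference) is retained as a comparator; on
overdispersed data it is anti-conservative, and the package's diagnostics
show the companion artifact that longer genes are pushed toward
significance under the misspecified model while the exact test shows no
length trend.

## Multiple testing and result assembly

Storey q-values: `π̂₀(λ) = #{p > λ} / (m(1−λ))` on the grid
`λ = 0.05, …, 0.95`, smoothed with a cubic smoothing spline (3 effective
degrees of freedom) and evaluated at `λ = 1`, clamped to `(0, 1]` with a
fallback to 1 when the fit exceeds 1 or fewer than 4 grid points are
usable.  A cubic *polynomial* fit was tried first and rejected: its
extrapolation variance at the boundary is large enough that a full-null
simulation of 2,000 p-values lands below `π̂₀ = 0.9` in roughly a quarter
of runs, whereas the smoothing spline — the standard smoother for this
estimator — is markedly more stable.  q-values are the usual step-up
`min_{j≥i} π̂₀ m p_(j)/j`, capped at 1; tied p-values share a q-value.

Per-gene results report the log2 fold change of normalized mean
proportions, zero-guarded with the pseudo-fraction `c = 0.5/M*` (about half
a read at the common library size; the original analysis does not state its
zero handling, so the guard is recorded in the result attributes), the
average log2 abundance `log2(mean_j y_gj/M_j)`, and a low-count flag at
average log2 abundance < −20 — a `2^-20` proportion is about one read per
million, a sensible "barely sequenced" threshold; the printed source does
not fix the logarithm base, so this definition is fixed here and recorded.
DE is called at q < 0.01 and given a direction (`B6>D2` or `D2>B6`) by the
fold-change sign.

## Allele-bias pipeline conventions

Pipeline A aligns every sample to the reference; pipeline B substitutes the
D2 alleles into the reference (positions where the reference holds `N`
stay `N`; positions whose stated reference allele contradicts the genome
are skipped with a warning), realigns *only* the D2 samples (B6 alignments
cannot change), and re-counts.  Substitution preserves genome length, so
coordinates and gene models carry over unchanged.  Three choices the
source text leaves open:

* **Common gene universe.**  Pipeline B filters genes to pipeline A's
  post-filter universe, so before/after states compare like with like;
  status-change semantics are undefined otherwise.
* **Dispersion is re-estimated** in pipeline B rather than reused — the
  realignment changes the count distribution it is estimated from.
* **Classification**: genes DE in both runs with the same direction are
  `retained_*`; DE only before, `lost_*`; DE only after, `gained_*`;
  non-DE in both, `stable_nonDE`; genes DE in both runs with opposite
  directions are tallied explicitly as `direction_flip` rather than forced
  into a lost/gained reading.

## Microarray concordance conventions

Probe-level processing (RMA/MAS5 summarization, VST/RSN transforms,
probe-to-genome alignment, detection p-values) happens upstream in the
platform vendors' and Bioconductor's own tools; this module consumes their
outputs as a contract: mapping flags, SNP-overlap flags, per-sample
present/marginal/absent calls, p/q-values and linear-scale fold changes.
Filters follow the stated rules — Affymetrix probesets need a unique-exon
gene mapping, at least 4 of 11 probes surviving SNP/uniqueness masking, and
no absent call in both strains; Illumina probes need perfect unique
mapping, a gene ID, no spanned SNP, and detection.  The detection exclusion
for Illumina is stated in the source only as a present threshold (p <
0.05); this package mirrors the Affymetrix "absent in ≥ 1 sample of each
strain" pattern for it, a documented assumption.  Array fold changes are
linear-scale by contract and log2-transformed internally for sign
comparison.  Per gene and platform the record with the best q-value is
kept (ties: smaller p, then lexicographic probe id).  The survivor set is
independent of filter order; only the per-rule removal tally depends on it
(first failing rule claims the removal).

## The synthetic-data generator

The generator emulates the study conditions: 10 B6 + 11 D2 single-end
76-base lanes across three flowcells; a toy genome (default two 60 kb
chromosomes, 40 genes of 1–3 exons of 150–350 bp) with optional exact
duplicated blocks (to exercise multi-mapping), `N` runs, and inter-gene
exon overlaps; strain SNPs at ~5 per exonic kilobase (the approximate
B6/D2 divergence) with an optional SNP-dense gene subset (a SNP every 9
bases, guaranteeing ≥ 3 per seed window); NB count matrices with log-normal
means (default mean ≈ 100 reads), common dispersion (default `φ = 0.1`, a
typical inbred-replicate value), DE fraction 0.1 with 2-fold planted
effects, and per-sample library-size factors; and probe tables whose
p/q/fold values derive from noisy per-sample gene signals, with configured
fractions of SNP-spanning, non-unique, unmapped and heavily-masked probes
so every filter rule fires.  Reads are sampled so the full 76-base window
lies within a single exon: the splice-unaware 43-base aligner then always
has an exact genomic target, which is the regime the pipeline is designed
for (a config flag can emit junction-spanning reads to demonstrate the
aligner's limitation).  In count simulations the per-sample totals `N_j`
are set equal, so library-size heterogeneity enters only through the
planted factors — the situation upper-quartile normalization corrects.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: sequencing-quality profiles and
quality-aware alignment, GC and hexamer-priming bias, gene-length effects
on read sampling beyond length-proportional windows, insertions/deletions
between strains, isoform structure beyond shared union exons, and real
hybridization physics on the arrays.  Conclusions from the planted-bias
fixtures are qualitative (direction and mechanism), not the source study's
gene counts, which depend on the deposited data and the production
aligner's exact behavior.

## Problem sizes and determinism

The test suite and the acceptance script run at fixed scales chosen to
exercise every code path with stable statistics: 2,000 genes × 21 samples
for count-level calibration (type-I error, dispersion recovery, factor
recovery, `π̂₀`), a 120 kb genome with 40 genes × 3,000 reads/sample for
the read-level bias pipeline, and exhaustive enumeration up to group sums
of 200 for the exact test.  Every stochastic step is seeded; the same seed
reproduces byte-identical synthetic data, and `scripts/acceptance.R`
derives all its sub-seeds from its `--seed` argument.

## Known limitations

* The aligner is ungapped and splice-unaware by design; junction-spanning
  reads go unmapped and are simply lost to counting.
* A single common dispersion is assumed; tagwise or trended dispersion,
  GLMs with covariates, and multi-factor designs are out of scope.
* Heterozygous genotypes are not modeled: both strains are inbred, so SNP
  substitution is haploid.
* The microarray module never re-derives probe-level statistics; garbage
  in its input contract propagates to the concordance summary (anomalies,
  such as DE probes with missing fold changes, are listed rather than
  repaired).
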