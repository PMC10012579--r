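---
title: "Calling canonical and non-canonical imprints from reciprocal hybrid data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling canonical and non-canonical imprints from reciprocal hybrid data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintatlas)
```

## The design and its assumptions

Reciprocal F1 hybrid crosses are the instrument that separates
parent-of-origin effects from strain effects. Writing the two strains A and
B, cross AB (A dam) and cross BA (B dam) assign each strain to each
parental role once. A gene whose allelic bias follows the *parent* keeps
its paternal expression ratio on the same side of 0.5 in both crosses; a
gene whose bias follows the *strain* flips sides. Everything in this
package rests on that identifiability argument, which carries three
assumptions worth stating:

1. allelic read assignment is unbiased between the two genomes (reference
   bias is assumed corrected upstream, e.g. by pseudogenome alignment);
2. replicates within a cross are exchangeable;
3. library-level allelic coverage is deep enough that the beta-binomial
   sampling noise of a ratio is small relative to the imprinting effect.

## Expression path: sentinel ratios and the t-test caller

The paternal expression ratio of a transcript in a sample is
`paternal / (paternal + maternal)` allelic coverage. Two filters precede
any statistic, and their failure modes are recorded as sentinels rather
than `NA` so that downstream bookkeeping can distinguish them: `-2` for
"not expressed" (RPKM < `rpkm_min`, default 1) and `-1` for "expressed but
allelically uninformative" (both allelic RPM < `allelic_rpm_min`, default
0.5 — a transcript may simply not overlap an informative variant). Sentinel
cells never enter a mean or a test.

Each transcript's valid cells, pooling replicates of both crosses, are
tested against 0.5 with a two-sided one-sample t-test. The null value 0.5
is our design choice: imprinting is a departure from allelic balance, and
the two-sided form catches maternal and paternal biases symmetrically.
Degenerate replicate sets (all valid ratios identical) take the t-statistic
limit: p = 0 when the common value differs from 0.5, p = 1 when it equals
it. Bonferroni correction is applied over the tested family; by default the
family is the set of transcripts with at least `min_valid` valid samples
(the set actually eligible for a call), with the wider "any valid sample"
family available as a switch (`family = "any_valid"`) since both
conventions are defensible. A call requires the adjusted p below `alpha`
(0.05) *and* `min_valid` valid samples — 6 by default, 4 for sparser
designs with fewer replicates.

Extraembryonic dissections travel through maternal decidua, so apparent
maternal expression there can be contamination. `decidua_filter()` flags
maternal extraembryonic calls whose transcript is expressed in adult blood
(RPKM > 1); flagged calls are retained with the `blood_expressed` flag but
excluded from final maternal lists. Imprinting calls are made on autosomal
transcripts; chrX is analysed separately (see XCI below), since imprinted
X inactivation would otherwise masquerade as maternal expression of every
X-linked gene.

## Linear-model path: parent vs strain with moderated variances

The t-test asks "is the ratio far from 0.5"; the linear model asks the
finer question "how much of the allelic difference is parent, how much is
strain". Genes enter if at least one allele reaches RPM 0.5 in at least two
replicates of *both* crosses. Each (gene, sample) contributes two
observations `log2(allelic RPM + pseudocount)` (pseudocount 0.5,
configurable), with covariates parent (+1 paternal / -1 maternal) and
strain (+1/-1) — the minimal design the reciprocal layout identifies; the
design is fit per tissue, since tissue-specific imprinting (the
non-canonical class) would otherwise be averaged away. With balanced
crosses the two covariates are orthogonal; with data from a single cross
they are perfectly confounded, and the fit is refused (rank deficiency →
not testable) rather than silently resolved.

Gene-wise residual variances s² with d degrees of freedom are shrunk
toward a scaled inverse chi-square prior. The hyperparameters are estimated
by method of moments on log s²: with
`e = log(s²) − digamma(d/2) + log(d/2)`, the prior df d0 solves
`trigamma(d0/2) = Var(e) − trigamma(d/2)` (Newton iteration on the
trigamma function, inverted to ~1e-8 relative precision) and
`s0² = exp(mean(e) + digamma(d0/2) − log(d0/2))`. When the observed spread
of log-variances does not exceed what sampling alone produces, d0 = ∞ and
every posterior variance equals the geometric-mean prior — the correct
degenerate limit when all s² coincide. Posterior variances
`(d0·s0² + d·s²)/(d0 + d)` give moderated t statistics on d + d0 degrees
of freedom; with a single parent coefficient the F statistic is t², so the
two-sided moderated t is the equivalent test. Calls require BH-adjusted
p < 0.05 and a ≥ 4-fold allelic change (|beta_parent| ≥ 2 on the log2
scale). The fold gate means genes whose true effect sits exactly at
4-fold are called at a ~50% rate by construction; the gate is a precision
device, not a power claim.

## Methylation path: smoothing, exact tests, origin classification

Per-CpG methylation differences between parental alleles are noisy at
realistic coverage, so raw fractions are smoothed with a coverage-weighted
moving average: each CpG's smoothed fraction is summed methylated reads
over summed coverage within ±250 bp (`smooth_span` 500 bp). This
transparent smoother and a Fisher exact test on pooled raw counts stand in
for a heavier shrinkage-based DMR machinery; they are exactly
reproducible, oracle-checkable, and keep the published thresholds (delta
> 10 percentage points, p < 0.001) meaningful. The trade-off is honest:
genome-wide DMR *counts* from this caller are not comparable to published
counts obtained with different smoothing internals, which is why the caller
is validated against planted truth instead.

Candidate CpGs are grouped greedily along the chromosome with gaps
≤ `dmr_max_gap` (300 bp), requiring ≥ `dmr_min_cpgs` (3) candidates and a
span ≥ `dmr_min_len` (50 bp). These grouping defaults are ours: 300 bp is
about the span at which two CpG-island shores stop being one regulatory
unit, three CpGs is the minimum for the signal not to hinge on one
dinucleotide, and 50 bp suppresses single-read artifacts. Tissue-wise DMR
sets are merged by interval union, then each merged DMR is summarised per
track (coverage filters: 5 reads for pooled tracks and gametes, 1 read for
allelic tracks) and classified by integrating the gamete methylomes, in
precedence order: gametic (gamete delta ≥ 50 points, maintained on the
matching parental allele), gametes-hypermethylated (both gametes ≥ 75% —
the 75% cutoff is our reading of "hypermethylated in both gametes" and is
configurable), somatic (gametes similar, tissue delta ≥ 50 points), else
ambiguous. The final filter keeps DMRs with ≥ 2 covered CpGs in every
track and parental delta ≥ 50 points.

CpGs are keyed to the plus-strand C throughout; strand-symmetric collapsing
is assumed done upstream, and replicates and reciprocal crosses are pooled
by summing counts before testing.

## Integration: canonical vs non-canonical

The mode classifier is deterministic given upstream calls. A gene is
**canonical** when imprinted in at least one tissue with a gametic DMR
assigned; **non-canonical** when paternal in the extraembryonic tissue,
not paternal in the embryonic tissue, with no gametic DMR, and supported by
a somatic maternal DMR or an oocyte H3K27me3 domain over the promoter;
a **transient candidate** when biallelic in both tissues yet
H3K27me3-marked (primed but not maintained); otherwise unclassified. A
weak, non-significant embryonic paternal bias does not block the
non-canonical label, because "not paternal" is evaluated on the *call*
(biallelic or not-testable), not the raw ratio.

DMR assignment takes the nearest DMR to the TSS, ties broken toward the
smaller start coordinate; "promoter" means overlapping the TSS or the 5 kb
immediately upstream, strand-aware. H3K27me3 promoter overlap uses the
same 5-kb upstream window (plus the TSS); the window is a parameter
(`promoter_window`). Manually curated assignments can be injected by
editing the annotated DMR table before `build_atlas()` — curation is
supported as data, not encoded as rules.

The ZFP57 scan is a fixed hexamer, TGCCGC, reported on both strands
(GCGGCA on the forward sequence is a minus-strand site). Overlapping
occurrences all count. The single-substitution neighbours GCAGCG (the
retroelement consensus) and GCGACA (the reverted variant segregating in
some rat strains) do not match, which is exactly the discriminating
behaviour the motif logic needs.

## Comparative oocyte epigenomes

Syntenic 1-kb bins pair positions across two genomes; Spearman rank
correlation (average ranks on ties) compares mark levels, and
species-specific H3K27me3 bins require both a K27 difference > 0.5 RPKM
and a reciprocal DNAme difference > 75 percentage points — the joint
condition reflects the K27/DNAme anticorrelation that defines these
domains. Counting is antisymmetric by construction: swapping the genomes
swaps the two counts. Domain calling takes maximal runs of bins at or
above a threshold (default: 90th percentile of non-zero bins, since an
absolute cutoff depends on library depth) and groups peaks within 3 kb;
size summaries use mean and median domain width, and the domain-size
comparison reports mean_A − mean_B in bp and percent of mean_A (positive =
A larger).

## Imprinted XCI

Per sample, valid paternal ratios are split into autosomal and X-linked
sets, and a two-sided Wilcoxon rank-sum test (normal approximation)
compares their locations; we report a rank-sum statistic centred at zero
so that relabelling the parental alleles negates it. The formal test is
our addition — distribution plots alone do not make "skew" assertable —
with defaults alpha 0.05, ≥ 10 X-linked and ≥ 50 autosomal transcripts.
Samples with no valid X-linked cells are flagged (near-zero allelic X
coverage is also the signature of an XO individual) rather than
auto-excluded.

## The synthetic-data generator

The generator emulates the statistical structure the inference assumes,
with defaults set to the study conditions: two reciprocal crosses, three
replicates per cross per tissue (12 samples over epiblast and EPC,
matching a duplicate/triplicate design), negative-binomial total counts
(mean 200, size 10), beta-binomial allelic splits with concentration 200 —
enough overdispersion that the t-test must genuinely survive replicate
noise — and class targets: biallelic 0.5, imprinted 0.95/0.05,
strain-biased 0.8 toward one strain (flipping with the cross), decidua
contamination as additive maternal reads in EPC proportional to a
simulated blood RPKM, and a paternal-X EPC ratio of 0.2. Methylomes plant
gametic, somatic and gametes-hypermethylated DMRs (hyper/hypo levels
92%/8%, beta-concentration 60, Poisson coverage mean 20) on a background
whose per-CpG mean is shared across alleles; planted DMRs carry
CpG-island-like density (~25 bp spacing) on a sparse genomic background,
as imprinted DMRs overwhelmingly sit at CGIs. Mark tracks draw
H3K27me3/H3K36me3 from a Gaussian copula (rho −0.5, log-normal margins)
over paired 1-kb bins and plant species-specific K27 domains (default
30:10) with reciprocal DNAme.

What the simulator does **not** emulate — and what green tests therefore do
not certify on real data: reference/alignment bias between genomes, SNV
density variation (every simulated read is allele-assignable at a fixed
rate), PCR duplicates and batch effects, non-uniform CpG coverage along
real chromosomes, partial or isoform-specific imprinting, and linked
clusters of imprinted genes sharing one control region.

## Problem sizes and numerics

The test-suite and acceptance-script problem sizes are chosen so each
check has resolution without waste: 2,000-gene null panels over 50–100
repeats for family-wise error, 5,000 genes for hyperparameter recovery
(where d0 is recoverable to ±1 and s0² to ±10%), ~10⁵ bins for the copula
moment check, 20 null methylomes for DMR silence, and the default
five-DMR layout for boundary recovery. Stochastic acceptance checks assert
calibration where the criterion sits exactly at a nominal error rate (a
perfectly calibrated 5%-level test leaves "no rejection" in ~95% of
repeats, so the rejection count is compared against its binomial
reference) and fixed tolerances elsewhere. All randomness flows from a
single integer seed; generators derive per-stage seeds by small offsets,
and identical configurations are byte-identical.

Known limitations: no beta-binomial dispersion modelling across biological
replicates in the DMR caller (counts are pooled; a shrinkage extension is
the natural next step), no isoform-level quantification, no voom-style
mean-variance weighting in the linear model, and no homology mapping —
cross-species gene-level comparison expects the user's orthology table.
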