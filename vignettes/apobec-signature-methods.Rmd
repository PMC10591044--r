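---
title: "Methods: simulating and quantifying APOBEC3 mutagenesis in tumor genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying APOBEC3 mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`apobecsig` implements, as a tested and reusable pipeline, the somatic-mutation
analyses used to characterize APOBEC3B-driven mutagenesis in tumor whole
genomes: variant quality filtering, pyrimidine-normalized SBS-96 spectra, the
TCW enrichment score with exact-test significance and FDR stratification,
signature refitting and de novo NMF extraction, indel and structural-variant
landscapes, and replication-timing / mutation-clustering topography. Because
real 30x murine tumor genomes are not reproducible at desk scale, every stage
is exercised end-to-end on a synthetic tumor-genome generator with exact,
ledgered truth. This vignette records the models, the tunable parameters, the
numerical choices, and — importantly — what the synthetic cohorts do and do
not establish about real data.

# The synthetic generator

`generate_genome()` draws contigs as i.i.d. bases at a requested GC content
(default cohorts use GC = 0.42, mouse-like). A mitochondrial contig (`chrM`,
16.3 kb) is always present and always seeded with a few mutations so the
chrM-exclusion rule is exercised on every run. The generator never emits `N`:
truth stays exact, and ambiguity handling is covered by hand-written string
fixtures in the tests instead.

Mutations are planted channel-first: a 96-channel is drawn from the mixture
`signatures %*% weights`, then a genome position is drawn uniformly (without
replacement — each site hosts at most one event) among positions whose
pyrimidine-strand trinucleotide matches the channel context. The truth ledger
records the channel of every event, so catalog construction can be checked
channel-by-channel, not just in aggregate.

Read support is modelled as `total ~ 10 + Poisson(depth_mean - 10)` and
`alt ~ Binomial(total, vaf_mean)` clamped into the filter-passing region, so
that clean variants always satisfy the downstream thresholds; a configurable
`contaminant_fraction` of variants is instead pushed below exactly one
threshold (low alt support, low depth, or VAF at or below 0.05) and flagged,
which lets the filter be tested for *exact* set equality rather than rates.

Indels are planted by seeded site search: a site is accepted only if the
event's canonical (left-aligned) representation is the planted one and the
microhomology condition of its category provably holds (for `del_*_MH`) or
provably fails (for plain 2–4 bp deletions). Searching for naturally
occurring microhomology sites — plentiful in random sequence — keeps the
reference genome immutable across all planting operations.

The background "aging" signature is the exactly uniform 96-vector rather than
a COSMIC signature; it needs no external data and makes planted mixtures
exactly known.

## The reference signature set is synthetic

No COSMIC signature data ships with this package. `reference_signatures()`
builds a 96 x 30 stand-in with the COSMIC v2 layout: SBS1 (C>T at NCG), SBS2
(C>T at TCN with TCA/TCT preference), SBS13 (C>G at TCN) and SBS5 (broad,
with the characteristic T>C tilt) are hand-specified with the structure those
signatures are known for; the remaining 26 are sparse random decoy profiles
from a fixed internal seed. Two design constraints matter:

* decoys are *peaked* (gamma(0.25) draws), so they are mutually
  near-orthogonal and do not absorb mass from the planted signatures;
* the SBS5 stand-in is deliberately kept distinct from the exactly uniform
  `flat` background — an earlier near-flat SBS5 made 50/50 SBS2/flat refits
  non-identifiable, splitting the flat mass between two nearly collinear
  columns.

Any real 96-row COSMIC-layout TSV can be substituted via
`read_signature_tsv()`; all downstream code sees only a `signature_set`.

# Quality filtering

`apply_quality_filters()` keeps a call iff alt reads >= 3, total reads >= 10,
VAF strictly over 0.05, caller FILTER is PASS, and the contig is not
excluded. "Over 0.05" is read literally as a strict inequality, and the
"minimum" thresholds as inclusive; the boundary case (3 reads, depth 10,
VAF 0.30) is kept. Every removed variant carries the complete set of reason
codes it violated. Mitochondrial exclusion is applied by default at the
enrichment step (where the exclusion is part of the method's definition);
`filter_policy(excluded_contigs=)` makes it available globally.

# The TCW enrichment score

For each informative mutation (an SBS at a C:G pair, off chrM, not C>A nor
its reverse-strand G>T equivalent) a 41-base window — 20 bases up- and
downstream of the mutated position — is censused:

$$E = \frac{\mathrm{Mut}_{TCW}/\mathrm{Con}_{TCW}}{\mathrm{Mut}_C/\mathrm{Con}_C}$$

with `Mut_TCW` the mutated cytosines in 5'-TCW-3' (W = A or T, pyrimidine
strand), `Mut_C` all mutated cytosines, and `Con_TCW`/`Con_C` the TCW motifs
and cytosines in the aggregated windows. Windows are clipped at contig ends
and overlapping windows double-count, by design: the census is made per
substitution and aggregated. Three conventions are deliberate choices where
the method's prose is ambiguous:

* **Both strands in the background.** `Con_C` counts C and G positions;
  `Con_TCW` counts TCW and its reverse complement WGA. Mutations are
  pyrimidine-normalized, so a strand-symmetric background is the consistent
  pairing; a single-strand census gives the same score on strand-symmetric
  genomes but depends on assembly orientation otherwise.
* **TCW in both margins of the exact test.** The significance test is a
  one-sided Fisher exact test on
  `[Mut_TCW, Mut_C - Mut_TCW; Con_TCW, Con_C - Con_TCW]`, computed by exact
  hypergeometric tail summation. The method's description mixes a `Mut_TCA`
  numerator with a `Con_TCW` background; we treat that as a typo and use the
  same motif on both margins, with a TCA-only mode available
  (`collect_enrichment_counts(motif = "TCA")`).
* **ES_high requires direction.** Samples are stratified ES_high iff the BH
  q value is below 0.1 *and* the score exceeds 1, so a significant
  *depletion* can never be labelled high.

## A known null bias of the window census

The 41-base window census is *not* unbiased under the null. If mutated
cytosines are drawn uniformly among C:G sites, `Mut_TCW/Mut_C` estimates the
genome-wide TCW fraction among cytosines, but the window-based
`Con_TCW/Con_C` estimates something systematically smaller: the two
positions adjacent to any cytosine can never be TCW motif centers (a TCW
motif needs T immediately 5' and A/T immediately 3' of its C — both
impossible next to a fixed C or G), so windows centered on cytosines are
depleted of TCW relative to the genome. For i.i.d. sequence at GC 0.42 the
depletion works out to a null expectation of about **1.05**, not 1.0, and it
inflates the one-sided exact test's type-I rate well above its nominal level
at realistic mutation burdens (about 0.14–0.16 at alpha = 0.05 with 1000
informative mutations per sample). The package implements the published
window definition faithfully and *documents* this property rather than
patching it; the test suite asserts the measured null against the analytic
prediction, and the strict 1.00-calibration check in the acceptance suite is
expected to fail for exactly this reason. A related, opposite-signed
artifact appears under planted enrichment: windows centered on TCW sites
*include their own center* in `Con_TCW`, so a k-fold planted enrichment is
recovered slightly below k (about 2.7–2.8 for k = 3 at n = 5000). Neither
artifact affects cohort *ranking* or stratification, which is how the score
is used.

"k-fold planted enrichment" itself is defined as: the probability that a
mutated cytosine sits in TCW equals k times the genome-wide TCW fraction
among cytosines. (Weighting TCW *sites* k-fold — an alternative reading —
converges to a score well below k and is not what the recovery property
means.)

# Signature refitting and de novo extraction

`refit_exposures()` follows the iterative scheme of the refitting tool named
for this analysis: the catalog is normalized to frequencies, weights are
optimized one signature at a time by golden-section line search on the
squared reconstruction error until no coordinate improves, and signatures
holding less than 6% of the fitted mass are discarded and the fit repeated
until stable. Two numerical choices: the line search runs at tolerance 1e-9,
and after pruning the surviving active set is polished by an exact
least-squares solve (accepted only when nonnegative and improving), which
makes refitting a fitted reconstruction reproduce its exposures to solver
precision. No trinucleotide-abundance renormalization is applied between
genome and exome: the package targets whole-genome catalogs.

`extract_denovo()` is multiplicative-update NMF minimizing generalized
Kullback–Leibler divergence — the objective family standard for mutational
signatures — with seeded uniform initialization, best-of-`n_restarts`
selection, and signature columns normalized to sum 1 with exposures rescaled
compensatingly. The updates guarantee a non-increasing objective (asserted
per-iteration in the tests). The factorization rank is a user parameter; no
automatic rank selection is attempted. For recovery experiments, per-sample
exposures are drawn sparse-Dirichlet (alpha = 0.7): tumors then differ
strongly in which signatures dominate, as real cohorts do — and without such
heterogeneity a rank-3 factorization is not identifiable by *any* method, so
uniform-exposure cohorts would test nothing about the implementation.

# Topography

Replication timing is handled as a bedGraph-like track of fixed-width bins
ranked into five equal-length quintiles, earliest first. Whether a high
timing value means early is reference-dialect dependent; the package default
is high = early, and `assign_timing_quintiles(early_is_high = FALSE)` flips
it explicitly — there is no silent guess. Mutations outside the assayed
track are excluded and counted, never imputed. Per-quintile mutation counts
are reported raw and normalized to the largest quintile, with a chi-square
test on the 2 x 5 contingency between groups; the TC-to-TT percentage per
quintile uses the pyrimidine-normalized C>T-with-5'-T class.

Cluster detection uses inter-mutation-distance rules adopted from the
clustered-mutagenesis literature (they are conventions, not values from the
study this package models): maximal runs with IMD <= 1 kb and >= 6 members
are kataegis; among the remainder, runs of 2–5 members with IMD <= 10 kb are
omikli; everything else is dispersed. Every variant lands in exactly one
class. All four thresholds are arguments.

# Cohort statistics

Group comparisons default to two-sided: Mann-Whitney U (exact for small
tie-free samples, normal approximation with tie correction otherwise),
Fisher's exact 2 x 2, and chi-square, all via the standard R implementations
and all cross-checked against independent enumeration oracles in the tests.
Correlations are Pearson or Spearman with pairwise-complete handling of
missing values — missing features are explicit, never silent zeros. The IHC
H-score is the exact weighted sum
`1 x %weak + 2 x %moderate + 3 x %strong`, range 0–300.

The ES-stratified structural-variation comparison contrasts WT controls with
the ES_low and ES_high strata of the transgenic arm; strata with fewer than
two samples are skipped with a notice. In the default cohort all transgenic
tumors are planted strongly enough to stratify ES_high, so the within-arm
ES_low stratum is empty by design and the headline comparison is ES_high
tumors versus ES_low controls.

# The default study conditions

`default_config()` fixes the synthetic study: a 0.87 Mb genome (500 kb +
350 kb autosomes + chrM) at GC 0.42; 15 "WT" controls whose 2500 SBS are all
drawn from the flat background; 15 "CAG_A3B" tumors whose SBS2 weight spans
0.35–0.8 (flat for the remainder), with early-replication bias
(2 : 1.5 : 1 : 0.75 : 0.5 across quintiles) applied to tumor mutations;
indel loads and SV counts coupled to the planted SBS2 dominance in the
transgenic arm; depth 30, VAF 0.3, no contaminants. Genome size and
per-sample burden were chosen once as the smallest cohort on which signature
refitting is stable (catalog recovery needs roughly >= 2000 SBS per sample)
and the full pipeline runs in well under a minute per stage on one CPU.

## What the synthetic cohorts do not show

The generator emulates the *statistical* structure the analyses consume —
trinucleotide-conditioned substitution channels, category-exact indels,
timing-binned rates, threshold-straddling read support — not the genomics
underneath: no repeats or homopolymer tracts beyond chance, no CpG
depletion, no chromatin- or transcription-coupled rate variation, no
sequencing error, no subclonal structure, and i.i.d. base composition.
Passing recovery tests therefore demonstrates that the *implementations* are
correct and the pipeline is internally consistent; it does not validate the
biological interpretation of any particular score threshold on real tumors.

# Reproducibility

Every stochastic step takes an explicit integer seed, and `run_pipeline()`
output is byte-identical for identical config + seed. The numbered scripts
under `analysis/` run the stages over plain-text intermediates (FASTA, VCF,
bedGraph, TSV, JSON); `scripts/acceptance.R --seed N --out file.json`
recomputes the headline quantities from scratch.
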