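---
title: "dynabind methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynabind methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynabind)
```

This vignette is the package's account of its science: what each
analysis layer computes, the conventions adopted where the field leaves
room, the stochastic models behind the synthetic-data generators, and
what passing the planted-truth tests does and does not establish about
real data.

## The setting

An overexpressed transcription factor in a therapy-challenged cancer
cell can relocate across the genome and exchange interaction partners.
The package's layers mirror the assays used to observe this: ChIP-seq
peak sets per condition (cistromes), RIME peptide tables (chromatin
interactomes), ORF viability and RNAi dependency screens, and patient
transcriptomes. The motivating system is AR-targeted therapy resistance
in prostate cancer — hence the domain vocabulary (enzalutamide
conditions, ARBS classes, a FOXA1-like pioneer factor, DEMETER
dependency scores) — but every operation is generic.

## Cistrome algebra

**Coordinates.** All user-facing coordinates are BED-convention: 0-based
starts, half-open ends. Internally intervals are `GRanges` (1-based
closed), converted at the boundary. An optional fifth BED column is
read as the absolute 0-based summit position and must lie inside the
interval.

**Overlap.** Two intervals overlap iff they share at least one base
pair; intervals that merely abut do not. This full-interval criterion is
the default for every overlap-based operation because the reference
sets involved (pioneer-factor unions, ARBS classes) are peak *regions*.
A summit mode (summit of the query inside the reference interval) is
available throughout, since peak callers emit summits and some studies
intersect on them; which criterion an upstream study used is rarely
stated, so both are provided and results should cite the mode.
Chromosome naming-style mismatches (`chr1` vs `1`) are an error, never
silently harmonized; `normalize_chr = TRUE` opts in to stripping the
prefix.

**Merging.** `merge_union()` merges overlapping *and* book-ended
intervals, matching the default of the common interval-merge tools, and
flags its output so downstream code can rely on disjointness.

**Differential classification.** A control peak is retained iff it
overlaps ≥ 1 treated peak (counted once however many it touches); the
treated side is classified symmetrically. The partition invariants
(`lost + retained = |control|`, `gained + retained = |treated|`) are
asserted on every call, not only in tests. Because the two conditions'
peak boundaries differ, the retained class is reported from both sides.

**ARBS taxonomy.** The tissue-stage ARBS classes are conceptually
disjoint, but supplied reference sets can still overlap a query peak
jointly. Precedence `metARBS > TARBS > NARBS > UARBS` resolves
conflicts, preferring the progression-specific classes that are the
object of this kind of analysis; a non-exclusive overlap count table is
returned alongside so the choice is auditable. Classes with zero peaks
report `NA` overlap fractions flagged `defined = FALSE` — never a
silent 0.

## Cistrome-library enrichment

The published GIGGLE method ranks reference ChIP-seq datasets by
interval-set similarity using an indexed search and a combo score. This
package substitutes a transparent statistic on a binned universe —
"GIGGLE-like", with no claim of replicating GIGGLE output: the genome is
cut into fixed bins (default 1000 bp, the typical peak length scale;
configurable), each set marks the bins it touches with ≥ 1 bp, and the
2×2 bin-occupancy table is scored by

* the exact conditional (hypergeometric) two-sided Fisher p — summing
  all tables with probability ≤ the observed one, not doubling a
  one-sided tail;
* the sample odds ratio, with the Haldane–Anscombe +0.5 correction on
  all four cells whenever any cell is zero (keeping the OR finite and
  the direction informative);
* the combo score ln(OR) · (−log10 p), which is 0 at independence,
  positive for enrichment and negative for depletion, echoing the
  published GIGGLE score's shape.

Ties in the ranking break by smaller p, then label. Because bin size
sets the resolution of "co-occupancy", rankings are comparable within a
run, not across bin sizes.

## RIME interactomics

**Quantification unit.** The unique peptide: the number of *distinct*
peptide sequences mapping to a protein in one replicate. Spectral
counts are carried through I/O but never summed into the quantity.

**Background subtraction.** Any protein detected (≥ 1 unique peptide in
any replicate) in the control IP — the tag-only/luciferase pulldown —
is removed entirely from the bait's table. This is deliberately
all-or-nothing (not ratio-based): RIME contaminant lists are dominated
by abundant background (keratins, ribosomes) for which partial
correction is unreliable. The operation is idempotent.

**Presence and replicate combination.** A protein belongs to a profile
if detected in ≥ 1 replicate (default) — with typical RIME designs of
two replicates, requiring all replicates is aggressive; that strict
rule is available as `presence = "all"`. The profile value is the mean
unique-peptide count over *all* replicates with absence contributing 0;
means like 7.5 over two replicates arise naturally from this
absence-inclusive averaging.

**Differential classes and correlation.** Lost/retained/gained is set
algebra on the two conditions' profile keys. The bait's own protein and
the epitope tag (`V5`) are excluded by default from both classification
and correlation: self-peptides measure pulldown efficiency, not
interactions, and would otherwise join every class and inflate
bait-specific signal. Flags restore the literal behavior. Correlation
is Pearson on the raw replicate-averaged counts aligned on the *union*
of proteins (absences = 0); a `log1p` option exists because the count
scale is not standardised across studies. Degenerate inputs (fewer
than 3 union proteins, zero variance) are errors, never a silent 0.

**Venn and nomination.** Region counts are exact set algebra over 2 or
3 named sets, validated against each set's cardinality at construction.
Co-factor nomination is a boolean filter (in all of, in none of,
optionally restricted to e.g. the retained ∪ gained group), returning a
deterministic sorted list. Conventionally these are computed on
control-subtracted, treated-condition sets; any condition can be
supplied.

## Screen analytics

Differential viability is Δ = z_treated − z_control with rank 1 the
largest Δ; dependency ranking is ascending in the average score (most
negative = rank 1, the DEMETER convention), percentile = rank / n · 100.
Ties take average ranks everywhere, consistent with the rank machinery
used for Spearman correlation. Missing scores (gene not screened in a
line) are excluded pairwise from group means and never imputed; a gene
missing in every group column is undefined (`NA`), not 0. Cell-line
group membership is configuration, not hard-coded.

## Signature association

Spearman rho is computed as average-rank transform followed by Pearson
on ranks; the two-sided p uses the t approximation
t = ρ√((n−2)/(1−ρ²)), the standard large-sample form that handles ties
gracefully. "Detectable" genes (the correlation universe) require
nonzero variance and expression > 0 in ≥ 20% of samples by default; the
threshold is a parameter because no standard exists. BH adjustment runs
over the full transcriptome-wide scan and rows are restricted to the
signature *afterwards* — restriction before adjustment would overstate
significance. The index gene reports ρ = 1 against itself and is
excluded from the BH family. Both raw p and q are emitted, since
published volcano plots are often ambiguous about which they display.
Batch correction is out of scope: the matrix is assumed already
adjusted.

## Synthetic data: what is planted and how

The generators exist so that every downstream stage has a recoverable
ground truth. One global seed is expanded into fixed per-stream
substreams, so adding one generator call does not perturb the draws of
another, and identical seed + parameters reproduce outputs
byte-identically.

**Apportionment.** Planted fractions are converted to counts by
largest-remainder apportionment, so counts always sum exactly to n
(`apportion(1000, c(0.2, 0.5, 0.3))` → 200/500/300).

**Peak placement** is rejection sampling of start positions with a
minimum separation of twice the peak width between neighbouring starts,
and a placement-attempt cap: infeasible packing raises an explicit
error rather than silently overlapping. The separation guarantees that
(a) planted sites remain distinct after merging the two conditions and
(b) the jittered treated copy of a retained site (shift ≤ width/4)
overlaps its control copy and nothing else — which is what makes
planted-class recovery exact rather than approximate. ARBS class sets
and the pioneer set are planted as sub-selections of the same anchors,
apportioned per class so per-class overlap fractions are exact where
divisible.

**RIME counts** follow a gamma-Poisson (negative binomial) model with
the gamma mixture at the *protein* level: each protein draws one latent
abundance λ ~ Gamma(1/δ, μδ) and every IP/replicate detecting it draws
Poisson(λ), floored at 1. Marginally counts are NB(μ, δ); crucially,
the shared λ makes the counts of a protein *correlate across baits and
replicates*, which is what real profile correlations of baits with
shared interactors are made of — with independent counts the
correlation of two baits sharing half their interactors is near zero
regardless of the sharing. At the defaults (μ = 4, δ = 0.3) two baits
sharing ~500 of ~800 union proteins correlate at R ≈ 0.3–0.45; a
near-identical bait pair (a wild-type/point-mutant comparison) is
emulated with higher protein-level dispersion (δ = 1.2), giving
R ≈ 0.7–0.8. Detection is Bernoulli per replicate; the default
detection probability of 1 makes recovery exact, and 0.9 is used in
tests to verify recovery stays within the exact binomial bounds implied
by the model (including the leakage paths retained→lost/gained and
contaminant→interactor).

**Defaults are the study conditions** the package emulates: 1000 sites
at 0.2/0.5/0.3; 506 interactors at 77/222/207 with 50 contaminants over
2 replicates; a three-bait experiment planting 504 shared interactions
of which 335 exclude the third bait and 83 are third-bait-exclusive
with the pioneer; ARBS class overlaps 12.7%/8.6%/0.2%; a pioneer-bound
fraction of 0.92 ("more than 90%"); one ORF hit generated at Z means
+14.5 (treated) and −1.3 (standard) among 2000 ORFs scored N(0,1); and
three dependency genes at mean −3 in the AR-positive group, +0.25
elsewhere (planted non-dependence, so their percentile is
reproducibly high outside the dependent group), background N(0, 0.5).
The expression generator drives each signature gene from a latent
standard-normal factor at Pearson ρ (default 0.6) and maps through
10·exp(·) to TPM-like units — strictly monotone, so Spearman statistics
are unaffected; the recovered Spearman is the slightly attenuated
(6/π)·asin(ρ/2) ≈ 0.58 at ρ = 0.6. Sizes are scaled to desk scale (the
study-scale equivalents are 17,255 ORFs and 503 cell lines; 2000 ORFs,
~50 lines and 2000 genes exercise identical code paths); the test suite
and the acceptance script state the sizes they use.

**What the generators do not emulate.** Peak width/intensity
distributions, chromatin accessibility and sequence composition;
protein identity structure (homologues, shared peptides between
proteins — protein inference is upstream); correlated contaminant
abundance; batch effects or library-size variation in expression; and
screen off-target structure. Passing the planted-truth tests therefore
establishes the *correctness of the computations* — partitions,
subtraction, set algebra, ranking, correlation — under a faithful
stochastic model, not the biological validity of any particular
upstream peak caller or search engine.

## Numerical choices and degenerate inputs

* Fisher p is clamped to (0, 1]; −log10 p in volcano tables clamps p at
  the smallest positive double instead of producing Inf.
* Odds ratios use +0.5 on all cells only when a zero cell exists, so
  ordinary tables are unbiased by the correction.
* Empty query sets: `overlap_fraction` and taxonomy error (a fraction
  of nothing is undefined); `overlaps` returns an empty flag vector.
* All-zero contingency tables, all-missing dependency genes,
  constant index genes, and sub-3-sample correlations are errors, not
  NA propagation.
* Ranks use average ties throughout.

## The pipeline layer

`run_pipeline()` executes stages in dependency order from a versioned
YAML config in which unknown keys are errors (silent typos being the
chief failure mode of config-driven pipelines), fails fast naming the
stage on missing input, removes the partial report on failure, and
writes every headline number into one JSON report with the seed and a
config echo; reports contain no timestamps, so identical config + seed
reproduce them byte-for-byte. Verbs of the thin CLI wrapper
(`inst/scripts/dynabind_pipeline.R`) map onto stage toggles; all logic
lives in the package functions.

## Known limitations

* The enrichment module is a transparent stand-in for indexed
  interval-similarity search; it is not benchmarked against GIGGLE and
  should be used for within-run ranking only.
* Unique-peptide logic trusts the upstream protein inference; shared
  peptides between homologous proteins will double-count.
* The Spearman p's t approximation is inaccurate below ~10 samples;
  an exact-permutation option is deliberately not provided, as the
  intended cohorts are two orders of magnitude larger.
* Differential peak classification is overlap-based presence/absence;
  it does not model signal strength, so a peak that halves in height
  but keeps its footprint is "retained".
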