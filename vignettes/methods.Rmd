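---
title: "Methods and design notes for radpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for radpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpopgen)
```

`radpopgen` implements the desk-side analysis pipeline for a RAD-seq SNP
panel genotyped across several weakly differentiated populations: quality
control, population structure, individual assignment, LD-based effective
population size with linkage-map-aware pair exclusion, and a
sliding-window divergence scan. This vignette records the statistical
models, the parameter choices and their rationale, the numerical
conventions, and the design decisions that were genuinely open.

## The data model

A `genotype_dataset` is an individuals × loci matrix of reference-allele
dosages (0/1/2, `NA` for missing), population labels, and per-locus
metadata: the RAD tag, the SNP's base position within the tag (1–93 bp for
~100-bp single-end tags), and an optional linkage-map assignment
(linkage group plus centimorgan position, always present or absent
together). Internally, cM positions are continuous and windows use
half-open intervals.

Two Genepop conventions deserve a note, because the format underdetermines
them:

* **Reference allele.** Genepop does not define a reference allele. We
  take the numerically smallest allele code at each locus. This rule is
  deterministic, identical for the 2- and 3-digit dialects, and — unlike
  "first allele seen in file order" — makes the write/read round trip the
  identity even when the first genotyped individual at a locus is an
  alternate homozygote.
* **Population labels.** Genepop has no label field, only anonymous `POP`
  blocks. The writer therefore emits individuals as `<pop>:<id>`, and the
  reader recovers labels from that prefix when every individual carries
  one, falling back to `pop_1 … pop_K` otherwise. Files from other tools
  parse unchanged.

A half-missing genotype (one zero allele) is treated as fully missing,
with a warning: a diploid dosage model has no meaningful single-allele
state.

## The synthetic-data generators

The package analyses real datasets; the generators exist so that every
stage can be tested against known truth. They emulate the *statistical*
structure that the analyses assume — not sequences, reads, or demographic
history.

**Island model** (`simulate_island_genotypes`). Per locus an ancestral
frequency is drawn uniformly on [0.05, 0.5]; group frequencies follow a
Balding–Nichols distribution Beta(p(1−F)/F, (1−p)(1−F)/F) around the
ancestral value, population frequencies around their group value, and
genotypes are binomial(2, p). The two-level composition mirrors a regional
hierarchy. Defaults are the study conditions the package is built around:
five populations of 56, 54, 57, 56, and 47 diploids in three groups,
10⁴ loci, F = 0.05 among groups and 0.005 within (overall multi-locus
θ ≈ 0.04), 3% missing genotypes, 34 linkage groups with lengths spaced
27.75–160.23 cM carrying ~10.5% of loci, and 1–3 SNPs per RAD tag at
distinct 1–93 bp positions. F = 0 is accepted as the point-mass
(no-differentiation) limit; F = 1 is rejected as degenerate. The realized
per-population frequencies are stored as attributes, which is what lets
`plant_selected_region` redraw an interval of the genome at elevated
divergence (F + boost) for power experiments, and lets the haploid-panel
generator know each paralog's latent frequencies.

What it deliberately does **not** emulate: linked neutral variation (loci
are exchangeable given frequencies), asymmetric divergence between
specific populations, allele-frequency spectra of real RAD discovery
(ascertainment), or inbreeding. Tests passing on these data show the
estimators are correct under their own assumptions, not that real data
meet those assumptions.

**Wright–Fisher drift** (`simulate_wf_genotypes`). A constant-size ideal
diploid population: each offspring draws two parents uniformly (selfing
allowed), gametes recombine between map-adjacent loci with the Haldane
probability c = (1 − e^(−2d/100))/2 of their cM distance and assort
independently across linkage groups; after `n_generations` (default 30,
ample for unlinked-pair LD to equilibrate at its ≈1/(3Nₑ) level) a sample
of S individuals is drawn without replacement. Founders are in linkage
equilibrium, so all LD is drift-generated. This is the validation harness
for the Nₑ estimator: truth is known by construction.

**Artifact injection** (`inject_artifacts`). PSVs are built by summing an
existing locus with an independent latent paralog and collapsing
(0→0, 4→2, otherwise heterozygote), which reproduces both the diploid
heterozygote inflation and the haploid heterozygous-call signature
(probability p₁(1−p₂) + p₂(1−p₁)); error SNPs are appended at tag
positions 88–93 with MAF ~ U(0.005, 0.03); duplicated individuals are
copies with independent missingness. The truth record suffices to score
every filter's sensitivity and specificity.

## The QC cascade

Filters are small pure functions returning the filtered dataset plus the
IDs removed; `run_cascade` composes them and keeps a per-step audit such
that input minus reported removals reproduces the output, and a second
pass removes nothing. The default order follows the count-audit narrative
of the motivating study (call rate → tag position → one SNP per tag →
MAF → paralog screen → HWE → LD pruning → individual missingness →
duplicates); the methods listing of that study orders LD earlier, so the
order is configurable and neither is asserted as canonical.

Boundary semantics are prose-ambiguous in the field, so they are fixed
and documented: keep a locus when call rate ≥ 0.80; remove when tag
position ≥ 88 bp; remove an individual when missingness > 0.15; flag a
paralog when haploid heterozygosity > 0.10. The MAF rule removes a locus
only when MAF < 0.05 in *every* population — a single informative
population retains it. Exact ties in the one-SNP-per-tag rule go to the
lowest tag position, then lexicographic locus ID, making the choice
invariant to input order; LD pruning processes offending pairs by
descending maximum r², removes the lower-call-rate member (lexicographic
tie-break), and lets removed loci drop out of later pairs.

The HWE test is the full-enumeration Levene exact test (two-sided: sum of
configurations no more probable than observed, with a 1+1e−12 relative
guard on the equality comparison). The LD statistic here is genotypic
(dosage-correlation) r², not EM-haplotype r²: phase is unobserved, the
dosage correlation is deterministic and oracle-testable, and at the 0.8
threshold the two agree to well within the decision margin.

Duplicate detection uses an identity-by-state statistic,
R = 2·IBS − 1 with IBS the mean shared-allele fraction over co-genotyped
loci. This is a deliberate, documented stand-in for maximum-likelihood
relatedness: for finding R > 0.9 duplicates the IBS statistic is
essentially equivalent and has closed-form expectations the tests verify.

## Population structure

`wc_theta` implements the two-allele Weir–Cockerham components with
unequal sample sizes; a locus contributes when ≥2 populations have a
genotyped individual, multi-locus θ is ratio-of-sums, and negative
components are never truncated (truncation would bias the downstream
sums). The implementation is vectorized over loci and is checked against
an independently transcribed scalar implementation to 1e−12 on >1000
random instances.

The AMOVA follows the three strata its use case reports: among groups,
among populations within groups, within populations. Alleles within a
population are treated as exchangeable (no within-individual stratum),
distances are allele mismatches, variance components are estimated locus
by locus by the method of moments with unequal-size coefficients and
summed before forming percentages. Because the within-individual stratum
is omitted, the one-group AMOVA ratio agrees with Weir–Cockerham θ only
up to the heterozygosity terms (observed agreement ~1e−4 on complete
data); this is a property of the chosen stratification, not an
implementation gap.

The differentiation test permutes individuals between two populations and
recomputes multi-locus θ; PCA centers loci on mean dosage, imputes
missing values with the locus mean (no frequency scaling by default), and
tests eigenvalues against nulls obtained by permuting each locus column
independently. Both use the add-one p-value estimator
(1 + #{stat_perm ≥ stat_obs})/(B + 1), which cannot return zero. These
are equivalents-in-spirit of the classical package tests, not
replications of any specific program's scheme.

`flag_fst_outliers_quantile` ranks loci against the *empirical* per-locus
θ distribution (nearest-rank quantile, strict exceedance). It is
explicitly not a coalescent-null outlier test: it has no false-positive
control and simply identifies the top tail, which is what the downstream
steps (outlier exclusion before Nₑ; candidate lists) need.

## Assignment

Baseline allele frequencies use the posterior mean (x + 1/k)/(n + 1)
under a uniform Dirichlet prior, so an individual carrying an allele
absent from a baseline keeps a finite log-likelihood. Leave-one-out
removes the focal individual's two allele copies per genotyped locus from
its own population's counts before evaluation — verified against explicit
dataset-minus-one recomputation to 1e−12. Ranking is by log-likelihood
only (no population priors); exact ties and individuals with no genotyped
loci are reported unassigned rather than broken arbitrarily. Missing loci
contribute nothing.

## Effective population size

Per pair of loci within a population, the composite Burrows
disequilibrium is Δ̂ = cov(g_A, g_B)/2 over co-genotyped individuals
(divisor S−1), standardized as r̂² = Δ̂²/[(p(1−p)+D_A)(q(1−q)+D_B)]
with D_A = P_AA − p² the within-locus homozygote-excess disequilibrium,
frequencies taken from the same individuals, capped at 1. The
heterozygote-excess correction in the denominator matters: it is the form
whose finite-sample expectation matches the calibrated
E(r²) = 1/S + 3.19/S² (S ≥ 30; 0.0018 + 0.907/S + 4.44/S² below 30) that
the estimator subtracts — with the plain p(1−p)q(1−q) denominator the
subtraction overshoots by ~1.3/S², which at 200 loci and S = 50 inflates
N̂ₑ about two-fold at true Nₑ = 500. Both forms were measured on
sampling-only simulations during development; the corrected form is used
throughout.

Pairs are screened per pair (MAF ≥ 0.02 and positive variance among the
co-genotyped individuals), weighted by w = S_ij, and averaged;
S̃ is the weighted harmonic mean of the S_ij. The point estimate inverts
r²′ = r̄² − E(r²) through the random-mating quadratic; r²′ ≤ 0 or a
negative square-root argument yields an infinite estimate (no drift
signal). In `unlinked` mode, pairs whose loci share a linkage group are
excluded — pairs with an unmapped locus are retained — and by default the
analysis restricts to mapped loci, mirroring an analysis design in which
only map-aligned markers enter the calculation (`mapped_only = FALSE`
lifts this).

Parametric confidence intervals place chi-square bounds on r̄² with
degrees of freedom equal to the number of retained pairs and map them
through the point estimator. With L loci the ~L²/2 pairs are strongly
cross-correlated (each locus participates in L−1 pairs), so these CIs are
anti-conservative: in the package's own Wright–Fisher recovery
experiments (20 seeds per setting, S = 50, 200 unlinked loci) the
realized coverage of the 95% interval is far below nominal at
Nₑ ∈ {50, 100} and ≈85% at Nₑ = 500, while the *median point estimate*
stays within ±10% of truth at all three settings. The degrees-of-freedom
convention is kept because it is the established parametric-CI recipe for
this estimator; treat the intervals as lower bounds on uncertainty, and
prefer jackknife-style intervals (out of scope here) when calibrated
coverage matters.

Census ratios divide N̂ₑ by mean yearly escapement N and by N·G (census
per generation, G the generation length in years), bracketing the
ambiguity of single-sample estimates in age-structured, multi-cohort
spawning systems; they are undefined for infinite N̂ₑ.

## Window scan

Per population pair, per-locus pairwise θ is computed once on mapped
loci; windows of width 5 cM step 1 cM along each linkage group, anchored
at 0 cM (the anchor is a convention — the first-marker alternative is a
one-line change — and half-open membership prevents double counting).
Windows with fewer than 2 SNPs are recorded but never tested. The null
for a window of n SNPs resamples n values with replacement from the
pair's own per-locus θ distribution (negative values included), 1000
replicates escalated to 5000 exactly when the window mean exceeds the 90%
nearest-rank quantile; significance requires strictly exceeding the 95%
quantile at the final replicate count. The whole scan is deterministic
given a seed. Because adjacent windows share loci, the per-window flag
rate under neutrality is mildly inflated relative to 5% (the acceptance
suite bounds it at 8%); region-level interpretation should rely on the
merged regions and on recurrence across population pairs
(`cross_pair_summary`), not on counting windows.

## Problem sizes in the test suite

The tests exercise the estimators at sizes chosen to make Monte-Carlo
envelopes tight while keeping the default suite quick: oracle-equivalence
checks use >1600 random small instances; calibration uses 400 datasets
for the differentiation test and 100 for PCA (99 permutations each);
parameter recovery uses 20 Wright–Fisher seeds per true Nₑ ∈
{50, 100, 500} with 200 loci and S = 50; power checks for the planted
selected region use two-population panels of 1000–1200 loci on dense
maps. The full suite runs in a few minutes on one core.

## Known limitations

* The generators produce exchangeable loci given frequencies; they do not
  model ascertainment, allele dropout, or genotyping-error processes
  beyond the injected defect classes, so filter sensitivity/specificity
  statements are relative to those classes.
* The island model carries no drift LD, so Nₑ on island-simulated panels
  is correctly (and intentionally) near-infinite; Nₑ validation lives in
  the Wright–Fisher harness.
* The outlier utility is an empirical ranking, not a selection test with
  error control.
* Parametric Nₑ CIs are anti-conservative, as discussed above.
* The AMOVA omits the within-individual stratum by design; inbreeding
  coefficients are out of scope.
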