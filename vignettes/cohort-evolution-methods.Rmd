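---
title: "Models and methods behind EvoCohort"
author: "EvoCohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind EvoCohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

EvoCohort analyses cohorts of tumour whole genomes, with clear-cell renal
cell carcinoma as the motivating disease. This vignette sets out the models
each stage implements, the assumptions they rest on, the parameters a user
may want to change, and the design choices that were genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The cohort container

A `CohortBundle` holds five tables — somatic mutations with alt/total read
counts, allele-specific copy-number segments, per-sample purity/ploidy/LOH
fraction, structural variants as breakend pairs, and clinical records —
plus optional binned covariate tracks and gene annotation. Everything
internal is 0-based half-open; the 1-based conventions of the TSV segment
and mutation formats are converted only at file boundaries, and BEDPE/BED
pass through unshifted. Sex chromosomes are dropped at load because every
downstream formula assumes a normal copy number of 2, which holds only on
autosomes. Indels within 10 bp of supplied common germline indels can be
removed at load, mirroring the usual upstream calling filter.

## Timing copy-number gains on the mutational clock

### Model

In a region gained once, mutations present on the gained allele before the
gain are duplicated with it and sit at multiplicity 2; everything later
sits at multiplicity 1. Writing pi for the fraction of clonal mutation
accumulation elapsed at the gain, the per-unit-time allele-copy weights
give, for the three states reachable by one gain or one WGD:

| state | pre-gain m=2 weight | m=1 weight | ML estimator |
|-------|--------------------|------------|--------------|
| 2+1   | pi                 | 3 − 2 pi   | 3 n2 / (n1 + 2 n2) |
| 2+0   | pi                 | 2 − 2 pi   | 2 n2 / (n1 + 2 n2) |
| 2+2   | 2 pi               | 4 − 4 pi   | 2 n2 / (n1 + 2 n2) |

These closed forms are the exact maxima of the two-category multinomial
likelihood; the acceptance suite verifies agreement with a brute-force
grid search to within 0.001 for every (n1, n2) with n1 + n2 ≤ 60. Higher
copy-number states are excluded: with more than one gain the order of
events is not identifiable from multiplicities alone. WGD is timed by
pooling (n1, n2) over all 2+2 segments of a sample, which is the ML
combination under the assumption of a single simultaneous duplication.

Confidence intervals come from a multinomial bootstrap of (n1, n2) with
B = 1000 resamples (B configurable; the seed is an argument, so intervals
are reproducible).

### Multiplicity, CCF and clonality

Multiplicity inverts the expected VAF of a clonal mutation,
m·rho / (rho·CNt + 2(1 − rho)), and rounds half-up — half-up rather than
R's banker's rounding so that results cannot depend on platform rounding
mode — then clamps into [1, major_cn]. CCF applies the same linear map
without rounding, capped at 1.5; its CI transforms a Clopper–Pearson
binomial interval on alt/depth, inheriting exact-interval coverage.

Clonality uses a per-mutation rule: clonal iff ci_high ≥ 0.9 and
ccf ≥ 0.7. Cohort tools in this space usually cluster CCFs across
mutations; a thresholded per-mutation rule was chosen instead because it
is deterministic, runs at desk scale, and its error is measurable on the
generator (the suite checks a planted 70/30 clonal/subclonal split at
depth 80 is recovered within 5 points). The cost is that borderline
subclones near CCF 0.7 blur into the clonal set more than a clustering
method would allow.

### Calendar time

The two-phase clock has relative mutation rate 1 until tumour initiation
at calendar-life fraction c, and rate k ≥ 1 afterwards. Total mutation
units over a life are M = c + k(1 − c); a gain at molecular time pi sits
at pi·M units, and inverting the piecewise map yields the calendar
fraction and hence years before sampling. k = 1 gives exactly
age·(1 − pi), the constant-clock identity the acceptance suite asserts.
This is the minimal model expressing "rates may have accelerated after
initiation"; the true rate history of a tumour is unknown, so k and c are
exposed as configuration with k = 1 the default rather than estimated.
The clock rate mu (clonal mutations per year, burden/age) is reported for
interpretation but does not enter the pi-to-years map, which depends only
on relative rates.

## Ordering driver events

Each tumour contributes pairwise "matches" between its co-called events:
early-clonal beats late-clonal beats subclonal; clonal mutations in
ungained regions (clonal-NA) carry no within-clonal resolution, so they
tie with early/late and beat subclonal; copy-number events compare on pi
with a tie margin of 0.05, below the typical width of a pi CI at
desk-scale mutation counts. Mixed mutation-vs-CNA pairs tie by default;
whether mutations and CNAs should compete in one league or be ranked
separately is genuinely open, so both modes are available by filtering
the call table.

The league is a Bradley–Terry model fitted by minorisation-maximisation on
win counts with ties split half-half; a small pseudo-win (0.1) on played
pairs keeps strengths finite when one event never loses, without changing
their order. Finishing position is the rank of strength; the CI bootstraps
tumours — not matches — because tumours are the independent units. The
suite verifies exact recovery of arbitrary total orders for up to five
events, invariance to relabelling and cohort duplication, and ≥95%
recovery of a planted three-event order across 50 simulated cohorts of 300
tumours.

## Driver landscape statistics

Co-occurrence and mutual exclusivity use the two-sided Fisher exact test
per gene pair with BH correction across pairs. The test is verified
against exhaustive hypergeometric enumeration. Fisher conditions on
margins and can overstate exclusivity when tumour mutation burden is very
heterogeneous; at the burden ranges simulated here the type-I error is
within its nominal band, but on real hypermutator-containing cohorts a
burden-conditioned permutation would be the safer choice. The
pathogenicity contrast reports one-decimal percentages (half-up, for
parity with how such fractions are printed) and a chi-squared association
p with continuity correction, switching to Fisher below 200 observations.

## Structural-variant hotspots

Simple-SV breakends (both ends of each rearrangement; complex-event
breakends are excluded as they reflect single catastrophic events rather
than recurrent selection) are counted in 100 kb bins — wide enough for
stable background regression, narrow enough to resolve locus-scale
hotspots. The background is a negative-binomial log-linear regression on
the supplied covariate tracks (GC, replication timing, gene density,
chromatin accessibility, repeats, expression) with a log bin-width offset;
if the NB fit does not converge the model falls back to Poisson with a
warning, which is also the correct limit when counts are genuinely
equidispersed.

Candidate regions come from exact penalised least-squares segmentation of
the per-chromosome profile after the Anscombe transform 2·sqrt(x + 3/8) —
the variance stabilisation matters because raw Poisson heteroscedasticity
breaks least-squares change-point placement. The penalty defaults to
3·log(n bins), a BIC-scale choice; gamma → infinity provably yields one
segment. Significance is by permutation: per chromosome, breakends are
redistributed over bins with probability proportional to the fitted
background mean, preserving totals, and a candidate's p is the fraction of
permutations whose maximal same-length window reaches the observed count
(add-one corrected), BH-adjusted across candidates. Redistributing
proportionally to the background — not uniformly — is what makes the test
ask "elevated beyond what covariates explain". Hotspots overlapping a gene
≥ 600 kb long in the latest replication-timing quartile are flagged as
likely fragile sites and excluded from the retained list; both the length
threshold and the quartile are configuration, as fragile-site definitions
vary between studies.

## Genome instability

WGD follows the common pan-cancer rule psi > 2.9 − 2·hom (strict
inequality). wGII averages, over the 22 autosomes equally, the
length-weighted fraction of each chromosome whose total copy number
differs from the baseline; the baseline defaults to round(psi) so a clean
tetraploid scores 0. TMB divides counts by a user-supplied callable size
in Mb — deliberately a parameter, since callable genome size is a property
of the upstream pipeline, with a hypermutator flag above 10 SNV/Mb.
Arm-level recurrence permutes each sample's calls across arms, exactly
preserving its total gain and loss burden, so the null asks "is this arm
special given how unstable each genome is"; arm calls require ≥50% of arm
length beyond baseline, the common convention, exposed as configuration.

## Non-coding burden

Passenger mutations calibrate per-channel rates over the 96
pyrimidine-centred trinucleotide substitution channels (96 rather than 32
because that is the convention mutation-signature work established);
rates times opportunities reproduce the total count by construction. An
element's expected burden multiplies its context composition by the rates
and by per-sample exposure factors (sample burden over cohort mean). The
observed count is tested against an NB upper tail whose dispersion is a
method-of-moments fit on passenger elements, collapsing to Poisson when no
overdispersion is detectable. P-values from multiple methods are combined
with Empirical Brown's method — Fisher's statistic referred to a scaled
chi-square whose scale and df come from the empirical covariance of
−2·log p across elements; the suite verifies the independence limit
(agreement with Fisher), the perfect-dependence limit (a duplicated method
adds nothing) and the k = 1 identity. Zero p-values are clamped to the
smallest positive double with a warning.

## Immune escape

A tumour is escape-positive iff it has LOH at any of HLA-A/B/C, a
nonsynonymous HLA mutation, or an inactivated antigen-presenting gene,
where "inactivated" means a truncating mutation or a biallelic
nonsynonymous alteration — the two quantities a cohort oncoprint of the
22-gene APG panel displays. The rule is deterministic, so the suite
demands exact recovery of generator truth. HLA LOH flags and neoantigen
counts are inputs: allele-specific HLA copy number and peptide-binding
prediction belong to specialised upstream tools.

## Survival and association scans

Cox models use Efron tie handling because day-granular times tie
frequently, with Wald CIs and per-covariate models alongside the
adjusters; separation and non-convergence are flagged rather than
reported as estimates. Kaplan–Meier/log-rank and
logistic/linear/negative-binomial scans adjusted for sex, age, stage and
grade follow the standard implementations in `survival` and
`stats`/`MASS`, with BH across scanned features. Calibration (null mean
ln HR within ±0.05 over replicates) and recovery (planted HR 0.6 at
n = 600, judged on the replicate mean because one fit's SE on ln HR is
≈0.11) are measured by the suite.

## What the generator emulates, and what it does not

`generateCohort()` produces a scaled-down whole-genome cohort on 22
autosomes of 10 Mb: driver indicators from an Ising-like joint sampler
whose per-gene fields are calibrated by damped fixed-point iteration to
hit the configured marginals exactly (components of the interaction graph
are enumerated, so pairwise exclusivity or co-occurrence of configurable
strength is exact, and infeasible marginal/interaction combinations raise
an error); whole-chromosome copy-number events — 3p loss in 90% of
tumours, a timed 2+1 gain of chromosome 5 in 60%, WGD with probability
0.166 converting the genome to 2+2; clonal mutations whose multiplicities
follow each state's accrual weights at the planted pi, with
binomially-sampled reads at Poisson depth 80 and Beta-distributed purity
(mean 2/3); a configurable fraction of low-CCF subclonal passengers;
SV breakends that are Poisson per bin around a log-linear covariate
background with planted fold elevations; immune-escape mechanisms at
rates 5.9% / 0.5% / 3.1%; and exponential proportional-hazards survival
with a protective VHL effect (HR 0.6) and independent censoring. Driver
marginal frequencies (VHL 0.80, PBRM1 0.50, SETD2 0.18, BAP1 0.10 ...)
sit near those reported for ccRCC cohorts.

Deliberate simplifications, which bound what passing tests show about
real data:

- Copy-number events span whole chromosomes; there is no focal
  architecture, no subclonal copy number, and no chromothripsis-like
  complexity beyond labelled "complex" decoy SVs.
- Driver timing classes used by the ordering stage are drawn from
  per-gene class probabilities and emitted as call tables; they are not
  re-derived from the driver mutations' read counts, since most driver
  loci in the simulation lie outside gained regions where early/late is
  undefined. Read-level class derivation is exercised separately on timed
  segments.
- Trinucleotide contexts default to uniform; mutational-signature
  structure is limited to what `context_probs` encodes.
- Survival is exponential with proportional hazards — the model the Cox
  stage assumes — so recovery tests certify the estimator, not the
  proportional-hazards assumption itself.

## Problem sizes and numerical conventions

The acceptance computations use: the exhaustive (n1, n2) sweep to 60; 200
segments per state at 500 expected mutations per segment (the
recovery-error and CI-coverage conditions); 50 cohorts of 300 tumours for
league recovery; 2000 elements × 3 methods for the Empirical Brown
comparison; 40–50 replicates of a 5-chromosome, 300-bin genome with two
planted 10× hotspots at 300 permutations for hotspot FDR/power; and 50
replicates of n = 600 for Cox recovery. All randomness flows from
explicit seeds; 32-bit-safe sub-seeds are derived arithmetically.
Percentages are reported half-up to one decimal. Bootstrap and
permutation p-values use add-one correction, so they are never exactly
zero.

## Known limitations

Multi-region and multi-sample phylogenies are out of scope, as are
subclonal reconstruction by clustering, focal-peak detection, SV
classification and signature extraction — those belong to dedicated
upstream tools whose outputs this package consumes. The pi estimators
apply only to 2+1, 2+0 and 2+2 states; tumours whose gains all sit at
higher copy numbers contribute no timing information. Real-time conversion
inherits every caveat of the clock model: if the true rate history is not
two-phase piecewise-constant, the years reported are a model-based
extrapolation, which is why the constant-clock default is the one the
package certifies exactly.
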