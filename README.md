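# EvoCohort

Cohort-scale analysis of tumour whole-genome sequencing, built for
clear-cell renal cell carcinoma (ccRCC) studies: when in a tumour's life did
its copy-number gains happen, in what order did driver events occur, where
do structural variants cluster beyond what local genomics explains, and
which genomic features carry clinical signal?

The package implements the bespoke computational stages of such a study as
reusable, tested R functions, together with a synthetic-cohort generator
that plants known truth for every stage, so that each estimator's accuracy,
calibration and power can be measured rather than assumed.

## What it computes

**Mutational-clock timing of gains.** A copy-number gain duplicates every
mutation already on the gained allele. Counting clonal mutations at
multiplicity 2 (n2, pre-gain) versus multiplicity 1 (n1) dates the gain in
molecular time pi — the fraction of clonal mutation accumulation elapsed at
the gain:

    pi(2+1) = 3 n2 / (n1 + 2 n2)        single-allele gain
    pi(2+0) = pi(2+2) = 2 n2 / (n1 + 2 n2)   gain with LOH / WGD

Multiplicity comes from the standard VAF decomposition
m = round(VAF / rho * (rho CNt + 2(1 - rho))), CCF from the same linear map,
and WGD is timed by pooling all 2+2 segments. A two-phase clock (relative
rate 1 before tumour initiation at life-fraction c, rate k after) converts
pi to years before sampling; with k = 1 this is exactly age * (1 - pi).

**Event ordering.** Per-tumour timing classes (early-clonal, late-clonal,
subclonal; pi for gains) feed pairwise precedence matches; a Bradley-Terry
league fitted by minorisation-maximisation ranks events by average
finishing position with a tumour-bootstrap CI. Per-gene clonality odds
ratios use Haldane-Anscombe-corrected 2x2 tables.

**Other stages.** Driver frequencies and Fisher-exact
co-occurrence/exclusivity with BH correction; SV breakpoint hotspots
against a negative-binomial covariate background (piecewise-constant
segmentation, background-proportional permutation p-values, fragile-site
exclusion); WGD calling (psi > 2.9 - 2*hom), wGII, TMB and arm-level
recurrence; non-coding burden testing with 96-channel trinucleotide
context adjustment and Empirical Brown p-value combination; immune-escape
classification (HLA LOH, HLA mutation, APG inactivation); Kaplan-Meier /
log-rank / Cox survival analysis and adjusted association scans.

## Worked example

```r
library(EvoCohort)

# a synthetic 100-tumour cohort with planted truth
g <- generateCohort(simulationConfig(n_tumours = 100), seed = 7)
cohort <- g$cohort
cohort
#> CohortBundle with 100 tumours
#>   mutations: 75763  segments: 2200  SVs: 331
#>   clinical records: 100  covariate bins: 2200  annotated genes: 10

# time every gained segment and WGD from read counts
tg <- timeCohortGains(cohort, B = 500, seed = 1)
head(tg[tg$chrom == "WGD", c("sample_id", "state", "n1", "n2",
                             "pi", "ci_low", "ci_high")], 3)
#>    sample_id state  n1  n2        pi    ci_low   ci_high
#> 22      T003   2+2 283 821 0.8529870 0.8348285 0.8697354
#> 45      T012   2+2 256 944 0.8805970 0.8652482 0.8940092
#> 64      T016   2+2 310 911 0.8545966 0.8376963 0.8704903

# convert one WGD time to years before sampling (age 62, constant clock)
convertToRealTime(0.68, 62, clockModel(k = 1))
#>   years_before_sampling
#> 1                 19.84
```

A pi of 0.68 means the duplication happened after 68% of the tumour's
clonal mutations had accumulated — under a constant clock, about 20 years
before the sample was taken from a 62-year-old patient. Against the planted
truth, mean |pi_hat - pi_true| on this cohort is 0.034.

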