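---
title: "Relationship inference from IBD segments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relationship inference from IBD segments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdrelate)
```

## The problem

Two individuals who share a recent common ancestor carry long genomic
segments that are identical by descent (IBD). The number and lengths of
those segments carry information about how recent the ancestry is: close
relatives share few-but-huge segments, distant relatives share few-and-short
ones, and nominally unrelated members of a population still share occasional
short segments ("background" or cryptic relatedness). `ibdrelate` estimates
the relationship between each pair of individuals from detector-reported IBD
segments by maximum likelihood, with a likelihood-ratio test against a
background-only null.

A relationship is parameterized as (d, a): `d` total meioses along the
path(s) through the common ancestor(s), and `a` the number of shared
ancestors (2 for full relatives, 1 for half relatives, 0 for direct
ancestor-descendant pairs). The conventional degree label is `d - 1` when
`a = 2` and `d` otherwise, so full siblings are 1st degree while avuncular,
grandparent and half-sibling pairs are all 2nd degree.

## Segment models

Throughout, `r` is the expected number of recombination events per meiosis
genome-wide (the total genetic map length divided by 100; about 35 in
humans) and `c` the number of autosomes (22).

**Lengths.** A segment inherited through `d` meioses is broken by
recombination at rate `d` per Morgan, so its length is approximately
exponential with mean `100/d` cM. Segments are also broken at chromosome
ends; accounting for that gives mean `100/(d + c/r)`, which converges to
`100/d` as `d` grows. The boundary-aware form is used for `a` of 0 or 1;
for `a = 2` the simple `100/d` form is used, which in practice compensates
a small upward bias in detector-estimated lengths for close relatives. For
ancestor-descendant pairs the first meiosis is invisible in a pairwise
comparison (every segment of the descendant's relevant haplotype comes from
the ancestor), so `d` is replaced by `d - 1`: mean `100/((d-1) + c/r)`.

**Counts.** The number of segments is Poisson. Writing coverage for the
expected fraction of the genome shared, the generic count mean is
`a(rd + c)/2^(d-1)`, and the ancestor-descendant variant is
`(r(d-1) + c)/2^(d-1)` (equal to `c` whole chromosomes for parent-offspring
at `d = 1`). These forms satisfy an exact conservation identity,

```
count_mean x 100r/(rd + c) = coverage x 100r,    coverage = a / 2^(d-1),
```

(`2^(1-d)` for `a = 0`), which the test-suite verifies both algebraically
and against gene-dropping simulation.

**Minimum length t.** Short segments are hard to distinguish from
background sharing, so segments below `t` (default 2.5 cM) are ignored and
every model is conditioned on length >= t: Poisson means are multiplied by
P(length >= t) and length densities renormalized on [t, Inf).

### Full siblings

Detectors that cannot distinguish IBD1 (one shared haplotype) from IBD2
(both) report, for full siblings, *merged* segments in which IBD2 stretches
bridge their flanking IBD1 neighbours. The sibling sharing process is the
union of two independent two-state Markov chains (one per parent), each
flipping at rate 2 per Morgan. From that process we derive, exactly
(ignoring chromosome ends):

* a merged segment contains `k` IBD2 bridges with probability `2^-(k+1)`
  (each continuation event has probability 1/2);
* conditional on `k`, the length is the sum of `2k + 1` exponential pieces
  of mean `100/(2d) = 25` cM, i.e. Gamma(2k+1, scale 25);
* summing the mixture gives the closed-form density
  `f(l) = exp(-l/25) cosh(l/(25 sqrt(2))) / 50`, with mean 75 cM;
* the expected number of merged segments is `rd/2 + 3c/4` at `d = 2`
  (51.5 for r = 35, c = 22), combining the interior start rate with the
  3/4 chance each chromosome begins inside a shared run.

A Kolmogorov-Smirnov test in the suite confirms that boundary-free
simulated merged segments follow this mixture, and the 22-autosome
simulation reproduces the 51.5 count and 0.75 genome fraction.

On a real genome, chromosome-end truncation shortens merged segments
(observed mean about 51 cM against the boundary-free 75), and a
boundary-free length law systematically loses sibling pairs to the
avuncular hypothesis, whose expected count is identical. The classifier
therefore uses the boundary-aware form of the same mixture: the
chromosome-boundary hazard `c/(100r)` is added to the piece exit rate —
exactly the correction the exponential models apply — giving piece scale
`theta = 100/(2d + c/r)` (21.6 cM), and the continuation probability is
fixed by the conservation identity the other families satisfy (mixture
mean x merged count = 0.75 x 100r): `rho = (M - theta)/(M + theta)` with
`M = 75r/(r + 3c/4)` (0.405, mean 51.0 cM), with the same closed form
`f(l) = (1-rho) e^(-l/theta) cosh(l sqrt(rho)/theta)/theta`. The two
parameterizations coincide as `c/r -> 0`. With this law, simulated
sibling and avuncular pairs are each assigned their own hypothesis about
96% of the time, in line with the published first-degree accuracy of the
approach; the boundary-free law remains available via
`sibling_length_logpdf(..., boundary_aware = FALSE)`.

With an IBD2-aware detector, the full-sibling model additionally uses the
IBD2 segments: under the alternative their count is Poisson with mean
`rd/2 + c/4` (40.5; again fixed by conservation, since IBD2 covers a
quarter of the genome in pieces of mean 25 cM) and lengths are exponential
with mean 25 cM; under the null, conditioned on the total merged IBD1
length T, the expected IBD2 count is the background count mean scaled by
`T/(100r)`, with background lengths.

### Avuncular pairs

Every sibling IBD2 stretch is IBD1 between uncle and nephew, and the
recombination bookkeeping of the extra meiosis cancels on average, so the
expected avuncular segment count equals the full-sibling merged count
exactly, for every (r, c). Lengths use the generic `100/d` exponential.
Both statements are approximations of the true avuncular process (whose
boundary density is 2.5 per 100 cM, count about 54.7 and mean length about
32 cM on the default map); the conservation test therefore carries a
documented 6.5% allowance on the avuncular count and none elsewhere.

### Parent-offspring

Parent-offspring pairs are IBD1 across the whole genome with no
stochasticity, so no likelihood is computed: a pair is called
parent-offspring when its genome-wide IBD fraction is at least `z` (default
2.33) standard deviations above the full-sibling expectation of 0.75. The
sibling standard deviation is not derivable in closed form on a finite map;
it is the package constant `SIGMA_SIB = 0.04416`, computed once from
10,000 gene-dropped sibling pairs on the default map with seed 104, and can
be overridden through `relate_params(po_sigma = ...)`.

## The null model and the test

The background model is fitted from a control cohort of putatively
unrelated pairs: the count of segments >= t per pair gives a Poisson mean
(pairs with zero segments count — the control manifest lists pairs, not
segments), and lengths above t are fitted as a shifted exponential whose
mean excess is the sample mean of (length - t). The retained empirical
sample supports a nonparametric variant; the parametric default keeps the
likelihood smooth on sparse control cohorts.

Under the alternative for hypothesis (d, a), `np` of the pair's `n`
segments follow the relationship model and `n - np` the background; the
likelihood is maximized over `np`, attributing the `np` longest segments to
the relationship. This is likelihood-optimal whenever the relationship's
length law dominates the background's in likelihood ratio (true for every
grid hypothesis against an exponential background with a shorter mean); a
brute-force search over all 2^n subsets guards the rule in the test-suite.
The test statistic is twice the gap between the best hypothesis and the
null, referred to a chi-square with 2 degrees of freedom (one for `np`, one
for (d, a), which act approximately as a single parameter); the statistic
is floored at zero since the grid maximum nests the null. The confidence
set contains every (d, a) within `qchisq(confidence, df)/2` of the maximum
(df = 2 by default; a 1-df profile variant is available via
`relate_params(profile_df = 1)` for users who prefer treating (d, a) as one
parameter). Ties in likelihood report the smaller `d`.

## Masking excess-IBD regions

Some genomic regions show far more detected IBD among controls than chance
allows (assembly gaps, centromeric regions, long-range LD). The scan tiles
the genome into 0.5 cM windows, truncates control segments at window
boundaries, and compares observed totals with the uniform expectation;
windows whose observed/expected ratio exceeds `h` (default 4) are coalesced
into mask regions. The 0.5 cM window resolves the >= 5 cM regions that are
worth reporting with at least ten windows each; expected IBD is computed
per cM of window, matching the genetic-length reporting of the mask. When
a segment wholly contains a region with at least `b` Mb (default 1) to
spare on both sides, the region's genetic length is subtracted from the
segment's; any other segment crossing a region boundary is truncated at
the boundary (left-to-right, keeping the longer outside portion when both
flanks are sub-`b`; remnants are re-processed), and segments inside a
region are removed. The summed masked length `m` is subtracted from `100r`
(`r -> r - m/100`) in all models, since recombination inside masked
regions can no longer be observed. Masking is optional and off by default.

## The gene-dropping simulator

The simulator is the package's oracle: founders receive distinct haplotype
labels, each meiosis places Poisson(`chrom_cM`/100) crossovers uniformly in
genetic distance (no crossover interference — the models being validated
are interference-free too), and true IBD1/IBD2 segments follow from label
identity. Output modes mirror the two detector conventions: exact state
tracks, merged-only segments, and merged-plus-overlapping-IBD2. Marker
emission supports de-novo mutation (default expected rate 1e-7 per
transmitted site) and genotyping error (default 0.001 per polymorphic
site). What the simulator does *not* emulate: detector boundary error,
phasing artifacts, and population LD — so passing tests demonstrate
correctness of the inference given well-estimated segments, not robustness
to detector noise (the `add_segment_noise()` helper exists for sensitivity
experiments).

Synthetic maps use the human autosome genetic-length profile scaled to
3500 cM with mild (0.7-1.3 cM/Mb) rate heterogeneity. One observable
consequence of finite chromosomes worth noting: the model's "IBD2 segments
average 25 cM" is the boundary-free excursion mean; measured over all true
IBD2 segments on the 22-autosome map, chromosome-end truncation shortens
the average to `(total/4) / (c/4 + total/100)` = 21.6 cM. The calibration
tests check both statements in their own regimes.

Synthetic control cohorts default to 2.0 segments (>= t) per unrelated
pair with mean excess 1.0 cM above t = 2.5 — representative of
post-masking background sharing in European-ancestry cohorts, where
unrelated pairs typically share a small handful of barely-above-threshold
segments. These values were fixed once, before any calibration runs, and
are not tuned.

## Problem sizes and numerical choices

The shipped validation uses 10,000 meioses and 10,000 sibling gene-drops
for calibration, 600 gene-drops per (d, a) for the conservation oracle,
100 pairs per degree for power (>= 95% at 5th degree, >= 50% at 8th, at
alpha = 0.001), and 1,000-2,000 background draws for type-I calibration —
sizes at which three Monte-Carlo standard errors resolve the quantities
being checked. Degenerate inputs are handled explicitly: a control cohort
with no segment above t yields a flagged degenerate background (null
log-likelihood -Inf for any observed segment); zero-segment pairs are
"unrelated" with p = 1; `cosh` in the sibling density is evaluated through
a log1p form to avoid overflow; sub-basepair segments after coordinate
rounding are widened to 1 bp. Physical coordinates are 0-based half-open
internally; the 1-based inclusive detector dialects are converted on read.

## Limitations

Joint modelling of segment number and length beyond the Poisson-exponential
family is out of scope, as are the IBD detectors themselves, phasing, and
population-structure-specific backgrounds (fit one background per control
cohort instead). Relationships beyond `d_max = 15` meioses are not
enumerated. The avuncular and `a = 2` length models are deliberate
approximations, as discussed above; half-sibling versus grandparent
disambiguation rests entirely on the (d, a) likelihood and is intrinsically
weak.
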