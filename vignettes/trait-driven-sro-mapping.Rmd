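---
title: "Trait-driven SRO mapping and disease-locus localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-driven SRO mapping and disease-locus localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sromapper)
```

## The problem

Contiguous gene syndromes arise from heterozygous deletions that remove
several adjacent genes. Different patients carry different deletions, and
many clinical traits of such syndromes are incompletely penetrant, so the
classical device for candidate-region mapping — the Shortest Region of
Overlap (SRO) shared by all affected patients' deletions — becomes weak
exactly where it is needed most: few penetrant deletions are available per
trait, and non-penetrant deletions, which are informative (a deletion that
removes a region *without* producing the trait argues against a fully
penetrant locus there), contribute nothing to an intersection.

`sromapper` implements a trait-driven pipeline for this setting. For each
trait it (1) delineates SROs from the trait-penetrant deletions, (2)
computes, inside each SRO, a per-window posterior probability for the
position of the disease locus (DL) that uses penetrant *and* non-penetrant
deletions, (3) estimates penetrance per SRO-overlap pattern with binomial
confidence intervals, and (4) for traits with two SROs, compares the
observed penetrance of deletions spanning both regions against the
heterogeneity-model expectation to flag possible epistasis. The package
ships the curated 38-patient 2p15p16.1 microdeletion cohort as its worked
fixture, together with an hg19 gene table for the region.

## Coordinate conventions

Published deletion tables print 1-based start/stop positions with a size
column equal to `stop - start`; the packaged cohort reproduces all 38
printed sizes under exactly this convention, so intervals are treated as
start-inclusive and stop-exclusive throughout. Two intervals overlap when
they share at least one base (`a.start < b.stop && b.start < a.stop`);
abutting intervals do not overlap. A point `p` "stabs" an interval when
`start < p <= stop`, i.e. `p` names the interval's last covered base. BED
and bedGraph exports subtract 1 from the start only, which is the UCSC
0-based half-open dialect; reading a written track recovers the printed
coordinates exactly.

One convention was inferred from the published values rather than stated
anywhere: the cohort's printed median deletion size is reproducible from the
printed sizes only as the *lower* middle order statistic (the 19th of 38
sorted values), so `size_summary()` reports the lower median (quantile
type 1). The printed mean is not reproducible from the printed sizes under
any rounding convention we tried; `size_summary()` reports the arithmetic
mean of the table as shipped.

## SRO delineation

`identify_sros()` uses greedy minimal interval stabbing: sort the penetrant
deletions by stop; take the uncovered deletion with the smallest stop and
use that stop as a stab point; mark every deletion containing the point as
covered; repeat. The earliest-end rule is optimal for one-dimensional
interval piercing, so the number of SROs is the minimum number of loci
needed to explain every penetrant deletion — the tests verify this against
exhaustive search on random instances.

Each SRO's *region* is the intersection of the penetrant deletions that
contain its stab point **and no other stab point**. Deletions spanning two
or more stab points are compatible with any one of those loci driving their
phenotype, so they carry no localizing information for an individual SRO;
letting them shrink a region mixes evidence across loci. On the packaged
cohort this choice is decisive in one place: one very large deletion
overlaps the end of the microcephaly SRO1 neighborhood by 2.9 kb while also
spanning the second stab point, and including it would collapse SRO1 to an
intergenic sliver instead of the BCL11A/PAPOLG region the per-pattern
penetrance counts require. Ties on stop are broken by smaller start, then
patient id; SROs are reported sorted by position and are provably pairwise
disjoint under this construction.

Two properties worth stating explicitly: adding non-penetrant deletions
never changes the SRO set (they are not inputs), and every penetrant
deletion overlaps at least one SRO. The converse caution also matters: a
penetrant *phenocopy* — a patient whose trait is unrelated to the deleted
region — either founds its own spurious SRO or, if its deletion happens to
contain exactly one stab point, joins that SRO's defining set and can pull
a region boundary off the true locus. This is structural to SRO logic, not
an implementation artifact; the synthetic validation below quantifies it,
and the packaged cohort itself contains a plausible example (the
neurodevelopmental-delay SRO defined by a single small EHBP1 deletion).

## The window posterior

Within one SRO, `tile_windows()` lays non-overlapping windows (default
1 kb, the final window may be shorter), and `window_posterior()` assumes the
SRO contains exactly one DL, uniform over windows a priori. The evidence
set for SRO *s* is every assessed deletion sharing a base with *s*.
Conditional on the DL lying in window *j*:

* deletions overlapping window *j* are carriers; with an unknown carrier
  penetrance given a Beta(*a*, *b*) prior (default uniform, a = b = 1),
  their k penetrant of n contribute the Beta-binomial marginal
  B(k + a, n − k + b) / B(a, b);
* a penetrant deletion that misses window *j* must be a phenocopy:
  factor *f* (default 0.01);
* a non-penetrant deletion that misses window *j* is an unaffected
  non-carrier: factor 1 − *f*.

Probabilities are normalized to sum to 1 within the SRO (the SRO contains
the DL by construction). `gene_cumulative_probability()` sums window mass
over each gene span (cp), and `export_profile()` writes raw and log10
tracks; log10 values are floored at −300 so browsers accept the file.

Two modeling choices deserve comment. First, the phenocopy default
f = 0.01 avoids hard zeros: with f = 0 a single penetrant deletion that
misses a window would exclude it outright, which is brittle against
breakpoint error; f = 0 remains available and shrinks support to windows
missed by no penetrant deletion. Second, when a trait has several SROs, a
penetrant deletion overlapping another SRO could be "explained elsewhere"
and exempted from the factor *f* for windows it misses. We expose this as
`explain_other_sros` but default it to off: penalizing every penetrant miss
concentrates mass where penetrant coverage is deepest, and on the packaged
cohort it is what places the posterior maximum on XPO1 inside both
XPO1-region SROs of the neurodevelopmental-delay analysis — the exemption
flattens those profiles and hands the top rank to a gene favored only by
window count. Because the published cp values come from a likelihood that
is not restated in the source analyses, cp values here are treated as rank
statements, never as numeric reproduction targets.

The posterior has a monotonicity guarantee the tests exercise: adding one
non-penetrant deletion covering window *j* never increases window *j*'s
posterior relative to an untouched window (at the default prior this holds
whenever the window's carrier count is below roughly 1/f, far above any
realistic cohort).

## Penetrance and the heterogeneity model

`penetrance_ci()` reports k/n with a 95% Wilson score interval by default —
well-behaved at the tiny denominators these cohorts produce and exact at
k = 0 and k = n — with Clopper–Pearson available. For a trait with two
SROs, `interaction_assessment()` computes the expected penetrance of
deletions spanning both regions if the loci act independently,

p_hm = p1 + p2 − p1·p2 = 1 − (1 − p1)(1 − p2),

from the exact single-SRO fractions, never from rounded decimals. The label
is a point-estimate comparison: observed above p_hm suggests epistasis,
observed at or below it (ties included, conservatively) is consistent with
independence. No significance machinery is attached — with group sizes of
5–17 none would be honest — but an exact binomial tail probability of the
observed count under p_hm is reported as descriptive context.
`gene_group_penetrance()` applies the same estimator to deletions grouped
by driver-gene hemizygosity (by default BCL11A alone, USP34/XPO1 alone, or
all three).

## The synthetic generator

`simulate_cohort()` emulates the structure of a curated deletion case
series: one deletion per patient over a multi-megabase region (default: the
fixture's chr2 span), log-normal sizes parameterized by the median (default
2.39 Mb, dispersion 0.5 on the log scale, truncated to 50 kb and the region
length), one or two hidden DLs with carrier penetrances p1, p2, a
both-carrier penetrance defaulting to the heterogeneity value, a phenocopy
rate f for non-carriers, and an assessment rate. Midpoints are drawn
uniformly over the sub-range where the deletion fits, so realized sizes
follow the configured law exactly (clipping at region boundaries would
deflate the size distribution). The default loci sit 4 Mb apart: recovery
of two loci by interval stabbing requires their separation to comfortably
exceed the typical deletion size, otherwise carriers of one locus routinely
contain the other locus's stab point and blur the region boundaries — at
1 Mb separation with 2.4 Mb deletions, even phenocopy-free recovery fails
in roughly one seed in seven.

What the generator does *not* emulate: ascertainment (real syndrome cohorts
are collected because patients are affected, concentrating deletions over
the critical region), breakpoint hotspots, measurement error on
breakpoints, multi-trait correlation, and inheritance. Passing synthetic
tests therefore demonstrates the estimators' statistical behavior under the
stated model, not robustness to those real-data features.

Measured behavior under the defaults (all reproducible via
`analysis/05_synthetic_validation.R` and the test suite): with n = 200,
p1 = p2 = 0.6 and no phenocopies, SRO delineation recovers exactly two
regions, each containing its true locus, in ≥95% of seeds, and the Wilson
intervals of the single-SRO pattern estimates cover the true penetrance
near the nominal rate (slightly below it, because deletions that overlap a
region without covering its locus dilute the group toward the phenocopy
rate). At the default f = 0.01, about one penetrant phenocopy arises per
cohort and recovery of both loci drops to roughly nine seeds in ten —
the quantitative form of the phenocopy caveat above. The epistasis label
fires in ≥90% of seeds when the simulated joint penetrance is inflated 1.5×
over p_hm, while under exact independence it fires at the ~50% rate that a
strict point-estimate comparison implies (the region-dilution just
mentioned adds a few points of systematic excess on top of the noise; a
truth-based grouping shows none).

## Numerical and degenerate-input choices

Likelihoods are computed in log space with `lbeta()` and normalized after
subtracting the finite maximum; f = 0 contributions are handled as exact
zeros rather than `0 * -Inf`. Penetrance is undefined (an error) when no
patient is assessed; a trait with assessed patients but no penetrant
deletion yields a structured no-SRO report with a warning rather than an
error. Cohort validation rejects duplicate patient ids, `stop <= start`,
and trait values outside `{+, -, na}`, naming the offending row. All
fixture-path computations are deterministic; report bundles are
byte-identical across reruns.

## Known limitations

The per-SRO posterior conditions on one DL per SRO and cannot represent two
loci inside one region. Breakpoint uncertainty is not modeled; the packaged
analyses use printed coordinates as exact, and the source cohort itself
contains one SRO split that finer breakpoint data might merge. The
epistasis call is a descriptive comparison of point estimates, with all the
fragility that implies at n ≤ 17. Region-based grouping attenuates
single-SRO penetrance estimates toward the phenocopy rate, which slightly
inflates both p_hm's inputs' downward bias and the epistasis-label rate
under independence. Problem sizes used in the shipped validation (100 seeds
at n = 200; one draw at n = 10,000) were chosen as the smallest sets that
make the Monte-Carlo bounds in the tests meaningful.
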