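---
title: "Autoantibody profiling and symptom association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoantibody profiling and symptom association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serosym)
```

## The problem

Antigen-array serology measures IgG reactivity of an individual's plasma
against hundreds to tens of thousands of protein fragments. In psychiatric
cohorts the scientific question is whether particular autoantibodies — or a
person's overall autoantibody burden — track clinical features such as
psychopathology symptoms, medication use, or cytokine levels. Two assay
formats are involved: planar protein microarrays (very wide, low
throughput, screened at the pooled-group level) and bead-based suspension
arrays (a few hundred antigens, one measurement per individual). serosym
implements the complete analysis chain for this design: broad-screen
selection, per-sample normalization, data-driven seropositivity cutoffs,
count stratification, a symptom-association screen, and a sensitivity
analysis — plus a synthetic cohort generator with planted ground truth so
that every stage can be validated without access-restricted patient data.

## Planar screening

Each pooled array's raw intensities $X$ are standardized per array,

$$\mathrm{timesSD} = \frac{X - \mathrm{mean}(X)}{\mathrm{SD}(X)},$$

and an antigen enters the follow-up panel when its standardized signal is
at or above 8 SD in at least one pool (inclusive threshold). The SD is the
sample SD ($n-1$); the mean and SD are taken over all antigens on the
array, with no exclusions. The 8-SD rule is deliberately stringent: at
array widths of $10^3$–$10^4$ antigens the expected number of Gaussian
false positives per array is far below one.

## Bead-array normalization and scoring

Raw bead-array MFI carries sample-specific background level and spread, so
each sample (row) is normalized by its own robust location and scale:

$$\mathrm{xMAD} = \frac{\mathrm{MFI} - \mathrm{median}(\mathrm{MFI})}{\mathrm{mad}(\mathrm{MFI})}.$$

By default the MAD carries the normal-consistency factor 1.4826 (the
`stats::mad` default in the environment this analysis style originates
from); `mad_constant = 1` gives the raw MAD. The choice rescales all xMAD
values per sample by a common factor and is exposed because the method
description alone does not pin it down.

xMAD values are then discretized onto a 16-level score scale with
left-closed, right-open bins of width 5:
score 0 for $x < 0$; 0.1 for $0 \le x < 5$; 0.2 for $5 \le x < 10$; … 1.4
for $65 \le x < 70$; and 1.5 for $x \ge 70$. Zero itself scores 0.1. Scores
are exact tenths internally (an integer bin index divided by ten), and
every downstream comparison of scores with cutoffs is done on integer
tenths, so floating-point bin-edge artifacts cannot change a call.

## Detection cutoffs

For each antigen the cohort's score vector is smoothed with a Gaussian
kernel density estimate and a cutoff is chosen by walking away from the
tallest peak:

1. `stats::density()` with its defaults — Silverman's rule-of-thumb
   bandwidth, 512 grid points spanning the data range plus three bandwidths
   on each side. These defaults are conventions, not claims: the method
   description names neither kernel nor bandwidth, so both are exposed
   through the function arguments.
2. The tallest peak is located. If its position is at or below 0.75 (the
   midpoint of the score scale) the walk runs upward in $x$; otherwise
   downward. Background-dominated antigens therefore cut just *above* their
   background mass, while highly reactive antigens (background already at
   high scores) cut just *below* it, keeping the reactive majority positive.
3. At each grid step the directional slope — density change per unit score
   travelled along the walk — is computed, and the walk stops at the first
   grid point at which the slope has fallen strictly below $-0.5$. We read
   "the first point where the slope passed the threshold" as the far end of
   the crossing segment. The near end is the discretized peak itself
   whenever the density is sharply peaked (the usual case for score data),
   and the discretized peak falls on either side of the peak's score level
   essentially at random; rounding up from it would then arbitrarily
   include or exclude the entire background population. The far endpoint is
   stable: one grid step past the peak, strictly beyond the peak's score
   level.
4. The stopping position is rounded up to the nearest score step and
   clamped into $[0, 1.5]$.

Individuals scoring at or above the cutoff are seropositive (inclusive
comparison). Degenerate inputs are handled explicitly: a constant score
vector gets a cutoff one step above the constant (all seronegative, with a
warning), and a walk that reaches the grid end without crossing uses the
grid end (rounded, clamped, with a warning).

### A resolution limit worth knowing about

When a minority of the cohort sits one score level below the majority
(e.g. 15% at score 0, 85% at 0.1) and the minority fraction drops below
about 25%, the lower quartile of the scores equals the majority level, the
IQR collapses to zero, and Silverman's rule falls back to the raw SD —
which is inflated by the reactive tail. The oversized bandwidth merges the
two background modes into a single peak *between* the score levels, and the
cutoff then lands on the majority level, calling the whole majority
positive. This is a property of the published algorithm under standard
density defaults, not of this implementation. The cutoff-recovery test
battery therefore uses "well-separated" antigens: background either
concentrated on a single level or split with a minority fraction of at
least 30%. On real data, antigens whose background straddles two score
levels in this ratio range should be reviewed manually.

## Autoantibody counts and stratification

An individual's autoantibody count is the number of antigens they are
seropositive for. The count distribution is summarized per individual and
per detected antigen, with Shapiro–Wilk assessing normality of the former.
Individuals below the 5th or above the 95th count percentile form the
"low" and "high" strata; membership is strict (boundary values belong to
neither), and percentiles use linear interpolation between order statistics
(quantile type 7). The convention is configurable because published
threshold values derived from percentile rules are not always internally
consistent; this implementation always computes the percentile from the
data and reports the resulting threshold rather than hard-coding one.

Each stratum is compared against all remaining individuals on a targeted
set of dichotomous clinical variables, plus cytokine concentrations
median-dichotomized with the median in the lower interval. Tables are
pairwise-complete (an individual missing one variable is dropped from that
variable's table only). These characterizations are explorative and carry
no multiplicity correction, which is stated in the output documentation
rather than hidden.

Profile similarity between individuals is examined with complete-linkage
hierarchical clustering on Euclidean distances (`stats::dist` +
`stats::hclust`, the canonical implementations; an $O(n^3)$ brute-force
agglomeration in the test suite independently verifies the merge heights).

## The association screen

Every (antigen, symptom) pair is assessed against three criteria plus an
FDR-controlled significance gate:

* **group size** — at least 10 seropositive individuals (antigen-level,
  full cohort), about 2% of a ~460-person cohort;
* **symptom prevalence** — $P(\mathrm{Sx}\mid\mathrm{Pos}) \ge 0.85$;
* **prevalence ratio** — the symptom at least 25% more prevalent among
  seropositive individuals. The default reads this as a ratio,
  $P(\mathrm{Sx}\mid\mathrm{Pos}) / P(\mathrm{Sx}\mid\mathrm{Neg}) \ge 1.25$,
  consistent with reporting the quantity as a "PR" column; a configuration
  switch provides the additive percentage-point reading, since the verbal
  phrasing admits both;
* **significance** — Benjamini–Hochberg adjusted $q < 0.05$.

The BH family is all pairs passing the group-size criterion (symptoms
constant or absent in the cohort are untestable and excluded). This is the
most conservative defensible family: the group-size rule is a data-independent
pre-filter at the antigen level, while prevalence-based criteria are
outcome-dependent and therefore must not shrink the corrected family.
Criteria are evaluated on exact fractions; rounding to whole percent and
one-decimal PRs happens only in the presentation formatter.

The exact test is the classical two-sided Fisher test: the p-value sums
hypergeometric probabilities no larger than the observed table's
(`method = "minlike"`, the default, matching `stats::fisher.test` and the
default of the dedicated 2×2 packages in this field), with the
conditional maximum-likelihood odds ratio and the exact central 95%
interval. A central two-sided p (twice the smaller tail) is available as
`method = "central"`. Zero cells produce 0/Inf estimates and bounds, which
the formatter renders symbolically. Note that matching-interval CIs (which
some 2×2 packages pair with the minlike p) can be narrower than the
central interval reported here; the point estimates are identical.

## Sensitivity analysis

Cutoffs are varied one at a time — count percentiles, each selection
criterion, and a uniform ±1 score-step shift of every detection cutoff —
and each baseline finding (selected associations; significant stratum
characteristics) is re-evaluated at each grid point, re-running only the
affected downstream stages. Grid points that make a stage degenerate (an
empty stratum) are recorded as not evaluable rather than failing. The
default grids are symmetric one-step neighborhoods around the baseline:
percentiles {(2.5, 97.5), (5, 95), (10, 90)}, minimum group size
{5, 10, 15}, minimum prevalence {0.80, 0.85, 0.90}, minimum PR
{1.15, 1.25, 1.35}, cutoff shift {−1, 0, +1}.

A practical note: shifting all cutoffs down by one step turns
background-level cutoffs (0.1) into zero, which makes *everyone*
seropositive for those antigens and dilutes any association past its
prevalence criteria. Associations carried by sparse antigens are therefore
expected to be lost at the −1 cutoff point; that is informative output, not
a defect.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the pipeline is designed
for, with known ground truth:

* **Background**: per-sample location and scale are lognormal (medians
  ~2000 and ~100 MFI); within-sample noise is Gaussian (0.55 sample-scale
  units). The pipeline only assumes that the per-sample median and MAD are
  meaningful, so the distributional families are conventions chosen for
  realism, not claims about the assay.
* **Antigen offsets**: each antigen's background sits at −2 or +2
  sample-scale units (±0.7 spread), bimodally. After per-sample median/MAD
  normalization this concentrates an antigen's background on score 0 (low
  group) or 0.1 (high group), which reproduces the empirical cutoff pattern
  (0.1 and 0.2 dominate) and the left-skewed per-antigen count distribution,
  including occasional borderline antigens with several hundred positives.
* **Seropositive spikes**: per-antigen seroprevalence rates are lognormal
  (left-skewed, median well below the mean), scaled so their mean equals
  `spike_rate` (default 25/380), giving per-individual true counts that are
  approximately normal around 25 — with ~68 antigens assigned rate zero to
  emulate an undetected fraction. Spike displacements are heavy-tailed
  (20 + lognormal sample-scale units), which lands called spikes across
  scores 0.2–1.5.
* **Planted associations**: each planted antigen receives an exact number
  of seropositive individuals, and symptom status is assigned with
  deterministic counts (`round(prevalence × group size)`) among positives
  and negatives, so the realized contingency table satisfies the planted
  margins *by construction* (defaults: 25 positives, 96% vs 40%
  prevalence). Infeasible margins — margins that do not strictly exceed
  the selection criteria — fail immediately rather than silently
  retrying. Planted antigens are drawn only from the safely-low part of
  the low-offset group, because antigens near the sample median leak
  background positives into the called group and would dilute the planted
  prevalence. Planted symptom columns are exempt from missingness so the
  margin guarantee stays exact.
* **Everything else**: distractor symptoms are independent Bernoulli with
  prevalences uniform on (0.1, 0.7); clinical variables and cytokines are
  independent of the profiles by default (2% MCAR missingness), and an
  optional logistic effect ties the odds of being female to the true count
  for stratification tests.

What the generator does *not* emulate: optical or bead-level physics,
batch and plate effects, antigen cross-reactivity, correlated symptom
structure, and longitudinal sampling. Tests passing on this generator
therefore establish the pipeline's correctness and its behavior under the
intended data shape — not robustness to assay artifacts absent from the
model.

## Numerical choices and problem sizes

* Scores and cutoffs compare as integer tenths; KDE uses `stats::density`
  defaults; the walk's first crossing is strict (`< −0.5`); cutoffs clamp
  to [0, 1.5] except for the degenerate constant-vector case, which places
  the cutoff one step above the constant so everything is seronegative.
* The BH adjustment is `stats::p.adjust(·, "BH")`; the test suite verifies
  it against a brute-force sort-and-cummin implementation, the exact test
  against direct hypergeometric enumeration (for tables with total ≤ 60),
  and the conditional-MLE OR against an independent root-finder on the
  noncentral hypergeometric mean equation.
* Test problem sizes: unit and property tests run on cohorts of 200 × 80
  (40 symptoms, 3 planted pairs), batteries of 100–120 constructed
  antigens at cohort size 461, and an end-to-end acceptance cohort of
  500 × 400 with 6 planted pairs. The full suite completes in well under a
  minute; the analysis scripts run the full 461 × 380 design in seconds.

## Limitations

* The cutoff algorithm's bandwidth-driven resolution limit described above.
* The generator's planted associations are pairwise independent; the screen's
  behavior under correlated antigens or symptoms is untested.
* Exact-test confidence intervals are central; matching intervals would be
  needed to reproduce some published interval widths exactly.
* With ~50,000 tested pairs the discrete exact test plus the triple criteria
  make false selections rare far beyond what the nominal FDR suggests; the
  FDR level is therefore best read as an upper bound, not an estimate of the
  realized false-discovery proportion.
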