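---
title: "Utilisation-based population segmentation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utilisation-based population segmentation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsegment)
```

`popsegment` segments a GP-registered population by how it uses care: seven
annual utilisation counts per patient — non-elective and elective inpatient
admissions, outpatient first and follow-up attendances, GP visits, distinct
drugs prescribed, A&E attendances — are clustered, and the resulting
segments are classified and profiled. This vignette explains the statistical
machinery, the package's defaults, and the design choices made where the
methodology was genuinely open.

## The clustering model and its assumptions

Patients are represented as points in a 7-dimensional count space. Each
variable is z-scored (sample mean and sample SD, denominator $n-1$) so that
every care setting contributes equally to the Euclidean distance; without
this, high-count variables such as prescribing would dominate. Two
consequences are worth keeping in mind:

* clustering is distance-based, not model-based — segments are compact
  regions of utilisation space, with no likelihood or posterior attached;
* z-scoring makes the analysis invariant to the units of any one variable
  (a property the test suite checks), but it also means segment geometry
  depends on the cohort's own dispersion.

The seven clustering inputs must be complete and non-negative integers.
Records violating this are fatal in strict validation or dropped (and
counted) otherwise; clustering distance is undefined on missing coordinates,
so imputation is deliberately out of scope. Profiling attributes may be
missing; summaries then use pairwise-complete values.

## Choosing the number of segments

Hierarchical clustering offers stopping rules that do not require fixing k
in advance, but it scales poorly and is outlier-sensitive, so it is run on
random subsets only: by default `n_subsets = 10` subsets of
`subset_size = 3000` patients, drawn without replacement within a subset and
independently across subsets, scanning `k_range = c(2, 20)`.

On each subset a Ward-linkage tree is built (`stats::hclust`, `ward.D2`) and
two indices are traced:

* **Calinski–Harabasz pseudo-F** at the k-group cut,
  $F(k) = \frac{B/(k-1)}{W/(n-k)}$, with $B + W$ equal to the total sum of
  squares about the grand mean. Its trace typically declines gently and is
  emitted for inspection rather than used to decide.
* **Duda–Hart** $Je(2)/Je(1)$ with **pseudo-T²** for the split taking the
  k-group cut to k + 1 groups: $Je(1)$ is the within-SS of the cluster being
  split, $Je(2)$ the summed within-SS of its two children,
  $T^2 = \frac{Je(1)-Je(2)}{Je(2)/(n_1+n_2-2)}$, and algebraically
  $Je(2)/Je(1) = 1/(1 + T^2/(n_1+n_2-2))$ — an identity the tests verify on
  every split.

### Operationalising the stopping rule

The qualitative rule — stop where the Duda–Hart index is high and pseudo-T²
low, with high pseudo-T² nearby — needs a concrete decision procedure. An
obvious reading, "flag k where pseudo-T² is a local minimum", turns out to
be wrong in a way worth recording: pseudo-T² is proportional to the size of
the cluster being split, so beyond the true number of clusters it keeps
falling as clusters shrink, and the true k is *not* a local minimum. What
identifies the true k is a **cliff**: the split from k − 1 to k separates
genuine clusters (huge T², tiny Duda–Hart), while the split from k to k + 1
cuts through a coherent cluster (small T², high Duda–Hart). The package
therefore flags k as a candidate when `pseudo_t2(k) < pseudo_t2(k-1)` and
`dh_index(k) > dh_index(k-1)`, and each subset suggests the flagged k with
the largest evidence contrast `pseudo_t2(k-1) / pseudo_t2(k)` (ties to the
smallest k). On planted-cluster cohorts this recovers k = 2, 3 and 10
unanimously across subsets and seeds; the local-minimum reading never
recovered the planted k in our experiments.

Subsets with no flagged candidate abstain; if all abstain the selection
errors out and asks for a manual k — structureless data should not silently
produce a cluster count. The consensus across subsets is the **median** of
the suggestions (half-integer medians resolve toward the modal suggestion),
chosen over the mean for robustness to one or two wild subsets. The full
per-subset trace is always returned (`tidy()`, `autoplot()`) so an analyst
can override the consensus.

Three further unreported details had to be fixed by design: the linkage
(Ward, because both stopping indices are within-SS quantities; average and
complete are available by configuration), the standardisation denominator
(sample SD, $n-1$), and whether subsets may overlap (they may; independence
is the weaker assumption).

## k-means on the full cohort

The final segmentation fits k-means with Lloyd's algorithm on the z-scored
variables: assign each patient to the nearest centroid (squared Euclidean;
ties to the lowest centroid index), recompute centroids as assigned means,
stop when the relative objective decrease falls below `tol = 1e-6` or after
`max_iter = 300` iterations. Initialisation is k-means++ with
`restarts = 10` seeded starts, keeping the lowest objective; a cluster
emptied during iteration is re-seeded with the point currently farthest
from its centroid. On tiny instances the fit attains the exhaustively
enumerated optimum in ≥95% of seeded runs (tested), and the objective trace
is non-increasing by construction. Segments are renumbered 1..k by
decreasing size (ties by original id) so runs are comparable.

## Need and complexity classification

Each segment's mean count per setting is divided by the population mean
(settings with zero population mean are flagged and excluded). With the
default thresholds a segment is **high need** if any ratio exceeds 2
(more than 100% above the population mean) or at least 4 ratios exceed 1.2,
and **high complexity** if at least 4 ratios exceed 1 — strict inequalities,
matching the "more than" wording of the rule. The classifier is monotone in
segment means and scale-invariant (both tested properties), reports every
qualifying setting, and `compare_characterisation()` diffs its output
against any supplied reference labels. The rule is never adjusted to match
a reference: applied to the built-in reference profiles it disagrees with
the published characterisation on six of ten segments (single-setting
ratios above 2 fire high need for segments 3, 5, 8 and 10; above-mean
counts in 4+ settings fire high complexity for 2, 3 and 7), and the package
surfaces exactly that disagreement. The thresholds, the minimum setting
counts and the settings list are all configurable so alternative readings
can be run.

## Profiling and the test battery

Per-segment summaries use sample SDs and pairwise-complete observations;
the population row of every mean-type variable equals the
population-weighted mean of the segment means (tested to 1e-9). Cost
summaries report each segment's total, per-head cost, cost share and the
cost-to-population ratio (cost share over population share).

The test plan follows variable type: utilisation counts and the LTC count
are non-Normal, so Kruskal–Wallis globally and Mann–Whitney pairwise; age
and the emergency-admission risk score use ANOVA and t-tests; proportions
use a k×2 chi-square and pooled two-proportion z-tests. Choices the
methodology left open:

* pairwise **t-tests use the Welch correction** by default (a
  pooled-variance switch exists): unequal segment variances are the norm;
* **Mann–Whitney** uses the tie-corrected normal approximation without
  continuity correction — segment sizes here are far beyond where exactness
  matters;
* the **z-test** pools the variance, so its square equals the uncorrected
  2×2 chi-square statistic (tested identity); no continuity correction;
* the **Bonferroni divisor is k − 1 = 9**, the comparisons of one segment
  against each other segment (0.05/9 = 0.0056), not the 45 unordered pairs;
  configurable, but the default matches how the adjusted level is used for
  the per-segment annotation tiers (differs from all k−1 / k−2 / k−3
  others);
* p-values are kept at full precision; formatting decisions belong to
  output layers.

Under a null cohort (all segments from one distribution) the familywise
rate of pairwise flags per segment-variable family stays within the
Bonferroni bound — verified by simulation (500 cohorts) in the test suite.

## The synthetic cohort generator

Real linked NHS records cannot ship with a package, so the generator
emulates the structure the analysis assumes. Its default parameterisation
(`default_generator_config()`) is a ten-segment finite mixture whose
weights, utilisation means, age, deprivation, smoking, risk-score, LTC and
frailty parameters are the built-in reference profiles of a deprived
GP-registered population of 79,607 patients
(`segment_reference_profiles()`): a dominant low-utilisation segment
(~50%), rare very-high-utilisation segments (~1%), and segment-specific
morbidity gradients.

Distributional forms are stand-ins with matched first (and where published,
second) moments, because only means and SDs are available:

* **counts**: negative binomial with mean $m$ and variance $m + m^2/\theta$
  ($\theta$ = `util_dispersion`, default 1) — chosen because the published
  SDs exceed the means almost everywhere, ruling out Poisson; degenerate at
  zero when $m = 0$;
* **age**: normal truncated to [0, 105] years; **booleans**: independent
  Bernoulli; **risk score**: beta with moments matched to the published
  mean/SD (infeasible moment pairs are a hard error);
* **cost**: unit prices × counts plus half-normal noise. The prices are
  plausible GBP tariffs, deliberately *not* calibrated to reproduce any
  published per-head cost — published cost checks are run on the reference
  table itself, not on synthetic data.

What the generator does **not** emulate: correlations between conditions
(flags are independent given the segment), within-segment correlation
between utilisation variables beyond what the mixture induces, published
per-segment SDs, or bed-day distributions. Tests passing on synthetic data
therefore demonstrate that the machinery recovers structure of this
mixture type — not that real utilisation data has that structure.

`generate_planted_gaussians()` is the method-recovery harness: k spherical
unit-SD Gaussian clusters in utilisation space, rounded to non-negative
counts, with true labels in a separate column that clustering never sees.
Centroids are drawn as a seeded isotropic cloud rescaled so the minimum
pairwise distance equals the requested separation. The isotropic layout
matters: separation concentrated on one axis does not survive per-axis
standardisation (the axis with the separation gets shrunk relative to the
noise in the others), whereas an isotropic spread keeps the geometry stable
under z-scoring.

## Determinism and numerical choices

Every source of randomness derives from one seed: subset draws, k-means++
restarts and cohort synthesis each obtain stage seeds from a fixed
congruential split, so partial re-runs reproduce. Degenerate inputs have
defined behaviour throughout: zero-variance utilisation variables abort
standardisation by name; $W = 0$ partitions report an infinite pseudo-F;
$Je(1) = 0$ leaves the Duda–Hart index undefined (missing) and $Je(2) = 0$
makes it 0 with infinite pseudo-T²; pairwise tests on segments with fewer
than two observations are reported missing rather than guessed.

Problem sizes used by the packaged checks — subset-based selection on
planted cohorts of 30,000 (10 subsets of 3,000, the default study design),
end-to-end runs at 20,000, moment checks at 50,000, 500 null-cohort
simulations for the type-I bound — were chosen to exercise the defaults at
realistic scale while keeping a full run in a few minutes on one core.

## Known limitations

* The hierarchical linkage, k-means initialisation and restart policy
  behind any previously published utilisation-based segmentation are
  rarely reported; this package's defaults are
  reproducible choices, not a replication recipe, and segment memberships
  on real data would not be expected to match any prior analysis exactly —
  only the structure of the procedure.
* The need/complexity rule is sensitive to single-setting ratio spikes
  (one setting above double the population mean suffices for high need);
  the configurable thresholds exist precisely because reasonable analysts
  may prefer stricter multi-setting readings.
* Cost figures in the reference table are printed rounded; ratios
  recomputed from them (e.g. a cost-to-population ratio of ~10.8 for the
  highest-cost segment) differ from the published ratios computed on
  unrounded costs (11.11), so printed ratios are reported as-is in the
  reference table while recomputations carry their own arithmetic.
* The generator's independence assumptions understate the co-occurrence of
  long-term conditions; prevalence profiles are marginally correct per
  segment but joint morbidity patterns are optimistic.
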