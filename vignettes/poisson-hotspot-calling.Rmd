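---
title: "Poisson error-model calling on RAS/BRAF hotspot panels"
author: "amplicall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson error-model calling on RAS/BRAF hotspot panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicall)
```

## The problem

Anti-EGFR therapy in colorectal cancer fails in the presence of activating
mutations in KRAS, NRAS or BRAF, so clinical assays interrogate a small set
of recurrently mutated codons — 12, 13, 59, 61, 117 and 146 of KRAS and
NRAS, and 600 of BRAF — in DNA from FFPE tissue or plasma. Amplicon deep
sequencing reads each of these positions tens of thousands of times, which
in principle resolves mutant fractions below one percent. In practice the
limiting factor is not depth but the background of non-reference reads
introduced by PCR and sequencing error: a caller must decide, position by
position, whether an observed non-reference count exceeds what that
position's own error process would produce.

`amplicall` implements that decision as a calibrated Poisson test, plus
everything needed around it: error-model calibration from normal samples,
exclusion of systematically noisy positions, data-driven selection of the
calling threshold, a simulation-based limit-of-detection estimator,
inter-assay concordance statistics, and a synthetic-data generator with
the statistical structure the method assumes.

## The model

For a panel position with reference base $r$ and an alternate base $b$, let
$x$ be the count of $b$-reads in a sample sequenced to depth $d$ at that
position. Calibration on $n$ normal (mutation-free) samples yields, for
every channel $(\text{position}, b)$, the per-sample error rates
$e_i = x_i / d_i$, their mean $\bar e$ and their across-sample standard
deviation $s$ (the $n-1$ estimator; with $n = 10$ the unbiased form
matters). The null hypothesis for a new sample is that its $b$-count is
background error only, with expectation

$$\lambda = (\bar e + k\,s)\, d,$$

where $d$ is the *new sample's* depth at that position and $k$ is a
conservatism knob (the SD multiplier). The channel is called
mutation-positive when the upper-tail Poisson probability

$$P(X \ge x \mid X \sim \mathrm{Pois}(\lambda)) < \alpha,
\qquad \alpha = 2 \times 10^{-5},$$

using a strict inequality. Equivalently, every $\lambda$ implies a minimum
read count `min_positive_count(lambda, alpha)`; the two formulations are
cross-checked against each other in the test suite.

Two modelling choices deserve comment, because the procedure is often
stated loosely as "$\lambda$ = ER + SD":

* **Depth enters multiplicatively.** A rate plus a rate is a rate; a
  Poisson test needs a count. Scaling the padded rate by the sample's own
  depth is the only reading under which the test is well defined across
  samples whose depths differ by a factor of four, so that is what
  `call_sample()` does.
* **The null rate is per alternate channel.** The dominant artifact on
  this panel is a position-specific G>A excess; a per-channel null
  prevents a noisy G>A channel from inflating $\lambda$ for a genuine G>T
  variant at the same position. Position-level *exclusion*, by contrast,
  uses the aggregate non-reference rate (all three alternates summed),
  which is how the error rate for a position is conventionally defined.
  Both rates live in the fitted `error_model` object.

## Calibration and position exclusion

`error_model()` is the package's central fitting function. Besides the
per-channel $(\bar e, s)$ pairs it records each position's aggregate error
rate, and marks as non-evaluable any position whose aggregate rate exceeds
`exclude_threshold` (default 0.01). On this panel three positions — KRAS
37G, KRAS 175G and NRAS 351G, all with a large G>A artifact (aggregate
rates roughly 0.18, 0.30 and 0.023 versus at most 0.007 elsewhere) — fail
that bar and are excluded from all calling. The default threshold of 0.01
is the smallest round value that separates those three from the rest of
the panel; it is configurable, and `flag_high_error_sites()` reports what
any threshold would exclude. Positions with zero depth in any calibration
sample are likewise flagged non-evaluable (with a warning) rather than
aborting the fit; a cohort of fewer than two samples is an error because
$s$ is undefined.

## Choosing the SD multiplier

The multiplier $k$ trades specificity against sensitivity. `sweep_k()`
re-calls a set of labelled samples (known positives with their variant
identities, known negatives) at each $k$ in $0,\dots,7$ and tabulates
recovered truth channels, missed truth channels and false-positive calls;
`select_k()` picks the smallest $k$ that classifies every labelled sample
perfectly, falling back (with a warning flag) to the best-recovering $k$
when none does. Truth is counted per variant, not per sample: a positive
sample called with the wrong variant contributes both a false positive and
a miss. Because each sample's labels may be incomplete — a real variant
outside the labelled region can legitimately surface in a "negative"
sample — `labeled_sample()` accepts an `ignore` set whose calls count
neither way.

Larger $k$ is strictly more conservative, so false positives and true
positives are both non-increasing in $k$; the suite asserts this on every
sweep. On dispersed synthetic cohorts the false-positive count typically
collapses between $k = 1$ and $k = 3$ and is zero well before $k = 7$;
with assay data whose across-sample variability is larger or
heavier-tailed than the generator's log-normal, the fully-correct $k$ sits
higher. The default `caller_config(k_sd = 7)` reflects the conservative
end of that trade-off: specificity at $\alpha = 2\times10^{-5}$ per
channel is what a screening assay needs, and the cost in detection limit
(see below) is modest at these depths.

## Limit of detection

`estimate_lod()` is an in-silico dilution series. For a channel with
background rate $\bar e$, a replicate at mutant fraction $v$ draws its
count from $\mathrm{Binomial}(d,\ v + \bar e)$ — signal and error additive
on the rate scale, capped at 1 — and is judged by the same caller. The
estimator descends two-fold from `vaf_max = 0.5` (mirroring how dilution
experiments are actually laid out) until a fraction fails the required
positive-call frequency (`target_rate`, default 0.95), then bisects the
bracket to 10% relative precision. If even `vaf_max` fails, a
"not detectable at this depth" sentinel is returned — which is exactly
what happens at an excluded position.

The additive-binomial mixture is the simplest generative stand-in for a
true dilution; it ignores pipetting error and the quantification
uncertainty of the reference method used to measure the diluent, so
published single-measurement dilution limits (0.58%–3.92% on this panel)
should be read as a band the simulation lands in, not as point targets.
At depth $4\times10^4$ with clean-position error rates the estimator
reports LoDs of a few tenths of a percent to a few percent, declining with
depth and rising with error rate and $k$ — all asserted as monotonicity
properties on a $3\times3$ grid.

## Concordance statistics

Sample-level agreement between two assays is summarised from the 2×2
table by `percent_agreement()` ($100(a+d)/n$), `cohen_kappa()`
($(p_o - p_e)/(1 - p_e)$, `NA` with a warning when the margins are
degenerate), and `discordance_rates()` (test-vs-comparator false-positive
rate $100\,b/(b+d)$ and false-negative rate $100\,c/(a+c)$). Kappa is
reported at full precision; conventional display rounding (three decimals
for kappa, one for percentages) is applied only in print methods. On the
published 100-sample comparisons this machinery reproduces the printed
92% / $\kappa = 0.833$ (vs allele-specific PCR) and 90% / $\kappa = 0.794$
with 11.5% / 7.7% discordance (vs droplet digital PCR) exactly.
`paired_concordance()` categorises matched tumor/plasma variant sets per
gene (both-empty, identical, overlapping, one-sided, disjoint) rather than
compressing them to a single percentage, because any scalar "concordance"
over such pairs depends on an arbitrary choice of denominator.

## The synthetic generator

`simulation_profile()` plus the generators emulate what the calibration
and tuning cohorts look like statistically:

* per-position aggregate background rates drawn uniformly from
  0.0007–0.0071, the range observed on clean positions, split evenly
  across the three alternate channels;
* the three characteristic high-error positions on by default, with their
  artifact rates (0.1755, 0.3016, 0.0233) loaded onto the ref>A channel,
  so exclusion logic is always exercised;
* depths log-uniform on $2\times10^4$–$8\times10^4$, covering the
  amplicon read-number medians reported for normal, FFPE and archived
  cohorts;
* across-sample dispersion as a mean-one multiplicative log-normal jitter
  on rates (`meanlog` $= -\sigma^2/2$), default $\sigma = 0.2$. The
  mean-one parameterisation keeps the cohort-mean rate equal to the
  profile rate, so parameter-recovery tests are unbiased statements, not
  approximations.

Counts are binomial per channel with the reference count as remainder, so
generated tables satisfy the allele-count invariants by construction. What
the generator does **not** model: sequence-context- or cycle-dependent
error, FFPE deamination beyond a static G>A rate, amplicon dropout, PCR
duplicates, and read-level structure. Tests passing on synthetic data
therefore demonstrate the *statistical* correctness of the pipeline under
its own assumptions; they do not certify performance on any particular
instrument's error spectrum.

## Numerical and interface choices

* Coordinates are 1-based CDS positions on the coding strand
  ("KRAS 37G" style); no genomic liftover is provided, since the panel is
  defined and published in CDS terms. Reference codons ship in the panel
  configuration.
* Depth is defined as the sum of the four nucleotide counts; indels and
  ambiguous bases are out of scope (the assay evaluates single-base
  substitutions).
* Protein annotation is standard-genetic-code translation of the
  substituted codon (`Biostrings::GENETIC_CODE`), with `*` for stops and
  repeated amino acids for synonymous changes (`A146A`). The annotator is
  verified against an independent translation for all nine substitutions
  of every panel codon.
* No multiple-testing correction is applied across the panel's ~108
  evaluable channels by default — $\alpha$ is a per-position level, which
  is how the decision rule is defined; `caller_config(adjust =
  "bonferroni")` is available for users who want family-wise control.
* `min_depth` (default 1000) guards degenerate inputs only; the assays
  this models never approached it.
* The Poisson tail uses `ppois(k - 1, lambda, lower.tail = FALSE)`;
  `min_positive_count()` inverts it by a local search seeded at the
  quantile, exact for all tested $\lambda \le 100$ against direct pmf
  summation at $10^{-12}$ tolerance.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
calibration cohorts of 10 samples (100–200 for convergence properties),
tuning cohorts of 10 positives at 10% VAF plus 10 negatives, dilution
simulations of 300–1000 replicates per fraction, and 3×3 LoD grids at 200–400
replicates. These sizes make every property statistically decisive at the
fixed seeds while keeping the whole suite near twenty seconds on a single
core.

## Known limitations

* With only 10 calibration samples, $s$ is itself noisy; $\bar e + 7s$
  absorbs that, but channels whose calibration counts are all zero get
  $\lambda = 0$, where a single read is formally significant. The
  `min_depth` guard and the per-channel rates make this harmless at panel
  depths, but sparse calibration data on a new panel deserves a larger
  cohort.
* The tuner treats labels as exhaustive per sample apart from the
  explicit `ignore` set; unlabelled real variants otherwise count as
  false positives.
* LoD estimates inherit simulation noise of roughly the bisection
  precision (10% relative); they are estimates of the model's detection
  limit, not of any wet-lab assay's.
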