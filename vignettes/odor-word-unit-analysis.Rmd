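---
title: "Screening and ensemble statistics for odor-related word responses in single units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and ensemble statistics for odor-related word responses in single units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorunits)
```

## The analysis problem

Human microwire recordings from the medial temporal lobe yield spike trains
of isolated single units in the amygdala, hippocampus, entorhinal cortex,
parahippocampal cortex and piriform cortex while a patient performs a
continuous word-recognition task: 300 visually presented German object
words (100 shown once, 100 twice), each displayed for 0.5 s and followed by
a post-stimulus interval jittered uniformly between 1.7 and 2.3 s. Half of
the word pool refers to objects that are sources of odors; the other half
are control words matched on syllable count, corpus frequency,
concreteness, arousal, imageability and valence, so that any differential
response can be attributed to the odor aspect of word meaning rather than
to surface or affective properties.

`odorunits` implements the complete statistical pipeline from spike-time
and trial-event tables to the three levels of inference this design
supports:

1. **per-unit screening** — is a unit stimulus-responsive (post-stimulus
   firing differs from baseline), and is it odor-associated (firing differs
   between odor-word and control-word trials)?
2. **regional prevalence** — are there more flagged units in a region than
   the per-unit test's false-positive rate would produce by chance?
3. **ensemble activity** — do z-scored firing rates averaged over a
   region's whole population differ between word categories, and when?

Because the patient recordings themselves are not redistributable, the
package includes a seeded synthetic session generator with known ground
truth. Every inferential stage is calibrated and power-tested against it.

## Window firing rates and baseline normalization

Analysis is restricted to first-presentation trials (200 of the 300), so
recognition-memory effects on repeats never enter. Spike counts are taken
in five onset-locked, half-open windows: a baseline `[-200, 0)` ms and four
consecutive 500-ms windows covering `[0, 2000)` ms. Half-open boundaries
`[start, end)` are a package convention; a spike at exactly +500 ms belongs
to the second post window.

Counts convert to rates by dividing by the number of trials and the window
duration — a factor 2 for the 500-ms windows and a factor 5 for the 200-ms
baseline. The *duration-correct* baseline conversion is the default and is
worth stating prominently because it interacts with the inclusion filter:
units are retained only if their across-trial mean rate reaches 2 Hz in at
least one of the five windows, and a 200-ms baseline count of 1 per 2.5
trials means 2 Hz under the duration-correct rule but only 0.8 Hz under a
uniform half-second rule. `rate_tensor(..., baseline_conversion =
"half_second")` switches to the uniform rule for sensitivity analyses.

Rates are normalized per unit as z-scores against the mean and standard
deviation (sample, $n-1$ denominator) of that unit's baseline rates across
all first-presentation trials. By construction every retained unit's
z-scored baseline has mean 0 and SD 1 across trials; the package asserts
this to 1e-10. Units with zero baseline SD (silent or perfectly regular in
the baseline) cannot be z-scored and are excluded from z-based analyses
with a logged reason.

## Per-unit screening

Stimulus responsiveness is tested with four two-sided **paired** t-tests
(each post window against the baseline window, paired across trials);
odor association with four two-sided **unpaired** pooled-variance t-tests
(odor-word vs control-word trials within each post window; Welch is
available behind a switch). A unit is flagged when at least one of its four
tests survives the family correction — Bonferroni $p < 0.05/4 = 0.0125$ by
default, or the Benjamini–Hochberg step-up applied to the same four-test
family. The response direction (increase/decrease) is read from the sign
of the mean contrast in the most significant window; if several windows
are below threshold with conflicting signs, the smallest-p window decides.

Two-sidedness is used uniformly: both directions of rate change are real
phenomena (inhibitory responses are common), and the direction split is
reported separately in the prevalence tables. Because the paired t statistic
is invariant under the unit-wise linear transform that defines the z-score,
screening on raw and on z-scored rates flags identical unit sets — a
property the test suite asserts on simulated sessions.

Zero-variance degeneracies are guarded rather than propagated: a window
whose paired differences have zero variance gets $p = 1$ (with a warning
when the constant difference is nonzero), and identical odor/control
values likewise yield $p = 1$, never a spurious detection.

## Regional prevalence

If every unit were tested at family level $\alpha = 0.05$, a fraction
$p_0 = 0.05$ of units would be flagged by chance. For each region the
package computes the exact upper-tail binomial probability
$P(X \ge k)$, $X \sim \mathrm{Bin}(n, 0.05)$, by direct summation of the
binomial mass — no normal approximation — where $k$ of $n$ units were
flagged. The upper tail is the appropriate sidedness for a prevalence
question (only an excess of flagged units is evidence of a population
response); it is also the convention under which the package's exact
computation reproduces published regional p-values of this paradigm from
their printed counts. Display formatting rounds to the conventions of
such tables (one significant figure at four decimals below 0.01), while
machine output retains the raw p.

## Ensemble mixed ANOVA

The ensemble analysis treats units as the random observations. Each unit
contributes a 2 × T matrix of cell means — CATEGORY (odor vs control, or
living vs nonliving, or food vs nonfood) crossed with TIME (the four
500-ms windows, or twenty 100-ms windows in high-resolution mode) — and
REGION is a between-unit factor. The package implements the univariate
split-plot decomposition directly: each within-unit effect is carried by an
orthonormal contrast of the 2T cells, tested against its own
effect-by-units-within-region error stratum, with unbalanced region sizes
handled by Type III (unweighted-means) sums of squares, matching the
conventional general-linear-model treatment. With 195 units in five
regions the CATEGORY × REGION interaction has df (4, 190). Partial
$\eta^2 = SS_\mathrm{effect} / (SS_\mathrm{effect} + SS_\mathrm{error})$,
equivalently $F\,df_1 / (F\,df_1 + df_2)$, is emitted for every effect and
the identity is asserted to 1e-10.

Design choices worth recording:

- **Unit-level cell means, not trial-level values**, are the observations —
  consistent with units as the random factor and with df (4, 190).
- **No sphericity correction by default.** The 2-level CATEGORY stratum is
  sphericity-trivial, and plain degrees of freedom are the reference
  output; Greenhouse–Geisser-adjusted p-values are available via
  `mixed_anova(..., gg = TRUE)`.
- **Time-resolution invariance.** Averaging the twenty 100-ms cell means
  within a category reproduces the four-window category marginals exactly
  (z-scoring is linear and uses the same baseline statistics), so the
  CATEGORY and CATEGORY × REGION F statistics are mathematically identical
  at both resolutions — asserted to 1e-8 in the tests. Only the
  TIME-bearing strata change.
- **LSD post-hocs** are per-region uncorrected paired t-tests on unit-level
  category marginals (averaged over TIME), the literal reading of Fisher's
  LSD after a significant omnibus interaction. The classic pooled-error
  variant (difference-score SD pooled across regions, df $N - r$) is
  available via `error = "pooled"` since the toolchains that popularized
  LSD differ on this point. Cohen's d is the mean difference over the SD
  of unit-level differences (paired-difference convention; no published
  formula exists to match, so the convention is stated rather than fitted).
- **The food-within-odor control** restricts to odor-word trials of one
  region and runs a two-within-factor repeated-measures ANOVA (FOOD × TIME),
  FOOD df $(1, N-1)$ — the same machinery with the between factor dropped.

The correctness anchor is an independent oracle: on balanced designs the
implementation reproduces base R's `aov()` Error-strata decomposition to
1e-8 (Type I and Type III coincide under balance), and under the null it
is calibrated — the CATEGORY × REGION test rejects at 5.0% ± 2.5% across
500 simulated null sessions at the full 195-unit scale.

## Cluster-based permutation tests

For time-resolved inference the package estimates instantaneous rates by
binning spikes at 10 ms and smoothing with a truncated Gaussian kernel
(SD 50 ms, ±3 SD support, unit mass); both parameters are configuration
keys, since any smoothing choice is a choice. The cluster test then: (1)
computes a two-sided t statistic per bin (paired or pooled-variance
unpaired); (2) forms maximal runs of contiguous same-sign bins with
per-bin $p < \alpha_\mathrm{sample} = 0.05$; (3) scores each run by its
summed t (max-sum cluster mass, the common default of this analysis
family); (4) builds the null distribution of the maximum absolute cluster
mass from 10,000 random sign flips (paired) or label shuffles (unpaired);
and (5) assigns each cluster $p = (1 + \#\{\mathrm{null} \ge
|\mathrm{mass}|\})/(n_\mathrm{perm}+1)$, so p has resolution
$1/(n_\mathrm{perm}+1)$ and is never exactly zero. Positive and negative
clusters are formed separately and compared to the same two-sided
max-|mass| null. The result object carries both the cluster-level
p-values and the raw supra-threshold mask, so downstream plots can
distinguish cluster-level significance from mere threshold crossings.

At the ensemble level the paired test operates across units on each unit's
odor-minus-control difference of trial-averaged z-scored rates
(`ensemble_difference_series()`); at the single-unit level odor-vs-control
comparisons permute trial labels (unpaired), because odor and control
trials have no trial-level pairing.

## The synthetic session generator

`synthetic_config()` defaults encode the study conditions this pipeline is
meant for: 195 units split 57/54/22/29/33 across amygdala, hippocampus,
entorhinal, parahippocampal and piriform cortex; a 300-trial run built
from the packaged 200-word list; spiking as an inhomogeneous Poisson
process with piecewise-constant rates. Choices the recordings do not pin
down, made once and documented here:

- **Poisson emission.** The minimal model on which a t-test/z-score
  pipeline can be calibrated; refractoriness, bursting and slow
  nonstationarity are deliberately omitted, so passing calibration shows
  correctness of the statistics under the model, not robustness to every
  feature of real spike trains.
- **Baseline rates log-normal, median 4 Hz, sdlog 0.5** — most units clear
  the 2 Hz filter (about 94% of the default 195 survive), as the
  inclusion criterion presupposes; only the ≥ 2 Hz criterion itself is
  reported for the recordings.
- **Response structure.** Responsive units multiply their baseline rate by
  a gain inside a `[0.3, 1.0]` s response window (default gain 2 for
  increases; 30% of responsive units instead decrease with gain 0.5).
  The window places the bulk of the modulation in the 500–1000 ms
  analysis bin, matching the modal response latency of this paradigm; the
  screening tests' modal best window is asserted to be 500–1000 ms.
- **Odor association** multiplies an additional gain (default 2.0; 20%
  decreasing at 0.5) on odor-word trials inside the same window, for a
  per-region fraction of units defaulting to the observed prevalence
  (12% amygdala, 2–5% elsewhere). These gains are free simulation
  parameters, not estimates — no per-unit effect magnitudes are published.
- **Repeat lag** between a word's two presentations is left uniform over
  legal orderings (a uniformly random token permutation); `min_lag` /
  `max_lag` options constrain it when a specific spacing matters.
  Slow-response delays are not simulated by default — the analysis is
  stimulus-locked — but a per-trial extra delay hook exists.

With all gains at 1 the generator is an exact null: screening flag rates,
ANOVA rejection rates and cluster false-alarm rates are then required (in
the acceptance tests) to sit at their nominal levels. With the default
effect sizes, 100% of truly odor-associated units are recovered across the
fixed seed set and the amygdala prevalence test is significant in every
run.

## The packaged word fixture

`word_fixture_path()` points to a deterministic **synthetic** 200-word
property table whose per-group means and sample SDs equal the published
group moments of the matched word pool (e.g. syllables 2.1 ± 0.9 vs
2.2 ± 0.6; odor rating 5.6 ± 1.8 vs 1.5 ± 0.5). Symmetric properties use a
two-point construction $m \pm s\sqrt{(n-1)/n}$ so the sample moments are
exact; frequency, whose SD exceeds its mean, uses a skewed two-point
construction (5 high-value items per group) to stay non-negative. The
fixture reproduces the matching profile — all six matched-property t-tests
p > 0.2, odor-rating contrast p < 0.0001 — without redistributing the
original German norms, whose semantics it does not attempt to model.
Category flags mark more odor words as living (60 vs 40) and food-related
(50 vs 10), mimicking the natural confound the LIVING and FOOD control
ANOVAs exist to rule out.

Property-matching t-tests are Student (pooled-variance) by default — the
historical default of the classical toolchains, with Welch behind a
switch — computed at item level with n = 100 per group, and reported
without multiplicity correction because matching is a design check, not
inference.

## Numerical conventions and degenerate inputs

- Half-open windows throughout; shared edge vectors guarantee bitwise
  tiling at any resolution.
- Sample (n−1) SDs everywhere.
- Zero-variance guards: paired or unpaired contrasts with no variance give
  p = 1 (warning when means differ); ANOVA strata with zero total
  variation report F = 0; zero-variance time bins get t = 0 and can never
  seed a cluster.
- Direction ties (several supra-threshold windows with conflicting signs)
  resolve to the smallest-p window.
- Every stochastic function takes a seed and restores the caller's RNG
  state; identical seeds give byte-identical pipeline output files.

## Problem sizes used in the test suite

Unit tests run on scaled-down sessions (30 units, 60 trials) chosen so the
whole suite exercises every stage in a few minutes; the calibration checks
run at the full study scale — 1,000 null units for the screening
false-positive rate, 500 full 195-unit null sessions for the ANOVA
rejection rate, 500 null ensembles at 1,000 permutations for the cluster
false-alarm rate — sizes at which the binomial noise on a 5% rate is
about ±1 percentage point, small against the ±2.5-point acceptance band.

## Known limitations

- Poisson spiking cannot probe robustness to refractoriness, bursting or
  rate drift; calibration results certify the statistics under the model.
- The prevalence tests pool units across patients, as is standard for
  human single-unit work; no hierarchical patient-level model is provided.
- The LSD error-term and Cohen's d conventions are stated package choices;
  other toolchains' post-hoc numbers may differ slightly in df.
- The word fixture matches group moments, not item semantics; analyses
  that depend on per-word structure beyond the category flags are outside
  its scope.
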