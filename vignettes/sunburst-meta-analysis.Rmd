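---
title: "Chance models and strategy classification for Sunburst-maze meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chance models and strategy classification for Sunburst-maze meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunburstmeta)
library(dplyr)
```

## The problem

A Sunburst-maze experiment yields one categorical choice per subject: after
training on a circuitous route, the route is blocked and each subject
commits to one of `K` novel radial paths. Pooling such experiments is
awkward because `K` ranges from 4 to 18 across apparatus variants, sample
sizes range from a handful to dozens, and the interesting paths differ by
design. The package therefore works entirely in terms of path *roles* —
shortcut, adjacent to the training route, outermost, cued, or unremarkable
("other") — attached as flags to each path. Geometry (angles, lengths) is
never modelled: every analysis in scope consumes roles, and the flags carry
all spatial meaning. Path indices are 1-based to match source-figure
labels.

## The chance model

Under the null hypothesis of random choice, each of the `N` scored
subjects picks one of the `K` non-excluded paths uniformly. `chance_null()`
draws `R` resamples of the full experiment (multinomial reallocations of
all `N` choices — exactly equivalent to tabulating `N` iid uniform picks),
converts each to percentages, and pools all `K·R` per-path values into a
single reference with mean `mu_r` and SD `sigma_r`. Pooling is justified by
exchangeability of paths under the null and gives one chance band per
experiment rather than `K` noisy per-path bands. Two consequences are worth
noting:

* `mu_r` is *exactly* `100/K` whatever the seed, because every resample's
  percentages sum to 100.
* `sigma_r` estimates the marginal binomial SD
  `100·sqrt((1/K)(1−1/K)/N)`, available analytically via
  `closed_form_null()` and used throughout the tests as the independent
  oracle for the resampler.

Thresholds are derived, not resampled quantiles: `thr_05 = mu_r +
1.650·sigma_r` and `thr_01 = mu_r + 2.326·sigma_r` (one-sided normal
z-scores). They hold as exact arithmetic identities on the object.
"Above chance" is always *strict* exceedance: a value exactly at a
threshold is not above it. Chance normalization is the linear map
`z = (observed − mu_r)/sigma_r`.

Degenerate inputs are rejected rather than patched: `K < 2` (chance is
undefined), `N = 0` (no percentages), and `sigma_r = 0` (normalization
undefined).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `resamples` (R) | 1000 | resamples per chance distribution; raise to 10^5 for oracle-grade agreement (relative SD error scales as `1/sqrt(2KR)`) |
| `seed` | 1 | every random component is seeded; per-experiment seeds derive as `seed + i − 1` with experiments ordered by id, so results never depend on row order |
| `z_cut` | 1.96 | categorization criterion, in pooled-null SD units |
| `criterion` | `"z"` | alternatively `"p05"`/`"p01"` to categorize against the percentage thresholds, for sensitivity analysis |

The literature states two kinds of cutoffs — 1.650/2.326 for flagging
single percentages, and a 1.96-SD criterion for categorizing experiments.
Both are implemented and applied where their sources apply them; the
package does not attempt to reconcile the inconsistency, it exposes both
(`above_chance()` accepts either form).

## Categorization

`role_percentages()` averages member paths for the two-path roles
(adjacent, outer), uses the single path for shortcut and cued, and reports
"other" as the *maximum* percentage among unlabelled, non-training paths —
an unremarkable path has to win outright for an experiment to be an
"other" experiment; averaging unremarkable paths would dilute exactly the
signal the category describes. A path carrying several flags (a shortcut
that is also adjacent, as in the small-maze variant) contributes to each of
its roles.

Because the pooled null is common to all paths of an experiment,
normalizing the averaged percentage equals averaging the member paths'
z-values; the identity is asserted in the tests, and the question of which
order to apply is therefore moot.

`categorize_experiments()` picks, among roles with `z > z_cut`, the role
with the highest percentage; *exact* ties (floating-point equality, which
occurs precisely when counts are equal) resolve by the priority order
`shortcut > adjacent > outer > cued > other`. The rule intentionally favours
shortcutting, so prevalence estimates err towards the classic claim. With no
role above chance the experiment is `no_pref`.

Inclusion rules are composable, pure, idempotent filters rather than
hard-coded exclusions: `include_first_choice()` (with a whitelist for
studies that only reported mixed-order choices), `drop_lesioned()`,
`drop_untrained()` and `combine_groups()` (pre-operative groups summed into
one record). The latter three act on optional columns (`is_lesioned`,
`is_untrained`, `combine_into`) because the canonical schema has no such
fields; datasets without them pass through unchanged.

## Contrasts and group tests

The paired contrasts (`adjacent_contrast()`, `outer_contrast()`) compare
the two same-role paths of each experiment on the z scale: intersecting vs
alternative adjacent path, first-turn vs alternative, reward-side vs
alternative outer path. Experiments enter only when both paths are flagged,
the focal side is unambiguous, and at least one side is above chance — the
contrast asks *which* of the preferred paths is preferred, so experiments
indifferent to both are uninformative.

No specific group-level test is prescribed by the sources for these
panels; the package adopts a two-sided sign-flip permutation test on the
per-experiment z differences. It is distribution-free, respects the
pairing, and matches the resampling spirit of the chance model. For 20 or
fewer experiments all `2^n` sign patterns are enumerated (via subset sums,
so n = 20 costs one million sums, not one million loops) and the p-value is
exact; otherwise 10^4 seeded random flips give the add-one estimate
`(1 + hits)/(B + 1)`. Equalities in `|mean|` are counted with a `1e-12`
relative tolerance so that mirrored patterns are never lost to rounding.
Reported alongside the p-value is the percentage of experiments with each
side above chance, since the per-experiment criterion and the group test
answer different questions and the sources are ambiguous about which their
significance markers reflect.

`experiment_distribution_ci()` summarises a per-experiment statistic (by
default the shortcut-minus-adjacent z gap) with nested 90/95/99% empirical
percentile intervals, using linear interpolation between order statistics
(`quantile()` type 7).

## Auxiliary statistics

`chi_square_expected()` is the textbook Pearson goodness-of-fit against
stated proportions (asymptotic p, no continuity correction, warning when
any expected count is below 5); `benjamini_hochberg()` is the step-up FDR
adjustment. Both delegate to the standard R implementations and are
verified in the tests against independent hand-rolled oracles.
`z_difference_test()` compares two chance-normalized values:
`((z_a − z_b) − (m_a − m_b)) / sqrt(s_a² + s_b²)`, where the shuffle
moments `m`, `s²` are *computed* by pushing each experiment's own resampled
draws through its normalization. By construction they come out at exactly 0
and 1 — the statistic then collapses to `(z_a − z_b)/sqrt(2)` — but
computing them keeps the definition honest should a null ever be
constructed differently. The "shuffle mean" is read as a mean of
normalized (z-space) values; the wording in the source caption admits a
raw-percentage reading, which is equivalent after the subtraction and so
not separately implemented.

## The synthetic-experiment generator

`simulate_experiment()` models each subject as one draw from a mixture of
five single-trial strategies: `shortcut` (map-like choice of the shortcut
path), `adjacent` (stimulus-triggered response next to the blocked route,
uniform over the two adjacent paths), `beacon` (approach the cued path),
`outer` (thigmotaxis / route repetition, uniform over the outer paths) and
`uniform` (exploration). Strategies are *path-role targets*, not
trajectories; no biomechanics, deliberation time or neural data are
simulated. Two optional refinements:

* `smear` spreads the shortcut strategy geometrically over neighbouring
  paths (weight `smear^d` at index distance `d`, default decay 0.5 per
  step), emulating the graded distributions predicted by noisy
  vector-integration accounts, as opposed to a single peaked preference.
* `bias_path` designates an unannotated sensory attractor (a dark or
  wall-adjacent alley, say); the beacon strategy approaches it when no
  cued path exists. This is how "other"-dominant experiments — an
  unremarkable path winning through an apparatus artifact — are generated
  without inventing a sixth strategy.

Layout presets encode the main apparatus variants by role: the original
18-path array (shortcut at printed position #6, paths 13–18 excluded, so
12 scorable paths and chance 100/12 ≈ 8.3%), a full circle whose training
path is itself a radial path, a 4-path T-like variant, an enclosed 8-path
maze (chance 12.5%), and a 6-path variant whose shortcut is also adjacent.
Where the sources do not print which adjacent path intersects the training
route or which outer path lies on the rewarded side, the preset fixes a
consistent choice once; these flags only matter for the paired contrasts,
which are exercised on synthetic data anyway.

Default generator conditions used across the tests — `N = 40–50` subjects,
dominant-strategy weight 0.6–0.8 with the remainder uniform, 1000-resample
nulls — mirror the sample sizes and effect strengths typical of the
replication literature; large-`N` checks use `N = 10000`.

### What passing tests do and do not show

The generator draws subjects independently from a stationary mixture. Real
Sunburst data have correlations the null and generator ignore: shared
odour trails, litter effects, sequential testing in the same room,
experimenter scoring idiosyncrasies. Recovery results on synthetic data
therefore validate the *pipeline arithmetic* (chance model, normalization,
categorization, contrasts), not the behavioural interpretation of any real
experiment.

One recovery property deserves a caveat. Under a pure-uniform mixture the
per-role z is approximately standard normal *however large N grows* (both
numerator and denominator shrink as `1/sqrt(N)`), and "other" is a maximum
over the ~7 unlabelled scorable paths of the 18-path layout. A uniform
experiment is therefore categorized `no_pref` only about four times in
five — roughly `1 − [P(z_max of 7 > 1.96) + 2.5% + …] ≈ 0.8` — and this is
a property of the 1.96 criterion itself, not a bug. The tests assert
`no_pref` as the modal outcome (and a ≥ 60% rate over 50 seeded runs,
three binomial SEs below the theoretical ~80%), not universality; the
same leakage slightly depresses `no_pref` prevalence in any real census
run with these rules.

## Numerical and design choices

* Percent units everywhere; raw values are kept unrounded in all machine
  output, and human-readable rounding (one decimal, or integers in
  headline tables) happens only at presentation time.
* `n_no_choice` is experiment-level metadata; subjects that never commit
  are not choices and never enter `N`.
* Excluded paths are removed before `K` is counted and are reported as
  absent (not zero) in percentage output.
* Unknown columns in input files ride along untouched, so source-specific
  annotations survive round trips.
* Determinism is end to end: every random component (resampler, generator,
  permutation test) takes a seed, restores the caller's RNG state, and
  identical configurations reproduce report bundles byte for byte.
  `run_analysis()` writes a manifest sufficient to reproduce a run and
  removes partial outputs when a stage fails.

## Known limitations

* The released digitized dataset of the replication literature is not
  bundled; the reader implements its schema, and an import shim is the
  adapter point if the published column names differ. Prevalence figures
  computed here on synthetic data exercise the machinery, not the
  historical record.
* The null is iid uniform across paths; correlated nulls (spatially
  smoothed choice tendencies) are out of scope.
* Chi-square p-values are asymptotic; no exact multinomial tests are
  provided because the sources use none.
* No meta-regression on moderators (species, training amount) — the
  sources report none quantitatively.

## A worked run

```{r example}
path <- system.file("extdata", "synthetic_experiments.csv",
                    package = "sunburstmeta")
data <- read_experiments(path, meta = sub("\\.csv$", "_meta.csv", path))

cats <- categorize_experiments(data, resamples = 1000, seed = 1)
select(cats, experiment_id, n, k, category, winning_role)
prevalence(cats)

ctr <- adjacent_contrast(data, mode = "intersect", seed = 1)
glance(ctr)
```
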