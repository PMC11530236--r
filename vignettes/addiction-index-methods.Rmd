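---
title: "Quantifying addiction-like behavior: indices, classification, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying addiction-like behavior: indices, classification, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addix)
```

## The problem

Large genetically heterogeneous rat cohorts phenotyped with extended-access
cocaine self-administration show wide individual differences: under long
(6-h) daily access, most animals escalate their intake while a minority
keeps a low, stable, short-access-like level. `addix` implements the scoring
pipeline used to quantify those differences and turn four behavioral assays
into a single severity scale:

1. **Escalation** — mean daily infusions over the last three long-access
   (LgA) sessions, out of 14.
2. **Motivation** — infusions earned under a progressive-ratio (PR)
   schedule after LgA.
3. **Compulsivity** (aversion-resistant responding) — infusions earned in a
   1-h session in which 30% of rewards are paired with a contingent
   footshock, compared with an unpunished 1-h "preshock" session the day
   before.
4. **Irritability** — bottle-brush test score (summed aggressive + defensive
   responses, averaged over observers) in withdrawal, minus the same score
   at baseline.

Each measure is normalized into a Z-score **within cohort and sex**
(`z = (x - mu)/sigma`, sample SD), which removes batch and sex effects from
the ranking. The **Addiction Index (AI)** is the unweighted mean of the
escalation, motivation and compulsivity indices. Irritability is excluded
from the composite: empirically it is near-orthogonal to the other three,
which load together on a single principal component.

Two classifications follow:

* **Resilient / vulnerable** — resilient if the escalation summary is under
  50 infusions per session (about 8 infusions/hr over 6 h, the level typical
  of short access); 50 or more is vulnerable. The boundary value 50 is
  deliberately classified vulnerable ("resilient" is defined by a strict
  `< 50`).
* **Severity quartiles** — rats ranked by AI are cut into Low / Mild /
  Moderate / Severe at cumulative counts `round_half_up(N * k/4)`,
  k = 1..3, ties broken by input order. This convention was chosen because
  it is the one that yields group sizes 128/128/127/128 at N = 511 — the
  anchor case — and it guarantees group sizes never differ by more than
  one. Because the indices are z-scored per sex, the AI distribution is
  comparable across sexes and each quartile ends up roughly sex-balanced.

## Progressive-ratio breakpoints

The response requirement of the j-th reward follows
`round(5 * exp(0.2 * j)) - 5` (half-away-from-zero rounding), which
reproduces the printed 18-term schedule 1, 2, 4, 6, 9, 12, 15, 20, 25, 32,
40, 50, 62, 77, 95, 118, 145, 178 exactly and extends it smoothly beyond;
within 1..18 the printed list is the authority and the test suite pins every
term. The **breakpoint** is the last ratio completed before a 60-min period
with no completed ratio. One deliberate design choice, isolated in
`compute_breakpoint()`: the 60-min rule also applies to the gap between
session start and the first completion (a rat silent for its first hour has
breakpoint 0) and to the trailing gap (which ends the session but removes no
completed reward). `behavior_summaries()` reports motivation both as rewards
earned and as the implied breakpoint; the Motivation Index consumes rewards
earned. By default the **first post-LgA PR session** (day index 2, the one
preceding the shock test) feeds the index; `pr_session = 3` switches to the
post-shock session.

## Missing sessions

An isolated interior session failure is imputed as the mean of the adjacent
days. Runs of two or more missing days and missing first/last days have no
defined two-neighbor rule; they are left missing, flagged, and warned about,
and any summary touching them (e.g. the escalation mean when days 12–14 are
affected) propagates `NA` rather than guessing. In the motivating datasets
such failures are under 2% of sessions, so the choice of rule is immaterial
at the population level.

## The synthetic cohort

`simulate_cohort()` generates populations with the statistical structure the
analysis assumes, plus the latent ground truth (`truth`), so every stage is
testable without animal data. Defaults are the study conditions: 567
cocaine rats and 49 naive animals in 12 balanced cohorts, half female.

* **Mixture**: each rat is vulnerable with probability 0.80. Resilient LgA
  intake is flat `N(35, 6)` per day; vulnerable intake ramps linearly from
  55 to 95 infusions/day by day 14, the ramp scaled by
  `(1 + 0.3 * b_esc)`, plus `N(0, 8)` daily noise. Under these trajectories
  the <50 rule recovers the mixture: about 80% classified vulnerable, with
  misclassification probabilities of order 1e-4.
* **Latent structure**: a single severity factor `a ~ N(0,1)` with equal
  loadings `lambda = 0.678` on the escalation, motivation and compulsivity
  latents (`b_k = lambda * a + sqrt(1 - lambda^2) * e_k`), so each pair
  correlates at `lambda^2 = 0.46`; the irritability latent is independent.
  A single factor with equal loadings is the simplest structure consistent
  with three indices loading on one component, and it gives the closed-form
  PC1 fraction `(1 + 2 * lambda^2)/4 = 48%` for the four-variable
  correlation-matrix PCA.
* **Sex effects** are additive standardized shifts, `+d/2` to females and
  `-d/2` to males (defaults: escalation 0.41, motivation 0.32, compulsivity
  0.67, irritability 0). Escalation and motivation shifts act on the
  latents. The compulsivity shift is applied on the **count scale** of the
  shock session, scaled by the cohort SD of the unshifted counts: the shock
  count is a logistic transform of its latent, and a latent-scale shift
  would attenuate the realized standardized difference to roughly 0.4.
  Applying it on the observed scale makes the generator realize its
  configured Cohen's d (up to a small loss from rounding and the floor at
  zero: about 0.64 realized at d = 0.67).
* **Shock suppression**: preshock 1-h infusions are `round(10 + 3a)`; shock
  infusions multiply them by `plogis(0.8 * b_comp - 0.4 + N(0, 1.65))`.
  The session-level noise SD of 1.65 was calibrated once, in a standalone
  simulation at n = 6e5, so that corr(preshock, shock) is about 0.58 while
  mean shock responding stays well below preshock responding; without it
  the shared `a` term forces the correlation to about 0.85.
* **Irritability**: baseline totals are `N(15, 4)`; withdrawal adds
  `0.89 * 4` for cocaine rats (naive rats get no shift) plus `4 * b_irr`,
  so the cocaine-vs-naive effect on the baseline-subtracted change is
  d = 0.89 and the observed irritability index is the standardized
  irritability latent. Scores split 60/40 into aggressive/defensive.
* **Determinism**: identical `(config, seed)` produce identical cohorts;
  the caller's RNG state is untouched. Sex is assigned as an exact count
  (`round(p_female * n)`, randomly ordered) so configured designs such as
  275 F / 292 M are realized exactly; cohorts are assigned round-robin on a
  random permutation.

What the generator does **not** emulate: within-session event streams
(except the evenly spaced PR fixture logs), acquisition learning curves,
catheter failures (the `excluded` flag is honored by the pipeline but never
set by the generator), inter-cohort batch effects, or any genetic structure.
Passing tests therefore validate the *scoring and classification machinery*
under the assumed population model — they are not evidence about real
animals.

## Statistical battery

* **Cohen's d**: pooled-SD standardized mean difference. The default 95% CI
  is the transparent asymptotic form
  `d ± 1.96 * sqrt((n1+n2)/(n1*n2) + d^2/(2*(n1+n2-2)))`; a noncentral-t
  inversion is available via `ci = "nct"`. The two can differ in the third
  decimal; the asymptotic form is the tested default.
* **Pearson r** and **Student's t** delegate to `stats::cor.test` /
  `stats::t.test` (pooled variance for unpaired).
* **PCA** (`pca_indices()`): columns centered and scaled to unit sample SD,
  components via `stats::prcomp` (equivalently, the eigenstructure of the
  correlation matrix — the test suite cross-checks against `eigen(cor(x))`);
  complete-case rows only; loading signs fixed so each component's
  largest-magnitude loading is positive, making output reproducible across
  linear-algebra backends.
* **Power** (`n_per_group_for_power()`): smallest per-group n for a
  two-sided two-sample t-test under a noncentral-t alternative, found by
  incrementing n from 2 (d = 1 gives 17/group, d = 0.67 gives 36, d = 0.2
  gives 394). With sex effects of d ~ 0.3–0.7, detecting them at alpha =
  0.05 with 80% power needs roughly 35–175 animals per group, which is why
  small-sample studies disagree about sex differences.

Repeated-measures ANOVA machinery (session-by-session tests with Bonferroni
post-hocs) is deliberately out of scope: it is standard methodology
available in any stats package and adds nothing to the scoring pipeline.

## Degenerate inputs and numerical conventions

* Z-scoring requires every (cohort, sex) group to have at least two
  non-missing values and positive SD; violations raise an error naming the
  group. Ten rats in one cohort can therefore not be scored — the pipeline
  is built for cohorts of tens of rats per cell.
* The AI is complete-case: missing any of its three components makes it
  missing, and such rats are left out of the severity quartiling
  (unassigned), mirroring how the population N shrinks between assays.
* Quartiling needs at least 4 scored rats; ties in the AI are broken by
  input order (stable).
* All simulated counts are integers, rounded then floored at zero.
* Excluded (catheter-failure) rats are dropped before cohort means and SDs
  are computed, so they never influence other rats' indices.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
the study's own scale: cohorts of 377–2000 rats, 20 replicates for
mixture-recovery and PCA checks, 50 replicates for effect-size recovery,
and 1000 random logs for the breakpoint oracle. A full run of everything
takes on the order of a minute on one core.
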