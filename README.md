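# addix — Addiction Index phenotyping for extended-access self-administration cohorts

`addix` is an R package for quantifying and classifying addiction-like
behavior in large, genetically heterogeneous rodent cohorts phenotyped with
extended-access drug self-administration. It is written for behavioral
neuroscientists and geneticists who screen hundreds of animals across
cohorts and sexes and need a single, reproducible severity scale per animal.

## What it computes

Four behavioral measures per rat:

* **escalation** — mean daily infusions over the last 3 of 14 long-access
  (6 h) sessions;
* **motivation** — infusions earned under a progressive-ratio schedule after
  long access (requirements 1, 2, 4, 6, 9, 12, …, generated by
  `round(5·e^(0.2j)) − 5`; breakpoint = last ratio completed before a 60-min
  period without a completion);
* **compulsivity** — infusions earned despite contingent footshock (30% of
  rewards punished) in a 1-h session;
* **irritability** — bottle-brush test score in withdrawal minus baseline.

Each measure is normalized within cohort and sex,

&nbsp;&nbsp;&nbsp;&nbsp;*z* = (*x* − *μ*<sub>cohort×sex</sub>) / *σ*<sub>cohort×sex</sub>,

and the **Addiction Index** is the unweighted mean of the escalation,
motivation and compulsivity z-indices (irritability is excluded: it is
empirically orthogonal to the construct the other three share). Animals are
classified **resilient** (escalation summary < 50 infusions/session, about
8 infusions/hr) versus **vulnerable**, and cut into **Low / Mild / Moderate /
Severe** quartiles of the Addiction Index (cumulative cuts
`round_half_up(N·k/4)`, so 511 scored rats split 128/128/127/128).

A calibrated synthetic-cohort generator (`simulate_cohort()`) reproduces the
statistical structure this analysis assumes — a ~20/80 resilient/vulnerable
mixture, a single latent severity factor giving pairwise index correlations
of 0.46 (hence a first principal component explaining ~48% of four-index
variance), configured standardized sex effects, preshock→shock responding
correlation ~0.58, and elevated withdrawal irritability (d = 0.89) — together
with per-rat latent ground truth for validation. A statistics battery covers
Cohen's d with 95% CI, Pearson r, Student's t, correlation-matrix PCA, and
noncentral-t power/sample-size computation.

## Worked example

```r
library(addix)

cohort    <- simulate_cohort(generator_config(), seed = 20)  # 567 + 49 naive
summaries <- behavior_summaries(cohort)
indices   <- build_indices(summaries)

table(indices$vulnerability)
#>  resilient vulnerable
#>         96        471

table(indices$severity)
#>      Low     Mild Moderate   Severe
#>      142      142      141      142

batt <- stats_battery(summaries, indices)
batt$tests[, c("statistic", "estimate", "ci_low", "ci_high")]
#>    statistic                             estimate ci_low ci_high
#>  1 sex_d_escalation                       0.323    0.157   0.488
#>  2 sex_d_motivation                       0.436    0.269   0.603
#>  3 sex_d_compulsivity                     0.659    0.490   0.828
#>  4 sex_d_irritability                    -0.00977 -0.174   0.155
#>  5 withdrawal_irritability_d_vs_naive     0.780    0.485   1.08
#>  6 preshock_shock_r                       0.517    0.454   0.575
#>  7 preshock_shock_paired_t                5.38     5.11    5.66
#>  8 n_per_group_80pct_power_escalation   152      NA      NA
#>  9 n_per_group_80pct_power_motivation    84      NA      NA
#> 10 n_per_group_80pct_power_compulsivity  38      NA      NA

batt$pca
#> PCA of 4 index variables on 567 rats
#> explained variance (%): 38.0, 25.0, 21.1, 16.0
#>                  PC1    PC2    PC3    PC4
#> escalation_z   0.483 -0.001  0.875 -0.025
#> motivation_z   0.621 -0.008 -0.322  0.714
#> compulsivity_z 0.608 -0.166 -0.356 -0.690
#> irritability_z 0.108  0.986 -0.061 -0.111
```

Reading the output: 83% of this simulated cohort escalates (vulnerable); the
severity quartiles are balanced by construction; females show small
standardized advantages in escalation/motivation and a medium one in
compulsivity (d ≈ 0.66) while irritability shows none; responding before the
shock session predicts responding during it (r ≈ 0.52); withdrawal
irritability is elevated versus naive animals (d ≈ 0.78). PC1 aligns the
three addiction indices with irritability nearly orthogonal — the pattern
that justifies leaving irritability out of the composite. The power rows say
a sex effect of the compulsivity size needs ~38 rats/group at α = 0.05 and
80% power (escalation-sized effects need ~150), e.g.
`n_per_group_for_power(0.67)` → `36`.

Single metrics are available directly, e.g.
`compute_breakpoint(pr_session_log(c(2, 9, 20, 45)))` → 4 rewards,
breakpoint 6; `hourly_rate(50, 6)` → 8.3 infusions/hr.

`run_pipeline(pipeline_config(...))` wires the stages end to end (simulate
or load CSVs → metrics → indices → classification → statistics) and writes a
CSV/JSON bundle that reproduces byte-for-byte under a fixed seed; a thin CLI
wrapper lives in `inst/cli/addix` (subcommands `simulate`, `metrics`,
`indices`, `stats`, `run`). The documented CSV schemas accept equivalently
structured real data (`read_study_tables()`).

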