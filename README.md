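# diurnalAab

Islet autoantibodies (GADA, IA, IA-2A, ZnT8A) are the working biomarkers of
type 1 diabetes: they select participants for trials of disease-modifying
therapy, monitor antigen-specific responses, and inform islet-transplant
decisions. Assay standardization programs have beaten down technical
variation, but one source remains unaddressed: the **time of day the blood
is drawn**. If titers move over the day, a morning draw and an afternoon
draw are not exchangeable — precision suffers, and titers near the
positivity threshold can flip detection status.

`diurnalAab` implements the two complementary analyses this question needs,
plus a synthetic-data generator that reproduces the statistical structure of
both study designs, so the full pipeline is testable without patient data.

**Longitudinal rhythmometry** (a small inpatient panel, draws every 4 h from
09:00 over 24 h, duplicate assays):

* participant z-scoring, daily ranges (max − min), diurnal CV vs the
  laboratory inter-assay CV, detection-change flags;
* single-component cosinor with fixed 24-h period,
  `Y(t) = M + A·cos(2π(t − φ)/24)`, fit through the linearization
  `Y = M + β·cos ωt + γ·sin ωt` (`A = √(β²+γ²)`,
  `φ = atan2(γ, β)/ω mod 24`), zero-amplitude F test, delta-method and
  subject-bootstrap acrophase confidence intervals;
* variance components for the balanced nested design
  `y_ijk = μ + b_i + u_ij + e_ijk` by expected mean squares —
  between-participant, time-of-day, and intra-assay shares of total
  variance;
* a bootstrap comparison of **time-restricted vs random clinical-day
  sampling**: resample subjects, read each one's titer at a fixed clock time
  (09:00/13:00/17:00) vs a random one, and summarize the SD ratio
  (restricted/random) over 10,000 replicates.

**Cross-sectional optimal-sampling-time discovery** (one draw per person,
times 07:00–16:00): round draw times to hours, fit a depth-limited
regression tree (CART) of ln titer on age and hour, turn each hour split
into an age-band × time-of-day contrast, and compare subgroups by two-group
ANOVA on ln titers (fold change = `exp(Δ mean ln)`), detection rates with
exact Clopper–Pearson intervals, and Pearson chi-square.

## Worked example

```r
library(diurnalAab)

panel <- gen_panel(panel_sim_config(seed = 20))
fit <- cosinor_panel(panel, "IA")
fit
#> <cosinor_fit> IA 24-h single-component fit
#>   MESOR -0.07251, amplitude 0.9755, acrophase 12:55 (12.91 h)
#>   zero-amplitude p = 8.87e-10  [n=70 obs, 10 subjects]
ci <- acrophase_ci(fit)
hours_to_clock(c(ci$lower, ci$upper))
#> "12:00" "13:49"
```

The generator planted its default IA acrophase at 13:00; the fitted peak is
12:55 with a CI that covers it, and the zero-amplitude test rejects — a
genuine circadian component. Variance decomposition and the value of
sampling everyone at the peak:

```r
variance_components(panel, "IA")
#> <variance_components> IA (n=10 subjects, t=7, r=2)
#>   between-participant: 59.9513  (91.58%)
#>   time-of-day:         4.53042  (6.92%)
#>   intra-assay:         0.98149  (1.50%)

bootstrap_sd_ratio(panel, "IA", 13, seed = 20)
#> <restriction_result> IA @ 13:00, 10000 bootstrap replicates (0 discarded)
#>   median SD ratio (restricted/random): 0.9886  [95% CI 0.7984, 1.1948]
#>   SD reduction: 1.1%
```

Between-person differences dominate (91.6%), but time of day explains
several times more variance than the assay itself (6.9% vs 1.5%). On the
cross-sectional side, the tree finds the planted early-morning advantage in
young participants:

```r
cohort <- gen_cohort(cohort_sim_config(seed = 20))   # n = 705, one draw each
rep <- subgroup_report(cohort, "IA-2A")
rep$table[rep$primary, c("age_hi", "tod_cut", "n_early", "n_late",
                         "diff", "fold_change", "anova_p", "chisq_p")]
#>   age_hi tod_cut n_early n_late     diff fold_change     anova_p      chisq_p
#> 1   18.5     8.5      58    281 1.185536    3.272441 4.42926e-14 8.118048e-06
```

Read: for participants up to ~18 years, draws at or before 08:00 ran
3.3-fold higher IA-2A titers than later draws (the generator plants
`exp(1.25) ≈ 3.49` in ages ≤ 16), and detection rates differ accordingly
(chi-square p ≈ 8e-6).

A command-line interface wraps every stage
(`inst/cli/diurnalAab simulate panel|cohort`, `cosinor fit`, `varcomp`,
`restrict`, `subgroups`, `run`), with `--seed` controlling named per-stage
RNG substreams so reruns are byte-identical.

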