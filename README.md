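# sewss

Ischaemia severity scoring and outcome validation for diabetic foot wounds.

Ischaemia is the worst prognostic factor for a diabetic foot wound, but the
non-invasive tests that measure it — pedal pulse palpation, the
ankle/brachial index (ABI), the toe/brachial index (TBI) and Doppler
waveform analysis — often disagree, and none is reliable alone (medial
calcification inflates the ABI, toe pressure is unmeasurable after a
first-ray amputation, palpation is subjective).  `sewss` implements the
four-point **Ischaemia Severity Scale** (ISS: 0 non-ischaemic, 1 mild,
2 moderate, 3 severe) that reconciles these tests, the **Saint Elian Wound
Score System** (SEWSS: ten wound factors subscored 0–3, summed to ≤ 30,
graded I/II/III), and the statistical battery used to validate an ordinal
severity scale against wound outcomes.  It is aimed at biostatisticians and
clinical researchers who want to score cohorts, audit such a scale on their
own data, or study its behaviour on simulated cohorts.

## The scoring model

For a patient with ankle pressures `P_dp`, `P_tp`, toe pressure `P_toe` and
arm pressures `P_arm`:

    ABI = max(P_dp, P_tp) / max(P_arm)        (high-ankle-pressure form)
    TBI = P_toe / max(P_arm)

ABI bands `[0.9, 1.2] / [0.7, 0.9) / [0.5, 0.7) / [0, 0.5)` and TBI bands
`[0.75, ∞) / [0.60, 0.75) / [0.30, 0.60) / [0, 0.30)` map to levels
0/1/2/3; waveform maps triphasic/biphasic/monophasic/absent to 0/1/2/3;
palpation grades 0–3 per artery combine by the worse artery.  An ABI above
1.2 is incompressible and defers to the other tests.  Discrepancies resolve
by precedence **waveform > TBI > ABI > pulse** (configurable).  SEWSS sums
band into grade I (≤ 10), II (11–20), III (21–30).

The validation battery: Cohen's kappa (overall and per dichotomised level),
per-level rate tables, odds ratios with Woolf CIs (Haldane–Anscombe
correction on zero cells), the Mantel–Haenszel (n−1)r² trend test,
Kruskal–Wallis, Kaplan–Meier curves by level, the k-group log-rank test and
a Cox proportional-hazards fit (Breslow ties, Newton–Raphson) with healing
as the event.  A seeded synthetic-cohort generator reproduces the
per-level summary distributions of the original 235-patient validation
cohort (159/24/25/27 across levels 0–3), so the full pipeline runs without
patient data.  See `vignette("iss-validation-methods")` for every modelling
decision.

## Worked example

```r
library(sewss)

# published per-level mean ABIs land on their own levels
iss_from_abi(c(1.1, 0.86, 0.68, 0.47))
#>   level         label decided_by
#> 1     0 non-ischaemic        abi
#> 2     1          mild        abi
#> 3     2      moderate        abi
#> 4     3        severe        abi

# full pipeline on a seeded synthetic cohort (n = 235, 159/24/25/27)
rep <- run_pipeline(pipeline_config(seed = 7))
rep
#> sewss validation report
#> ISS composition: 157/26/27/25 (levels 0-3)
#>
#> Rates (% per level):
#>                             0     1    2  3
#> male                     46.5  46.2 44.4 56
#> smoking                  30.6  23.1 29.6 20
#> pulse_dorsalis_palpable 100.0 100.0 92.6 12
#> pulse_tibialis_palpable 100.0 100.0 88.9 12
#> wound_healing            82.8  46.2 29.6 20
#> major_amputation          1.9   7.7 25.9 60
#> abandonment              13.4  46.2 44.4 20
#> early_death               1.9   0.0  0.0  0
#>
#> log-rank chi-squared = 80.42, df = 3, p = 2.5e-17
rep$cox
#> Cox proportional-hazards fit (Breslow ties)
#>           coef     se      HR ci_low ci_high
#> level_0 2.7031 0.4685 14.9254 5.9586 37.3857
#> level_1 1.5410 0.5394  4.6694 1.6222 13.4408
#> level_2 0.8553 0.5759  2.3521 0.7607  7.2724
#> loglik: null -713.8668 -> fitted -666.5708; 7 Newton iterations
```

The composition row says scoring recovered the latent levels almost exactly
(157/26/27/25 scored vs 159/24/25/27 generated).  Wound healing falls from
82.8% to 20% as severity rises while major amputation climbs from 1.9% to
60%; the log-rank test rejects equal healing curves decisively, and the Cox
hazard ratios (against the severe reference) say a non-ischaemic wound
heals about 15 times faster than a severe one, a mild wound about 5 times —
the ordering the scale exists to predict.

A thin CLI wraps the same functions
(`Rscript inst/cli/sewss-cli.R simulate|score|validate ...`).

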