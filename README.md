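# iahfluid

Quantifies transcapillary fluid and protein shifts in a porcine model of
acute intra-abdominal hypertension (IAH): two groups of n = 8 pigs
(~42 kg) observed every 30 min from −60 to 240 min, with the intervention
group's intra-abdominal pressure stepped to 15 mmHg at t = 0 and 30 mmHg at
t = 120 min under continuous crystalloid infusion (10 ml/kg/h) and threefold
replacement of blood losses. The package is written for experimental
physiologists analysing this kind of tracer-dilution fluid-balance
preparation, and for anyone who wants the full estimator chain with a
testable synthetic ground truth.

## What it computes

The central statistic is per-interval **fluid extravasation**

```
FE  = NFB − ΔPV            (ml per 30-min interval)
FER = FE / (weight · Δt)   (ml/kg/min)
```

where `NFB = (infusion + replacement) − (urine + blood loss)` and plasma
volume comes from carbon-monoxide tracer dilution: the CO dose over the
carboxyhemoglobin rise gives circulating hemoglobin mass (Hüfner constant
1.39 ml CO/g Hb), hence blood volume, hence `V_RBC`; red cells are then
propagated through recorded blood losses and converted at each measured
hematocrit via `PV = V_RBC (1 − Hct)/Hct`.

Around that core: window statistics (baseline −60–0, early 0–120, late
120–240 min; per-animal means first), solute masses (concentration ×
simultaneous PV), reference-sample microsphere regional blood flow
(`(n/n_ref)·q_ref·100/mass` ml/min/100 g), wet/dry total tissue water,
derived hemodynamics (SVR, PVR, CPP, L/P ratio), and a from-first-principles
split-plot repeated-measures ANOVA (group × time, subjects nested in group)
with the paired-t / Welch-t / exact Mann-Whitney post-hoc battery.

A synthetic-data module generates full cohorts in two modes: *trajectory*
mode prescribes true PV and NFB schedules (for exact round-trip validation
of the pipeline) and *mechanistic* mode integrates a two-compartment
Starling model (`J_v = K_f[(P_c − P_i) − σ(π_c − π_i)]`, venous pressure
coupled to IAP, lymph attenuated under IAH) at 1-min Euler steps with
per-step conservation audits.

## Worked example

```r
library(iahfluid)

ds  <- simulate_cohort(n_c = 8, n_p = 8, mode = "trajectory", master_seed = 1)
rep <- run_pipeline(ds, verbose = FALSE)
subset(rep$window_fluid, variable == "fer_ml_kg_min")
#>         variable group   window  mean     sd n
#> 19 fer_ml_kg_min     C baseline 0.183 0.0450 8
#> 20 fer_ml_kg_min     C    early 0.179 0.0250 8
#> 21 fer_ml_kg_min     C     late 0.168 0.0216 8
#> 22 fer_ml_kg_min     P baseline 0.165 0.0297 8
#> 23 fer_ml_kg_min     P    early 0.231 0.0172 8
#> 24 fer_ml_kg_min     P     late 0.277 0.0136 8
```

The control group's extravasation rate stays near its baseline
(~0.17–0.18 ml/kg/min, essentially the infusion it receives) while the
intervention group rises to ~0.27 ml/kg/min in the 120–240 min window —
fluid leaving the circulation faster than the ledger adds it, i.e. plasma
volume contraction with hemoconcentration:

```r
rep$anova$fer
#> Split-plot repeated-measures ANOVA
#>        effect df       ss        ms     f         p
#>         group  1 0.027519 0.0275186 52.65 4.186e-06
#>  animal:group 14 0.007318 0.0005227    NA        NA
#>          time  2 0.019452 0.0097260 11.32 2.501e-04
#>    group:time  2 0.032543 0.0162713 18.93 6.295e-06
#>      residual 28 0.024064 0.0008594    NA        NA
#>         total 47 0.110895        NA    NA        NA
```

The group × time interaction is the signature of IAP-driven extravasation.
The numbered drivers under `analysis/` run the same workflow stepwise
(`01` simulate → `02` volumes & balance → `03` tissue & hemodynamics →
`04` repeated-measures statistics), writing tables under `results/`.

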