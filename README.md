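# stagecif

Estimation tools for **staged disease progression toward an absorbing
diagnosis**, built for clinical-staging cohorts such as offspring at
familial risk of bipolar disorder, where psychopathology is hypothesized to
unfold in a forward sequence of stages (well → non-mood disorder → minor
mood disorder → major mood disorder → bipolar disorder), with stage
skipping allowed and no backward transitions.

Two complementary frameworks are implemented on the age time scale, for
biostatisticians and psychiatric epidemiologists who want to fit both to
the same event-history data and compare them:

1. **Cox proportional hazards with internal time-varying covariates.**
   Earlier stages enter the hazard of the terminal diagnosis as 0/1
   covariates that switch on at first diagnosis:

   α(t | x(t)) = α₀(t) · exp(β′x(t)).

   The fit is a Newton–Raphson maximum partial-likelihood estimate on
   counting-process (start, stop] data (Breslow ties by default, Efron
   optional), with Wald inference and the Breslow cumulative-hazard
   increments

   ΔÂ(s) = δ(s) · exp(β̂′x*(s)) / Σᵢ Yᵢ(s) · exp(β̂′xᵢ(s)),

   giving the cumulative incidence CIF(t) = 1 − exp(−Σ_{s≤t} ΔÂ(s)) for any
   covariate path x*(·).

2. **Nonparametric Markov multi-state model.** Stages are explicit states;
   transition hazards are Nelson–Aalen estimates
   Λ̂ₕⱼ(t) = Σ_{s≤t} δₕⱼ(s)/Yₕ(s), and the transition probability matrix is
   the Aalen–Johansen product integral

   P̂(s, t) = ∏_{u ∈ (s,t]} (I + ΔΛ̂(u)),

   yielding state occupation curves and absorbing-state cumulative
   incidence with delta-method standard errors and complementary log-log
   confidence bands.

The two frameworks produce **conditional CIFs** of the absorbing diagnosis
given occupation of an earlier stage at a conditioning age (e.g. bipolar
disorder after age 18 given major mood disorder before 18); the package
compares them head-to-head and, with its seeded Markov cohort simulator
(exponential sojourns, proportional-hazards effects, right censoring),
demonstrates that the two estimators converge as the sample size grows.

## Worked example

```r
library(stagecif)

# simulate a 500-subject staging cohort (5 stages, censoring at ages 15-30)
cohort <- simulate_cohort(default_sim_config(n = 500, seed = 3))
h <- cohort$histories

# Cox model: major mood disorder as a time-varying covariate for bipolar
cp  <- to_counting_process(h, "MajorMood", "Bipolar")
fit <- fit_cox(cp)
print(fit)
#> Cox time-varying-covariate fit (breslow ties): n = 699 rows, 72 events
#>           estimate    se      z p hazard_ratio
#> MajorMood   2.0816 0.275 7.5703 0       8.0177
#> partial log-likelihood -392.8902 (null -423.9900), 5 iterations

# multi-state model: Nelson-Aalen hazards and Aalen-Johansen probabilities
haz <- nelson_aalen_transitions(to_transition_long(h))
round(state_occupation(haz, 20), 3)
#>      Well   NonMood MinorMood MajorMood   Bipolar
#>     0.262     0.186     0.143     0.284     0.124

cif <- cif_confidence_band(cif_absorbing(haz, "Well", "Bipolar"), haz)
round(as.data.frame(cif)[findInterval(c(20, 29), cif$time), ], 4)
#>        time    cif     se  lower  upper
#> 616 19.9975 0.1238 0.0157 0.0963 0.1584
#> 707 28.8920 0.2063 0.0271 0.1588 0.2656

# head-to-head conditional CIF: bipolar after 18 given major mood at 18
cmp <- conditional_cif_pair(h, "MajorMood", 18, "Bipolar")
print(cmp)
#> Conditional CIF comparison (n = 500): MajorMood occupied at age 18 -> Bipolar
#>   Cox curve: 24 jumps, final 0.2415
#>   MSM curve: 20 jumps, final 0.2583
#>   sup distance: 0.01677
```

The Wald row reads as in any Cox regression: a prior major mood diagnosis
multiplies the bipolar hazard by exp(β̂). The occupation vector is the
top row of P̂(0, 20). The comparison object shows the structural contrast
between the frameworks — the Cox curve jumps at every terminal event, the
multi-state curve only at terminal events out of the conditioning state —
while the two curves stay close (and provably converge as n grows).

A command-line interface wraps the same functions:

```sh
./exec/stagecif simulate --n 500 --seed 3 --out run1
./exec/stagecif fit-msm  --input run1/cohort.csv --out run2
./exec/stagecif compare  --input run1/cohort.csv --condition-state MajorMood \
    --condition-age 18 --absorbing Bipolar --out run3
```

Each run writes CSV outputs plus a `manifest.json` with the seed, flag set
and input digests.

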