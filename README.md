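# predselect

Inference of size- and growth-selective predation on juvenile fish from
otolith-reconstructed age–length data.

## The problem

Predators of juvenile marine fish may take prey at random, prefer
absolutely smaller fish (*size selection*), or prefer slower growers at any
given age (*growth selection*). None of this can be watched in the open
sea, but daily-increment otoliths survive digestion: a survey haul yields
otoliths of the population's survivors ("netted" juveniles), and predator
stomachs yield otoliths of the victims ("consumed" juveniles). Each otolith
gives an age, a length at capture and a back-calculated length-at-age
trajectory. `predselect` is for fisheries ecologists who have both otolith
collections and want a formal answer to *which predation mode acted*, plus
the standard feeding-habit descriptors (digestion timing, occurrence rates,
predator–prey mass ratios) and the bias screens the comparison requires.

## The model

The original population (before net sampling and predation) is
`f0(a) · φ(l; β₀ + β₁a, σ)`: a discrete age distribution times a Gaussian
length law linear in age, estimated from the netted sample by weighted
least squares with weights `1/retention(SL)` to undo the net's length bias.
Predation reweights it:

    f_c(a, l) = f0(a) φ(l; β₀ + β₁a, σ) w(a, l; θ) / Z(θ)

with `w ≡ 1` (random), a decreasing logistic in `l` (size selection,
half-point and width θ), or a decreasing logistic in the residual
`l − (β₀ + β₁a)` (growth selection). The three models are fitted to the
consumed sample by maximum likelihood and compared by
`AIC = 2k − 2 lnL` (k = 0 or 2) and by a parametric-bootstrap
likelihood-ratio test against the random null (default 2,000 iterations,
`p = (1 + #{LR_b ≥ LR_obs})/(B + 1)`).

Around that core: biological-intercept back-calculation
(`SL(a) = SL_h + (R(a) − R_h)(SL_c − SL_h)/(R_c − R_h)`), left/right otolith
pairing within stomachs (2-mm rule, optimal assignment), digestion-time
inversion of a gastric evacuation line (`DR = −0.176 t + 59.462` by
default), a head-rejection site screen (flag when the netted unpalatable
share α exceeds 5% and the consumed share falls below
`0.4·α·100/(100 − 0.6α)` %), Ward-linkage hatch-cohort assignment, and
MANOVA comparison of back-calculated growth trajectories at 5-day
intervals. A synthetic-survey generator with known ground truth makes every
stage testable end to end.

## Worked example

Simulate a survey under known growth selection, fit the population from the
net sample, and compare the three predation models:

```r
library(predselect)
sv <- simulate_survey(
  sites = data.frame(site = c("St.04", "St.15"), year = 2008,
                     n_netted = 40, n_consumed = 10),
  spec = selection_spec("growth", half = -2, width = 2),
  seed = 11)

netted   <- subset(sv$fish, source == "netted"   & site == "St.04")
consumed <- subset(sv$fish, source == "consumed" & site == "St.04")

pop <- fit_population(netted, retention_curve())
pop
#> Population model (original age-SL law)
#>   mean SL = -2.626 + 1.042 * age,  sigma = 2.349 mm
#>   age support: 15-66 dph (52 points)
#>   fitted from 40 netted records

compare_models(pop, consumed, scope = "site:St.04", B = 500, seed = 3)
#> Predation-model comparison [site:St.04], n = 10 consumed
#>   random : lnL =  -63.542  AIC =  127.084
#>   size   : lnL =  -62.870  AIC =  129.741
#>   growth : lnL =  -58.894  AIC =  121.789 **
#>   selected (min AIC): growth
```

The fitted population line recovers the generator's truth
(β₀ = −5, β₁ = 1.1, σ = 3 within sampling error of 40 fish), and the
growth-selection model — the generating mechanism — wins on AIC with a
bootstrap `p < 0.01` (starred) against random predation. Feeding-habit
helpers work the same way:

```r
occurrence_rate(4, 50)                    # 8   (% of stomachs with the prey)
round(expected_rejection_bound(74.4), 1)  # 53.8 (% upper bound under head rejection)
digestion_duration(24.262)$duration       # 200 (minutes since ingestion)
```

The full pipeline — validation, reconstruction, events, screening,
selectivity at site/year/pooled scopes, cohort trajectory tests, CSV
outputs — runs from a YAML/list configuration via `run_pipeline()`; see the
vignette in `vignettes/selective-predation.Rmd` for the model's assumptions,
numerical choices and limitations.

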