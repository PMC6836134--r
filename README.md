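# maskmix

Statistical toolchain for **cued metacontrast-masking experiments with
continuous report**: does spatial attention interact with visual
masking, or do the two combine additively?

In these experiments an observer reports the orientation of a target
bar that is pre-cued (centrally for endogenous attention, peripherally
for exogenous) at some cue-target onset asynchrony (CTOA) and followed
by an annular metacontrast mask at some stimulus onset asynchrony
(SOA). `maskmix` provides, per observer:

* **Error measures** — signed report errors wrapped to
  [−90°, 90°), and *transformed performance*
  `TP = 1 − |error|/90` (1 = perfect, 0.5 = chance), summarised into
  masking functions (TP vs SOA) with baselines.
* **Design-validation criteria** — C1 (no ceiling: best masked cell
  significantly below baseline, one-tailed Welch) and C2 (no floor:
  worst masked cell significantly above 0.5).
* **The regression ladder** — 21 embedded polynomial models
  `Y ~ {1, τ, τ², n, τ·n, τ²·n}` (τ = SOA, n = CTOA) compared by BIC
  and adjusted R²; the additive model M16 is "no interaction", wins by
  M19–M21 indicate one. BIC difference x ⇒ `e^-x`-to-1 odds.
* **Mixture models of the error distribution** — G (Gaussian
  encoding), GU (+ uniform guessing with weight `w_u`), GUCA/GUNN
  (+ misbinding Gaussians on the closest-angle or nearest-neighbour
  distractors), scored by uniform-prior log marginal likelihood
  computed with Riemann-grid integration ("BMC"):

  `ln L(m) = ln Lmax − Σ_j ln R_j + ln ∫ exp(lnL(θ) − lnLmax) dθ`

  BMC difference x ⇒ `e^x`-to-1 odds.
* **Bootstrap inference** — per-cell resampling (B = 500), parameter
  means/SEs, ladder regression of each parameter surface over
  (SOA, CTOA), and Pearson correlations of parameters with masking
  functions.
* **A synthetic-data generator** reproducing the study structure
  (endogenous: 6 bars, 100%-valid cue, 3 CTOAs × [5 SOAs + baseline]
  × 100 = 1800 trials; exogenous: 4 bars, 25%-valid cue, 1200 valid of
  ~4800 trials) with a configurable guess-weight surface
  `w(τ, n)` that is additive by default and can inject interactions.

## Worked example

```r
library(maskmix)

scenario <- scenario_endogenous(seed = 42)  # calibrated default truth
trials <- generate_dataset(scenario)        # 1800 trials, 18 cells

check_ceiling_floor(trials)
#> <criteria_report: observer S1, alpha 0.05, PASS>
#>   C1 (ceiling): cell (ctoa 500, soa 120), t(130.6) = -3.95, p = 6.344e-05 -> PASS
#>   C2 (floor): cell (ctoa 0, soa 80), t(99.0) = 3.95, p = 7.296e-05 -> PASS

masking_function(trials, ctoa = 0)
#> <masking_function: observer S1, CTOA 0 ms>
#>  soa_ms   mean_tp     sem_tp n_trials
#>      20 0.7248624 0.02753895      100
#>      40 0.6632950 0.02826902      100
#>      60 0.6446288 0.03052152      100
#>      80 0.6202431 0.03043274      100
#>     120 0.7122880 0.02836758      100
#>   baseline: mean_tp 0.863 (sem 0.016, n 100)

masking_ladder(trials)$selection
#> <ladder_selection: winner M16 (BIC -3858.79); nearly equal: M17>
```

The masking function is U-shaped (worst visibility at 80 ms SOA, well
above the 0.5 chance floor and below the 0.86 baseline ceiling), and
the ladder picks the additive model M16 — no attention-masking
interaction, as built into this scenario.

```r
cell <- subset(trials, ctoa_ms == 0 & soa_ms == 60)
ctx <- trial_contexts(cell)
scores <- list(
  bmc_score("G",    cell$error_deg),
  bmc_score("GU",   cell$error_deg),
  bmc_score("GUCA", cell$error_deg, ctx, bins = 16),
  bmc_score("GUNN", cell$error_deg, ctx, bins = 16))
compare_models(scores)
#> <bmc_comparison>
#>   BMC: G -513.80, GU -507.17, GUCA -507.13, GUNN -507.31
#>   winner: GUCA
```

The guessing models crush the pure-Gaussian G (GU − G = 6.63, i.e.
`exp(6.63)` ≈ 760-to-1 odds), while GU, GUCA and GUNN sit within 0.2
BMC of each other (odds near 1-to-1): this cell has no misbinding
signal, and the misbinding weight fits to ~0 — exactly the "nearly
equal, prefer the simpler model" reading the comparison is designed
to support. The full pipeline (criteria + ladder + per-cell BMC +
bootstrap) runs as

```r
bundle <- run_pipeline(run_config(scenario = scenario, seed = 42,
                                  out_dir = "out"))
```

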