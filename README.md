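# carkin — multiphasic CAR-T cell kinetics

CAR-T cells are a living drug: after infusion their circulating counts
decline while the product distributes through the body, expand
antigen-dependently to a peak, contract steeply, and then persist for years
at a slowly decaying level. `carkin` is an R package for scientists modeling
these kinetics in hematological cancers (ALL, CLL, DLBCL, MCL). It
implements a mechanistic five-compartment ODE model in which the CAR-T
population is split into distributed (CD), effector (CT), memory (CM) and
exhausted (CE) phenotypes coupled to a logistically growing tumor (T):

    dCD/dt = -(β + η) CD
    dCT/dt = η CD + κ(t) F(T) CT - (ξ + ε + λ) CT + θ T CM - α T CT
    dCM/dt = ε CT - θ T CM - μ CM
    dCE/dt = λ CT - δ CE
    dT/dt  = r T (1 - b T) - γ f(CF, T) T,        CF = CD + CT

with the time-dependent expansion rate κ(t) = r_min + p1 / (1 + (p2 t)^p3),
the antigen saturation F(T) = T/(A + T), and the cytotoxicity saturation
f(CF, T) = CF/(ϑT + a + CF). Each kinetic phase is dominated by one
phenotype, so the log-linear slope of each phase identifies a rate: the
distribution slope ≈ −β, the expansion slope ≈ r_min + p1 − ξ, the
contraction slope ≈ −δ, the persistence slope ≈ −μ. The expected engrafted
cells are EC = η/(β+η) · dose.

The package provides:

* a fast compiled fixed-step RK4 simulator with impulsive (split) dosing
  (`simulate_kinetics()`, trajectories as tidy tibbles),
* automated piecewise log-linear phase segmentation and slope-based
  first-pass estimates (`segment_phases()`, `fit_phase_slopes()`,
  `slopes_to_estimates()`),
* patient-specific multi-start least-squares calibration against
  left-censored observations (`fit_patient()`, with broom-style `tidy()` /
  `glance()` and `autoplot()` methods),
* kinetic outcome metrics: per-phenotype AUCs, non-exhausted fraction,
  peak/dose ratio, engraftment, theoretical relapse time, and CR/PR/SD/PD
  classification (`kinetic_summary()`, `classify_outcome()`),
* a synthetic-cohort generator emulating sparse qPCR sampling, lognormal
  noise and detection-limit censoring (`generate_cohort()`), and an
  end-to-end cohort pipeline (`run_pipeline()`, `plot_cohort_map()`).

## Worked example

Simulate the documented timescale-separated reference patient (dose 1e8
cells, initial tumor burden 1e7 cells) and summarize the outcome kinetics:

```r
library(carkin)

kp <- textbook_params()
traj <- simulate_kinetics(kp, schedule = 1e8, t_end = 365, dt = 1e-3)
kinetic_summary(traj, threshold = 2.5e6)
#> <carkin_summary>
#>   peak: C = 3.68e+10 cells at day 9.3 (368 x dose)
#>   engrafted cells: 14998
#>   AUC 0-28: 1.41e+11 cell day, non-exhausted fraction 0.450
#>   AUC 0-60: 1.48e+11 cell day, non-exhausted fraction 0.474
#>   AUC 0-90: 1.52e+11 cell day, non-exhausted fraction 0.489
#>   theoretical relapse at day 501.6
```

Reading the output: of the 1e8 infused cells only ~1.5e4 engraft (the rest
die during distribution at rate β); the engrafted effectors expand ~368-fold
past the dose, peaking on day 9.3; 45% of the first-28-day CAR-T exposure is
non-exhausted (CD + CT + CM) cells; the tumor is driven below the 2.5e6-cell
detection threshold and regrows across it on day 502 — the theoretical
relapse.

The automated phase analysis recovers the generating rates from the
trajectory alone (β = 2, δ = 0.3, μ = 0.01, p1 + r_min = 3.05):

```r
obs <- tibble::tibble(day = textbook_sampling(),
                      value = approx(traj$time, traj$C, textbook_sampling())$y)
slopes_to_estimates(fit_phase_slopes(obs), assumed_xi = kp$xi)
#> # A tibble: 4 × 3
#>   parameter     estimate from_slope
#>   <chr>            <dbl> <chr>
#> 1 beta            1.75   md
#> 2 p1_plus_r_min   2.54   me
#> 3 delta           0.267  mc
#> 4 mu              0.0109 mp
```

`autoplot(traj)` draws the phenotype time courses; see the vignette
(`vignettes/cart-kinetics.Rmd`) for the model's assumptions, the calibration
strategy, identifiability caveats and the synthetic-cohort design.

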