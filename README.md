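# picodiel

Mechanistic attribution of daily *Prochlorococcus* mortality to viral
lysis, nanoflagellate grazing, and other density-dependent losses, from
multi-signal diel time series.

## The problem

In oligotrophic gyres, *Prochlorococcus* abundances oscillate every day —
division at night, net loss during the day — while staying remarkably
stable across weeks. That balance means daily production ≈ daily loss,
but abundance data alone cannot say *who* eats the difference: cyanophage
(lysis) or heterotrophic nanoflagellates (grazing), or something else.
`picodiel` answers this with model–data integration: a multitrophic ODE
model under diel light forcing is fitted to four concurrently measured
signals, and the fitted model's loss fluxes are decomposed.

The model tracks susceptible cells $S$, infected cells $I$, free virions
$V$ and grazers $G$ (per litre):

```
dS/dt = μ(t)S − m_P S(S+I) − φ(t)SV − ψSG
dI/dt = φ(t)SV − m_P I(S+I) − ηI − ψIG
dV/dt = βηI − φ(t)(S+I)V − m_V V²
dG/dt = ε_eff ψ(S+I)G + γG − m_G G²
```

with diel division `μ(t) = μ_ave (1 + δ_μ sin(2π(t + δ_t)))` (`t` in days,
`t = 0` at 06:00 local) and, in a model variant, a mean-preserving diel
step in the adsorption rate `φ(t)`. Total cell mortality partitions as

```
m_total = ηI (lysis) + ψ(S+I)G (grazing) + m_P (S+I)² (other),
```

reported as time-averaged fractions over the sampling window. The grazer
generalism rate `γ` (0 = pure specialist) indexes a family of model
variants fitted side by side.

What the package provides:

* a fast compiled integrator with correct handling of the forcing
  discontinuities, burn-in to diel-stationary dynamics, and extinction
  masking (`simulate_community()`, `run_to_stationary()`);
* observation I/O with the detrended-fitting convention
  (`read_observations()`, `fit_trend()`, `detrend()`, `retrend()`);
* Bayesian inference of the eleven free life-history parameters (plus
  initial conditions and noise scales) by a seeded affine-invariant
  ensemble sampler with split R-hat / ESS diagnostics
  (`prior_spec()`, `sample_posterior()`, `compare_variants()`);
* mortality partitioning, residence times and posterior propagation
  (`partition_mortality()`, `residence_times()`, `partition_posterior()`);
* sensitivity sweeps 0.25×–4× per parameter and the adsorption×clearance
  covariation grid with extinction masking (`sweep_single()`,
  `sweep_pair()`, `arc_classification()`);
* a cruise-like synthetic-data generator and parameter-recovery harness
  (`generator_config()`, `generate_observations()`,
  `recovery_experiment()`).

Everything takes and returns tidy tables; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(picodiel)

p <- life_history()          # open-ocean coexistence defaults (specialist)
st <- run_to_stationary(p, burn_in = 1000)
glance(st)
#> # A tibble: 1 × 5
#>   stationary  max_rel_diff extinct     min_P n_steps
#>   <lgl>              <dbl> <lgl>       <dbl>   <dbl>
#> 1 TRUE       0.00000000286 FALSE   93982359.   13749

partition_mortality(st)
#> # A tibble: 1 × 6
#>   f_lysis f_grazing f_other m_total_daily per_capita_grazing lysis_to_grazing
#>     <dbl>     <dbl>   <dbl>         <dbl>              <dbl>            <dbl>
#> 1  0.0599     0.880  0.0599     47954225.              0.432           0.0680

residence_times(p, st)
#> # A tibble: 1 × 3
#>   grazer_residence virus_residence virus_residence_quadratic
#>              <dbl>           <dbl>                     <dbl>
#> 1             20.4            1.18                      1.19
```

After a 1000-day burn-in the default parameters settle on a diel limit
cycle (state at `t` and `t + 1` day agree to 3×10⁻⁹ relative). On the
stationary day, grazing accounts for ~88% of cell losses, lysis and other
density-dependent losses ~6% each, out of ~4.8×10⁷ cells L⁻¹ d⁻¹ total;
grazers turn over in ~20 days and virions in ~1.2 days. Total
*Prochlorococcus* peaks at night (`st$time_days[which.max(st$S + st$I)]`
is ≈ 0.85, about 02:30 local).

A full inference round trip on synthetic observations:

```r
obs <- generate_observations(generator_config(seed = 1))
fit <- sample_posterior(detrend(obs), prior_spec(gamma = 0), seed = 1)
tidy(fit)                          # posterior medians, 95% CI, R-hat, ESS
tidy(partition_posterior(fit, obs))  # mortality fractions with uncertainty
```

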