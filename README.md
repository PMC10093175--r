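# turtledrift

Current-corrected dispersal analysis for satellite-tracked juvenile sea
turtles — and for anyone who needs to turn irregular, noisy ARGOS fixes
into daily tracks, split ground motion into ocean-current advection and
active swimming, and model what drives directional swimming persistence.

The package implements the full chain as tested, reusable functions:

1. **Dispersal classification** — an animal is *dispersive* if any raw fix
   lies > 10 km from the island polygon, *residential* otherwise.
2. **State-space regularization** — a continuous-time 2-D random walk
   observed through each fix's ARGOS error ellipse; the process SD
   σₚ (km day^(-1/2)) is estimated by exact Kalman maximum likelihood and
   daily positions are RTS-smoother states on a 24-h grid.
3. **Current correction** — per day, ground velocity **g** from the daily
   positions, current **c** sampled from a gridded ocean product
   (× 86.4 to km day⁻¹), swimming velocity **s** = **g** − **c**;
   integrating **s** rebuilds the current-corrected trajectory.
4. **Persistence velocity** — with daily step length L and turning angle
   θ between successive swimming vectors, V = L·cos θ: the signed
   tendency to keep moving in the prior direction (V = L straight ahead,
   −L for a reversal, 0 for a right angle).
5. **Circular statistics** — two-sample Watson U² comparisons of heading
   and current-direction distributions, with a seeded permutation null,
   p = (b+1)/(B+1).
6. **Persistence GAMM** — V ~ fixed effects (current speed, SST,
   sargassum, body weight, tracking period) + thin-plate-style
   s(lat, lon) + per-animal random intercepts, with pooled ARMA(p, q)
   daily residual correlation; AIC backward elimination of fixed effects
   and ACF/PACF-seeded, BIC-judged residual-order selection.
7. **A synthetic world** — uniform/vortex current fields with closed-form
   evaluators, goal-directed von Mises swimmers, passive drifters, and
   ARGOS-like noise (negative-binomial fix counts, class-scaled error
   ellipses), so every stage is verifiable against exact ground truth.

See `vignettes/persistence-methods.Rmd` for the models, assumptions,
defaults and design choices.

## Worked example

The numbered drivers under `analysis/` run the whole study at desk scale
(outputs land under `results/`):

```sh
Rscript analysis/01_simulate.R    # two release cohorts + drifters
Rscript analysis/02_analyze.R     # classification -> SSM -> correction
                                  #   -> metrics -> tests -> GAMM
Rscript analysis/03_recovery.R    # ground-truth recovery experiments
Rscript analysis/04_report.R      # one markdown report
```

`02_analyze.R` prints, for the default seed:

```
Cohort:  40 animals; 24 dispersive, 16 residential
Buffer filter removed 110 fixes; 0 animals unusable after filtering

Circular contrasts (Watson U2, permutation p):
                 contrast        u2     p   n   m
      headings:Jan-vs-Jul 2.7789036 1e-04 191  89
      currents:Jan-vs-Jul 5.0598214 1e-04 191  89
 headings-vs-currents:Jan 5.9989631 1e-04 191 191
 headings-vs-currents:Jul 0.9794489 1e-04  89  89
```

Forty simulated animals split into 24 dispersive and 16 residential (the
residential count is a scenario parameter, recovered exactly by the
classifier). All four circular contrasts are significant at the
permutation floor p = 1/(B+1): the two cohorts were generated with
different goal distributions and different current regimes, and the
turtles swim against the current, so headings differ from current
directions within each period. The elimination trace and the final
coefficient table follow; in this scenario geometry the period contrast
is absorbed by the spatial smoother (the two cohorts occupy disjoint
regions), which is why the package's recovery experiments use spatially
exchangeable cohorts instead (see the vignette).

`03_recovery.R` checks the chain against generator truth:

```
Swim recovery, median relative error: 0.07 %
sigma_p within 20% of truth in 50 of 50 replicates
Watson null rejection at alpha=0.05: 0.045 ; power (90-degree separation): 1
Period effect (truth 6.2): 4.67 +/- 1.78 ; AR(1) estimate (truth 0.5): 0.51
```

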