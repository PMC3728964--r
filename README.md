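# vitalrecon

Inverse demographic inference for size-structured populations under
directional environmental change.

Long-term drivers — land degradation, chronic anthropogenic disturbance,
climate change, succession — shift survival, growth and reproduction over
decades. Following marked individuals across such a period is rarely
feasible; what ecologists often have instead is a sparse **time series of
population size structures and densities** (from monitoring records, or
from a chronosequence of sites treated as one population's temporal
stages). `vitalrecon` reconstructs the underlying vital rates and their
temporal trends from exactly that kind of data, and ships the full
simulation machinery for judging when the reconstruction can be trusted.

## The model in brief

The population is a density n(x, t) over log-size x, advanced annually by
a time-varying integral projection model (IPM):

    n(y, t+1) = ∫ k(y, x, t) n(x, t) dx,
    k = s(x,t) · g(y | x, t) + f1(x,t) · f2(y, t)

Survival s (logit link), the growth transition g (Gaussian, identity-link
mean), per-capita fecundity f1 (log link) and the offspring-size density
f2 (Gaussian, time trend only) are each driven by a linear predictor
a0 + a1·x + a2·t + a3·x·t — 16 parameters in all (18 with the optional
time-varying survival ceiling s_max(t) = [1 + exp(β1 + β2·t)]⁻¹ for
long-lived species). Candidate parameters are scored by the composite
log-likelihood

    l = l_n + w · l_d

(l_n: observed individual sizes as i.i.d. draws from the predicted,
normalized structure; l_d: lognormal density model, mean equal to the
predicted density; w rebalances one density datum per year against many
size data). Bounded multi-start quasi-Newton maximization across
w ∈ {0, 1, 10, 100, 1000}, clustering of the resulting optima, Pearson
accuracy metrics (r_s, r_g, r_f, r_d and their mean r_m) against a known
truth, and biological plausibility screening of alternative solutions
complete the workflow. See the methods vignette
(`vignettes/methods.Rmd`) for assumptions, conventions and limitations.

## Worked example

Simulate an artificial species, observe it sparsely and noisily, fit it
back, and score the reconstruction:

```r
library(vitalrecon)

mesh      <- size_mesh(0, 10, 50)     # log-size mesh
intervals <- default_intervals()      # parameter box ("ample" behaviours)

set.seed(1)
truth <- draw_species(intervals, mesh)         # viable random species
obs   <- make_dataset(truth, sampling_config(), mesh)
obs
#> <observed_series> 10 years (33-89), 490 individuals
#>   carries true generating parameters (validation run)

plan <- start_plan(truth, error_levels = 0, bounds = intervals)
fits <- fit_multistart(obs, plan, intervals,
                       w_values = c(0, 1, 10, 100, 1000), mesh = mesh)

rules <- plausibility_rules(survival_size = "+", fecundity_size = "+")
sel   <- select_solution(fits, rules, t = 33:89)
sel[, c("w", "l", "label")]
#> # A tibble: 1 × 3
#>       w      l label
#>   <dbl>  <dbl> <chr>
#> 1   100 -4821. plausible

fit_metrics(sel$fit[[1]], obs)
#> # A tibble: 1 × 5
#>     r_s   r_g   r_f   r_d   r_m
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1 0.999 1.000 0.998 0.926 0.981
```

The selected solution is the highest-likelihood biologically plausible
fit at the smallest nonzero w whose runs converged and passed the screen.
`r_s`, `r_g`, `r_f` correlate the true and reconstructed survival, growth
and fecundity surfaces over the size-by-time grid, `r_d` the reconstructed
and observed densities; their mean `r_m = 0.98` says the species'
demography — and its temporal change — was recovered almost exactly from
ten noisy snapshots totalling 490 individuals.

`tidy()`, `glance()` and `autoplot()` methods work on the fitted objects;
`run_pipeline()` executes the whole simulate–fit–validate cycle from a
config file; `inst/cli/vitalrecon.R` is a thin command-line wrapper.
For chronosequence users, `map_disturbance_to_time()` converts a linearly
accumulating disturbance index into years since onset, and
`cylinder_log_volume()` converts field measurements to log-size.

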