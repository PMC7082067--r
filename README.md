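# imtracer

Time-dependent isolation-migration inference from pairwise coalescence
rates.

Sequentially Markovian coalescent methods estimate piecewise-constant
pairwise coalescence rates within and across populations —
λ₁₁(t), λ₂₂(t), λ₁₂(t) — from whole genome sequences. Those rate functions
confound population size change with population separation. `imtracer`
re-parameterizes the rate triple into a two-island isolation-migration
model with time-dependent diploid sizes N₁(t), N₂(t) and a time-dependent
symmetric migration rate m(t), fitted by minimizing a regularized
chi-square discrepancy between the coalescence-time distributions implied
by the model and by the rate table:

    chi^2 = sum_i [ sum_{s0} (P_IM(i|s0) - P_MSMC(i|s0))^2 / P_MSMC(i|s0)
                    + beta1 * m_i * dt_i
                    + beta2 * ((N1_i - N2_i)/(N1_i + N2_i))^2 ]

with s0 ranging over the three start states of a lineage pair (both in
island 1, one in each, both in island 2). The central derived quantity is
the cumulative migration probability

    M(t) = 1 - exp( - int_0^t m(t') dt' ),

the fraction of cross-population ancestry that has merged by time t;
`1 - M(t*)` estimates ancestry contributed by lineages diverged deeper
than t*. The package is aimed at population geneticists who have pairwise
rate estimates (or want to simulate them) and need interpretable
separation histories: split times, post-split gene flow, and archaic or
otherwise deep ancestry fractions.

Beyond the fitting function the package ships everything needed to
reproduce the underlying simulation study without external data: an exact
structured-coalescent rate engine for scenario demographies, a pairwise
SMC' hidden Markov model rate estimator with EM over piecewise-constant
rates (composite likelihood across haplotype pairs), msprime-backed
sequence simulation to the multihetsep format, switch-error injection and
a block bootstrap.

## Worked example

Fit the isolation-migration model to exact (noise-free) rates of a clean
population split at 75 kya between two populations of 20,000:

```r
library(imtracer)

grid <- make_time_grid("1*2+25*1+1*2+1*3")   # 28 segments, 32 intervals
tab  <- exact_coal_rates(scenario_clean_split(75), grid)
fit  <- im_fit(tab, config = fit_config(beta1 = 1e-8, beta2 = 1e-6))
summary(fit)
```

```
Isolation-migration fit over 28 time segments
  chi-square: 4.81074e-08 (initial 1.38082e-06 )
  status: converged
  M(t) median: 80739 years

M(t) percentiles (years):
    1%    25%    50%    75%    99%
 74950  77303  80739  86612 113890

migration pulses:
  start_gen end_gen mean_gen delta_M
1      2582    3938     3260  0.9903

deep-ancestry fractions 1 - M(t):
 300kya  600kya  800kya 1000kya
0.00965 0.00965 0.00965 0.00965
```

Reading the output: the fitted migration rate forms a single pulse whose
M(t) median sits at ~81 kya — within one time segment of the simulated
75 kya split (the segment containing the split spans roughly 75–114 kya).
Essentially no ancestry deeper than 300 kya remains (`1 - M ≈ 0.01`, the
residual left once the migration regularization stops adding rate to an
already-merged model), as expected for a clean split. `plot(fit)` draws m(t) and M(t) with the relative cross
coalescence rate overlaid; `coef(fit)`, `predict(fit)`, `residuals(fit)`
and `as.data.frame(fit)` expose the fitted trajectories.

The full estimation pipeline from sequences mirrors the conventional
three-run workflow:

```r
sp    <- scenario_split_with_migration(75)          # 10-15 kya gene flow
files <- simulate_sequences(sp, seed = 1)
g     <- make_time_grid("1*2+25*1+1*2+1*3", spacing = "log")
e11   <- estimate_rates(files, "0,1,2,3", hmm_config(g))
e22   <- estimate_rates(files, "4,5,6,7", hmm_config(g))
e12   <- estimate_rates(files,
           "0-4,0-5,0-6,0-7,1-4,1-5,1-6,1-7,2-4,2-5,2-6,2-7,3-4,3-5,3-6,3-7",
           hmm_config(g))
fit   <- im_fit(combine_cross_coal(e11$table, e12$table, e22$table))
```

A thin command-line wrapper with `estimate-rates`, `combine`, `fit` and
`summarize` subcommands is installed under `inst/scripts/imtracer`.

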