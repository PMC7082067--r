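---
title: "Tracking population separation with a time-dependent isolation-migration model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking population separation with a time-dependent isolation-migration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imtracer)
```

## The problem

Pairwise sequentially Markovian coalescent methods estimate, from whole
genome sequences, piecewise-constant coalescence rates between pairs of
haplotypes: within a population ($\lambda_{11}(t)$, $\lambda_{22}(t)$) and
across a pair of populations ($\lambda_{12}(t)$). These rate functions mix
two very different historical signals — population size change and
population separation. `imtracer` disentangles them by re-parameterizing the
rate triple into a two-island isolation-migration (IM) model with
time-dependent diploid sizes $N_1(t)$, $N_2(t)$ and a time-dependent
symmetric migration rate $m(t)$, all piecewise constant on a shared time
discretization. The quantity of main interest is the cumulative migration
probability
$$ M(t) = 1 - \exp\Big(-\int_0^t m(t')\,dt'\Big), $$
the probability that a cross-population lineage pair has merged into a
common ancestral pool by time $t$. Plateaus of $M(t)$ below one indicate
ancestry contributed by deeply diverged lineages: $1 - M(t^*)$ estimates the
fraction of ancestry older than $t^*$.

## The pair process

A pair of lineages is tracked on a four-state continuous-time Markov chain
with states $S_{11}$ (both lineages in island 1), $S_{12}$ (one in each),
$S_{22}$ (both in island 2) and an absorbing coalesced state $C$:

* $S_{11} \to C$ at rate $1/(2N_1)$, $S_{22} \to C$ at rate $1/(2N_2)$;
* $S_{12} \to S_{11}$ at rate $m/2$ and $S_{12} \to S_{22}$ at rate $m/2$.

Migration in this pair process acts on the separated pair only: a cross
pair merges into one island at total rate $m(t)$. Three observable
consequences fix this kinetic choice, and all three are properties the
method is expected to reproduce:

1. $M(t)$ is *exactly* the probability that a cross pair has merged, so the
   plateau of $M(t)$ for a post-split migration window with per-direction
   migration integral $0.5$ is the pair-mixing probability
   $1 - e^{-(0.5+0.5)} \approx 0.63$, and the plateau in an archaic
   admixture scenario with pulse fraction $\alpha$ sits near $1-\alpha$.
2. The within-island states are untouched by $m$, so the fitted sizes
   remain close to the inverse within-population coalescence rates,
   $N_i(t) \approx 1/(2\lambda_{ii}(t))$ — size change and separation are
   separated by construction.
3. A population split appears as a single pulse of $m(t)$ at the split
   time, with no compensating distortions elsewhere.

An alternative parameterization in which within-island pairs also scatter
(each lineage performing an independent island-switching walk) was
implemented and rejected: it halves the apparent sizes after any merge
phase, turns clean splits into double pulses, and breaks the pair-level
reading of $M(t)$.

Coalescence-time densities $P^{IM}(t \mid s_0)$ for the three start states
are obtained by chaining dense matrix exponentials of the generator across
the piecewise-constant segments; the four-state problem is small enough
that generic dense exponentiation is robust, including at $m \to 0$
degeneracies.

## The fitting objective

The target rate table is first converted into coalescence-time
distributions via the piecewise-exponential
$P^{MSMC}(t \mid s_0) = \lambda(t) \exp(-\int_0^t \lambda)$, selecting the
rate column matching the start state. The fit minimizes a regularized
chi-square discrepancy, summed over time segments $i$ and start states:
$$ \chi^2 = \sum_i \Big[ \sum_{s_0}
   \frac{(P^{IM}_i(s_0) - P^{MSMC}_i(s_0))^2}{P^{MSMC}_i(s_0)}
   + \beta_1 m_i \Delta t_i
   + \beta_2 \Big(\frac{N_{1,i}-N_{2,i}}{N_{1,i}+N_{2,i}}\Big)^2 \Big], $$
with defaults $\beta_1 = 10^{-8}$ and $\beta_2 = 10^{-6}$. Two numerical
choices matter and are configurable:

* **Evaluation point.** Residuals compare instantaneous densities at each
  segment's *right* boundary, evaluated with that segment's own hazards
  (the left-continuous limit); the open-ended final segment is evaluated
  one last-segment span past its left boundary. Evaluating at left
  boundaries instead systematically drags fitted migration pulses one
  segment toward the present, because a piecewise table's density at a left
  boundary already reflects that segment's average hazard. A per-segment
  probability-mass variant (`fit_config(residual = "mass")`) is provided;
  it is exactly zero at a model-matching table but weights recent sharp
  transitions more heavily.
* **Denominator floor.** Target values below a floor (default $10^{-12}$
  per generation) are clamped to the floor rather than dropped. Dropping
  them leaves the recent cross-rate segments — where $\lambda_{12}$ is
  genuinely zero before a split — unconstrained, and the optimizer can then
  hide spurious early migration there.

The migration penalty is accumulated per segment as
$\beta_1 m_i \Delta t_i$, so its total equals $\beta_1 \int m\,dt$; the
open-ended final segment uses the span of the last finite interval.
Estimated sizes are capped at $10^7$; reported migration rates after the
first time $M(t) \ge 0.999$ are masked in summaries, as the model is
over-parameterized once the populations have fully merged — this is the
reason the regularization exists at all.

## Optimization

The fit is deterministic. Sizes are initialized from the inverse
within-rates; migration is initialized by a sequential one-dimensional
root-solve that matches each segment's cross-pair coalescence mass (the
model inversion view: the IM model is essentially a re-parameterization of
the rate triple). Two candidate refinements are then run: coordinate
descent over segments sweeping recent-to-old, and a minimal-migration start
swept old-to-recent (which builds migration from the deep end and therefore
favors the least-migration solution under $\beta_1$). Each candidate's
per-segment step optimizes that segment's $(N_1, N_2, m)$ against the full
downstream objective, so the sweeps are exact coordinate descent and the
objective never increases. Both candidates are finally polished by bounded
L-BFGS-B on $(\log N_1, \log N_2, \log(m + \epsilon))$, and the better
final objective wins. There are no random restarts; the result is a pure
function of the input table and configuration.

## Time discretization

Atomic interval boundaries follow the exponential-quantile convention of
the PSMC family: boundary $i$ of $n$ sits at $-\log(1 - i/n)$ in coalescent
units, divided by the number of haplotype pairs analysed jointly, and
scaled to generations by $2 N_{ref}$ with $N_{ref} = 20{,}000$ by default
(the simulation-study size). Intervals are grouped into parameter segments
by the conventional pattern string, by default `1*2+25*1+1*2+1*3` (28
segments over 32 intervals). With one pair the grid spans roughly 1.3 k to
140 k generations — about two decades of time. Analyses that must resolve
both a recent migration window (10–15 kya) and million-year structure on
the same axis use the geometric alternative
(`make_time_grid(..., spacing = "log")`), which spans roughly 3 kya to
4 Myr. Scaling the quantile boundaries by the pair count was considered
and rejected for the estimation pipeline: it compresses the grid so much
that most cross-population coalescences fall beyond the last boundary,
which visibly biases the rate estimates. All internal computation is in
generations;
conversion to years uses a configurable generation time (29 years by
default — the source analyses report year axes without printing their
conversion, so this is fixed here once and used consistently on both the
simulation and reporting sides, making recovery results
conversion-invariant).

## The scenario engine and sequence simulation

The simulation study is reproduced end-to-end from code. A scenario is a
plain-text description of demes with piecewise-constant sizes and
backward-time events (splits, pulse admixture, windows of continuous
symmetric migration). Two consumers read it:

* `exact_coal_rates()` computes noise-free rate tables by exact propagation
  of the lineage-location CTMC (unordered deme pairs plus a coalesced
  state) through epochs — matrix exponentials within epochs, stochastic
  relabeling matrices at instantaneous events — and reports exact
  segment-average hazards, i.e. what an ideal estimator would return.
* `simulate_sequences()` runs a coalescent-with-recombination simulation
  via a bundled msprime helper (diploid samples, finite-sites binary
  mutations) and writes multihetsep files; output is a pure function of
  (scenario, seed).

The predefined scenarios are two constant-size 20,000 populations with a
clean split at time $T$; the same with a 10–15 kya window of symmetric
migration whose per-direction integral is 0.5; a split at 75 kya with a
30 kya admixture pulse from an unsampled deme diverging 1 Mya ago (pulse
fraction $\alpha$); the same with a factor-30 bottleneck in population 1 at
40–60 kya; and a single-population zigzag alternating between 3,000 and
30,000 across exponentially growing intervals (knots at $1000 \cdot 2^k$
generations — the alternation schedule is this package's own choice, as
only the size range and the exponential spacing are prescribed). Default
simulation dimensions follow the study (22 chromosomes of 100 Mbp, mutation
rate $1.25 \times 10^{-8}$, recombination rate $10^{-8}$; the zigzag uses
$0.3 \times 10^{-8}$); tests and examples reduce chromosome number and
length, never the biological parameters.

What the generator does *not* emulate: variable recombination and mutation
landscapes, genotyping error and missingness masks, unphased or
statistically phased data (switch errors can be injected separately with
`inject_switch_errors()`), and multi-allelic sites. Passing recovery tests
on this generator therefore demonstrates correctness of the estimator and
fit under the model's own assumptions, not robustness to real-data
artifacts.

## The pairwise SMC' rate estimator

`estimate_rates()` is a self-contained pairwise SMC' hidden Markov model
with expectation-maximization over the piecewise-constant coalescence
rates, composited over haplotype pairs:

* **Hidden state**: the time interval containing the local pairwise tMRCA,
  on the atomic intervals of the grid, rates tied within parameter
  segments.
* **Transitions**: the SMC' recombination process. From tMRCA $t$, a
  recombination falls on the local tree with probability
  $1 - e^{-2\rho_w t}$ ($\rho_w$ the per-window recombination rate); the
  cut point is uniform on $(0, t)$; the floating lineage re-coalesces at
  rate $2\lambda$ below $t$ (half of which restores $t$) and $\lambda$
  above. For piecewise-constant rates all integrals have closed forms,
  assembled in $O(K^2)$ via a stable recursion for the recombination-point
  kernel.
* **Emissions**: observations are aggregated over 100 bp windows (the
  classical binning of the PSMC lineage); a window with $n$ called sites
  and $j$ heterozygous sites has probability $(1-p_k)^{n-j} p_k^j$ with
  $p_k = 1 - e^{-2 t_k \mu}$ at the interval's representative time.
  Phase-ambiguous sites contribute the average over their listed phasings
  (for a pair, the constant $1/2$). Called-site counts between records are
  allocated to windows proportionally.
* **Representatives**: $t_k$ is the conditional mean of the interval under
  a constant initial rate estimated from heterozygosity, and is then held
  fixed. Freezing the representatives makes the E/M alternation a proper
  EM in the transition and initial-distribution parameters, so the
  composite log-likelihood is provably nondecreasing — the property the
  tests assert. The cost is a slightly coarser emission model than
  re-deriving representatives each iteration.
* **M-step**: bounded L-BFGS-B on the tied log-rates (and, by default, a
  single scalar effective recombination rate) of the expected
  complete-data objective, warm-started from the incumbent.

A block bootstrap over fixed-length physical blocks, resampled with
replacement and concatenated into pseudo-chromosomes, quantifies estimator
uncertainty; replicates are deterministic given a seed.

## Known limitations

* **Archaic fractions from noise-free tables.** On exact rate tables the
  deep-ancestry reading $1 - M(300\,\mathrm{kya}) \approx \alpha$ is not
  identified for small pulse fractions: the archaic tail depresses the
  within-population-1 rates by about $2\alpha$ and the cross rates by about
  $\alpha$, and a fully merged model whose merged pairs coalesce at the
  average of the two island hazards reproduces the cross curve to first
  order in $\alpha$. The chi-square optimum therefore absorbs the archaic
  signal into the size trajectories, and $M(t)$ saturates; the residual
  margin favoring the $\alpha$-preserving solution is $O(\alpha^2)$,
  below what the regularized objective discriminates. The package reports
  what the objective supports: deep fractions are underestimated on exact
  tables, increasingly so for small $\alpha$, while the *location* of deep
  migration pulses is recovered once $\alpha$ is large enough
  ($\gtrsim 10\%$) for the second pulse to surface.
* **Plateau overshoot.** Fitting exact rates for the split-with-migration
  scenario yields an inter-pulse plateau of $M \approx 0.75$ rather than
  the analytic pair-mixing value $0.63$ — the within-rate dip caused by
  separated within pairs during the migration window is absorbed as a size
  increase, which in turn pushes the fitted migration integral up. The
  same overshoot, to the same level, is the documented behavior of the
  approach this package re-implements.
* **Temporal resolution.** Migration phases closer than roughly one time
  segment merge into single pulses; events inside the first segment cannot
  be located. The estimator itself smears sharp rate changes over adjacent
  intervals at realistic data sizes.
* **Two populations.** The model is strictly pairwise-population;
  multi-deme structure enters only through the scenario engine used for
  validation.

## Problem sizes used in the shipped tests

The test suite exercises the full pipeline at deliberately small problem
sizes chosen to keep the suite fast while leaving every qualitative
behavior intact: single-pair estimator checks use one 3 Mb chromosome;
recovery checks use 2–3 chromosomes of 10–20 Mb with four diploid samples;
fits of exact tables always use full-resolution grids. The vignette's and
README's worked examples use the same reduced dimensions. Scaling the
simulated genomes back to the study's 22 x 100 Mb changes only run time
and the tightness of stochastic tolerances.
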