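# cycnoise

Protein noise decomposition under noisy cell-cycle and gene-duplication
timing.

## What this package is for

Inside a single cell, the copy number of a stable protein is shaped by
three distinct random processes: transcription fires in **bursts**, **cell
division** happens at random times and halves the protein content, and the
molecules are **partitioned** between the daughter cells with binomial-like
errors. On top of that, **genome duplication** doubles (or more generally
multiplies by a dosage factor *f*) the burst arrival rate at a random point
inside the cycle. `cycnoise` is a toolbox for systems biologists who want
to know how much each of these mechanisms contributes to the observed
cell-to-cell variability, and to estimate expression parameters (burst
size, partitioning error) from single-cell measurements.

The core quantities are the lineage steady-state mean and the squared
coefficient of variation, decomposed additively as

    CV^2 = CV_E^2 + CV_R^2 + CV_P^2

where `CV_E^2` is the **extrinsic** contribution of random
division/duplication timing, `CV_R^2` the **partitioning** contribution and
`CV_P^2` the **production** (bursty synthesis) contribution; the last two
form the intrinsic noise. For a cell-cycle time with mean `<T>` and squared
coefficient of variation `CV_T^2`, the package's closed forms include

    <x>    = kx <B> <T> (3 + CV_T^2) / 2
    CV_R^2 = 4 alpha / (3 (3 + CV_T^2)) / <x>
    CV_P^2 = (3 CV_T^2 + 5) / (3 (3 + CV_T^2)) * (<B^2>/<B>) / <x>

with burst arrival rate `kx`, burst-size moments `<B>`, `<B^2>` and
partitioning-error parameter `alpha` (`alpha = 1` is binomial
partitioning). Cell-cycle and duplication timing are modeled as
phase-type (mixture-of-Erlang) clocks, which cover every positively-valued
distribution with CV ≤ 1 and admit an exact Markov-chain treatment.

Three independent engines compute the same quantities and cross-validate
each other:

* **analytics** — exact closed forms (means, noise components,
  f = 2 duplication, the unstable-protein limit, stage-conditioned moments
  for synchronized cells);
* **moment ODEs** — the exactly closed linear moment system over cycle
  stages, solved directly for steady states or integrated for transients
  (this is the route for general dosage factors and degradation);
* **simulator** — an exact event-driven stochastic simulation of a
  single-cell lineage (C++ backend), including the hybrid model variants
  used to isolate the noise components.

An inference layer inverts the intrinsic-noise formulas: burst size from a
single mean/Fano observation, or burst size *and* partitioning error
jointly from a two-condition design in which the burst size is perturbed
(e.g. an RBS mutation).

## Worked example

```r
library(cycnoise)

b   <- burst_model(kx = 10, burst_mean = 1.5)       # geometric bursts
clk <- erlang_mixture_from_target(1, 0.05)          # Erlang-20 clock
p   <- partition_model(alpha = 1)                   # binomial partitioning

decompose_noise(b, clk, p)
#> Protein noise decomposition
#>   mean                  22.875 molecules
#>   CV^2 extrinsic     0.0541969
#>   CV^2 partition     0.0191108
#>   CV^2 production    0.0984204
#>   CV^2 total          0.171728
```

Read: of a total `CV^2` of 0.17 at a mean of ~23 molecules, about a third
(0.054) comes from random division timing alone — a floor that does not
shrink as expression increases — while the partitioning and production
terms scale as 1/mean, with production dominating partitioning here by the
burst moment ratio `<B^2>/<B> = 4`. The moment-ODE engine
(`decompose_numeric(clk, b, p)`) returns the same numbers to 1e-8, and

```r
est <- lineage_moments(simulate_lineage(clk, b, p, n_cycles = 20000, seed = 7))
est
#> mean = 22.9478 (se 0.102); CV^2 = 0.174744 (se 0.0019); 20 batches
```

confirms them by simulation. The two-condition inference example:

```r
estimate_B_alpha_two_condition(fano_ref = 6, fano_perturbed = 4, mean_ratio = 0.5)
#> $burst_mean [1] 3.6     $alpha [1] 3.25
```

a Fano factor dropping from 6 to 4 when the burst size is halved implies a
mean burst of 3.6 molecules with strongly over-dispersed partitioning
(`alpha = 3.25`).

A command-line front end (`inst/cli/cycnoise.R`) exposes the same
operations as subcommands (`decompose`, `scan-mean`, `scan-beta`,
`simulate`, `sync`, `infer`, `validate`) over YAML/JSON configs.

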