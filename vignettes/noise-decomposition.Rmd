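---
title: "Decomposing protein noise across expression, partitioning and cell-cycle timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing protein noise across expression, partitioning and cell-cycle timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycnoise)
```

## The model

`cycnoise` follows a single cell through an infinite line of descent. A
stable protein (no active degradation by default — many bacterial and
mammalian proteins outlive the cell cycle) is produced in bursts: burst
events arrive as a Poisson process with rate $k_x$, and each adds $B$
molecules, $B$ drawn from a burst-size distribution with moments
$\langle B\rangle$ and $\langle B^2\rangle$. At random division times the
molecule count is halved on average, with the daughter's allotment $x_+$
satisfying

$$\mathbb{E}(x_+ \mid x) = x/2, \qquad
  \mathrm{Var}(x_+ \mid x) = \alpha x / 4 .$$

$\alpha = 1$ is independent binomial segregation, $\alpha = 0$ perfectly
even splitting, $\alpha > 1$ the over-dispersion typical of proteins that
aggregate or form multimers. A constant-variance alternative
($\mathrm{Var} = \alpha$) is supported in the continuous model variants.

The cell-cycle time is a **phase-type clock**: a mixture of Erlang
distributions realized as a Markov chain of exponential stages $G_{ij}$,
with stage exit rate $ik$ in a branch of order $i$. With that convention
the mean is exactly $1/k$ whatever the mixture, the squared coefficient of
variation is $CV_T^2 = \sum_i p_i/i \in (0, 1]$, and the normalized third
moment is $1 + 3CV_T^2 + 2\sum_i p_i/i^2$ — so noisier clocks are
necessarily more positively skewed, which is why the steady-state mean
$\langle\bar x\rangle = k_x\langle B\rangle\langle T\rangle(3+CV_T^2)/2$
*increases* with timing noise (long cycles accumulate disproportionately
much protein). Genome duplication is modeled by concatenating two
phase-type clocks ($T_1$ before, $T_2$ after duplication) with the burst
rate multiplied by a dosage factor $f$ in the second phase;
$\beta = \langle T_1\rangle/\langle T\rangle$ locates the duplication in
the cycle.

## The decomposition strategy

The total stationary $CV^2$ splits additively into extrinsic
($CV_E^2$, division/duplication timing), partitioning ($CV_R^2$) and
production ($CV_P^2$) components. The split is *defined* by a hybrid-model
ladder, and every engine in the package implements it the same way:

1. **hybrid B** — deterministic accumulation at rate
   $k_x\langle B\rangle$, error-free halving: its $CV^2$ is $CV_E^2$;
2. **hybrid C** — deterministic accumulation, noisy partitioning:
   its $CV^2$ minus hybrid B's gives $CV_R^2$;
3. **full model** — discrete bursts, noisy partitioning: its $CV^2$ minus
   hybrid C's gives $CV_P^2$.

Because the stage indicators $g_{ij}$ are binary, the moment dynamics of
$(\langle g_{ij}\rangle, \langle x g_{ij}\rangle, \langle x^2
g_{ij}\rangle)$ close **exactly** — no moment-closure approximation is
involved anywhere. `build_moment_system()` assembles the linear generator
(division transitions carry $1/2$, $1/4$ and $\alpha/4$ coefficients on
the first and second moments), and `steady_state_moments()` solves it
directly. The closed forms in `analytics.R` are the same steady states
evaluated symbolically; the test suite checks agreement to $10^{-8}$
relative over a thousand random parameter draws, and the event-driven
simulator provides a third, sampling-based route checked to four
batch-means standard errors.

Two noteworthy identities double as internal consistency checks: with
$B \equiv 1$ and $\alpha = 1$ the intrinsic noise is exactly
$1/\langle\bar x\rangle$ for *any* clock, any duplication fraction and any
conditioning stage; and as $k_x \to \infty$ the total noise falls to the
extrinsic floor, which equals $1/27$ for perfectly periodic cycles.

## Parameters that matter

| parameter | meaning | units | default / typical |
|---|---|---|---|
| `kx` | burst (transcription) arrival rate | 1/time | swept; 10 in examples |
| `burst_mean` | $\langle B\rangle$ | molecules | 1.5 (reference scan); 0.5–5 typical |
| `burst_family` | burst-size law | — | geometric on $\{0,1,\dots\}$ |
| `alpha` | partitioning error | — | 1 (binomial) |
| `mean`/`cv2` of clocks | cycle / phase timing | time, — | $\langle T\rangle = 1$, $CV_T^2 = 0.05$ |
| `f`, `beta` | dosage factor, duplication fraction | — | 2, scanned |
| `gamma_x` | decay rate (unstable proteins) | 1/time | off |

Time is measured in units of the mean cell-cycle length throughout the
examples; nothing depends on that choice. The reference parameter set used
in the noise-versus-mean scan (geometric bursts with
$\langle B\rangle = 1.5$, Erlang-20 clock, $\alpha = 1$) and in the
duplication scan ($\langle B\rangle = 10$, mean 170 molecules, phase CVs
0.05) reflects typical bacterial expression measurements: burst sizes of a
few molecules and cell-cycle timing CVs of a few percent.

**Burst-size support convention.** For a geometric burst distribution the
moment ratio $\langle B^2\rangle/\langle B\rangle$ is $1 + 2\langle
B\rangle$ on support $\{0, 1, \dots\}$ but $2\langle B\rangle - 1$ on
$\{1, 2, \dots\}$. The inference formulas are written in the
$\{0,\dots\}$ convention, so that is the package default
(`geometric0`); the shifted variant is available as `geometric1`. This is
a genuine modeling choice the user should be aware of when comparing
burst-size estimates across studies.

## Construction and numerical choices

* **Clock construction.** For a target $(\,\langle T\rangle, CV_T^2\,)$,
  `erlang_mixture_from_target()` returns the pure Erlang of order
  $1/CV_T^2$ when that is an integer, otherwise the unique two-component
  mixture of the *adjacent* orders $\lfloor 1/CV_T^2\rfloor$ and
  $\lfloor 1/CV_T^2\rfloor + 1$. Many mixtures share the first two
  moments (they differ in the third), and nothing canonical singles one
  out; the adjacent-order rule is minimal in state count and makes the
  third moment a deterministic function of the target, which the
  documentation flags. A requested $CV_T^2 = 0$ cannot be represented by
  any finite phase chain; it is honored in the closed forms and mapped to
  a pure Erlang of order `n_det` (default 200) with a warning for
  sampling and ODE work.
* **Steady states** are computed by replacing one redundant occupancy
  balance row with the normalization $\sum\langle g_{ij}\rangle = 1$ and
  solving the three moment blocks in sequence — exact and cheap, instead
  of integrating to large times. **Transients** use `deSolve::lsoda` with
  the exact constant Jacobian at `rtol = 1e-10`; the system becomes stiff
  for high Erlang orders.
* **Extrema over $\beta$** (duplication-timing optima at fixed mean) are
  bracketed on a grid of step $10^{-4}$ and refined by golden-section
  search to $10^{-8}$. With equal phase CVs both intrinsic extrema sit at
  $\beta = 2 - \sqrt 2$.
* **Partition sampling.** The partitioning framework fixes only two
  conditional moments, so the simulator uses, per regime: a fair-coin
  split of the odd molecule at $\alpha = 0$ (residual variance $1/4$,
  negligible in relative terms); a Binomial$(x, 1/2)$-versus-even-split
  mixture for $0 < \alpha \le 1$; and a symmetric beta-binomial with
  intra-class correlation $(\alpha-1)/(x-1)$ for $\alpha > 1$, which
  matches the variance exactly whenever $2 \le \alpha < x$ and falls back
  to plain binomial below (the variance target $\alpha x/4$ is
  mathematically unreachable for very small $x$). In the continuous
  hybrid C the allotment is a Gamma draw with mean $x/2$ and variance
  $\alpha x/4$, truncated to $[0, x]$; the constant-variance law uses a
  truncated normal, as no discrete counterpart is determined by the two
  moments.
* **Synchronized-cell sampling** draws observation times uniformly over
  the *pooled* time the chain spends in the requested stage, about one
  draw per cycle. Per-cycle uniform draws would over-weight short stage
  sojourns and bias the conditional mean low by
  $k_x\langle B\rangle\langle\tau\rangle/2$; occupancy-time uniformity is
  what realizes the stationary stage-conditioned law.
* **Lognormal cycle times** (not phase-type) are supported in the
  analytics through the closed third-moment ratio $(1+CV_T^2)^3$ and in
  sampling by direct renewal draws; stage-resolved quantities are not
  defined for that mode.
* **Degenerate inputs.** $k_x = 0$ lineages are legal (the protein stays
  at zero); negative $\alpha$ and CVs outside $(0,1]$ are rejected with
  messages naming the constraint; inference refuses Fano factors below
  the partitioning floor $4\alpha/9 + 5/9$ rather than returning a
  clipped estimate, and flags negative two-condition solutions as
  model-inconsistent.

## Design choices where the design was open

* **General dosage factors.** Closed forms for the intrinsic noise exist
  only at $f = 2$; any other $f$ (and any degradation scenario) is routed
  through the numeric moment-ODE path, which needs no special casing and
  is exact. `duplication_intrinsic_f2()` refuses $f \ne 2$ and points to
  the numeric path instead of silently extrapolating.
* **Fixed-mean comparisons** (the $\beta$ scans) rescale $k_x$
  analytically from the duplication mean formula at every grid point, so
  the scans compare noise at identical means rather than identical rates.
* **Lineage statistics.** All stationary quantities are long-run time
  averages along a single line of descent. These differ from
  population-snapshot averages of a growing culture, where fast-dividing
  subtrees are over-represented; users comparing against
  population-resolved microscopy data should be aware of the distinction.
* **Intrinsic noise on simulated data** is defined operationally as the
  total $CV^2$ minus the extrinsic $CV^2$ of the matching hybrid B model,
  mirroring the decomposition; a dual-color assay simulation is out of
  scope. Correspondingly, how extrinsic contamination is removed from
  *experimental* Fano factors is outside the model and remains the
  user's responsibility — the two-condition worked example assumes the
  Fano factors are intrinsic-only.

## Validation scales and what the tests show

The test suite validates: (i) closed forms against the moment-ODE engine
to $10^{-8}$ relative over $10^3$ random parameter draws (mixtures up to
order 20, $\alpha$ up to 4–5, the three burst families, duplication
schedules with phase CVs in $[0.05, 1]$); (ii) the simulator against both,
within four batch-means standard errors, using lineages of
$4\,000$–$20\,000$ cycles with a 50-cycle burn-in and 20 batches; (iii)
the deterministic-timing duplication extrinsic term against
Richardson-extrapolated ODE solves (the error of a phase-type stand-in for
a delta clock is linear in $CV^2$, so two solves at $CV^2 = 10^{-2}$ and
$5\times10^{-3}$ extrapolate to the limit); and (iv) the fast-turnover
closed forms at $\gamma_x\langle T\rangle = 50$, where the residual
$O(1/\gamma_x\langle T_i\rangle)$ relaxation correction is visible and the
agreement tolerance (2% at $\beta = 1/2$) is set accordingly. These sizes
make the full suite run in well under a minute while leaving Monte-Carlo
bands a few standard errors wide — comfortably separating real defects
from noise.

What passing does **not** show: the generator-free parts of real data —
correlated mother–daughter cycle times, dependence between $T_1$ and
$T_2$, cell-size ("adder") feedback on division timing, size-dependent
transcription, and promoter on/off switching — are all outside the model
class. The simulator emulates exactly the model the analytics describe,
so agreement between the engines validates the mathematics, not the
biology.

## Known limitations

* Phase-type clocks cannot represent timing distributions with $CV > 1$,
  nor an exact delta; both limits are handled analytically but only
  approximated generatively.
* The unstable-protein formulas are leading-order in
  $1/(\gamma_x\langle T\rangle)$; at $\gamma_x\langle T\rangle = 50$
  expect percent-level deviations (larger when one cycle phase is short).
* Whole-population (branching) statistics, concentration (per-volume)
  statistics and moments above order two are out of scope.
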