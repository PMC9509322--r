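---
title: "Predicting ligand residence times from steered-MD pull forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ligand residence times from steered-MD pull forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bellevans)
```

## The problem

The residence time (RT) of a drug on its receptor — the mean lifetime of the
bound complex, the reciprocal of the dissociation rate constant $k_{off}$ —
often predicts in-vivo efficacy better than equilibrium affinity does.
Spontaneous unbinding of a tightly bound ligand is far beyond routine MD
timescales, so steered molecular dynamics (SMD) accelerates it: a harmonic
spring of stiffness $k$ (kJ/mol/nm²) attached to the ligand's centre of mass
is retracted at constant velocity $v$ (nm/ps), and the pull force is recorded
every 0.1 ps. This package post-processes such experiments: it never runs MD
itself, and a built-in stochastic rupture simulator stands in for the engine
so the whole pipeline can be exercised and validated at desk scale.

## The Bell-Evans model

Escape over a single activation barrier under applied force $F$ follows the
Bell rate $k(F) = k_{off}\,e^{F x_b / k_B T}$, where $x_b$ (nm) is the
distance from the bound state to the transition state projected on the
pulling direction. Under a force ramp with loading rate $LR = k\,v$ (here
converted to pN/s: $LR = k \times 1.66054 \times v \times 10^{12}$), the most
probable rupture force is

$$F^{*} = \frac{k_B T}{x_b}\,\ln\!\frac{LR\,x_b}{k_B T\,k_{off}}.$$

$F^{*}$ is linear in $\ln LR$, so pulling at several velocities and
regressing the mean maximum unbinding force $F_R^{max}$ (pN) on $\ln LR$
gives a slope $m = k_B T / x_b$ and intercept $c$ from which the kinetics
follow. `bell_evans()` is the fitting function; it returns a classed model
object with the usual `print`/`summary`/`coef`/`predict`/`plot`/
`residuals`/`simulate` methods.

Two $k_{off}$ estimators are provided:

* **`intercept_ratio`** (default): $k_{off} = b/m$ with $b = |c/m|$ the
  magnitude of the x-intercept of the fitted line. This is the convention
  used in published SMD residence-time tables and is what the packaged
  worked example reproduces. Note that it divides a ln-space quantity by a
  pN-valued slope; its unit bookkeeping is not derivable from the modal-force
  relation, and we implement it as the field reports it.
* **`exponential`**: $k_{off} = e^{-c/m}/m$. Setting $F^{*} = 0$ in the
  modal-force relation gives the loading rate $LR_0 = k_B T k_{off}/x_b$ at
  which the line crosses zero force, so $k_{off} = LR_0\,x_b/(k_B T) =
  e^{-c/m}/m$. This estimator exactly inverts the generative model: fed
  noiseless modal forces, it returns the generating $(x_b, k_{off})$ to
  machine precision (a property the test suite asserts at $10^{-6}$).

The signed x-intercept $-c/m$ is negative whenever the data lie at positive
force and positive slope; the model object stores both the magnitude (the
reported-table convention, which makes $b/m > 0$) and the signed value.

## Worked example

The packaged per-velocity summary table (41 replicas per velocity, $k = 600$
kJ/mol/nm², five velocities from 0.0001 to 0.0010 nm/ps) reproduces the
published kinetics for the A2A adenosine receptor agonist NECA:

```{r}
tab <- read_table_csv(system.file("extdata", "table1_summary.csv",
                                  package = "bellevans"))
neca <- tab[tab$system == "2YDV", ]
fit <- bell_evans(force ~ ln_lr,
                  data = data.frame(ln_lr = neca$ln_lr,
                                    force = neca$f_max_mean))
fit
```

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `temperature` | K | 303.15 | typical membrane-protein simulation temperature; $k_B T$ = 4.185 pN·nm |
| `spring_k` | kJ/mol/nm² | 600 | stiff enough that the ramp, not the spring, limits loading |
| velocities | nm/ps | 0.0001–0.0010 | slow-to-fast sweep spanning one decade of loading rate |
| replica count | — | 41 | where the bootstrap SE of the mean rupture force flattens |
| `favorable_threshold` | kJ/mol | −1.00 | per-residue contribution below which a pocket residue counts as favourable |
| pocket `cutoff` | Å | 5.0 (inclusive) | heavy-atom ligand–residue contact distance |
| `noise_sd` | pN | 20 | AR(1) trace-noise SD, the order of replica-to-replica rupture-force SDs |
| `post_rupture_decay` | ps | 50 | relaxation time of the force after rupture |

Boltzmann's constant is fixed at $k_B = 0.0138065$ pN·nm/K. Forces are
stored in the GROMACS native kJ/mol/nm and converted once
(1 kJ/mol/nm = 1.66054 pN); times are stored in ps, with the ps→s factor
applied only inside the loading-rate computation, so each conversion is
testable in isolation.

## The rupture simulator

`bell_params()` + `synthesize_force_trace()` emulate one pulling replica:
a rupture force is drawn by inverse-CDF sampling from the survival law
$S(F) = \exp[-\frac{k_{off} k_B T}{LR\,x_b}(e^{F x_b/k_B T} - 1)]$, the
rupture time $t_r = F_r/LR$ is snapped onto the 0.1 ps force-output grid,
and the trace is a linear ramp to $(t_r, F_r)$, an exponential decay
afterwards, plus stationary AR(1) noise with ~1 ps correlation time. The
companion distance trace advances at $v$ and is saved every 1 ps, mirroring
the coarser coordinate-output interval of pull simulations.
`write_ensemble()` writes the same XVG dialect the reader consumes, with a
YAML manifest recording every parameter and per-replica child seed
(`child = (master + 1664525·counter) mod 2147483629`), so a whole ensemble
regenerates byte-identically.

What the generator does **not** emulate: spring–ligand compliance and
receptor restraints, rebinding, multi-minima landscapes (published force
profiles show secondary peaks; the simulator emits a single rupture), and
tether elasticity. Passing tests therefore validate the post-processing
chain and the estimators, not force-field realism.

## Numerical choices

* Rupture extraction takes the **first** sample attaining the global
  maximum (deterministic under ties, and consistent with reading the first
  major peak as the initial-unbinding event).
* The rupture distance is looked up at the distance-trace sample nearest in
  time (earlier sample on ties), with no interpolation — coordinates are
  saved 10× more coarsely than forces, and nearest-sample lookup is
  reproducible and unbiased at that resolution.
* The two-sample t-test defaults to the pooled-variance form with
  $df = n_1 + n_2 - 2$ (Welch available via `var_equal = FALSE`): with equal
  group sizes the two are numerically indistinguishable, and the pooled form
  reproduces published summary-table p-values at print precision.
* Sample SDs use divisor $N-1$ throughout.
* The bootstrap sweep resamples the **first** $N$ replicas at each grid
  point and reports both the SD of bootstrap means and the mean of
  within-resample SDs, since published convergence plots do not always say
  which "σ" is shown.
* The regression is unweighted OLS by default (per-point SDs are available
  but published fits are unweighted); weights can be supplied.
* $R^2$ is the squared Pearson correlation.
* RT is computed from the unrounded $k_{off}$. A published table whose RT
  equals $1/0.04$ exactly implies rounding $k_{off}$ before inverting; we
  document this rather than emulate it.

## Known limitations

* **The intercept is ill-conditioned.** The data sit at $\ln LR \approx
  25$–$28$ while the x-intercept lies ~22 ln-units away, so small force
  errors are amplified roughly tenfold into the intercept and exponentially
  into the `exponential`-mode $k_{off}$. Feeding the regression means that
  are rounded to two decimals already moves a small x-intercept by ~10%;
  slope-derived quantities ($x_b$, $R^2$) are far more stable. This is also
  why the goodness of fit recomputed from a rounded summary table can differ
  in the second decimal from the value computed on unrounded data.
* **Mean vs mode.** The Bell-Evans relation describes the *modal* rupture
  force, but ensemble pipelines (including this one, following field
  practice) regress the *mean* maximum force. In the high-force limit the
  rupture law is a reversed Gumbel distribution whose mean lies
  $\gamma\,k_B T/x_b$ ($\gamma \approx 0.577$) **below** the mode, which
  biases the `exponential`-mode $k_{off}$ upward by about $e^{\gamma}$; the
  slope (hence $x_b$) is asymptotically unaffected.
* **Extreme-value bias of the global maximum.** With additive trace noise,
  the maximum of ramp-plus-noise exceeds the underlying rupture force, and
  more so at slow velocities where more samples lie near the peak. At the
  default 20 pN noise this flattens the fitted slope noticeably, inflating
  $x_b$; recovering generating parameters from fully noisy traces is
  therefore reliable for the slope but not for the extrapolated intercept.
  The test suite asserts exact recovery on the deterministic (modal-force)
  path and documents the noisy-path behaviour rather than hiding it.
* The per-residue MMPBSA energies are consumed, never recomputed; entropy,
  membrane dielectric and SD propagation into totals are out of scope.

## Problem sizes used by the tests

Unit tests run ensembles of 5–10 replicas at 2–3 velocities; the
distribution-level checks use $10^4$–$10^5$ sampler draws; the end-to-end
checks use the full 5-velocity × 41-replica grid with $B = 10^4$ bootstrap
resamples. The complete suite and the reproduction script each run in
about a minute on one CPU.
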