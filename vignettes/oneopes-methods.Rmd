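---
title: "OneOPES on model potentials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OneOPES on model potentials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
three bias layers, the replica-exchange coupling, the reweighting estimators,
the toy systems that stand in for biomolecular benchmarks, and the numerical
and design choices made where the method description leaves freedom. It
states no empirical number that the test suite or `scripts/acceptance.R` do
not themselves compute.

## 1. The sampling problem and the ladder

A CV-biased simulation converges at the pace of the slowest degree of
freedom *missing* from the biased CVs. OneOPES hedges against imperfect CVs
by running `n` replicas (default 8) of the same system at one thermostat
temperature, layering three bias types of increasing aggressiveness, and
exchanging coordinates between neighbours:

* every replica carries an **OPES Explore** bias on the leading CVs;
* replicas `m..n-1` additionally carry the `m`-th **auxiliary-CV** Explore
  bias (weak, slow) to agitate transversal coordinates;
* replicas `4..n-1` carry an **expanded-ensemble (MultiThermal)** bias on
  the potential energy with a graded maximum temperature.

Replica 0 is the convergence end: its ensemble is exactly the
main-bias-only ensemble (swap moves satisfy detailed balance with respect to
the product of the replica ensembles), so reweighting replica 0 with its own
instantaneous bias is unbiased regardless of what the exploratory replicas
do. Transitions generated upstream by temperature excursions or auxiliary
biases diffuse down the ladder through exchanges.

## 2. Bias layers

### OPES Explore

The sampled distribution of the leading CV is estimated with height-1
Gaussian kernels deposited every `PACE` steps and compressed on the fly: a
new kernel merges into its nearest neighbour when it lies within one
Mahalanobis unit of the deposition width `sigma0` (heights add; the merged
center/variance are the height-weighted first/second moments). The bias is

$$V(s) = k_BT\,(\gamma-1)\,\log\!\Big(\frac{\hat p(s)}{Z}+\varepsilon\Big),
\qquad \gamma = \Delta E / k_BT ,$$

frozen between depositions so the system relaxes under a static potential.
Two conventions for the regularizer are selectable:

* `explore` (default): $\varepsilon = e^{-\Delta E/(k_BT(\gamma-1))}$, the
  pairing under which $V \ge -\Delta E$ holds *exactly*, with equality in
  unexplored regions. This is the bound the test suite enforces.
* `paper`: $\varepsilon = e^{-\Delta E/(k_BT(1-1/\gamma))}$, the
  standard-OPES relation, kept selectable because published descriptions of
  the Explore variant print it; with the $(\gamma-1)$ prefactor it does not
  bound the range by $\Delta E$, so it is not the default.

Two properties worth knowing. First, with the default $\gamma=\Delta E/k_BT$
the `explore` regularizer *increases* with the barrier towards $e^{-1}$
(it only vanishes at fixed $\gamma$). Second, the bias is bounded below by
$-\Delta E$ but not above by a comparably tight cap: early in a run, when
few kernels exist, $\hat p/Z$ at the current basin can reach
$\mathcal O(2)$ and the recorded bias range on the default toy runs reaches
$\sim 1.7\,\Delta E$ before settling. `BARRIER` limits the *depth* the bias
can fill, not the instantaneous peak-to-floor span.

`Z` is estimated as the mean of $\hat p$ over the kernel centers — a
discrete average of the density over the explored region. The estimator has
implementation freedom; this choice is exact for a single kernel, invariant
under merging of coincident kernels, and costs $O(K^2)$ per deposition with
$K$ kept small by compression. Kernel widths are *fixed* (adaptive-sigma
schemes interact badly with exchange-induced jumps and are deliberately not
implemented).

**SIGMA default.** The width should be the standard deviation of the CV in
the starting basin. The package computes it as the harmonic estimate
$\sqrt{k_BT/\partial_s^2 U}$ at the relaxed starting minimum rather than
from a short unbiased pre-run: on the toy double wells a 300 K pre-run
crosses basins (the shallow 1-D barrier is only $\approx 2\,k_BT$), which
makes a sample-s.d. estimate bimodal and far too wide. The curvature
estimate is deterministic, equals the in-basin s.d. in the harmonic limit,
and can be overridden with an explicit `sigma0` in the config.

### OPES MultiCV

Auxiliary biases are ordinary Explore biases with `BARRIER` fixed at
3 kJ/mol and deposition every `2*PACE` steps, in phase with the main bias.
Their job is perturbative: a few kJ/mol along a transversal coordinate is
enough to multiply barrier-crossing rates without distorting exchanges.

### OPES MultiThermal

The expanded-ensemble bias over a temperature grid is

$$V(U) = -k_BT \log\Big( \tfrac{1}{N_T}\sum_j
  e^{-(\beta_j-\beta)U + \beta_j \Delta F_j} \Big),$$

with uniform target weights $1/N_T$ across grid temperatures. The shifts
$\Delta F_j$ obey
$e^{-\beta_j \Delta F_j} = \sum_k w_k e^{-(\beta_j-\beta)U_k} / \sum_k w_k$
with on-the-fly weights $w_k = e^{\beta V_k^{TOT}}$, maintained in streaming
log-sum-exp accumulators ($O(N_T)$ memory, permutation-invariant, no
trajectory re-scans, overflow-safe). $\Delta F$ at the thermostat
temperature is zero by construction. The grid is geometric in $\beta$
between $\beta(T_{min})$ and $\beta(T_{max})$ with the thermostat point
inserted if absent; `N_T = 20` by default, ample for toy-system energy
fluctuations (a PLUMED-style auto-tuning of `N_T` is unnecessary here). The
force on coordinates is $-\,\mathrm dV/\mathrm dU\,\nabla U$ by the chain
rule.

### Exchanges

Every `PACE/10` steps, coordinate (and velocity) swaps are attempted on
alternating even/odd neighbour pairs — a deterministic sweep; the method
description does not fix the pair-selection scheme, and alternation gives
every pair equal attempt frequency with no RNG coupling between pairs. The
acceptance is Metropolis–Hastings on
$\bar U = U + V^{TOT}$; with identical Hamiltonians and one thermostat the
bare-energy terms cancel identically and only bias cross-terms remain.
Bias states never move: swapping exchanges configurations only. Healthy
ladders keep every neighbour acceptance above roughly 20%; the
`exchange_statistics()` diagnostic flags pairs below that threshold.

## 3. Model systems, integrator, oracles

The built-in systems replace force-field benchmarks:

* `double_well_1d` ($h=5$, $d=2$ kJ/mol): near-ideal-CV control.
* `hidden_barrier_2d` ($h_x=5$, $h_y=25$, $k_c=8$, $d=2$ kJ/mol): the
  central benchmark. `x` separates the states across a shallow barrier, but
  interconversion requires flipping `y` across a $\sim 10\,k_BT$ barrier
  that `x`-biasing cannot see — a caricature of a suboptimal leading CV.
* `mueller_brown`: the standard four-Gaussian surface.
* `harmonic_2d`: exactly solvable; used for equipartition and multithermal
  calibration tests.

Dynamics are BAOAB Langevin (half-kick, half-drift, Ornstein–Uhlenbeck
refresh, half-drift, half-kick), chosen for its configurational accuracy at
large timesteps; at zero friction it reduces to symplectic velocity Verlet
(energy drift $<10^{-3}$ kJ/mol over $10^4$ steps in the tests). An
Euler–Maruyama alternative sits behind a flag for comparison. Units are
PLUMED-compatible: kJ/mol, nm, ps, K, with
$k_B = 0.0083144621$ kJ/(mol·K) fixed. RNG streams are derived
deterministically from one root seed (splitmix-style mixing of
`(seed, stream)` feeding mt19937-64, with hand-mapped uniforms and
Box–Muller Gaussians so results do not depend on compiler library choices);
replica $i$ uses stream $i$ and exchanges use stream 1000. Runs are
bit-reproducible given the seed.

Ground truth comes from quadrature, not simulation: basin masses and FES
profiles integrate the Boltzmann weight with fixed-order Gauss–Legendre
panels along the CV and Simpson's rule across the transverse coordinate
(801 nodes by default), which makes the oracle stable to $10^{-6}$ kJ/mol
under grid doubling; a coverage guard rejects grids or domains missing more
than $10^{-6}$ of the probability mass. Custom (non-coordinate) CVs fall
back to a dense-grid histogram of lower accuracy.

## 4. Reweighting and thermodynamics

* **Weights**: $w_t \propto e^{\beta V_t}$ with $V_t$ the instantaneous
  *main* Explore bias of replica 0 (default) or the total stack; the first
  10% of frames are zero-weighted. $\Delta F(t)$ convergence curves
  recompute weights per checkpoint, applying the same discard rule to the
  truncated trajectory (cumulative, not windowed).
* **Errors**: 10 contiguous equal-length blocks; the standard error of the
  weight-weighted per-block estimates. Blocks where a basin is unpopulated
  are dropped from the spread (they carry no ratio information).
* **Multi-temperature**: $w_t \propto e^{\beta_0 V^{TOT}_t}
  e^{-(\beta'-\beta_0)U_t}$ from a MultiThermal-carrying replica
  (replica 6 by convention — exploratory enough to heat, not the wildest);
  targets outside the sampled range warn (extrapolation) rather than error.
* **Van't Hoff**: weighted least squares of $\Delta F = \Delta H - T\Delta S$.
  When per-point errors are supplied they are treated as known, so the
  parameter covariance is $(X^TWX)^{-1}$; $T_m = \Delta H/\Delta S$ with a
  first-order (delta-method) uncertainty; $\Delta S \approx 0$ flags an
  undefined melting temperature instead of dividing by it.

Basin definitions are explicit CV intervals in the config (half-open,
`lo <= s < hi`); the default hidden-barrier basins are $[-3,0)$ and
$[0,3)$ on `x`. Transition counting uses hysteresis — a crossing requires
full entry into the opposite basin — so gap noise is never counted.

## 5. Study conditions and problem sizes

The default configuration *is* the benchmark condition set, chosen once:
thermostat 300 K, `dt` 0.002 ps, friction 5 ps$^{-1}$, mass 1; `PACE` 1000
steps, `BARRIER` 30 kJ/mol (the recommended conservative starting value;
comfortably above the hidden barrier), MultiCV `BARRIER` 3 kJ/mol on `y`,
`TEMP_MAX` schedule 400/450/500/600 K for replicas 4–7 (graded to protect
the 3–4 exchange boundary), `N_T` 20, exchange/record stride `PACE/10`,
MultiThermal stride `PACE/100`, MultiCV pace `2*PACE`, $2\times10^6$ steps
(4 ns) per replica, 10% discard, 10 blocks. Five independent seeds
constitute a batch; the acceptance script reports the batch's mean absolute
$\Delta F$ error in $k_BT$ and the minimum neighbour exchange rate. These
sizes keep a full batch under a minute per seed on one CPU while giving the
reweighted estimator a few hundred effective basin visits.

## 6. What the toy benchmarks do and do not show

The generator emulates the *structure* of the hard problem — a suboptimal
leading CV orthogonal to the slow barrier, entropy/enthalpy balance across a
temperature range, exchange bottlenecks — with exactly known answers. It
does not emulate: rough many-minima landscapes, solvent and friction
anisotropy, CVs that are nonlinear functions of many coordinates, or the
cost structure of force-field MD. Passing the suite therefore validates the
estimators and the ladder mechanics, not the claim that any particular
biomolecular system will converge.

Known limitations, reproduced deliberately:

* The FES is trustworthy in the basins but not at the transition state —
  exchanges import configurations that bypass the barrier top, so tests
  assert basin depths only.
* The recorded Explore bias span exceeds `BARRIER` during the early
  transient (Section 2); only the $-\Delta E$ floor is exact.
* $\Delta F(T)$ curves on the toy ladder have an oracle slope
  ($\sim$0.2 kJ/mol across 320–480 K) far below the per-point statistical
  error, so monotonicity in $T$ is not a resolvable property at these run
  lengths; each point is instead checked against the per-temperature
  quadrature oracle within 3 standard errors.
* The single-replica Explore control on the hidden-barrier system is not
  transition-starved — the strong `x` bias eventually drags the system over
  the coupled barrier — but its $\Delta F$ estimate is hysteretic and
  seed-dependent (several $k_BT$ spread), which is the pathology the ladder
  removes.

## 7. Degenerate inputs and guards

`BARRIER <= kB*T` (i.e. $\gamma \le 1$) is rejected as degenerate; empty
kernel estimators refuse density/Z queries (the bias itself is defined as 0
before the first deposition); `N_T = 1` at the thermostat temperature gives
an identically zero MultiThermal bias; non-finite forces, coordinates, CV
values and ragged or header-less COLVAR files raise immediate, located
errors; quadrature rejects under-covering grids; single-temperature Van't
Hoff designs are singular by construction and error out. Numerical ties in
kernel merging resolve to the nearest kernel (first minimum); exchange
draws accept strictly below $\alpha$.
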