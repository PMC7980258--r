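---
title: "A stochastic sum-of-products model of filopodial growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic sum-of-products model of filopodial growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(filodyn)
```

## The model

Filopodia and filopodia-like structures (FLS) grown on supported bilayers
elongate and shrink erratically, yet their growth velocities collapse onto a
strikingly simple law: a bi-exponential (Laplace) distribution, implying
exponentially distributed lengths. `filodyn` implements a minimal generative
explanation. Each of $K = M \cdot N$ actin regulators at the tip complex has a
concentration $A_i(t)$ relaxing toward a baseline $\tilde A_i$ as an
Ornstein--Uhlenbeck (OU) process,

$$\mathrm{d}A_i = \theta(\tilde A_i - A_i)\,\mathrm{d}t + \mathrm{d}W, \qquad
\langle W(t)W(s)\rangle = 2\theta\eta^2\,\delta(t - s),$$

so the deviations $X_i = A_i - \tilde A_i$ are stationary Gaussian with
variance $\eta^2$ and relaxation time $1/\theta$. Regulators act in complexes:
the growth force (equal to the velocity in the overdamped regime) is a sum of
$M$ products of $N$ fluctuating deviations,

$$F_{M,N}(t) = \sum_{i=1}^{M}\prod_{j=1}^{N} X_{N(i-1)+j}(t),$$

and the length obeys $\mathrm{d}L/\mathrm{d}t = F$ with $L \ge 0$ and
$L = 0$ before initiation. For $M = N = 2$ the stationary force is *exactly*
Laplace: the product of two standard normals has a Bessel-$K_0$ density, and
the sum of two independent such products is Laplace. `laplace_density_check()`
verifies this by Monte Carlo, and also that a single product fails the same
comparison. For independent stationary factors,
$\operatorname{Var}(F_{M,N}) = M\eta^{2N}$.

A mass-action reduction (`simulate_reaction_network()`) grounds the product
terms biochemically: $2M$ species produced at rate $\sigma$ pair at rate
$\rho$ into $M$ complexes decaying at rate $\eta_{\text{decay}}$. Setting
$\dot a = \sigma - \rho a^2 = 0$ gives the species steady state
$\sqrt{\sigma/\rho}$ (the balance equation forces the square root). Species
fluctuate with OU dynamics reflected at zero; the claim that the velocity
approaches a Laplace in the large-variance regime holds for the
*signed* combination $\nu = \sum_j (-1)^j \dot b_j$ (regulators of growth
versus shrinkage): the unsigned sum of positive pair fluxes is right-skewed
and stays visibly non-Laplace, whereas the signed velocity passes a KS
comparison against an MLE-matched Laplace at $n = 10^5$ (measured KS
$\approx 0.009$). Both variants are exposed through the `signed` flag. The
reduction needs two fluctuation parameters the printed rate equations do not
fix (`theta_a`, `eta_a`); defaults put the system deep in the large-variance
regime ($\eta_a = 10\sqrt{\sigma/\rho}$).

## Parameters and defaults

| Parameter | Units | Default | Why |
|---|---|---|---|
| `M`, `N` | counts | 2, 2 | smallest combination with an exactly Laplace force |
| `theta` | 1/min | 11 | per-protein relaxation rate consistent with a fitted velocity relaxation of ~22/min shared over $N = 2$ factors |
| `eta` | conc. units | 2 | places simulated 20-min lengths across the 5--20 um analysis window |
| `dt` | s | 1 | Euler--Maruyama step |
| `duration` | min | 20 | the standard length-collection time point |
| truncation | um | [5, 20] | excludes immature structures and axial-resolution artifacts |
| SG smoothing | frames | 11 / order 3 (snapshot series), 5 / order 2 (tracked filaments) | segmentation-noise suppression, exact on low-order trends |
| pixel size | um/px | 0.1487 | the 2.97 um / 20 px ROI geometry of the imaging protocol |

## Numerical choices

**Discretization.** `theta` is specified in 1/min and converted internally;
the explicit update $A \leftarrow A + \theta(\tilde A - A)\,dt +
\sqrt{2\theta\eta^2 dt}\,z$ requires $\theta\,dt < 1$ (checked at
construction). The scheme is an AR(1) with coefficient $1 - \theta\,dt$, so
its stationary variance is biased upward by the factor $1/(1 - \theta dt/2)$
— about +10% at $\theta = 11$/min, $dt = 1$ s. This leaves the *shape* of
the force distribution untouched (every factor is still Gaussian and scales
cancel under the unit-variance normalization and under MLE-matched fits),
but closed-form OU checks are run at $\theta\,dt \approx 0.017$, where the
bias is below 1%.

**Length constraint.** $L \ge 0$ is enforced by projection,
$L \leftarrow \max(0, L + F\,dt)$, not reflection; only the non-negativity
condition itself is part of the model.

**Stationary sampling.** Stationary velocities are drawn by running many
independent regulator chains for a burn-in of $10/\theta$ and composing one
force sample per chain — exactly stationary, mutually independent draws.
Within the `scan_mn()` grid the normalized stationary shape depends only on
$(M, N)$, so the simulation uses $\theta = 6$/min, $\eta = 1$ for fast
equilibration.

**Estimators.** The Laplace MLE uses the lower median for even $n$ (a
deterministic tie-break) and the mean absolute deviation as scale; the
distribution's variance is $2b^2$. The doubly truncated exponential MLE
solves the truncated-mean equation in the stable parametrization
$\bar y = a + d\,h(u)$ with $h(u) = 1/u - 1/(e^u - 1)$, $u = d/s$; samples
whose mean exceeds the window midpoint have no MLE and are flagged rather
than extrapolated. Q--Q scale is the regression-through-origin slope on unit
exponential quantiles, so exact quantile inputs land on the identity line.

**Model selection.** "Normalized" velocity comparisons scale each sample to
unit variance before the two-sample KS statistic. The `fit_theta()`
objective is the KS distance after median-ratio scaling of the truncated
(>5 um) length samples — a grid search for reproducibility. Cells of the
$(M, N)$ grid along the ridge $N \approx$ best-$N(M)$ are genuinely
near-degenerate with $(2, 2)$ (asymptotic normalized-KS distances of
0.008--0.010 for (5,3)/(6,3)); with $2\times 10^4$ simulated velocities per
cell the global argmin can occasionally land on that ridge rather than at
$(2, 2)$ — which restates, rather than contradicts, the observation that
many regulator amalgamations produce the same velocity law. The scan's
reference sample is $10^5$ velocities, the order of the measured reference.

**Timescale prediction.** The per-protein relaxation rate is $\lambda/N$;
the characteristic recovery time uses the reciprocal convention $60/(\lambda/N)$
seconds (matching the printed ~5 s for $\lambda = 22$/min, $N = 2$);
$\ln 2$-based half-life is available as an option.

## Post-processing conventions

Records below 0.5 um effective base diameter are dropped (strictly below:
0.50 um is kept). "Top half" enrichment and cohort percentiles are computed
per field of view by default — global thresholds would conflate illumination
differences between fields — with the global variant available. Negative
background-corrected intensities are preserved (ranks are unaffected).
Track repair merges fragments whose lifetime-average base positions are
within 1 um (strict), separated by at most 6 frames, without temporal
overlap, greedily by ascending distance; the result is independent of input
order on chain fixtures. Cross-correlation averages per-trajectory Pearson
coefficients unweighted, each trajectory contributing only at shifts it
fully covers; negative shifts mean intensity precedes velocity. Shaft
profiles use a 66% residual-resampling bootstrap interval; all other
intervals are 95% t-intervals of the mean.

The filament tracker follows the printed constants throughout: 11-px
Gaussian local threshold, 13x13 patches at 20:1 negative sampling (minimum
five samples per leaf; tree depth is left unrestricted, which in practice
matches a depth cap of 50), <40 px component cleanup (strict), DBSCAN with
radius 7 and 20 points, skeletonization, tip joining within 20 px and 30
degrees (tangents averaged over the three pixels nearest each tip, compared
as undirected lines), longest-path length measurement with 1/sqrt(2) step
weights (diagonal steps that shortcut an axial corner are pruned so paths
cannot zig-zag), Hungarian frame linking with cost
$0.6\,d + 0.4\,|L_1 - L_2|$ gated at 30 px, and removal of tracks under 5
frames. The printed cost's signed length term would reward pairing with
longer filaments; the absolute difference is the default, the signed form
sits behind a flag. The z-stack segmenter extends traces to the nearest
next-plane candidate strictly within the tracing radius (radius 0 therefore
disables tracing), ties broken by detection order.

## What the synthetic data emulates — and what it does not

Each generator is a pure function of its parameters and seed, and its
ground truth determines every downstream statistic's true value:

* **Trajectory sets** reproduce the study conditions: random initiation on
  0--20 min, collection at 20 min.
* **Intensity tables** use lognormal marginals (non-negative, right-skewed,
  as microscopy intensities are) with a Gaussian copula imposing the target
  *Spearman* structure — only rank correlations are analysed downstream. The
  planted enrichment effect is calibrated so that the expected
  `enrichment_length_change()` readout for the >= 2-enriched buckets equals
  the nominal effect: a naive multiplier on those records would be diluted
  by the enriched records' own contribution to the field mean (about half
  the records have >= 2 of 3 channels in the top half under independence,
  so a naive +10% would read out as ~+4.8%).
* **FRAP traces** have a prebleach plateau, instantaneous drop,
  single-exponential recovery of the mobile fraction, multiplicative
  acquisition bleaching on both structure ROIs, and the protocol's
  nonuniform sampling (0.5 s x 40 frames, then 1 s). Because single noisy
  traces carry >10% half-time uncertainty at realistic noise, recovery
  checks compare the median fit over repeated traces, as the experiments
  pool tens of structures per protein.
* **Rod stacks and filament movies** provide voxel/pixel ground truth
  (base centroids, areas, tip positions, skeletons, identities). Movie
  filaments are laid out as a separated, leading-edge-like field so that
  identity is recoverable — the generator emulates resolvable structures,
  not entangled crossing bundles. Annotations mark every rendered filament
  pixel, as a human tracer would.

None of the generators model shot noise, depth-dependent PSFs, uneven
illumination or photobleaching of the structures themselves; passing tests
demonstrate correctness of the algorithms against their stated contracts,
not robustness to every artifact of real microscopy.

## Problem sizes

The shipped analyses and checks use: $10^5$ stationary velocities for the
Laplace comparison and the scan reference; $2\times 10^4$ simulated
velocities per scan cell on the 6x6 grid; 5,000 trajectories per `fit_theta()`
candidate against 3,000 observed lengths; 2,000--3,000-trajectory sets for
length and persistence distributions; intensity tables of 10 fields x 2,000
records; 15 FRAP traces per condition; movies of 5 filaments x 20--40
frames at 128x128 px. These sizes keep every stage's Monte-Carlo error
comfortably inside the tolerances it is checked against.

## Known limitations

* The mapping from fitted $\theta$ values to the velocity relaxation rate
  $\lambda$ is not modelled; $\lambda$ is a user input to
  `predict_fluctuation_timescale()`.
* The truncated-exponential machinery is validated on synthetic draws; the
  printed characteristic length/area of the original microscopy data are
  not recomputable without the raw images.
* Exact longest-path measurement assumes skeletons are trees after
  redundant-diagonal pruning; genuine loops are broken at their shortest
  edges and flagged.
* The $(M, N)$ scan identifies complexity only up to the near-degenerate
  ridge discussed above.
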