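# filodyn

Stochastic modelling and image analysis of filopodial growth dynamics.

Filopodia and reconstituted filopodia-like structures (FLS) grow and shrink
erratically, driven by a heterogeneous assembly of actin regulators at their
tip. Their growth velocities follow a Laplace (bi-exponential) distribution
and their lengths an exponential one — signatures that simple monomer
addition/removal cannot produce. `filodyn` implements a generative
explanation and the analysis stack around it, for quantitative cell
biologists and biophysicists working on actin-based protrusions:

* **Stochastic model** — regulator concentrations relax as independent
  Ornstein–Uhlenbeck processes, dA<sub>i</sub> = θ(Ã<sub>i</sub> −
  A<sub>i</sub>)dt + dW with ⟨W(t)W(s)⟩ = 2θη²δ(t−s); the growth velocity
  is a sum of M products of N fluctuating deviations,
  F = Σ<sub>i</sub> Π<sub>j</sub> X<sub>N(i−1)+j</sub>, and dL/dt = F with
  L ≥ 0. For M = N = 2, F is exactly Laplace; Var(F) = M·η^(2N). A
  mass-action reaction network (production σ, pairing ρ, complex decay)
  grounds the product terms biochemically.
* **Inference** — Laplace and doubly-truncated-exponential maximum
  likelihood, exponential Q–Q diagnostics, persistence-time extraction, a
  Kolmogorov–Smirnov model-selection scan over (M, N), single-parameter θ
  fitting of length distributions, and the per-protein fluctuation-timescale
  prediction λ/N.
* **FLS post-processing** — diameter/length filters, ring background
  correction, greedy track repair, Savitzky–Golay velocities, per-field
  Spearman correlation matrices, enrichment cohorts, velocity–intensity
  cross-correlation, shaft-profile decay fits.
* **FRAP** — four-ROI normalization (background subtraction, acquisition
  bleach correction, prebleach = 1, bleach frame = 0) and A(1 − e^(−kt))
  recovery fitting.
* **Image pipelines** — a difference-of-Gaussians z-stack segmenter with
  greedy z-tracing, and a machine-learning filament tracer/tracker
  (local thresholding, random-forest pixel classification, DBSCAN cleanup,
  skeletonization with tip joining, longest-path lengths, Hungarian frame
  linking, Savitzky–Golay track velocities).
* **Synthetic data** — deterministic generators with full ground truth for
  every stage: trajectory sets, rank-correlated intensity tables, FRAP
  traces, 3D rod stacks, 2D filament movies with planted track breaks.

## Worked example

Simulate growth trajectories, fit the velocity distribution, and scan model
complexity:

```r
library(filodyn)

params <- growth_model_params(M = 2, N = 2, theta = 11, eta = 2,
                              duration = 20, seed = 1)
scene <- gen_trajectory_set(params, n_traj = 2000, initiation_window = 20)
vel <- as.vector(scene$velocities[, scene$times > 2])
fit_laplace(vel)
#> Laplace MLE: location -0.0095, scale b 4.404 (variance 38.79), n = 2160000

ref <- sample_stationary_velocities(
  growth_model_params(M = 2, N = 2, theta = 6, eta = 1, duration = 1, seed = 3),
  1e5, seed = 3)
scan <- scan_mn(ref, M_range = 1:6, N_range = 1:6, n_sim = 2e4, seed = 4)
scan$best_cell
#> M N
#> 2 2

predict_fluctuation_timescale(lambda = 22, N = 2)$per_protein_rate
#> [1] 11      # per-protein relaxation rate, 1/min -> ~5 s recovery time
```

The Laplace location sits at zero (growth and shrinkage balance), the scale
`b` sets the single free width parameter (variance 2b²), and the scan's
best-fitting cell recovers the generating complexity (M = 2, N = 2), with
the best N per M increasing slowly with M. Dividing a fitted velocity
relaxation rate of 22/min over N = 2 factors predicts an 11/min per-protein
exchange rate, i.e. a ~5-second recovery timescale, the order observed for
the fastest tip-complex components.

The numbered scripts under `analysis/` run the full set of analyses
(simulation and velocity fits, length distributions and persistence times,
the (M,N)/θ scans, enrichment and correlation statistics, FRAP recovery,
and the imaging pipelines end to end) and write their tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

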