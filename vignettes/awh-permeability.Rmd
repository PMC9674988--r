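---
title: "Adaptive-bias sampling and membrane permeability on Langevin model systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-bias sampling and membrane permeability on Langevin model systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awhperm)
```

## The problem

The permeability coefficient $K_P$ of a molecule crossing a stacked lipid
barrier (such as the intercellular lamellae of the stratum corneum) is, under
the inhomogeneous solubility–diffusion model,

$$\frac{1}{K_P} = R = N_{\mathrm{bilayers}} \int_{z_1}^{z_2}
\frac{e^{\beta\,\Delta G_{\mathrm{rel.solvent}}(z)}}{D(z)}\,dz,$$

where $\Delta G_{\mathrm{rel.solvent}}(z)$ is the free energy of the permeant
at depth $z$ relative to the reference solvent, $D(z)$ the local diffusion
coefficient, $\beta = 1/k_BT$, and $N_{\mathrm{bilayers}}$ the number of
bilayers the permeant crosses in a full barrier (here modelled as
$12\pm0.4$ intercellular lipid regions of $2.5\pm0.5$ bilayers each,
i.e. $30\pm6$).

Estimating $\Delta G(z)$ and $D(z)$ in a gel-phase membrane is the hard part:
correlation times are enormous because the permeant's orientation and its
packing environment relax extremely slowly. This package implements the
sampling strategy that addresses this — the accelerated weight histogram
(AWH) method on a two-dimensional reaction coordinate combining the spatial
depth $z$ with an *alchemical* coordinate $\lambda$ that gradually decouples
the permeant from its environment — together with the friction-metric
diffusion estimator and the permeability post-processing pipeline.
Everything runs on analytically known Langevin model systems, so every
estimate can be checked against quadrature.

## The sampler

### Extended ensemble and adaptive bias

The reaction-coordinate space is a grid of points $m = (z_j, \lambda_l)$:
spatial bins crossed with a discrete ladder of coupling states
($\lambda = 0$ fully interacting, $\lambda = 1$ fully decoupled; 21
equidistant states by default). A walker is a Langevin trajectory in the
continuous coordinates $(z, \theta)$ governed by the Hamiltonian of its
current reference point: a harmonic umbrella $\tfrac{k}{2}(z - z_j)^2$
(default $k = 25{,}000$ kJ mol$^{-1}$ nm$^{-2}$) plus the coupled landscape
potential at $\lambda_l$.

Every `mc_interval` integration steps (10 by default; 100 is the other
standard cadence) the reference point is redrawn by a Gibbs sweep over the
candidate points — all $\lambda$ states, and spatial bins within $4\sigma$
of the walker, $\sigma = \sqrt{k_BT/k}$ — with weight

$$w(m) \;\propto\; \rho(m)\, e^{\beta f(m)}\, K(z, z_m)\,
e^{-\beta\,[U_{\lambda_m}(z,\theta) - U_{\lambda_{\mathrm{cur}}}(z,\theta)]},$$

where $\rho$ is the target distribution, $f$ the current free-energy
estimate, and $K$ the umbrella kernel. An accepted $\lambda$ move switches
the governing Hamiltonian instantaneously, in the expanded-ensemble
convention. Each move contributes its normalised weight vector as one sample.

Because walkers move by *reflected* dynamics at the domain boundaries, the
conditional distribution of $z$ around a reference near a wall is the
*folded* Gaussian. The kernel $K$ therefore includes the mirror images
across both walls (or the periodic images). Without the image terms the
reference-point free energy acquires a spurious $\sim k_BT\ln 2$ lift at the
edge bins — exactly the kind of boundary spike that edge trimming
(`trim_edges()`) removes from profiles produced by tools that do not fold
the kernel. With the folded kernel our own decoupled-state slice is flat to
within sampling noise.

### The update rule

With accumulated sample weights $\Delta W(m)$ from a batch of $n$ samples
(10 per update by default, pooled across communicating walkers), the
free-energy estimate is updated by the weighted-histogram rule

$$f(m) \;\leftarrow\; f(m) - k_BT\,
\log\frac{N\rho(m) + \Delta W(m)}{N\rho(m) + n\rho(m)},$$

then re-anchored so that $\min_m f(m) = 0$ over the target support (any
consistent anchor works; the minimum keeps $f$ interpretable as a
non-negative bias). The update vanishes in expectation when the sampled
marginal equals the target, and its magnitude scales as $1/N$, so the
reference histogram size $N$ plays the role of an adaptive learning-rate
inverse.

The initial size is set indirectly from an error estimate:
$$N_0 = \left(\frac{k_BT}{\varepsilon_0}\right)^2
\frac{\tau_{\mathrm{cross}}}{\Delta t_{\mathrm{sample}}},
\qquad
\tau_{\mathrm{cross}} = \max\!\left(\frac{L_z^2}{D_z^{\mathrm{in}}},
\frac{1}{D_\lambda^{\mathrm{in}}}\right),$$

with $\varepsilon_0$ the assumed initial error (10 kJ/mol by default) and
$D^{\mathrm{in}}$ the *input* diffusion constants — estimates of the
system's actual mobility that control only the histogram size, never the
measured diffusion profile. The rule is monotone (larger assumed error
$\Rightarrow$ smaller $N_0$ $\Rightarrow$ larger first updates), and at the
solvation-leg default $D_\lambda^{\mathrm{in}} = 10^{-3}$ ps$^{-1}$ it
implies the familiar $\sim$1 ns expected crossing time of the alchemical
axis.

### Initial stage, covering and stages

During the initial stage $N$ is held fixed between *covering* events. A
covering requires the union of qualifying walkers to have visited every
target-supported grid point, where a walker qualifies only if it has
individually traversed the whole $\lambda$ ladder (flag on by default) and
a spatial diameter of at least 0.8 nm (capped at the grid extent) since the
last covering. Each covering multiplies $N$ by the growth factor (3), resets
the per-walker covering bookkeeping, and the sampler leaves the initial
stage once $N$ reaches the number of samples collected so far; from then on
$N$ grows by one per sample. A bias that is never covered stays in the
initial stage indefinitely — the characteristic failure mode of
spatial-only sampling in slowly relaxing systems, and the reason
`extract_pmf()` warns when asked for a PMF from an initial-stage bias.

### Target distribution

Along $z$ the target is uniform. Along $\lambda$ the end states matter most
— the difference between the fully interacting and fully decoupled levels
is the insertion free energy — so the default puts weight 4 on the
interacting state and 2 on the decoupled state against 1 for each interior
state, normalised. These weights are this package's own choice of
end-state emphasis; they are configurable (`make_target()`), and nothing in
the validation suite depends on their exact values.

## The model systems

The built-in landscapes stand in for an all-atom barrier system:

* a membrane profile $G_{\mathrm{mem}}(z)$ over $z \in [0, L]$ (half-system
  with mirror symmetry; reflective boundaries by default, periodic by
  config) composed of Gaussian barriers and wells on a constant solvent
  level — the full-size default uses $L = 5.21$ nm with 25 and
  15 kJ/mol barriers and a 10 kJ/mol well;
* an alchemical axis along which one scalar $\lambda$ scales *all*
  permeant–environment terms simultaneously. Sequential
  electrostatics-then-dispersion schedules are intentionally absent: in a
  gel phase the molecule inserted with only dispersion forces on can lock
  into the wrong orientation, which simultaneous switching avoids. The
  repulsive part is attenuated through a Beutler-style soft core
  ($\alpha = 0.5$, $\sigma = 0.3$ nm): the fully coupled repulsive energy
  $E$ is mapped to an effective inverse-12 pair distance via
  $E = \epsilon(\sigma/r)^{12}$, giving
  $V(\lambda) = (1-\lambda)\,\epsilon/(\alpha\lambda + \sqrt{\epsilon/E})^2$,
  which is exact at $\lambda = 0$, zero at $\lambda = 1$, and capped at
  $(1-\lambda)\epsilon/(\alpha\lambda)^2$ in between however large $E$ is.
  With this energy-to-distance map $\sigma$ cancels algebraically; it
  remains the documented length scale of the mapping while $\alpha$ stays
  active. Attractive and orientational terms scale linearly with
  $(1-\lambda)$;
* optionally a slow orientational degree of freedom $\theta$: a
  favourable-orientation well of depth $d(z)$ behind an orientational
  barrier $B(z)$, both with a Gaussian envelope inside the membrane and both
  proportional to $(1-\lambda)$. At full coupling with $B = 25$ kJ/mol the
  orientational flip time exceeds any desk-scale budget — the "gel-phase
  trap" — while at full decoupling $\theta$ is a free rotor. This is the
  mechanism that makes the 2D spatial $\times$ alchemical coordinate
  qualitatively faster than spatial-only sampling: a walker can decouple,
  reorient freely, and re-couple in the other basin.

What the toys deliberately do **not** emulate: molecular detail (the
"permeant" is one particle), position-dependent intrinsic friction (the
Langevin friction is uniform, so the true $D(z)$ is flat and known), slow
collective environment modes other than the single $\theta$ trap, and any
force-field realism. Passing tests on these systems validate the
*estimators* — that the sampler recovers known free energies, that the
friction metric recovers known diffusion, that the pipeline reproduces a
known $K_P$ — not the realism of any membrane model.

Because every analytic reference is available by quadrature
(`reference_pmf()`, `reference_solvation()` integrate over $\theta$ and the
$\lambda$ path directly), the oracles are independent of the sampling code
they check.

## Diffusion from the friction metric

The local diffusion coefficient is estimated from the autocovariance of the
umbrella (bias) force. Per walker and spatial bin,

$$g(z) = \beta^2 \int_0^\infty \langle \delta F(t)\,\delta F(0)\rangle_z\,dt,
\qquad D(z) = g^{-1}(z),$$

evaluated with a blocked estimator: the run is cut into `n_blocks`
contiguous time blocks (128 by default), $s_b(z)$ is the time-integrated
force fluctuation collected in block $b$ while the walker's reference bin
was $z$, and
$\hat I(z) = \sum_b s_b^2(z) \,/\, 2\sum_b T_b(z)$ with $T_b$ the occupancy
time. The placement of the $\beta$ factors is fixed by requiring that a
walker on a flat landscape recovers its free diffusion coefficient
$k_BT/(\gamma m)$, and the same convention is used everywhere. Three
estimator conventions matter in practice:

* the sampling interval and block boundaries come from the *full* force
  series; restricting to the fully coupled $\lambda$ state leaves occupancy
  gaps, not a coarser clock (treating the filtered series as uniformly
  spaced would scale $g$ by the inverse occupancy fraction);
* samples are conditioned on the walker's *reference* bin, not its
  instantaneous position — the reference point is what defines the umbrella
  whose force is being correlated;
* the whole run, including the initial stage, contributes by default (the
  production convention); `t_min` excludes early data, and on the toys we
  exercise both and see differences well inside the estimator's noise.

Finite reference residence truncates the force autocorrelation: each Gibbs
move that displaces the reference ends a correlation segment. The estimator
is therefore accurate when the force correlation time $\tau_c = \gamma m/k$
is short against the residence time — which the production-stiff umbrella
($k = 25{,}000$: $\tau_c = 0.02$ ps at the overdamped validation friction)
and the slower MC cadence comfortably satisfy. On fixtures where residence
is only a handful of $\tau_c$ the estimated $D$ runs 10–30% high; the
validation fixtures are chosen in the safe regime and the recovery contract
is 25%. Noise from 128 blocks is $\sim$12% per bin, which is why profiles
are combined across walkers (on the friction scale — the friction, unlike
the bias, is *not* communicated between walkers, so the cross-walker spread
is an honest single-set uncertainty) and smoothed with a 0.2 nm rolling
median, whose truncated edge windows and exact removal of single-bin spikes
are part of the contract.

## The permeability pipeline

Post-processing follows a fixed order, each step a small exported function:

1. `combine_sets()` — mean and SE over independent simulation sets (the
   shared bias makes one set's internal spread unreliable, so a single set
   yields `se = NA` with a warning);
2. `calibrate_relative_to_solvent()` — subtract the solvation free energy
   from a vacuum-referenced PMF. Conventions: the decoupled state defines
   zero, and $\Delta G_{\mathrm{solv}} = G_{\mathrm{coupled}} -
   G_{\mathrm{decoupled}}$ (insertion; negative = favourable), so the
   calibrated profile is $\approx 0$ wherever the environment equals the
   reference solvent;
3. `trim_edges()` — replace the two outermost points at each end by their
   inner neighbours (boundary-spike removal);
4. `offset_nonnegative()` — choose the additive constant so the profile is
   never below zero. This changes the absolute resistance by
   $e^{\beta c}$ but is applied identically to every profile, preserving
   comparisons — the algebra is verified in the tests;
5. `resistance()` — composite trapezoid of $e^{\beta \Delta G(z)}/D(z)$ on
   the PMF grid (Simpson by flag), with $D$ linearly interpolated when the
   grids differ by more than $10^{-9}$ nm (warning) and missing $D$ bins an
   error, never silently filled;
6. `total_permeability()` — scale by the layer count
   ($30 \pm 6 = (12\pm0.4)\times(2.5\pm0.5)$, delta-method SE
   $\sqrt{(2.5\cdot0.4)^2 + (12\cdot0.5)^2} \approx 6.08$, rounded only at
   reporting), convert with $1\ \mathrm{nm/ps} = 3.6\times10^{8}$ cm/h, and
   report $\log_{10} K_P$ with the propagated uncertainty. By default only
   the layer-count SE is propagated
   ($\mathrm{se} = \mathrm{se}_N / (N \ln 10)$, in quadrature with an
   optional resistance SE); `permeability_pipeline(uncertainty = "mc")`
   additionally resamples the PMF within its per-bin SE and adds the spread
   of $\log_{10} K_P$. Both modes are labelled in the result because which
   error sources belong in a reported $K_P$ uncertainty is a modelling
   choice, not a fact.

Using 80 bilayers instead of 1 lowers $\log_{10} K_P$ by
$\log_{10} 80 \approx 1.9$; the linearity
$\log_{10}K_P(N) - \log_{10}K_P(1) = -\log_{10} N$ holds to machine
precision by construction and is asserted in the tests.

## Numerical choices

* **Integrator**: BAOAB splitting of velocity Langevin dynamics. The
  Ornstein–Uhlenbeck substep is exact, so free-particle velocity statistics
  are exact at any step size; configurational accuracy degrades as
  $O((\omega\,\Delta t)^2)$, which is why the friction-validation fixtures
  reduce the step to 0.5 fs when they combine a stiff umbrella with strong
  friction. The default 3 fs step at $\tau_t = 2$ ps matches the production
  protocol values.
* **RNG**: each walker owns an xoshiro256++ stream seeded by
  (run seed, walker id) with Box–Muller normals implemented in the package,
  so runs are bit-reproducible across platforms and adding a walker never
  perturbs the others' noise. Identical seeds give bit-identical results;
  this is a tested contract.
* **Degenerate inputs**: a spatial-only grid (`n_lambda = 1`) and a
  $\lambda$-only grid (`n_z = 1`, the solvation leg) are both first-class;
  a single-point grid is rejected at bias initialisation. Out-of-domain $z$
  is mapped by the boundary convention, never extrapolated. Zero target
  weight excludes a point from sampling, updates and anchoring.
* **Symmetrization** averages mirror-paired bins on the free-energy scale
  and is idempotent; it requires a uniform grid. Cross-boundary sampling
  weight is handled by the folded-kernel scheme described above, which is
  this package's resolution of how boundary weights should be accounted;
  the edge-trimming step remains available for externally produced
  profiles.
* **Resolution**: the umbrella width sets the spatial resolution — the
  reference-point free energy converges to the kernel-convolved PMF, so a
  softer umbrella pairs with a coarser grid (the desk configuration uses
  $k = 2{,}500$ with 0.02 nm bins against the production
  $k = 25{,}000$/0.01 nm). The validation suite compares both against the
  bare quadrature PMF (coarse tolerance) and against the kernel-convolved
  reference (tight tolerance, purely statistical residual).

## Validation scales

The test suite and the acceptance script run entirely on desk-scale
problems chosen so the whole suite completes in a few minutes on one CPU:
membrane toys of 1.6–2.6 nm with 5–11 $\lambda$ states and $10^6$–$10^7$
steps across 2–4 walkers, solvation toys with up to 21 states, and
$5\times2\times10^5$-step runs for the 2D-vs-1D benchmark. At these sizes
the sampler's statistical error is a few tenths of kJ/mol — comfortably
inside the 0.3 kJ/mol recovery contracts — and the full 2D-vs-1D comparison
(`demo_convergence()`) shows the gel-trap phenomenon with median PMF RMSD
roughly 0.5 vs 1.8 kJ/mol at equal sample budget.

## Known limitations

* The friction metric inherits a 10–30% positive bias on $D$ whenever the
  reference residence time is not long against the force correlation time;
  choose `mc_interval` accordingly when $D$ matters.
* The sampler estimates the umbrella-convolved PMF; barrier heights narrower
  than the umbrella width are attenuated. This is intrinsic to the method
  (resolution is set by the force constant), not an implementation artifact.
* Uncertainties from a single simulation set cover only the cross-walker
  diffusion spread and the layer count; PMF uncertainty needs independent
  sets.
* The toys' $\lambda$ dependence between the end states is a modelling
  choice (the soft-core map above); only the end states carry physical
  meaning in the validation, matching how insertion free energies are used.
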