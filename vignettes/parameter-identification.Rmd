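---
title: "Activation and repolarization mapping by parameter identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activation and repolarization mapping by parameter identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electrocardiographic imaging (ECGI) tries to recover the electrical activity
of the heart from potentials measured non-invasively on the body surface.
The dominant approach reconstructs epicardial potential maps by regularized
inversion of a torso Laplace problem; its Tikhonov-style smoothing notoriously
wipes out the steep wavefront gradients and produces artefactual lines of
block in activation maps.  `ecginverse` implements an alternative that never
reconstructs potential patterns at all: every heart-surface node is given a
*parametric action potential*, and the inverse problem becomes the
identification of the parameters of that waveform.  Regularization is
implicit in the waveform model; the activation map falls out as one of the
identified parameter fields.

## The transmembrane-voltage ansatz

The waveform is the two-variable Mitchell-Schaeffer ionic model,

$$v' = \frac{h\,v^2(1-v)}{\tau_{in}} - \frac{v}{\tau_{out}}, \qquad
  h' = \begin{cases} (1-h)/\tau_{open} & v < v_{gate} \\
                     -h/\tau_{close} & v > v_{gate}, \end{cases}$$

integrated from the excited state $(v,h)(0) = (0.15, 1)$ and completed by
$v \equiv 0$ for $t < 0$.  The resting state is $(0, 1)$.  The standard
constants $\tau_{in} = 0.3$ ms, $\tau_{open} = 120$ ms and $v_{gate} = 0.13$
shape the upstroke and excitability threshold; they are fixed (configurable
but never optimized).  The two remaining time constants have direct
electrophysiological meaning and are identified per node: $\tau_{close}$ is
essentially the plateau duration and $\tau_{out}$ the speed of
repolarization.  The transmembrane voltage at node $x_i$ is the shifted,
rescaled template

$$V_m(x_i, t) = A\, v\!\left(\tau_{out,i}, \tau_{close,i};\, t - \tau_i\right),$$

with one global amplitude $A$ and a per-node activation time $\tau_i$.  On a
mesh with $N_H$ vertices this gives $1 + 3N_H$ unknowns.  A distributed
amplitude is deliberately not offered: with per-node $A_i$ the identification
is unstable (amplitudes of mixed sign fit the data equally well), so the
amplitude stays a single scalar.

## Forward model

Extracellular potentials follow from spatial-mean referencing,
$\phi_e(x_i,t) = \overline{V}_m(t) - V_m(x_i,t)$ with $\overline{V}_m$ the
unweighted mean over all vertices (epicardial and endocardial together, when
both are present; the discrete mean is used rather than an area-weighted
integral, matching the discretization of the surface integral by a plain
vertex sum).  The body-surface projection assumes an infinite homogeneous
medium:

$$\phi_T(y_j, t) = \sum_{i=1}^{N_H} \frac{1}{4\pi\,\lVert x_i - y_j \rVert}\,
\phi_e(x_i, t).$$

Conductivity ratios are folded into $A$, so potentials carry arbitrary
units.  Both maps are linear, so the whole forward model is linear in $A$
and the uniform-parameter field maps to identically zero torso potentials —
a useful analytic null that the test suite checks to round-off.

## The identification problem

The cost is the mean-centered least squares misfit

$$J(\mathcal{P}) = \tfrac12 \sum_{k=1}^{T_{max}} \sum_{j=1}^{N_T}
\left[ (\phi_T(y_j,t_k) - \bar\phi_T(t_k)) -
       (\phi^\star(y_j,t_k) - \bar\phi^\star(t_k)) \right]^2,$$

where the bars are per-time means over the electrodes.  Centering removes
the reference-potential freedom (the same role Wilson's central terminal
plays in electrocardiography): adding any per-time constant to the target
leaves $J$ unchanged.

The gradient is computed analytically by the chain rule through the
implemented pipeline: the electrode centering is the projection
$I - \mathbf{1}\mathbf{1}^\top/N_T$, the transfer matrix transposes, the
spatial-mean referencing is the symmetric matrix
$\mathbf{1}\mathbf{1}^\top/N_H - I$, and the ansatz partials close the
chain.  $\partial V_m/\partial A$ and $\partial V_m/\partial \tau_i$ come
from the template and its interpolant slope; the repolarization partials
$\partial v/\partial\tau_{out}$ and $\partial v/\partial\tau_{close}$ are
co-integrated with the template as forward sensitivity equations.

Two nondifferentiable points need conventions:

* **The gate switch.**  The $h$-equation changes regime where $v$ crosses
  $v_{gate}$ (the strict inequalities leave $v = v_{gate}$ undefined; the
  closing branch is assigned at equality).  The sensitivity system uses the
  nominal trajectory's regime at each Runge-Kutta stage *and* applies the
  standard jump condition for state-dependent switching,
  $s(t_s^+) = s(t_s^-) + (f^- - f^+)\,\mathrm{d}t_s/\mathrm{d}p$ with
  $\mathrm{d}t_s/\mathrm{d}p = -s_v(t_s)/v'(t_s)$, at the crossing located by
  linear interpolation within the step.  A frozen-regime scheme without the
  jump was evaluated first; it leaves a persistent error of order 10% in the
  sensitivities after the downward gate crossing, while with the jump the
  traces match fine-step finite differences to better than 1% everywhere
  outside a ±2 ms window around the crossing itself.
* **The onset.**  $v$ jumps from 0 to 0.15 at $t = \tau$, and the voltage is
  *exactly* zero before activation — causality is an analytic property of
  the ansatz that the implementation preserves to the bit.  Consequently
  $\partial V_m/\partial\tau$ is also zero strictly before the onset, and on
  the first template step it is the interpolant's segment slope.  The jump
  itself therefore contributes no derivative: the discretized cost is
  insensitive to sub-step onset shifts, and the gradient is kept exactly
  consistent with that discretized cost.  (The alternative — smearing the
  jump into a finite pre-onset subgradient — was evaluated and rejected: a
  gradient component that the cost does not corroborate makes the
  learning-rate search collapse and pins activation times at sample-aligned
  values.)  The signal that moves an activation time comes from the smooth
  parts of the waveform, which span many recording samples.

Optimization is RMSprop,

$$\kappa \leftarrow \gamma\kappa + (1-\gamma)\,\nabla J \odot \nabla J,
\qquad
\mathcal{P} \leftarrow \mathcal{P} - \eta\, \nabla J \oslash
(\kappa^{\circ 1/2} + 10^{-7}),$$

with $\gamma = 0.9$.  The learning rate is not fixed: at every iteration the
tentative update is evaluated on a 15-point log-spaced grid spanning
$[10^{-5}, 10^2]$ and the rate with the lowest resulting cost is taken (ties
to the smaller rate; the step is taken even if every candidate raises the
cost, as plain RMSprop would).  The grid is a declared convention — the
method only requires "an optimal rate chosen at each iteration in that
range" — chosen because it is deterministic, testable, and costs exactly 15
forward evaluations per iteration.

Initialization is uniform: $A = 10$, $\tau_{out} = 6$ ms,
$\tau_{close} = 150$ ms, and a constant activation time $\tau_0$
(60 ms by default; 75 ms is a standard robustness variant).  Because the
initial field is uniform, the initial torso potentials are exactly zero.
The loop stops when the relative change of $J$ stays below $10^{-6}$ for 10
consecutive iterations, or at `max_iterations` (default 500; the packaged
benchmark uses 300).

Positivity of the time constants is enforced by clipping after each update
($\tau_{out} \ge 0.5$ ms, $\tau_{close} \ge 10$ ms).  No upper bounds and no
spatial regularization of any field are imposed — the absence of explicit
smoothing is the method's point, and reconstructed repolarization times are
allowed to run beyond the physiological range rather than being pushed back
by a constraint.  Activation times are unconstrained reals.

## Synthetic validation protocols

Reference data of the kind this method is validated against (monodomain
reaction-diffusion simulations on an anatomically realistic heart-torso
model) are far beyond desk scale, so the package ships a generator that
emulates their *evaluation surface* — activation maps, repolarization maps,
and forward-projected body-surface recordings:

* **Geometry.**  A truncated half-ellipsoid epicardial shell (default
  semi-axes 30 × 30 × 60 mm), open at the base like a ventricle, optionally
  with a nested endocardial shell inset by a uniform wall thickness
  (8 mm default), and electrodes in near-uniform rings on a torso cylinder
  (radius 100 mm, height 240 mm).
* **Activation.**  Geodesic front spread from pacing sites at an effective
  surface speed (default 0.8 mm/ms).  This is deliberately faster than
  ventricular fiber conduction (~0.5 mm/ms): on a real heart the epicardial
  breakthrough pattern is fed by transmural and subendocardial wavefronts,
  so apparent surface speeds are higher, and with the default geometry this
  yields paced-beat total activation times around 130 ms, consistent with
  paced QRS durations.  Disconnected epicardial/endocardial shells are
  joined by nearest-pair transmural bridge edges at the basal rim, so a
  single activation graph covers both surfaces.  Activation maps satisfy the
  eikonal (1-Lipschitz) bound edge by edge.
* **Repolarization structure.**  $\tau_{close}$ and $\tau_{out}$ fields are
  base values plus an endo-epicardial offset (default −20 ms on
  $\tau_{close}$: endocardial plateaus shorter, mimicking transmural
  repolarization gradients), an apex-base gradient (default +15 ms), and
  smooth vertex noise (Gaussian, smoothed by 3 rounds of one-ring
  averaging).  Fields are clipped to $\tau_{out} \in [2, 20]$ ms,
  $\tau_{close} \in [50, 300]$ ms.
* **Reference repolarization times** are extracted from the clean
  extracellular potentials as the time of the steepest positive slope after
  the activation time plus a 50 ms plateau guard — the same rule applied to
  reconstructions, so reference and recovered maps are always on the same
  footing.
* **Noise and model mismatch.**  Optional i.i.d. Gaussian noise at a target
  SNR ($10\log_{10}(P_{signal}/P_{noise})$), and two mismatch modes that
  break the inverse crime: generation on a once-subdivided (4× faces) mesh,
  or generation with perturbed fixed constants
  ($\tau_{in} = 0.35$, $v_{gate} = 0.15$).

What the inverse-crime benchmark shows — and what it does not: with data
generated by the same forward model, a high activation-map correlation
demonstrates that the cost, gradient, and optimizer are implemented
correctly.  It does not demonstrate robustness to torso inhomogeneity,
measurement noise, or waveform mismatch; the noise and mismatch modes exist
precisely so those effects can be studied separately.

It also exposes, usefully, the problem's practical non-identifiability.  On
the packaged benchmark the test suite measures an activation-map CC of
about 0.92 after 300 iterations with the cost at about 2% of its initial
value, and continuing the descent pushes the cost to a fraction of a
percent while the CC *saturates* — indeed, substituting the true activation
times into the recovered parameter set *raises* the cost above that of the
recovered solution.  Errors of tens of milliseconds in the activation time
of individual nodes are compensated by the repolarization parameters and
the amplitude to produce body-surface recordings closer to the data than
partial truth is: the `1/(4πr)` kernel smooths single-node contributions
below observability at this electrode count.  This is the same
ill-posedness that limits every ECGI method; here it appears as a flat,
curved valley of the cost rather than as the smoothed wavefronts of
Tikhonov inversion.

## Numerical choices

* Integrator: explicit fixed-step RK4, `dt_template = 0.05` ms.  The model
  is only mildly stiff at the upstroke, and fixed steps make the
  sensitivities, the caching, and every test deterministic.  RK4 at 0.05 ms
  agrees with a 0.005 ms reference to < 1e-4 in $v$.
* Templates are cached per unique $(\tau_{out}, \tau_{close})$ pair
  (rounded to $10^{-6}$ ms), so a cost evaluation does one ODE solve per
  *unique* pair, not per vertex; the per-vertex evaluation is vectorized
  linear interpolation on the shared uniform grid.  Recording grids are
  coarser (1 ms default) than templates.
* Geodesics are Dijkstra on the mesh edge graph with Euclidean weights, not
  exact polyhedral geodesics: at the mesh resolutions used here the
  edge-graph error is below mesh resolution, and published localization
  distances do not state which convention they use — the edge graph is this
  package's standardized choice.
* Endo-epi pairing uses Euclidean closest points (geodesic pairing across
  separate shells is undefined); ties break to the smallest vertex index,
  as do ties in earliest-activation localization.
* Box-plot summaries of transmural delays use linearly interpolated
  quartiles (`type = 7`), matching Tukey-style box plots.
* Quantities beyond the template end hold the final value with zero slope;
  negative activation times are allowed (same formula).
* The automatic exclusion of isolated early-activation outliers before
  pacing-site localization (a manual, visual step in practice) is available
  as an optional filter but off by default.

## Problem sizes

The packaged benchmark — the scale every shipped result refers to — uses a
100-vertex epicardium-only ventricle, 64 electrodes, a single epicardial
pacing site at the mid free wall, a 0–550 ms recording at 1 ms, and 300
RMSprop iterations; a two-shell variant (~130 vertices) exercises the
endocardial code paths.  These sizes were chosen so that a full synthetic
round trip (simulate, invert, evaluate) completes in minutes on one core
while keeping the vertex count of the same order as clinical-resolution
coarse meshes (a few hundred nodes).

## A full round trip

```{r demo}
library(ecginverse)
arts <- run_pipeline("demo", default_config())
arts$report
```

## Known limitations

* The infinite-medium kernel ignores torso boundedness and inhomogeneity;
  absolute potential scales are meaningless (by design, folded into $A$).
* Transmural delays are systematically underestimated when both surfaces
  are included: seen from the torso, the two surfaces are nearly
  indistinguishable, and the endocardial activity is masked by the
  epicardial one.
* Repolarization parameters are identified less precisely than activation
  times — their sensitivities act only during the slow phases of the AP —
  so recovered repolarization maps are expected to be noisier than
  activation maps, and APD estimates can err in either direction over large
  areas.
* The geodesic front generator produces kinematically consistent activation
  maps but no reaction-diffusion effects (wavefront collision curvature,
  anisotropy, breakthrough dynamics).
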