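---
title: "Modeling scale-by-scale skin color patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling scale-by-scale skin color patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalepatterns)
```

## The system

In several lizard lineages the color of individual skin scales flips
between two states (green/yellow and black) during post-hatching growth,
so that the adult pattern is written scale by scale on a fixed polygonal
lattice: the number of scales and their adjacency do not change while the
animal grows. `scalepatterns` implements three families of models of this
process on such lattices, together with the imaging steps that produce
the lattices from surface scans, the error metrics used to compare
simulated and observed patterns, Bayesian optimization of model
parameters, and two uncertainty analyses (skin-geometry heterogeneity and
sensitivity to the measured initial colors).

All data the package consumes can be generated synthetically
(`gen_random_patterns()`, `gen_truth_series()`, `gen_normal_map()`,
`gen_matched_pair()`, `perturb_colors()`); every generator is a pure
function of its configuration and a seed.

## Models

### Stochastic cellular automaton (sCA)

Each scale carries a binary state. The probability that a scale flips at
one synchronous iteration depends only on its own state and on the number
i in 0..7 of isochromatic direct neighbors: 16 rules in total.
`infer_sca_rules()` estimates the rules from a pattern time series by
Bayesian inference with a flat prior: a configuration observed n times
with k flips gets the posterior-mean probability E[p] = (k+1)/(n+2)
(the MAP estimate k/n is also reported). Scales with more than 7
neighbors — possible on irregular Voronoi lattices — are clipped into the
i = 7 bin so that the 16-configuration set is preserved; boundary scales
enter the statistics with their actual reduced neighbor counts
(`neighbor_stats(include_boundary = FALSE)` excludes them instead; no
exclusion rule is canonical, so both are available).
`simulate_sca()` runs synchronous iterations until the cumulative flip
count reaches a target (one iteration typically flips several scales, so
runs are stopped at the first iteration crossing the target).

### Lenz-Ising model

The two-parameter reduction treats green and black scales as +1/-1 spins
with dimensionless energy beta H = -betaJ sum s_i s_j - betaB sum s_i
over lattice edges. `simulate_ising()` uses single-site Metropolis sweeps
— any ergodic reversible kernel has the same stationary law, which is the
object of interest. `fit_ising_params()` estimates (betaJ, betaB) by
maximum pseudo-likelihood (the per-site conditional is logistic in the
neighbor spin sum), which is consistent, fast, and needs no partition
function; estimates at the box bound (e.g. uniform patterns, where betaB
diverges) are flagged. Under the green = +1 convention, antiferromagnetic
(labyrinthine) patterns give betaJ < 0 and black-favoring fields betaB < 0.

### Reaction-diffusion (RD)

Three components (u, v, w): u and v are short-range factors with equal
diffusivities, w is long-range (Dw >> Du). Production terms are linear
forms clamped to [0, Fmax] etc.; the clamping is the only non-linearity.
Decay is linear. Default reaction/decay/diffusion coefficients are the
published ocellated-lizard estimates (cu = 0.020, cv = 0.025, cw = 0.06,
c1..c9, Du = Dv = 1.125, Dw = 12.5, P = 0.00889). The clamp ceilings
Fmax = Gmax = Hmax = 0.5 are package placeholders (the source of the
coefficient set does not print them); they only bind far from the steady
state, and every analysis here checks the middle-branch validity of the
HSS (`solve_hss()$valid`) under whatever caps are configured.

Three solvers share the reaction core:

* `simulate_drd()` — one node per scale; the finite-volume reduction on
  arbitrary polygons gives per-scale coupling P D / (A_i eps) * sum_j
  (u_j - u_i) L_ij, which on a regular hexagonal lattice collapses
  exactly to 2 P D / (3 sqrt(3) S eps) sum_j (u_j - u_i). Boundaries are
  zero-flux (missing neighbors contribute nothing). Integration by
  `deSolve::lsoda`.
* `simulate_crd2d()` — pixel grid with face diffusivities; the interscale
  boundary band (distance to the Voronoi edge below eps/2) carries the
  reduced diffusivity P D. Semi-implicit stepping: sparse-Cholesky
  implicit diffusion (factorization cached while the growth factor is
  constant), explicit reaction.
* `simulate_crd3d()` — curvilinear structured grids between a scale
  surface and a chromatophore-depth bottom. See "3D discretization"
  below.

Growth enters through the logistic mean edge length
S(tau) = k1 / (exp(-k2 tau + k3) + 1) and the rate factor q = dt/dtau;
with geometry referenced to the last observation and eps_ref = 1, all
lengths scale in proportion and the diffusion term acquires the factor
(S_ref / S(tau))^2. Growth is off by default (`k1 = NULL`).

### Linear theory and the color transforms

`linear_stability()` linearizes the per-scale equation about the HSS with
the neighbors pinned at the steady state (sum_j u_j ~ 6 u*), giving
du/dt = M u + b with M = A - 6 k D. The sign of the leading eigenvalue
lambda1 classifies the per-scale fate; with lambda1 > 0 trajectories
collapse onto the dominating eigenvector line through u*, whose
intersections with the clamping planes are the two attracting extremities
u_g and u_b (labeled so v_g > v_b). `analytic_linear_solution()` is the
closed-form solution via the spectral decomposition.

Observed juvenile CIELAB colors are mapped to RD space by
`colors_to_rd()`: orthogonal projection onto the line through the two
K-means cluster colors (T1), affine transfer onto the u_g–u_b line (T2),
contraction toward the HSS by the factor r (T3). The reverse map for
later time points (`fit_color_transform()`, `rd_to_colors()`) matches the
PCA ellipsoids of the RD and color clouds: Q = V_C D_C^(1/2)
(V_u D_u^(1/2))^(-1). Eigenvector signs are fixed by requiring paired
projections to correlate positively (identical clouds then give exactly
the identity); eigenvalues are sorted descending. The transform is refit
at each comparison time point. CIELAB conversion uses the D65/2-degree
observer.

## Metrics

`e16d()` is the L2 norm, divided by the scale count, of the 16 signed
differences in neighbor-configuration counts between two patterns;
`esbs()` is the mean per-scale color distance normalized by the
green-black cluster separation (the fraction of mismatched scales in the
binary case); `pattern_objective()` is the time-averaged L1
neighbor-count mismatch used as the optimization objective, with
simulated colors thresholded to the nearer cluster center (the consistent
analogue of K-means thresholding of observations). `error_pca()`
summarizes populations of 16-dimensional error vectors.

## Bayesian optimization

`bayes_opt()` minimizes an expensive objective with a noise-free
Gaussian-process surrogate: Matern-5/2 kernel with one length scale per
parameter, zero prior mean, hyper-parameters refit each iteration by
marginal-likelihood ascent with 5 random restarts, expected-improvement
acquisition maximized by multi-start L-BFGS-B. Numerical choices: kernel
jitter 1e-10 escalated tenfold to at most 1e-6 on Cholesky failure;
non-finite objective values are recorded as a large penalty; evaluations
are cached by parameter vector. The default stop is 50 successive
non-improving proposals — a desk-scale default; the full-scale analyses
this models used 1000. `iterative_param_addition()` wraps the loop in
greedy forward selection starting from the always-optimized pair (q, r).
`sensitivity_scan()` perturbs parameters jointly, uniform within
+/- 0.1 of the fitted length scales, and fits a gamma law to the
resulting scale-by-scale errors.

## Imaging

`mean_curvature()` computes H from a normal field through the first and
second fundamental forms of the graph surface (central differences,
one-pixel border and near-horizon pixels masked). `detect_scales()`
filters H (Gaussian sigma = s/10, then a median window of about s/3 — a
window as large as the scale itself, appropriate at scan resolutions of
hundreds of pixels per scale, erases the basins at this package's
working resolutions of tens of pixels per scale), segments by watershed
with h-minima suppression at 5% of the dynamic range, drops segments
touching the image border, and places each center at the centroid of the
basin's near-minimum region (robust to asymmetrically clipped basins).
Scale colors exclude pixels within s/10 of the cell boundary; mean,
median and per-channel mode are all retained for the uncertainty
analyses. `match_pair()` grows correspondences from 3 or more seed
matches by local least-squares affines (3–10 nearest matched neighbors),
accepting transfers within eps = 0.05 times the mean neighbor distance
(ties: smaller distance, then smaller id). `unify_network()` keeps scales
tracked at every time point, maps all time points onto the first by the
closed-form similarity fit (rotation, isotropic scale, centroid
translation — shear and anisotropic scaling are excluded so the topology
is not biased toward the reference), averages centers, and rebuilds one
Voronoi lattice, making adjacency time-invariant by construction.

## 3D discretization

The pointwise curvilinear Laplacian (`curvilinear_laplacian()`) estimates
the covariant basis per node by least-squares regression of index offsets
on Cartesian offsets over the 3x3x3 stencil, with reduced stencils and
mirror closure at boundaries; it is exact on rectilinear grids and
second-order on smoothly warped ones. The time integrator, however, uses
the flux-form operator `curvilinear_flux_operator()`: a conservative
finite-volume two-point-flux scheme whose transmissibilities come from
metric face areas. The reason is physical: for a field that is uniform
across the shell thickness, a pointwise Laplacian with index-space
zero-flux closure reduces to a flat 2D Laplacian — shell thinning at
scale borders would then have no effect at all, because the constriction
physics lives entirely in the slanted-boundary Neumann condition. The
flux form expresses it directly: thin necks have small faces. On
rectilinear grids the two operators coincide (standard 7-point stencil)
and volume-weighted total concentration is conserved exactly; backward
Euler keeps the diffusion step unconditionally stable, with BiCGSTAB
(diagonal preconditioner, tolerance 1e-8, 500 iterations) and a cached
sparse-LU fallback for strongly anisotropic grids.

3D domains are hexagonal arrays of super-Gaussian bumps, h(r) = h_e +
(h_c - h_e) exp(-(r^2 / 2 sigma^2)^p), blended by pointwise maximum, with
per-bump and per-edge heights drawn from normal laws. The published
species example is p = 1, sigma = 0.28 S. Two geometric caveats matter at
desk scale. First, the saddle height between adjacent bumps is set by
sigma (the max-blend at the midpoint), not by h_e, which only floors the
interstitial regions. Second, a flat-bottom domain becomes numerically
singular at deep necks; the chromatophore shell (bottom = top - dm(d),
with dm the quadratic chromatophore-depth map fitted by
`fit_dm_mapping()` from 75th-percentile melanophore depths) is smooth and
is the domain the models actually concern. The package's 3D fixtures use
sigma = 0.16 S on a quadratic shell, chosen once so that the
saddle-to-center thickness ratio is comparable to the 2D boundary factor
P — the regime in which the 3D model holds per-scale patterns.
`thickness_error_experiment()` then measures the scale-by-scale error
induced purely by height heterogeneity, against the homogeneous-domain
reference, with a generalized extreme-value fit of the error histogram
(GEV maximum likelihood is hand-written; no extreme-value package is a
dependency).

## Sensitivity to initial colors

`divergence_trajectories()` perturbs the observed juvenile colors by
C = C_ref + s C', s uniform on (0, 1) and rows of C' drawn from the
normal law with the covariance of the reference colors, maps each noisy
condition to RD space, and tracks the full-state Euclidean distance to
the reference trajectory. `lyapunov_exponent()` is the least-squares
slope of log(delta_tau / delta_0) over the pre-saturation window —
samples below half the trace maximum and within the first half of the
horizon (a documented default; only "before saturation" is canonical).
`ic_to_final_error()` summarizes the initial-to-final error relation by
an isotonic trend with local empirical spread at probe values (the probes
in practice are the mean/median/mode color-measurement alternatives
retained by `extract_scale_colors()`).

## Study conditions and problem sizes

The test-suite and acceptance fixtures run at sizes a workstation handles
in minutes, chosen once: hexagonal lattices of 16–400 scales with edge
length S = 4 (the geometry at which the published coefficient set is
Turing-unstable both per scale and across the lattice spectrum), 6
observation time points on tau in [0, 1200] for recovery experiments,
CIELAB measurement noise of 2 units (typical of color measurement error),
2D grids of about 60 x 50 pixels, 3D grids of about 20 x 17 x 5, 50,000
Metropolis sweeps for stationary-law comparisons, and optimization
budgets of 60 evaluations. Cluster colors in synthetic series are
Cg = (65, -35, 45), Cb = (28, 2, 8) — a green and a near-black.

## What the synthetic data do and do not show

The generators reproduce the statistical structure the analyses assume:
near-binary scale colors drifting between two cluster centers, spatially
correlated random patterns across length scales, logistic growth,
analytic bump relief, and similarity-related lattice pairs with jitter
and dropout. They do not emulate scan artifacts (shading, stitching
seams, specularity), anatomical color distributions, or the ~5% of scale
matches that required manual correction in real scans (tests use
ground-truth seed matches instead). Passing tests therefore demonstrate
correctness of the algorithms under their stated assumptions, not
end-to-end performance on real scan data.

## Known limitations

Single-block structured 3D grids cannot represent extreme necking with a
flat bottom boundary; Voronoi construction assumes a convex clip region;
the sCA update schedule is synchronous (the observed dynamics constrain
only the cumulative flip count, not the schedule); Esbs comparisons of
3D runs label scales by thresholding the per-scale mean of u at the HSS
value; the Lenz-Ising fit is pseudo-likelihood, not maximum likelihood.
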