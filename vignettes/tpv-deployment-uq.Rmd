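---
title: "Methods: a reduced-order uncertainty pipeline for simulated TPV deployment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order uncertainty pipeline for simulated TPV deployment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Self-expanding transcatheter pulmonary valves (TPV) are deployed in right
ventricular outflow tracts (RVOT) whose tissue properties are unknown at the
patient level and altered by surgical history (notably a transannular patch
left by the primary repair of Tetralogy of Fallot). Finite-element screening
simulations must therefore *assume* wall material parameters, and the
question this package addresses is how sensitive the simulated outcome
metrics — stress and strain percentiles, deployed geometry, enclosed device
volume — are to those assumptions.

`tpvuq` implements a desk-scale version of that sensitivity study: an
anisotropic hyperelastic wall model, a reduced-order deployment solver, a
polynomial-chaos uncertainty engine with Sobol indices, a transannular-patch
heterogeneity sweep, and the outcome metrics, all reproducible from a single
seeded configuration.

# Wall constitutive model

The vessel wall uses the uncoupled Holzapfel–Gasser–Ogden (HGO) law: an
isotropic ground matrix plus two symmetric dispersed fiber families at
$\pm\gamma$ from the circumferential direction,

$$\tilde\Psi \;=\; \frac{c}{2}\,(\tilde I_1 - 3)
 \;+\; \frac{k_1}{2k_2}\sum_{\alpha=1,2}
 \left[e^{\,k_2\langle \tilde E_\alpha\rangle^2}-1\right],
 \qquad
 \tilde E_\alpha = \kappa(\tilde I_1-3) + (1-3\kappa)(\tilde I_{4\alpha}-1),$$

with $\tilde I_1 = \operatorname{tr}\tilde{\mathbf C}$,
$\tilde I_{4\alpha} = \mathbf a_{0\alpha}\!\cdot\!\tilde{\mathbf C}\,
\mathbf a_{0\alpha}$ and $\tilde{\mathbf C} = J^{-2/3}\mathbf F^\top\mathbf F$.
Parameters (units kPa, degrees): ground-matrix shear modulus $c = 200$,
fiber modulus $k_1 = 13480$, exponential coefficient $k_2 = 1.06$, mean
fiber angle $\gamma = 18.85$, dispersion $\kappa = 0.33$, bulk modulus
$k = 1500$.

Three numerical decisions are worth making explicit:

* **Tension-only fibers.** The printed energy has no positive-part operator,
  but the standard HGO convention excludes compressed fiber families; the
  switch $\langle\cdot\rangle$ is on by default and exposed as
  `hgo_params(tension_only = )` so its effect can be measured.
* **Volumetric energy.** The volumetric part is implemented as
  $U(J) = \tfrac{k}{2}\!\left[\tfrac{J^2-1}{2}-\log J\right]$, the only
  reading consistent with $k$ being a bulk modulus
  ($U(1)=0$, $U'(1)=0$, $U''(1)=k$); the tests verify those identities by
  finite differences.
* **Stress derivation.** The Cauchy stress uses the standard uncoupled
  push-forward
  $\sigma = \tfrac{2}{J}\operatorname{dev}\!\big[\tilde{\mathbf F}
  (\partial\tilde\Psi/\partial\tilde{\mathbf C})\tilde{\mathbf F}^\top\big]
  + U'(J)\mathbf I$. A central-finite-difference oracle over 100 random
  deformation states (relative tolerance $10^{-5}$) is the arbiter of
  correctness, together with frame-indifference and $\gamma$-symmetry
  property tests.

The transannular patch and the crimping tube are isotropic comparators,
realized as compressible neo-Hookean solids matched to $(E,\nu)$ at small
strain ($\mu = E/2(1+\nu)$, $K = E/3(1-2\nu)$); a small-strain Hooke law
would not be objective at deployment strains.

# The deployment surrogate

The central reduction replaces the 3-D contact problem between a
beam-element device frame and a patient mesh by **independent per-station
thick-walled-ring equilibria**. At each axial station the wall is an
incompressible plane-strain ring, deformed by the map
$r(R) = \sqrt{r_i^2 + R^2 - R_i^2}$, whose internal pressure is the
thick-wall integral

$$p_w(r_i) = \int_{r_i}^{r_o}\frac{\sigma_{\theta\theta}-\sigma_{rr}}{r}\,dr,$$

evaluated by 3-point Gauss panels (one panel per wall layer). The device is
a linear radial-force law
$p_s = K_s\,\max\!\big(0,(r_\mathrm{free}-r_i)/r_\mathrm{free}\big)$.
Equilibrium is the bracketed root $p_w = p_s$ on
$[R_i, r_\mathrm{free}]$ — the bracket is guaranteed because $p_w$ increases
and $p_s$ decreases with radius — found by bisection to a $10^{-10}$ mm
bracket followed by Newton polishing; the tests require the residual below
$10^{-8}$ kPa and agreement with a brute-force potential-energy scan to a
relative $10^{-4}$.

**What the surrogate keeps:** the constitutive content (the full HGO law
enters the pressure integrand), through-wall stress and strain fields with
the exact radial-equilibrium $\sigma_{rr}$ profile, hoop-stretch-driven
geometry, and every outcome metric. **What it gives up:** axial coupling
between stations, bending of the wall at the device ends, true contact
mechanics, and any stress concentration at material interfaces. The
consequences for the sensitivity ranking are discussed at the end.

## Stent law calibration

$K_s$ is a configuration value, not a fitted constant. It was set once so
that the baseline (table-value) vessel deploys to roughly the middle of the
80–95 % band of the device free radius at the narrowest station:
$K_s = 400$ kPa gives $r_i \approx 10.7$ mm against the 12.5 mm free radius
(≈ 86 %). A 45 mm device is centered in the 60 mm vessel and divided into
equal axial thirds for regional enclosed-volume reporting.

## Heterogeneous (patch) stations

A station crossed by the patch has two circumferential sectors (patch arc
and remaining vessel arc). Two composite couplings are implemented
(`deploy(..., coupling = )`):

* **`"parallel"` (default, shared stretch).** All sectors deform with the
  same hoop stretch and their wall pressures add arc-weighted:
  $\sum_s \phi_s\, q_s(\lambda) = p_s(\lambda R_i)$. This represents a
  patch embedded flush in the wall, whose deformation is dictated by the
  surrounding tissue; a stiffer patch then carries more stress while its
  strain falls as the composite stiffens — the behaviour reported for
  embedded transannular patches.
* **`"series"` (shared load).** All sectors carry the same transmural
  pressure; each inverts its own thick-wall law
  $\lambda_s = q_s^{-1}(p)$ (capped at the device free radius — the frame
  cannot push a sector beyond its own free size) and the arc-weighted mean
  stretch closes the ring. This coupling lets a stiff sector stretch
  visibly less than its neighbours, but it has a structural property worth
  recording: at equal shared load the *softer*, more stretched sector
  always carries the *higher* inner-surface peak stress (the through-wall
  stress profile concentrates at the inner surface as stretch grows), so
  patch peak stress would fall, not rise, with patch stiffness.

Because the study's qualitative findings — patch stress increasing and
strain decreasing with stiffness — are reproduced only by the shared-stretch
coupling, it is the default; the series coupling is retained for comparison
and for the per-sector stretch contrast. Both reduce exactly (to
$10^{-8}$ mm) to the homogeneous solve when every sector has the same
material, which the test suite asserts.

# Synthetic geometry

The generator replaces the segmented patient anatomy with a tube of
revolution: stations every 1.5 mm (the surface mesh size), wall thickness
1.5 mm extruded outward in 1–6 hexahedral layers, circumferentially closed
quad surface (Euler characteristic 0, every interior edge shared by exactly
two quads). The default radius profile has two Gaussian narrowings
(minimum radii 9 and 10 mm at $z = 16$ and 44 mm, width 8 mm, base radius
16 mm over a 60 mm length) so that *both device ends impinge the wall while
the mid-vessel stays wide* — the contact pattern characteristic of deployed
RVOTs — and so that the two patch positions (distal $z=16$, proximal
$z=44$) sit at device–wall interaction sites. The slight distal/proximal
asymmetry makes the two patch positions genuinely different conditions.

The diamond patch (30 × 20 mm diagonals, long diagonal axial) lives in
unrolled mid-wall coordinates $(u = R_\mathrm{mid}\theta,\ v = z)$ with
membership $|u-u_0|/(d_u/2) + |v-v_0|/(d_v/2) \le 1$; stations inside the
diamond get a patch sector whose angular width follows the diamond
cross-width, and surface quads are relabelled by centroid membership
(`material_id = 2`). Embedding is idempotent and a degenerate patch is a
no-op.

Device oversizing at the narrowings (free diameter 25 mm against an 18 mm
waist) is within the range used for self-expanding pulmonary devices, which
anchor by oversize. The 25 mm free diameter follows the device designation;
it is a configuration default, not a measured value.

# Uncertainty machinery

Each uncertain parameter $x_j \in \{c, k_1, k_2, \gamma, \kappa\}$ gets a
moment-matched gamma distribution from its mean and a standard deviation
expressed as a percent of the mean (media-layer arterial variability:
49.61, 32.96, 39.83, 26.69 and 36 %): shape $(\mu/\sigma)^2$, scale
$\sigma^2/\mu$. Two constraint-driven choices:

* **$\kappa$'s mean.** A gamma distribution centered at the isotropic limit
  $1/3$ would place half its mass above the admissible range, so the
  $\kappa$ distribution is centered on the media-layer mean 0.25
  (configuration `materials$uq_kappa_mean`) while the baseline deployment
  keeps $\kappa = 0.33$.
* **$\kappa$ draws above $1/3$** are rejected and redrawn (a `clip`
  alternative exists for comparison). The PCE basis stays orthonormal with
  respect to the *untruncated* gamma measure; the small truncation is part
  of the input measure, not of the basis.

The emulator is a total-degree-4 expansion in products of generalized
Laguerre polynomials, built by three-term recurrence and orthonormalized
under each parameter's gamma weight; orthonormality is verified to
$10^{-8}$ by Golub–Welsch quadrature. With $d = 5$ and order 4 the basis
has $\binom{9}{4} = 126$ terms; the design adds 10 Monte-Carlo oversamples
for a 136-row least-squares fit (QR), which reproduces any polynomial of
total degree ≤ 4 exactly (tested to $10^{-9}$) and matches an independent
tensor-quadrature projection to $10^{-6}$. Failed model evaluations are
dropped before the fit (drop-and-refit), with an abort threshold of 2.5 %
of the design.

Sobol indices come directly from the orthonormal coefficients:
$V = \sum_{\alpha\neq 0} a_\alpha^2$,
$S_i = \sum_{\alpha:\,\text{only }i} a_\alpha^2 / V$,
$S_{Ti} = \sum_{\alpha:\,\alpha_i>0} a_\alpha^2 / V$, validated against a
closed-form/nested-quadrature ANOVA oracle. The fitted emulator is then
queried with 1000 fresh seeded parameter draws for the distribution
summaries (min/quartiles/median/max).

# Outcome metrics

* **Volume-weighted percentiles.** Field statistics use the plotting
  position $p_i = (C_i - w_i)/(W - w_i)$ on the weight-sorted sample with
  linear interpolation; for equal weights this is exactly the standard
  inclusive (`type = 7`) quantile, and it is invariant to weight rescaling
  and reordering. Weights are the tributary reference shell volumes of the
  through-wall sample nodes (reference volume equals deformed volume under
  the incompressible map).
* **Intramural profiles** report the first principal Green–Lagrange strain
  against the distance ratio $t\in[0,1]$ through the wall. "Lagrangian
  strain" is taken as Green–Lagrange throughout.
* **Mesh-layer convergence** re-runs the deployment with 1–6 layers and
  selects the smallest count whose 95th/99th-percentile strain changes from
  the previous count fall below 1 %. Because through-wall sampling refines
  with the layer count, the upper percentiles wobble at coarse resolution;
  the selection is deterministic for a fixed configuration.
* **Geometry distances** (Hausdorff, mean and 95th-percentile symmetric
  distance) use seeded area-weighted surface sampling plus all mesh
  vertices, with exact point-to-triangle minimization (Eberly's region
  scheme) and a centroid-radius prefilter; on point-set inputs the
  implementation degenerates to the exact brute-force max–min, which the
  tests exploit as an oracle. The 95th-percentile symmetric distance is the
  95th percentile of the pooled two-directional distances.
* **Perimeter-derived diameter** is the cross-section perimeter over $\pi$
  at the narrowest station; **enclosed volume** integrates
  $\pi r_i(z)^2$ by trapezoid within each device third.

# Problem sizes and runtimes

The default study uses 41 stations × 4 layers (205 through-wall samples),
136 deployments for the UQ design, 1000 emulator queries, and 9 patch
conditions. One deployment takes well under a second; the full UQ study
about ten seconds; the whole acceptance pipeline under a minute. These
sizes were chosen so the entire analysis reruns comfortably on a laptop
while keeping every pipeline stage statistically meaningful.

# What the surrogate does and does not show

The synthetic study reproduces, and the tests assert: the published
variability-table arithmetic exactly; the 136-row design; the
stress-up/strain-down patch trends and their position dependence (peak
stress in the patch for the distal position and stiff conditions, away from
it otherwise); a finite mesh-layer selection by the 1 % criterion; and
deployed geometries that vary by only a few percent of the narrowest
diameter across the whole material design (Hausdorff distances of roughly
2–7 %).

Two quantitative claims do **not** transfer from the full 3-D setting to
this surrogate, and the acceptance suite reports them honestly as failures
rather than adjusting the conditions:

* **The sensitivity ranking.** In pure hoop inflation both fiber families
  are always in tension, so the fiber-alignment term
  $(1-3\kappa)k_1(\tilde I_4-1)$ — with $k_1$ four orders of magnitude
  above $c$ — controls the wall stiffness, and $\kappa$ dominates every
  Sobol index (first-order ≈ 0.96). In full 3-D deployments the stress
  hotspots are bending-dominated regions at the device ends where fibers
  go slack and the ground matrix $c$ governs; a per-station inflation
  model cannot represent that regime, so the expectation that $c$ leads
  the 95th-percentile strain sensitivity fails here.
* **Enclosed-volume invariance.** The stiffest patch spans roughly a third
  of the waist circumference and, under shared-stretch coupling, drags the
  whole ring; the enclosed volume varies by ≈ 1.4 % across the nine patch
  conditions, marginally above the 1 % band that holds in the 3-D setting
  where the frame's axial continuity bridges local stiffening.

Both observations are properties of the reduced model, measured by the
suite itself, and should be read as the cost of replacing a contact FE
problem with per-station rings — not as statements about real deployments.

# Reproducing the studies

```{r example}
library(tpvuq)
cfg <- default_config()

run_convergence(cfg)            # 6-row layer study + selection
uq <- run_material_uq(cfg)      # 136 deployments -> PCE -> Sobol
run_patch_study(cfg)            # 9-condition patch sweep

sobol_indices(uq$models$strain_p95)
```

The same pipeline is scripted in `scripts/acceptance.R`, which recomputes
every headline quantity from scratch and writes them as JSON, and in the
`inst/cli/tpvuq` command-line wrapper (`synth`, `converge`, `uq`, `patch`,
`metrics`, `all` subcommands over YAML/JSON configurations).
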