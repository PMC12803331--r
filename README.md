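# tpvuq

Sensitivity and uncertainty analysis of simulated self-expanding
transcatheter pulmonary valve (TPV) deployment in the right ventricular
outflow tract (RVOT), at desk scale.

Patients with repaired Tetralogy of Fallot often need pulmonary valve
replacement in an RVOT whose tissue stiffness is unknown and spatially
heterogeneous (a surgical transannular patch stiffens part of the wall).
Simulation-based device screening must assume wall material parameters, so
the practical question is: *which parameters actually matter for the
simulated outcome, and how much does a patch change it?* `tpvuq` answers
that question with a fully scripted, seeded pipeline aimed at
cardiovascular-biomechanics researchers and simulation engineers.

## What is inside

* **Wall mechanics** — the uncoupled Holzapfel–Gasser–Ogden (HGO)
  anisotropic hyperelastic model,

  Ψ̃ = (c/2)(Ĩ₁−3) + (k₁/2k₂) Σ_α [exp(k₂⟨Ẽ_α⟩²)−1],
  Ẽ_α = κ(Ĩ₁−3) + (1−3κ)(Ĩ₄α−1),  U(J) = (k/2)[(J²−1)/2 − ln J],

  with tension-only fiber families at ±γ from the circumferential
  direction, plus neo-Hookean isotropic comparators for patch and tube
  (`hgo_params()`, `cauchy_stress()`, `isotropic_stress()`).
* **Deployment surrogate** — per-station incompressible thick-walled-ring
  equilibria against a linear stent radial-force law, with a composite-ring
  treatment of patch heterogeneity (`deploy()`, `solve_station()`), full
  through-wall stress/strain fields and deployed geometry.
* **Uncertainty engine** — gamma distributions moment-matched from
  std-as-percent-of-mean, a fourth-order polynomial chaos expansion on
  generalized-Laguerre bases (136-run design), first-/total-order Sobol
  indices and a 1000-query emulator (`pce()`, `sobol_indices()`,
  `query_emulator()`).
* **Outcome metrics** — volume-weighted percentile field statistics,
  intramural strain profiles, mesh-layer convergence, Hausdorff and
  symmetric surface distances, perimeter-derived diameter, per-third stent
  enclosed volume (`metrics_report()`, `mesh_distances()`).
* **Study runners** — `run_convergence()`, `run_material_uq()`,
  `run_patch_study()` orchestrate the three studies from one configuration
  (`default_config()`, YAML/JSON via `read_config()`), with provenance
  headers and byte-reproducible outputs; `inst/cli/tpvuq` is a thin
  command-line wrapper.

The methods vignette (`vignettes/tpv-deployment-uq.Rmd`) documents the
model, every tunable parameter, the surrogate's assumptions and its known
limitations.

## Worked example

```r
library(tpvuq)
cfg   <- default_config()
geom  <- build_geometry(cfg)            # idealized two-waist RVOT tube
stent <- build_stent(cfg, geom)         # 25 mm device, K_s = 400 kPa
res   <- deploy(geom, stent, build_materials(cfg))
res
#> TPV deployment (per-station ring surrogate)
#>   41 stations, 17 in contact, 0 non-converged
#>   waist: R = 9.03 -> r = 10.70 mm (86% of free radius)
#>   max 1st principal stress 634.3 kPa, strain 0.2030
summary(res)
#> Deployment field summary (volume-weighted)
#>   stress1 (kPa): max 634.27, 95th 359.73, 75th 79.08, mean 67.72
#>   strain1:       max 0.2030, 95th 0.1545, 75th 0.0658, mean 0.0343
#>   stent enclosed volume 23472 mm^3
```

The device opens the 9 mm waist to 10.7 mm (86 % of its 12.5 mm free
radius); stress and strain concentrate at the two narrowings where the
device impinges the wall, and the volume-weighted 95th percentiles
(360 kPa, 0.155) summarize the field away from point hotspots.

The uncertainty study propagates the five HGO parameters through 136
deployments and reads sensitivities off the emulator:

```r
uq <- run_material_uq(cfg, seed = 1)
uq
#> Material UQ study: 136 runs (0 failed), seed 1
#>   largest first-order index for 95th%ile strain: kappa
```

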