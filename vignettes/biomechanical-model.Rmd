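---
title: "A stress-coupled model of glioma growth, vascular compression and drug delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stress-coupled model of glioma growth, vascular compression and drug delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements: the
equations, the assumptions behind them, the parameters that matter, what the
synthetic virtual-patient generator does and does not emulate, and the
numerical choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The coupled model

The package simulates a brain tumor as a growing hyperelastic inclusion in a
host tissue whose stiffness varies in space, as it would be measured by
magnetic resonance elastography (MRE). Six physics layers are coupled in a
staggered loop.

**Elastography-derived stiffness.** MRE reports a storage modulus $G'$ and a
loss modulus $G''$ at the driving frequency $\omega$. For a
single-relaxation-time solid,
$G' = G(\omega\tau_m)^2/(1+(\omega\tau_m)^2)$ and
$G'' = G\,\omega\tau_m/(1+(\omega\tau_m)^2)$, which inverts uniquely to the
elastic shear modulus $G = G' + G''^2/G'$ and decay time
$\tau_m = G'/(G''\omega)$ (`reconstruct_shear_modulus()`). Only the elastic
branch enters the mechanics: growth-scale strain rates (days) are many orders
of magnitude slower than the relaxation rate (tens of milliseconds), so
transient viscoelasticity is discarded. $\tau_m$ is computed and carried for
inspection.

**Growth kinematics.** The deformation gradient is decomposed
multiplicatively, $F = F_e F_g$, with a diagonal growth tensor
$F_g = \mathrm{diag}(\lambda_{gx},\lambda_{gy},\lambda_{gz})$. Each stretch
obeys $\dot\lambda_{ga} = \Gamma_a\, r_g\, \lambda_{ga}$ where the
anisotropy multipliers
$\Gamma_a = \exp(A\sigma_{aa}/k)\big/\sum_b \exp(A\sigma_{bb}/k)$
distribute the mass growth over the laboratory axes according to the normal
Cauchy stresses: growth is biased toward the least compressed directions,
with dimensionless gain $A$ ($A=0$ is isotropic growth). The mass growth
rate is oxygen-limited, $r_g = k_1\, c_{ox}/(k_2+c_{ox})\, T_{cel}$. Because
$\sum_a\Gamma_a = 1$, the volumetric growth rate
$\mathrm{d}\ln\det F_g/\mathrm{d}t = r_g$ is independent of how growth is
distributed — a property the tests assert exactly, since the update uses the
exponential map $\lambda_{ga} \leftarrow \lambda_{ga}
e^{\Gamma_a r_g \Delta t}$, which solves the frozen-coefficient equation
without truncation error.

**Stress balance.** Quasi-static biphasic equilibrium,
$\nabla\cdot(\sigma_s - p_i I) = 0$, with the solid Cauchy stress derived
from a compressible neo-Hookean energy
$W = \tfrac{G}{2}(\bar I_1 - 3) + \tfrac{k}{2}(J_e-1)^2$, where
$\bar I_1 = J_e^{-2/3} I_1$ is the isochoric first invariant of $F_e$. The
isochoric correction makes the reference state exactly stress-free; the
uncorrected invariant (which does not) is available behind
`isochoric = FALSE` for comparison. The far boundary is clamped ($u = 0$),
standing in for the skull.

**Interstitial fluid.** Darcy flow $v_f = -k_{th}\nabla p_i$ with Starling
filtration from the vasculature and lymphatic drainage restricted to host
tissue (functional intratumoral lymphatics are absent in solid tumors):
$-\nabla\cdot(k_{th}\nabla p_i) = L_p S_v (p_v - p_i) -
L_{pl} S_{vl}(p_i - p_{vl})$. The classic two-regime behavior falls out of
the parameters: defining $\phi^2 = L_p S_v / k_{th}$, the tumor core
plateaus at $p_i \to p_v$ once $\phi R \gg 1$, with a rim boundary layer of
width $1/\phi$. At the package defaults $\phi R \approx 1.5,\ 6.0,\ 13.6$
for vessel-wall pores of 100, 200, 300 nm, so the 300 nm case plateaus
within 1% of $p_v$ while the 100 nm case stays well below. The reference
values of $\gamma$ and $k_{th}$ were chosen from this closed-form analysis
so that all three regimes are resolvable on the study meshes.

**Oxygen and cells.** Oxygen follows convection–diffusion with
Michaelis–Menten uptake and transvascular supply
$Per_{ox} S_v (c_{iox} - c_{ox})$; since its dynamics are minutes against
growth steps of half a day, the growth loop uses the quasi-steady solution.
Cancer-cell density $T_{cel}$ (normalized to $10^7$ cells/cm$^3$) follows an
anisotropic reaction–diffusion equation whose diffusion tensor comes from
DTI; the reaction is the oxygen-limited growth inside the tumor and constant
proliferation $\rho_{cell} T_{cel}$ for escaped cells in the host.

**Vasculature.** Vascular surface density starts uniform at $S_{v0}$ and is
reduced by stress-induced vessel compression,
$S_v = (d/d_0) S_{v0}$. The diameter ratio follows an exponential
half-compression law
$d/d_0 = \exp\!\big(-\ln 2\, \max(0, -\mathrm{tr}\,\sigma_s)/
\sigma_{1/2}\big)$: monotone, bounded, one interpretable parameter
($\sigma_{1/2}$, the compressive bulk stress that halves the diameter,
default 1 kPa). The published source for the compression law gives no
closed form, so this is the package's choice; the interface accepts any
monotone replacement.

**Drug delivery.** A bolus at day 41 decays in plasma as
$C_{iv} = e^{-(t-t_0)/k_d}$ and crosses the vessel wall by Starling's
approximation
$Q = Per\,S_v(C_{iv}-c_f) + L_p S_v (p_v-p_i)(1-\sigma_f) C_{iv}$. Wall
coefficients derive from pore geometry and drug size: $L_p = \gamma
r_0^2/(8\eta L_{vw})$, $Per = \gamma H D_0/L_{vw}$, $\sigma_f = 1-w$, with
hard-sphere hindrance factors built from the Bungay–Brenner centerline
resistances $K_t, K_s$: partition $F=(1-\lambda)^2$, $H = 6\pi F/K_t$,
$w = F(2-F)K_s/(2K_t)$, $\lambda$ = drug radius / pore radius. When the
pore size is swept, the wall is modeled with a fixed pore *number density*:
the area fraction scales as $\gamma \propto r_0^2$ relative to the 200 nm
reference. This choice matters: with a fixed area fraction, a 2 nm drug's
permeability would be nearly pore-size independent ($H \approx 1$), whereas
published delivery measurements in such models show transvascular delivery
rising strongly with pore size; fixed density reproduces that direction
(a `"fixed_fraction"` switch retains the alternative). The
resistance series coefficients are the canonical published table; the tests
pin them against an extended-precision evaluation and the exact
$\lambda\to0,1$ limits. In the tissue, free drug convects, diffuses, binds
($k_{on} c_e \Phi$), unbinds ($k_{off}$) and is internalized ($k_{int}$);
the readout is internalized drug at day 43.

## The virtual patient

No patient MRE/DTI volumes are distributed with the study this model
addresses, so the package generates them. The generator smooths white noise
with a Gaussian kernel (σ = correlation length), rescales affinely to a
target mean/SD and clips at a positive floor; the loss modulus is a fixed
fraction (default 0.4) of the storage modulus, sufficient because the
mechanics uses only the reconstructed elastic modulus. DTI tensors are
$D = \bar D[(1-f)I + 3f\,nn^T]$ with a smoothed random unit direction field
$n$: exactly trace-preserving and SPD for anisotropy fraction $f<1$. A
separate "patient tumor" field is generated on its own rectangular
parallelepiped and mapped affinely onto the cube circumscribing the 5 mm
spherical seed, mirroring how patient tumor data are embedded into a common
seed geometry.

Defaults (host $G'$ 1500 ± 300 Pa at 8 mm correlation, tumor $G'$ 1100 ±
400 Pa at 2.5 mm, DTI trace/3 = 0.02 mm²/day at 30% anisotropy) are
literature-plausible magnitudes for brain at 50 Hz — **not** values from any
acquisition; no distributional statistics are published to validate them
against. What the synthetic fields do emulate: positive, spatially
correlated, heterogeneous moduli with distinct tumor statistics, and SPD
anisotropic diffusion tensors. What they do not: gray/white-matter anatomy,
ventricles, fiber-tract topology, skull geometry, registration artifacts.
Trend conclusions (heterogeneity widens the vascular-density distribution;
smaller drugs deliver more; larger pores level the IFP) exercise the same
couplings as real data would, but quantitative outputs should not be read
as patient predictions.

## Geometry, discretization, solvers

The domain is a concentric-spheres idealization: a 5 mm tumor seed centered
in a 50 mm host ball with clamped outer boundary — the brain surface's only
mechanical role here is the far-field constraint. The mesh is built from
radial shells of a subdivided-octahedron sphere triangulation (octant-
symmetric, so angular asymmetry metrics have no mesh bias): a tetrahedral
fan at the center and prism layers between shells, each prism split by the
global-least-vertex rule. One shell always lies exactly on the seed surface,
whose triangulation is retained to measure deformed tumor shape: volume,
area and sphericity come from the advected closed surface, and overlaps
between runs integrate the star-shaped radius functions over solid angle.

Mechanics uses first-order tetrahedra, total-Lagrangian, with an analytic
residual and a consistent element-level finite-difference tangent; Newton
with backtracking line search, relative residual tolerance $10^{-8}$, and
automatic sub-incrementation of $F_g$ on non-convergence. Scalar transport
shares the mesh: lumped mass (conservation is then exact for the splitting
schemes, as the tests assert), backward-Euler diffusion, integrated-by-parts
conservative convection, and exact or RK4 integration of local kinetics.
Interstitial pressure is a single sparse solve per step. The staggered order
per 0.5-day step is: growth rate → anisotropy multipliers → growth
stretches → mechanics → fluid → oxygen → cells → vasculature, with the drug
sub-loop (60 s steps) between injection and readout re-using a cached
factorization.

Numerical caveats worth knowing:

* **Volumetric locking.** Displacement-only P1 tetrahedra lock as
  $k/G$ grows. On the oracle-equivalence benchmark the radial stress
  profile error is ~4% of the profile norm at $k/G=3$ but ~17% at
  $k/G=15$ on the same mesh. Defaults therefore use drained-tissue
  compressibility ($k = 5$ kPa, $k/G \approx 3\text{–}4.5$, Poisson ratio
  ≈ 0.40) — the right regime for a biphasic model, where the fluid carries
  the rest — and the solver-verification tests run at $k/G = 3$.
* **No discrete maximum principle.** P1 diffusion on general tet meshes can
  undershoot slightly; densities tolerate (and the oxygen steady solve
  clips) bounds violations at solver-noise level.
* **Transport on the reference configuration.** The transport operators are
  not pushed forward through the deformation; intratumoral statistics use
  deformed element volumes ($J \times$ reference volume) and the advected
  material mask. At the simulated deformations (tumor radius roughly
  doubles) this is a recognized approximation.
* **Faceting.** The polyhedral ball underestimates the sphere volume
  (about 9% at angular subdivision 2, 2% at 3); shape metrics are therefore
  always compared between runs on the same mesh, never against closed-form
  sphere values.

## Parameters

The study's parameter table is not available in the source text, so every
constant below is a package assumption, chosen once from the tumor-biophysics
literature and from the closed-form analyses above, and documented here;
none was fitted to an acceptance outcome.

| block | parameter | default | meaning |
|---|---|---|---|
| material | $\omega$ | $2\pi\cdot50$ rad/s | MRE driving frequency |
| material | $k$ | 5000 Pa | drained bulk modulus (both regions) |
| growth | $k_1$ | 0.035 /day | maximal specific growth rate |
| growth | $k_2$ | 0.25 | oxygen half-saturation (normalized) |
| growth | $A$ | 25 | anisotropy degree (0, 25, 50 in the study) |
| growth | $\rho_{cell}$ | 0.02 /day | host proliferation of escaped cells |
| fluid | $k_{th}$ | $4\times10^{-7}$ mm²/(Pa·s) | hydraulic conductivity |
| fluid | $p_v$ | 2000 Pa | vascular (gauge) pressure |
| fluid | $L_{pl}S_{vl}$ | $1.6\times10^{-8}$ /(Pa·s) | host lymphatic drainage |
| vascular | $S_{v0}$ | 7 /mm (70/cm) | reference vascular density |
| vascular | $\sigma_{1/2}$ | 1000 Pa | half-compression bulk stress |
| oxygen | $Per_{ox}$ | $2\times10^{-4}$ mm/s | effective vascular O₂ exchange |
| oxygen | $A_{ox}, k_{ox}$ | $4\times10^{-4}$ /s, 0.15 | uptake kinetics |
| wall | $\gamma$ | $10^{-3}$ at 200 nm | pore area fraction (fixed-density scaling) |
| wall | $L_{vw}$ | 5 µm | vessel wall thickness |
| wall | pore | 200 nm (100–300 swept) | tumor wall pore diameter |
| drug | sizes | 2, 70, 150 nm | drug diameters |
| drug | $k_d$ | 0.25 day | plasma circulation decay |
| drug | $k_{on},k_{off},k_{int}$ | $10^{-3},10^{-4},10^{-5}$ /s | binding kinetics |
| drug | threshold | 0.5 | "well-treated" cut: half the injected plasma level |

Two calibrations deserve explanation. $k_1 = 0.032$/day places the day-43
heterogeneous run at the vascular operating point the field's published
intratumoral statistics imply (mean functional density about two thirds of
the host reference, i.e. mild-to-moderate compression), which also lands
the tumor near twice the seed radius; the simulated "day" is explicitly a
model unit, decoupled from patient chronology, so $k_1$ sets pacing rather
than biology. And $\gamma, k_{th}$ jointly set the IFP regimes as derived
above. Sensible ranges for all of these are one knob away in the YAML
config (`write_config_yaml()` / `read_config_yaml()`).

## The reference study and problem sizes

`reference_study()` is the packaged experiment: one synthetic patient; runs
at $A = 0, 25, 50$ with heterogeneous stiffness; the region-averaged
constant-stiffness control; pore sweeps 100/200/300 nm; drug sizes
2/70/150 nm sharing the $A=25$ flow history. It reports Dice overlaps of
the deformed tumor shapes, sphericity, intratumoral mean/SD of vascular
density and internalized drug, octant-based angular asymmetry, the
fraction of tumor above the drug threshold, and the IFP core plateau per
pore size. The study runs on the angular-subdivision-2 mesh
(~1200 nodes, 86 half-day steps per run); the solver-verification
benchmarks use finer meshes (up to ~9000 nodes) and a 1D spherically
symmetric reference solver. These sizes are the package's reference
configuration; everything scales through `simulation_config()`.

Open modelling choices resolved here (and why): laboratory-frame (not
co-rotated) normal stresses drive the anisotropy multipliers, because the
growth tensor is defined diagonal in the laboratory frame; the bulk stress
driving vessel compression is the full trace $\mathrm{tr}\,\sigma_s$ (the
$1/3$ convention can be absorbed into $\sigma_{1/2}$); $\lambda$ in the
hindrance factors is the radius/radius ratio; the bolus is zero before the
injection time; lymphatics are host-only; oxygen is initialized at the
vascular level.

## Limitations

Beyond the numerical caveats above: no angiogenesis or vessel
normalization; no radiotherapy or cytotoxic feedback of the drug on cells;
single-exponential plasma kinetics; elastic properties constant in time;
simplified spherical anatomy; growth anisotropy aligned to laboratory axes
rather than fiber directions. Quantitative values printed by the reference
study characterize the synthetic study conditions, not any patient.
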