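---
title: "A steady-state reaction-diffusion model of the cyanobacterial CO2-concentrating mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state reaction-diffusion model of the cyanobacterial CO2-concentrating mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmsim)
```

## The model

Cyanobacteria concentrate inorganic carbon around RuBisCO by pumping
bicarbonate into the cell and converting it to CO2 inside a protein
microcompartment, the carboxysome. `ccmsim` solves the steady state of the
two coupled species — CO2, $C(r)$, and bicarbonate, $H(r)$ — in a
spherically symmetric cell of radius $R_b$ with a single central
carboxysome of radius $R_c$:

$$0 = D\nabla^2 C + R_{CA}(H, C) - R_{Rub}(C), \qquad
  0 = D\nabla^2 H - R_{CA}(H, C),$$

with the reactions active only where the enzymes sit (the carboxysome, a
central scaffold, or the whole cytosol, depending on the scenario).
Carbonic anhydrase follows reversible Michaelis–Menten kinetics,

$$R_{CA}(H,C) = \frac{V_{ba} K_{ca} H - V_{ca} K_{ba} C}
                     {K_{ba}K_{ca} + K_{ca} H + K_{ba} C},$$

positive when bicarbonate is dehydrated to CO2. Its zero defines the
equilibrium ratio $K_{eq} = H/C = K_{ba}V_{ca}/(K_{ca}V_{ba}) \approx 5$
near pH 7 (`equilibrium_ratio()`). RuBisCO carboxylation competes with O2,
$R_{Rub} = V_{max} C / (C + K_m'(1 + O/K_O))$, and the wasteful oxygenation
reaction uses the symmetric competitive form
$V_{maxO}\,O/(O + K_{mO}(1 + C/K_C))$.

At the cell membrane, Robin conditions carry passive leakage of both
species ($k_{mC} \gg k_{mH}$, since membranes pass CO2 far more readily
than a charged ion), active bicarbonate import $j_c H_{out}$, and a
saturable CO2-to-bicarbonate conversion ("facilitated uptake")
$\alpha\,C_{cyt}/(K_\alpha + C_{cyt})$ that removes CO2 from and delivers
bicarbonate to the cytosolic face. The carboxysome shell is a zero-thickness
interface with a single non-selective permeability velocity $k_c$:
$D\,\partial_r C = k_c\,(C_{cyt} - C_{carb})$ on both faces, and likewise
for $H$.

Units are uM for concentrations, cm and s for space and time, cm/s for all
membrane/shell velocities, uM/s for volumetric enzyme rates; whole-cell
fluxes are reported in pmol/(cell s) (1 uM = 1e-9 mol/cm^3).

## Parameters

Defaults (the `"table1_table2_defaults"` preset) describe a cell of radius
0.5 um with a 50 nm carboxysome: $D = 10^{-5}$ cm^2/s, $k_{mC} = 0.3$ cm/s,
$k_{mH} = 3\times10^{-4}$ cm/s, $H_{out} = 14$ uM, $C_{out} = 0.14$ uM
(carbon-limited conditions, 15 uM total), O2 fixed at 260 uM, and
carboxysome-volumetric enzyme rates $V_{ca} = 1.5\times10^7$,
$V_{ba} = 8.8\times10^6$, $V_{max} = 1.8\times10^5$ uM/s with
$K_{ca} = 3.2$ mM, $K_{ba} = 9.3$ mM, $K_m' = 270$ uM. The reference
operating point is $j_c = 0.6$ cm/s and $k_c = 10^{-3}$ cm/s with
$\alpha = 0$. The `"sucrose_carboxysome"` preset lowers the interior
diffusivity to $10^{-7}$ cm^2/s, the value expected for small molecules in
a 60% sucrose solution, to emulate a crowded carboxysome lumen.

Two choices deserve comment:

* **Oxygenation constants.** $V_{maxO}$, $K_{mO}$ and $K_C$ are not part of
  the published parameter set. We adopt the standard paired competitive
  RuBisCO form, which forces $K_C = K_m'$ and $K_{mO} = K_O$ (one O2
  constant; the literature's $K_i$ and $K_O$ name the same quantity, and the
  package exposes a single field `KO`). $K_O$ is fixed a priori at 900 uM, a
  typical O2 half-inhibition constant for cyanobacterial RuBisCO, and
  $V_{maxO}$ was calibrated once (script `scripts/calibrate_oxygenation.R`)
  so the oxygenation/carboxylation flux ratio at the reference operating
  point equals the published budget ratio 0.82%, giving
  $V_{maxO} = 5.71\times10^4$ uM/s. With these defaults the 1%-error CO2
  level is $C_{99\%} =$ `r round(c99_concentration(260, rubisco_kinetics()))`
  uM. All transport and leakage results are insensitive to these constants,
  because oxygenation consumes no carbon and is a $\lesssim 10^{-2}$%
  share of the budget.

* **Enzyme totals across scenarios.** The published whole-cell and
  carboxysome volumetric rate columns are mutually inconsistent with the
  single volume ratio $(R_b/R_c)^3 = 1000$ (they imply factors 1704, 587
  and 1011 for the three reactions). The presets store the carboxysome
  column verbatim, and `rescale_for_scenario()` conserves total enzyme
  ($V_{max} \cdot V_{active}$ invariant) from that column, so organization
  comparisons are strict like-for-like; the literal cell column is kept as
  `table2_cell_column()` for reference.

## Numerics

`solve_ccm_numeric()` uses a conservative finite-volume discretization on
a radial grid of 400 nodes by default: uniform inside the carboxysome,
cosine-clustered towards the shell and the membrane outside. The node at
$R_c$ is duplicated in the carboxysome scenario so the shell is a genuine
zero-thickness flux jump between the twin nodes. Cytosolic face
conductances use the exact spherical-shell diffusive resistance
$4\pi D/(1/r_i - 1/r_{i+1})$, which reproduces the harmonic $a + b/r$
profiles of the reaction-free cytosol exactly at any resolution; halving
the mesh moves carboxysomal CO2 by well under 0.5%.

The nonlinear system is solved by damped Newton iteration with the
analytic Jacobian of both rate laws, starting from the uniform external
state, with step halving, a concentration floor at zero, and a fall-back
under-relaxation factor of 0.5 if a full step fails. Convergence is
declared when the summed absolute residual falls below $10^{-9}$ of the
total flux turnover — a global mass-balance closure metric; the iteration
also stops if the line search exhausts itself within three decades of that
floor, which happens when the residual reaches the rounding noise of the
flux differences on the clustered boundary mesh. Converged budgets close
carbon conservation to ~1e-12 relative. Everything is deterministic: no
randomness, no seeds.

Degenerate inputs are handled explicitly: enzyme rates far below the
diffusive scale collapse to the uniform solution; negative concentrations
during iteration trigger damped retries and a final non-negativity
assertion; non-convergence raises an error carrying the residual history.

## Closed-form solutions

In the enzyme-free cytosol both species are harmonic ($a + b/r$). Inside
the active region, any affine rate law $R_{CA} \approx p_0 + aH - bC$,
$R_{Rub} \approx q_0 + gC$ turns the system for $(u, v) = (rC, rH)$ into
$w'' = Mw + sr$ with a constant real $2\times2$ matrix $M$; its
eigen-decomposition yields modified-Helmholtz modes $\sinh(\kappa r)/r$ for
positive eigenvalues and polynomial modes for zero eigenvalues (the
degenerate zero-eigenvalue case gets the cubic particular solution).
Matching the shell flux-jump and membrane Robin conditions closes a 6x6
linear system (2x2 for the whole-cell scenario; value-and-flux continuity
replaces the jump for the scaffold).

`solve_ccm_analytic()` offers two linearizations:

* `"limit"` reproduces the textbook branch forms: *unsaturated* carbonic
  anhydrase (low occupancy, $R_{CA} \approx (V_{ba}/K_{ba})H -
  (V_{ca}/K_{ca})C$) and *saturated* dehydration at capacity. For the
  saturated branch we retain the linearized reverse flux,
  $R_{CA} \approx V_{ba}(1 - K_{eq}C/\bar H)$, iterated to
  self-consistency in the carboxysomal mean $\bar H$: dropping it (a pure
  constant source) misses the equilibrium ceiling $C \le H/K_{eq}$ that in
  this parameterization limits the CO2 level throughout the physically
  interesting range, and would make the branch wrong by factors of
  several. Retaining it also makes the two branches meet continuously at
  the saturation transition $\bar H = K_{ba}$.
* `"operating_point"` (the default) takes the first-order Taylor expansion
  of the full rate laws about the self-consistent carboxysomal operating
  point, found by a damped fixed-point iteration. The solution family is
  identical — sinh modes and polynomials — and reduces to the limit
  branches in their asymptotic regimes, but is uniformly accurate in
  between: because the carboxysome is small enough that its interior is
  nearly well mixed, this closed form agrees with the finite-volume
  solver to better than $10^{-5}$ across the scanned $(j_c, k_c)$ range,
  making it a genuinely independent oracle (no discretization shared with
  the numeric path) and a fast engine for phase scans.

Branch classification follows concentration thresholds: carbonic anhydrase
is *saturated* when the carboxysomal $H$ reaches $K_{ba}$ (ties label
saturated), RuBisCO when $C$ reaches the effective $K_m$. A solution
reports `regime$valid = FALSE` when its own assumptions fail at its
solution (or the fixed point did not converge), and `solve_ccm_analytic()`
raises a regime error directing callers to the numeric solver when no
branch is self-consistent. The membrane conversion term is linearized as
$(\alpha/K_\alpha)C$, so the closed form is quantitative only while
cytosolic CO2 stays well below $K_\alpha$; the numeric solver carries the
full saturable form.

## Flux budgets and a capacity bound

`flux_budget()` evaluates the membrane fluxes from the boundary
concentrations and integrates the reaction rates over the active volume,
reporting each as a percentage of gross active transport
$j_c H_{out} \cdot 4\pi R_b^2$. One structural property of the equations is
worth knowing when reading budgets: every CO2 molecule that leaks out of
the cell must first cross the carboxysome shell, and a positive net
dehydration rate requires $C_{carb} < H_{carb}/K_{eq}$, so CO2 leakage is
bounded by $k_c \cdot 4\pi R_c^2 \cdot H_{cyt}/K_{eq}$. At the reference
operating point this bound is about 0.7% of gross transport — the budget
the package computes there puts CO2 leakage near 0.4%, bicarbonate
leakage near 99.6%, and carboxylation near 0.03%, with the cytosolic pool
at 27.9 mM, close to the transport-leakage balance
$H_{out}(1 + j_c/k_{mH}) = 28$ mM (`hcyt_closed_form()`).

## Attribution of the conversion flux

The model has a single membrane conversion term, but two biological
readings: *facilitated uptake* of external CO2 and *scavenging* of CO2
escaped from the carboxysome. `uptake_partition_scan()` splits the total
conversion flux by linearity of the cytosolic CO2 field in its sources:
with the shell flux switched off the cytosolic CO2 would sit at the uniform
level $C_{out}k_{mC}/(k_{mC} + \alpha/K_\alpha)$; the conversion flux
sustained by that component is facilitated uptake, the remainder is
scavenging. At the optimal shell permeability the cytosol holds almost no
escaped CO2, so scavenging is negligible under either attribution one
might choose, and facilitated uptake overtakes active transport only when
external CO2 exceeds roughly 80% of the inorganic pool — CO2 uptake is
throttled by membrane permeation even at equal pump velocities.

## Other analyses

`phase_scan()` solves the model over a log-spaced $(j_c, k_c)$ grid (the
closed form where valid, numeric otherwise) and extracts
iso-concentration contours by log-log interpolation: the $K_m$ and
$C_{99\%}$ carboxysomal CO2 lines, the CA-saturation boundary, and the
30 mM cytosolic bicarbonate line (which is nearly vertical at
$j_c \approx 0.64$ cm/s, since the cytosolic pool is set by transport and
leakage alone). `optimal_kc()` minimizes over $k_c$ the transport needed
to reach a CO2 target; with the calibrated defaults the optimum for
$C_{99\%}$ sits at a few $10^{-4}$ cm/s, an order of magnitude consistent
with the $10^{-3}$ cm/s headline value and far below the pore-geometry
diffusive bound `kc_upper_bound()`. `organization_compare()` re-solves the
model with equal total enzyme for the four canonical organizations,
tuning $j_c$ per scenario to a 30 mM cytosolic pool; co-localization
buys roughly one order of magnitude in central CO2 and an optimally
permeable shell buys well over another. `physiology_estimates()` converts
a budget into transporter surface density, carbon-fixation mass rate and
division-time arithmetic.

## What the defaults do and do not emulate

The default configuration *is* the study condition: a single centered
carboxysome, fixed O2, constant external carbon, equal shell permeability
for both species, no cytosolic interconversion (the uncatalyzed reaction
is far slower than every other process), and no explicit pH dynamics
(pH enters only through $K_{eq}$ and the external speciation). Passing
tests therefore say nothing about multi-carboxysome cells, charge-selective
pores, time-dependent carbon drawdown, or pH microenvironments.

## Known limitations

* The closed-form solver requires volumetric carbonic anhydrase placement;
  the shell-localized variant is numeric only (it agrees with the
  volumetric case to ~0.004% at defaults, and within ~0.4% at
  $D_{carb} = 10^{-7}$ cm^2/s, consistent with a nearly well-mixed lumen).
* The pore-geometry permeability bound evaluates to ~3.3 cm/s with the
  standard pore counts and dimensions; treat it as the geometric formula's
  value, not as a sharp physical ceiling (charge effects can only lower
  it). See the README for why this number is reported as computed.
* Published budget tables associated with this parameterization are not
  steady states of these equations (they exceed the shell capacity bound
  above); the package reports what the equations give. The test suite
  marks those comparisons accordingly rather than adjusting parameters
  toward them.
* Test and example problem sizes: unit tests solve on 150-200 radial
  nodes and use modest scan grids (up to 12x10); production defaults are
  400 nodes and 40x40 scans, which the same code paths handle in a few
  tens of seconds.
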