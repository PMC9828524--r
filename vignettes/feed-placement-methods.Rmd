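---
title: "Feed-point placement and compartment-model simulation: models and methods"
author: "gradmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-point placement and compartment-model simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradmix)
```

# The problem

Industrial stirred tanks and bubble columns (tens to hundreds of cubic
metres) mix on the scale of minutes, while a fed-batch culture consumes
its substrate on the scale of seconds. The feed therefore forms
gradients: substrate-rich, oxygen-depleted zones near the inlet and
starved zones far from it, with pH excursions whenever corrective agents
are pulsed in. `gradmix` implements two complementary tools for studying
this problem: an analytic theory of *where* feed points should be
placed, and a 3D compartment-model simulator to evaluate *how much* a
given arrangement actually mitigates the gradients in a specific vessel.

# Placement theory

Macromixing along one dimension of an insulated vessel is modelled as
turbulent diffusion. After a pulse feed the dimensionless concentration
(spatial mean 1) is an eigen-series

$$u(x,t) = 1 + \sum_{m\ge1} A_m e^{-k_m t},$$

with axial rates $k_{zm} = m^2\pi^2 d/H^2$, radial rates
$k_{rm} = \beta_m^2 d/R^2$ ($\beta_m$ the roots of $J_1$, because the
wall is a symmetry boundary), and tangential rates
$k_{\phi m} = 4m^2\pi^2 d/(\Phi^2 r^2)$. The pre-exponentials carry the
feed position: axially $A_m \propto \cos(m\pi z_0/H)$, radially
$A_m \propto J_0(\beta_m r_0/R)$. The placement rules all follow from
making the slowest pre-exponentials vanish:

* a **centred axial feed** ($z_0 = H/2$) kills every odd mode, so the
  limiting rate jumps from $k_{z1}$ to $k_{z2} = 4k_{z1}$ — a four-fold
  mixing rate versus a top or bottom feed;
* **N axial feeds** at $z_i/H = (2i-1)/2N$ split the height into $N$
  insulated-equivalent subdomains of height $H/N$, multiplying the
  limiting rate by $N^2$ (so $4N^2$ versus an end feed);
* a **single radial feed** at $r_0/R = \alpha_1/\beta_1 \approx 0.628$
  ($\alpha_i$ the roots of $J_0$) kills the first radial mode, leaving a
  $(\beta_2/\beta_1)^2 \approx 3.35$-fold rate;
* **N radial rings** at $r_i/R = \alpha_i/\beta_N$ kill the $N$-th mode
  for every ring; per-ring weights that kill the remaining modes
  $m < N$ solve a small linear system (rows $J_0(\beta_m r_i/R)$, plus
  a row of ones forcing the weights to sum to one). For $N = 2$:
  radii 34.3 % and 78.7 % of $R$, weights 0.302 : 0.698 (1 : 2.31);
* **tangential counts** per ring should be proportional to the ring
  radius (equal perimeter per feed point keeps the tangential rate
  constants equal across rings); the package rounds
  $N\,r_i/r_N$ to the nearest integer (minimum 1), which for two rings
  gives the 1 : 2 pattern and a rounding error below 15 % of a count.

```{r}
placement_table(n_axial = 2, n_radial = 2)
```

Note that the exact two-ring optimum is $\alpha_1/\beta_2 = 0.3428$;
reported percentages in the literature vary between 34.3 and 34.4 in
the last digit, and the package always returns the exact Bessel ratio.

Two closed forms complete the theory. The mixing time of the axial
model is the time at which
$\sigma(t) = \{\sum_m 2\cos^2(m\pi z_0/H)\,e^{-2k_{zm}t}\}^{1/2}$
falls to the 5 % threshold ($t_{95}$); `mixing_time_1d()` brackets the
unique crossing geometrically and bisects to $10^{-8}$ relative. And
because mixing-time correlations give
$t_{95} \propto (P/\rho V)^{-1/3}$ and $t_{95} \propto V^{2/9}$,
`scale_equivalents()` converts a rate improvement into the equivalent
specific-power fold ($\mathrm{rate}^3$) or volume fold
($\mathrm{rate}^{9/2}$): doubling the rate by feed placement is worth
an 8-fold power input, and a 10-fold rate equals mixing a ~31600-fold
smaller volume.

**Series truncation.** The default is 50 terms. The truncated tail of
$u$ is bounded by a geometric series,
$2e^{-k_{n+1}t}/(1-e^{-(k_{n+2}-k_{n+1})t})$, negligible for
$t > 0.2/k_1$ at $n = 50$; small-time evaluation (where the series
represents a near-delta) is the only regime that would need more terms,
and $\sigma$ near $t_{95}$ needs only the leading few.

# The compartment models

A reactor is discretised into `nz` axial layers, `nr` equal-width radial
rings (volumes proportional to annulus area, centroids at area
centroids), and `nphi` sectors. Flows between compartments are of two
kinds: directed convective loops and equal-opposing exchange pairs.

*Stirred tanks* (per impeller stage): nested recirculation loops above
and below the impeller plane — radial discharge at the impeller layer,
return flow along the far layer, one loop per adjacent ring pair;
axial exchange between every adjacent layer pair, weaker across stage
boundaries (default 0.15 of the impeller pumping rate
$Q = \mathrm{Fl}\,n D^3$, versus 0.5 within a stage) — the inter-stage
exchange is the axial bottleneck that makes feed placement matter in
multi-impeller tanks; unidirectional tangential circulation around each
ring; turbulent radial exchange between adjacent rings at every layer.

*Bubble columns*: upflow in the inner rings, downflow in the outer
ring, with the radial turning flows confined to the top and bottom
parts (nested loops turning at successive layers, `nz/5` deep); the
middle part carries only vertical convection plus exchange; axial
exchange from the dispersion closure
$D_\mathrm{ax} = 0.35\,T^{4/3}(g u_G)^{1/3}$; tangential *exchange*
(no net swirl); and radial exchange between the counter-flowing
streams.

The radial exchange deserves emphasis. Without lateral mass exchange, a
vessel-spanning circulation makes the feed height a mere phase along
the loop: the slow eigenmodes come in complex travelling-wave pairs
whose excitation is independent of where on the loop the pulse enters,
and the centre-feed advantage disappears entirely. Lateral exchange
between the rising and falling streams converts the coherent loop into
an axially dispersive process (the Taylor mechanism), restoring the
diffusion-like behaviour on which the placement theory — and the
experimentally observed feed-position sensitivity — rests. Tangential
and radial homogenisation in these vessels is fast relative to axial
transport over the full height, which is why the defaults make those
exchanges comparatively strong (fractions 0.6–1 of the local
convective rate).

**Absolute flow scale.** The topology and flow *ratios* above are
structural choices; the absolute magnitudes in any particular vessel
are not knowable from geometry alone. `calibrate_flow_scale()`
therefore anchors each network to a measured top-feed mixing time
(the catalog carries literature values: R4 154 s, R1 141 s, B13 103 s,
B6 135 s). Because the transport operator is linear in the flow scale,
$t_{95}$ is exactly inversely proportional to it, so one simulation
fixes the scale and a second verifies it to 1 %. Consequences of this
anchoring: simulated mixing times for *other* feed arrangements are
predictions of relative placement effects, not reproductions of any
particular published table, and the package's quantitative claims
about arrangements are orderings and ratios.

**Grids.** Defaults are (6 per impeller, 3, 12) for tanks and
(30, 3, 12) for columns — enough to resolve the loop structure while
keeping a full four-reactor study on one CPU in well under a minute.
Coarser axial grids overestimate the centre-feed advantage (the
placement ratio converges with refinement; from a 12-layer base in the
single-impeller tank, doubling the grid moves the
$t_{95}$(top)/$t_{95}$(centre) ratio by about 13 %).

**Feed deposition.** Each feed point maps to the compartment with the
nearest centroid. A point equidistant from several centroids — the
centre feed on a layer boundary of an even grid is the canonical case —
is split equally among them; this preserves the symmetry that cancels
the antisymmetric modes, exactly as the continuous theory requires, and
avoids an arbitrary tie-break that would halve the placement effect.

# Transient scenarios

`simulate_tracer()` integrates $\dot u = Au$ with a stiff sparse-BDF
integrator (relative tolerance $10^{-8}$) and monitors the
volume-weighted standard deviation $\sigma(t)$ of the dimensionless
tracer. $t_{95}$ is the *last* downward crossing of the 5 % threshold —
circulation loops can make $\sigma$ locally non-monotone, and the last
crossing is the conservative choice — refined by dense re-integration
over the bracketing interval and log-linear interpolation so that
$\sigma(t_{95})$ matches the threshold to $10^{-6}$. The inhomogeneity
number $N_I = \sigma(t_{95}/2)$ summarises how homogeneous the vessel
was *during* mixing; initial $\sigma$ values differ across feed
arrangements because feed compartments have unequal volumes, and the
median-type definition is deliberately robust to that.

The pH scenario models a 100 mol m⁻³ carbonate buffer (pKa 6.35)
initially at pH 4.8. A carbonate pulse sized to bring the *overall* pH
exactly to 6.0 (28.1 mol m⁻³ of vessel volume) is injected at the feed
points and advected; only carbonate is transported, bicarbonate being
total minus carbonate pointwise. The mean carbonate concentration is
conserved from $t=0^+$, but the mean pH is not — pH is a concave
function of carbonate in the relevant range, so the mean pH approaches
6 from below as the field homogenises; with a top feed it is still
visibly short of the target after 10 s, which is precisely the
pH-control hazard of poorly placed corrective feeds. One numerical
caveat is intrinsic to point pulses: the required pulse exceeds the
local buffer pool of any realistically sized feed compartment, so the
two-species closure cannot hold there at $t = 0^+$. Reported local pH
is therefore capped at pKa ± 2 (the conventional 100:1 buffer validity
range) wherever carbonate leaves $(0, \mathrm{total})$; the capped
region is a tiny volume fraction and vanishes within the first seconds.

# Fed-batch pseudo-steady state

The bioreaction scenario is a snap-shot of a fed-batch culture at fixed
biomass $X$ (default 10 g/L; 50 g/L supported as an override) and
volumetric feed rate $F$ = 4 g/L/h, with Monod uptake
$r_S = q_S X S/(S+K_S)$. The steady field solves
$A S + f - r_S(S) = 0$, where the source $f$ concentrates each feed
point's weight share of $F$ into its compartment. The solver is the
backward-Euler pseudo-time march with the analytic Jacobian and sparse
LU steps (step doubled on residual decrease, halved otherwise, from
$10^{-3}$ h), initialised at the ideal-reactor concentration
$S^* = K_S\phi/(1-\phi)$, $\phi = F/(q_S X)$, and converged to an RMS
residual below $10^{-10}F$. At convergence the volume-weighted mean
uptake equals $F$ identically — the closure every run is checked
against.

Dissolved oxygen (modelled in the tank with measured transfer data,
$k_La$ = 180 h⁻¹) balances transfer $k_La(O_e - O)$ against consumption
$1000\,Y_{OS} r_S\, O/(O+K_O)$ over the frozen substrate field; the
factor 1000 bridges the g/L substrate and mg/L oxygen unit scales, and
$O/(O+K_O)$ is the aerobically respired fraction. The solubility
$O_e$ = 12.69 mg/L follows from Henry's law (dimensionless constant
0.0266 at 35 °C) at the oxygen partial pressure prevailing at
mid-height: head pressure 1.5 bar plus the hydrostatic head of the
*ungassed* liquid column at half its height, density 994 kg/m³.
Evaluating the hydrostatic term at half the gassed working height
instead would give 12.84 mg/L; the ungassed convention is the one that
reproduces the reference value and is the package's convention.

Derived per-compartment quantities: the linearised consumption
time-scale $\tau_S = (S+K_S)/(q_S X)$ (about 15 s at the ideal point —
the root of the reaction-mixing competition) and the instantaneous
yield $y_{XS} = Y_{XS} - (q_d/q_S)(1+K_S/S)$, negative below
$S \approx 1.3$ mg/L, which is how severe top-feed gradients at high
biomass can drive the *overall* yield negative. `field_statistics()`
reports the volumetric mean and standard deviation plus the Monod
concavity diagnostics: by Jensen's inequality heterogeneity always
lowers the volume-averaged Monod factor, with second-order Taylor
correction $K_S\sigma_S^2/(\langle S\rangle+K_S)^3$, so at a fixed
overall consumption ($=F$) a broader substrate field must run at a
higher mean concentration.

# Population balance

Biomass adaptation is modelled by dividing $X$ into 10 classes of
specific growth rate $\mu_i = Y_{XS} q_S (2i-1)/20$ (or uptake rate
$q_i = q_S(2i-1)/20$). Class $i$ transfers biomass at the rate
$(X_i/\Delta\mu)(1/T_X + \mu_i)(\mu_{eq} - \mu_i)$ g/L/h toward its
neighbour in the drift direction, where
$\mu_{eq} = Y_{XS}q_S S/(S+K_S)$ is the local equilibrium rate
(constant-yield, no decay). The division by the class width follows
from dimensional analysis — the drift factor
$(1/T_X+\mu_i)(\mu_{eq}-\mu_i)$ is a velocity in rate space (h⁻²), and
dividing by $\Delta\mu$ converts it to a transfer frequency; the
worked example (class 3 at $\mu_{eq}=0.2$ h⁻¹ transferring at
$0.7875\,X_3$) is consistent only with this reading. Transfers use
donor-class upwinding (positivity) and are clamped at the grid ends
(conservation). Spatial transport applies the same operator to every
class; the coupling to substrate is one-way (the field is frozen),
justified by the fast uptake-adaptation time-scale.

For any spatially uniform substrate field the steady distribution
collapses onto the two classes bracketing $\mu_{eq}$, with the ratio
fixed by the flux balance at the shared boundary — at the ideal point
($\mu_{eq} = 0.2$ h⁻¹), $X_4/X_5 = 0.625/0.575 \approx 1.087$. Under a
heterogeneous field the distribution broadens; because
$T_X = 2.5\,\mathrm{h} \gg T_S = 0.025$ h, the growth-rate
distribution is nearly uniform in space while the uptake-rate
distribution tracks the local substrate, so its per-class volumetric
spread is much larger. The steady state is computed by the same
backward-Euler pseudo-time contract (here with a large factorised
step — the scheme is linear in the class concentrations, and the
iteration is an inverse iteration onto the conservative kernel).

# What the fixtures do and do not show

The test fixtures are built in code: exchange chains whose slowest
eigenvalue has a closed form, two-compartment systems with analytic
$\sigma(t) = e^{-4qt/V}$, toy tanks small enough for dense eigen- and
Newton-oracles, and the four-reactor catalog at desk-scale grids. They
verify the discretisation against the analytic theory (chain
$t_{95}$ matches the 1D closed form within 2 %; eigen-series matches an
independent finite-volume integration within 0.5 %) and the structural
claims (orderings, conservation, concavity, class collapse). They do
not validate the networks against CFD or plant data; gas-phase oxygen
transport, non-Newtonian rheology, micromixing, and two-way
population-substrate coupling are all outside the model, and absolute
mixing times for non-calibrated arrangements inherit the uncertainty
of the flow-ratio defaults.

# Reproducing the headline numbers

```{r}
# analytic placement constants
p2 <- optimal_radial_placement(2)
c(single_radius = optimal_radial_placement(1)$radial_fractions,
  weight_ratio = p2$weights[2] / p2$weights[1])

# ideal-reactor operating point (mg/L)
st <- ideal_reactor_state(kinetic_params())
c(S_mg = st$S * 1000, O = st$O,
  Oe = oxygen_solubility(reactor_catalog("R4")))

# four-fold centre-feed rate in the 1D model
mixing_time_1d(diffusion_problem("axial", 1, 1, feed_position = 1)) /
  mixing_time_1d(diffusion_problem("axial", 1, 1, feed_position = 0.5))
```

The full simulation study (calibrated catalog, tracer orderings,
gradient mitigation, pH recovery) runs in the acceptance test suite;
`scripts/acceptance.R` recomputes the analytic targets from scratch.
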