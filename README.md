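# gradmix

Feed-point placement theory and compartment-model simulation of
large-scale bioreactors.

Large stirred tanks and bubble columns (8–240 m³) mix in minutes while
fed-batch cultures consume substrate in seconds, so poorly placed feeds
create gradients of substrate, dissolved oxygen and pH that degrade
yields and confound probes and control. `gradmix` is for bioprocess
engineers and modellers who want to (1) compute *theoretically optimal*
feed-point arrangements and (2) quantify, with fast 3D compartment
models, how much a given arrangement mitigates the gradients in a
specific vessel.

## The core model

Macromixing along each cylindrical dimension is treated as 1D turbulent
diffusion in an insulated domain. The pulse response is the eigen-series
`u = 1 + Σ A_m exp(-k_m t)` with axial rates `k_zm = m²π²d/H²` and
radial rates `k_rm = β_m²d/R²` (`β_m` the roots of the Bessel function
J₁). Optimal placement makes the slowest pre-exponentials vanish:

* N axial feeds at `z_i/H = (2i-1)/2N` → limiting rate ×N² (×4N² vs an
  end feed); a single centred feed is 4× faster than the usual top feed;
* a single radial feed at `r₀/R = α₁/β₁ ≈ 0.628` (`α_i` the roots of
  J₀) → ×3.35; N radial rings at `α_i/β_N` with weights from a small
  Bessel linear system (for N = 2: 34.3 % and 78.7 % of R, weighted
  1 : 2.31), tangential counts proportional to the radii.

For evaluation, a vessel is discretised into axial × radial ×
tangential compartments connected by impeller/buoyancy-driven loops and
turbulent exchange flows; the absolute flow scale is anchored to a
measured top-feed mixing time. On the resulting sparse transport
operator the package simulates tracer mixing (t95 and inhomogeneity
number), carbonate-buffer pH pulses, fed-batch pseudo-steady Monod
substrate and oxygen fields with kLa transfer, and a ten-class
population balance of growth/uptake-rate adaptation.

## Worked example

```r
library(gradmix)

# where to put feed points: two radial rings with weights and counts
placement_table(2, 2)$radial
#>   N  r_over_R    weight tangential_points
#> 1 1 0.6276122 1.0000000                 1
#> 2 2 0.3427832 0.3018564                 1
#> 3 2 0.7868306 0.6981436                 2

# ideal homogeneous fed-batch reference at the default kinetics
st <- ideal_reactor_state(kinetic_params())
c(S_mg = st$S * 1000, O = st$O, Oe = oxygen_solubility(reactor_catalog("R4")))
#> S* = 16.7 mg/L, O* = 0.113 mg/L, Oe = 12.69 mg/L

# does it work in a real vessel? 23.8 m^3 four-impeller tank, flow scale
# anchored to its measured 154 s top-feed mixing time
net <- calibrate_flow_scale(build_network(reactor_catalog("R4")))
op  <- transport_operator(net)
for (code in c("Top", "A1R1T1", "A2R2T2")) {
  tr <- simulate_tracer(op, locate_feed_compartments(net, feed_arrangement(code)))
  cat(sprintf("%-7s t95 = %6.1f s   NI = %.3f\n", code, tr$t95, tr$NI))
}
#> Top     t95 =  154.0 s   NI = 0.260
#> A1R1T1  t95 =   38.5 s   NI = 0.244
#> A2R2T2  t95 =    5.8 s   NI = 0.252
```

Reading the output: the single centred feed (`A1R1T1`) delivers the
theoretical four-fold mixing rate over the conventional top feed, and
the twelve-point `A2R2T2` arrangement (two axial levels × six points)
brings a 23.8 m³ industrial tank down to laboratory-scale mixing times.
The same calibrated network feeds the bioreaction and pH scenarios
(`solve_substrate_field()`, `solve_oxygen_field()`,
`simulate_ph_pulse()`, `solve_population_field()`), where additional
feed points shrink the substrate, oxygen and pH gradients toward the
ideal-reactor point printed above.

A command-line workbench wraps the same functions:

```sh
inst/cli/gradmix placement --axial 4 --radial 2
inst/cli/gradmix mix --reactor R4 --feed A2R2T2
inst/cli/gradmix react --reactor R4 --feed Top --out results/
```

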