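# dendrocable

Semi-analytical cable theory and model reduction for branched dendrites,
in R.

Morphologically detailed neuron models — trees of cylindrical sections read
from SWC reconstructions, with Hodgkin–Huxley style ion channels — are
expensive to simulate and hard to interpret. `dendrocable` implements the
classical semi-analytical toolbox around the one-dimensional cable equation
for such models, and uses it to derive small compartmental models that
reproduce the full model's behaviour at chosen locations.

## What it computes

**Impedances and response kernels.** For a membrane linearized around an
expansion point (the *quasi-active* approximation), each channel `c`
contributes a complex admittance density `ḡ_c λ_c(ω)` with

    λ_c(ω) = o_c(y₀) + (v₀ − e_c) Σᵢ (∂o_c/∂yᵢ) yᵢ∞′(v₀) / (1 + iωτᵢ(v₀)).

Each cylinder then carries a propagation constant `γ(ω) = √(r·y_m(ω))` and
characteristic impedance `z_c(ω) = √(r/y_m(ω))` (axial resistance per length
`r = r_a/(πR²)`, membrane admittance per length `y_m = 2πR(g_lin + iωc_m)`).
Koch's two-sweep recursion propagates sealed-end boundary conditions from
the leaves to the root and back, giving input and transfer impedances
`Z(ξ₁, ξ₂, ω)` that are continuous in space — locations are `(node, x̄)`
pairs with `x̄ ∈ [0,1]`, never snapped to a grid. Time-domain response
kernels follow from the cosine transform
`k(t) = (2/π)∫₀^∞ Re Z(iω) cos(ωt) dω`. Freezing the channels at their
steady state (*passifying*) yields a strictly passive, low-pass tree.

**Eigenmode expansions.** For passive trees the Green's function separates
as `Σ_k φ_k(ξ₁) φ_k(ξ₂) e^(−t/τ_k)`, with the decay constants `τ_k` found
as zeros of a transcendental characteristic function and the spatial modes
`φ_k` normalized under the capacitance-weighted inner product
(`∫ c φ_j φ_k dx + C_soma φ_j φ_k |_soma = δ_jk`).

**Model reduction.** The inverse of the resistance matrix `Z` evaluated at
the compartment sites yields the conductance parameters of the reduced
model directly: leak and coupling conductances minimize `‖Z G(θ) − I‖_F`
(linear least squares), channel conductances are fitted jointly over up to
sixteen holding potentials, capacitances match either the local membrane
time constant or the slowest eigenmode, concentration pools
(`d[ion]/dt = −γ i_ion − ([ion] − c_inf)/τ`) are rescaled by the ratio of
full to fitted carrying conductance, and leak reversals are placed so that
the reduced equilibrium equals the full one.

**Simulation.** A built-in second-order finite-difference simulator
(backward-Euler voltage step, exact exponential gating and pool updates,
current and AMPA/NMDA/GABA synaptic stimuli) integrates both the full
discretized models and the reductions, and serves as the numerical oracle
for every analytical engine.

## Worked example

```r
library(dendrocable)

tree <- make_ball_and_stick(L = 1000, R = 1, soma_R = 10)  # passive preset
gt   <- passify(tree, v0 = -70)

locs <- data.frame(node = c(1, 11, 22), x = c(0, 0.5, 1))  # soma, mid, tip
round(resistance_matrix_tree(gt, locs), 1)
#>       [,1]  [,2]  [,3]
#> [1,] 331.0 247.5 214.5
#> [2,] 247.5 296.4 256.9
#> [3,] 214.5 256.9 381.4

round(find_time_scales(gt, tau_min = 0.1), 3)
#> [1] 20.000  2.487  0.650  0.280  0.152

fit <- fit_model(tree, data.frame(node = c(1, 11), x = c(0, 0.5)))
round(fit$comp_tree$nodes[, c("g_c", "ca", "g_leak", "e_leak")], 5)
#>       g_c      ca  g_leak e_leak
#> 1 0.00000 0.02654 0.00133    -70
#> 2 0.00671 0.04531 0.00227    -70
```

The resistance matrix is in MΩ: 331 MΩ somatic input resistance, falling
off toward 214 MΩ soma-to-tip transfer. The time constants are in ms; the
slowest equals the membrane time constant (20 ms) because the membrane is
uniform. The fit returns a two-compartment model (conductances in µS,
capacitances in nF) whose simulated step responses match the full model at
both sites to within a few percent.

A command-line interface (`exec/dendrocable`) wraps the same functions:

```sh
dendrocable make-fixture ball-and-stick --out-dir model/
dendrocable impedance model/ --loc 1:0 --loc 22:1 --out z.json
dendrocable sov model/ --tau-min 0.1 --out sov.json
dendrocable reduce model/ --locs locs.json --out reduced.json
dendrocable simulate model/ --T 500 --out traces.csv
```

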