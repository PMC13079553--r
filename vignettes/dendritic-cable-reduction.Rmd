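---
title: "Semi-analytical cable theory and compartmental reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-analytical cable theory and compartmental reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocable)
```

This vignette describes the models and algorithms behind `dendrocable`:
what is being computed, which approximations are involved, how the
numerical pieces are built, and what the built-in synthetic models do and
do not probe.

## The model class

A neuron model is a tree of cylindrical sections (one per SWC node, radii
taken verbatim — cylinders, not truncated cones) with an iso-potential
spherical soma at the root (membrane area $4\pi R^2$; the SWC format gives
no principled contour for the soma, and a lumped sphere is what the
analytical algorithms require). Each node carries a membrane capacitance
$c_m$ (µF/cm²), axial resistivity $r_a$ (Ω·cm), leak $g_L, e_L$, channel
densities $\bar g_c$ (S/cm²), and optionally ion pools. Voltage obeys the
cable equation on every cylinder,
$$ c \,\partial_t v = \frac{1}{r}\,\partial_x^2 v - g_L (v - e_L)
   - \sum_c \bar g_c\, o_c(\mathbf y_c)\,(v - e_c), $$
with per-length quantities $r = r_a/(\pi R^2)$, $c = 2\pi R\, c_m$, sealed
ends at the tips, continuity and current conservation at branch points, and
a capacitive/conductive balance at the soma. Channel state variables
follow first-order kinetics $\dot y = \alpha(v)(1-y) - \beta(v) y$,
equivalently $\dot y = (y_\infty(v) - y)/\tau_y(v)$; both parameterizations
are accepted and are interchangeable ($y_\infty = \alpha/(\alpha+\beta)$,
$\tau_y = 1/(\alpha+\beta)$). A `q10` factor multiplies all rates; it
divides every $\tau_y$ and cancels in $y_\infty$. Gating expressions may
read pooled ion concentrations (e.g. an SK-type channel gated by
$[\mathrm{Ca}]$).

Locations are `(node, x̄)` pairs with $\bar x \in [0,1]$ continuous along
the cylinder; `(parent, 1)` and `(child, 0)` denote the same point and
canonicalize to the parent representation, with ties at branch points
resolved the same way. Distances are arc lengths from the soma center.

**Computational tree.** Reconstructions contain long unbranched runs of
identical nodes. `build_computational_tree()` merges maximal runs whose
radius and every physiological parameter agree within a relative tolerance
(default `1e-8`: only numerically identical runs merge unless the user
loosens it) into single cylinders, with bidirectional coordinate maps so
the user always works in original coordinates. Any parameter mutation
discards the merged tree, since its validity cannot be guaranteed
afterwards. Total length and membrane area are conserved exactly.
Arbitrary resampling of a morphology is out of scope; the merge is the only
geometry-altering operation.

## Quasi-active linearization

Linearizing the channel current around an expansion point
$(v_0, \mathbf y_0, \mathbf{conc}_0)$ gives a frequency-dependent
admittance density $\bar g_c \lambda_c(\omega)$ with
$$ \lambda_c(\omega) = o_c(\mathbf y_0) + (v_0 - e_c) \sum_i
   \frac{(\partial o_c/\partial y_i)\, y_{i\infty}'(v_0)}
        {1 + i\omega\tau_i(v_0)}. $$
Derivatives are taken symbolically (base R's `D()` on the channel
expressions). At $\omega = 0$, $\lambda$ equals the DC slope conductance
per unit $\bar g$; for $\omega \to \infty$ the gating terms vanish and
$\lambda \to o_c(\mathbf y_0)$ — the *passified* membrane, which freezes
channels into the leak and is always low-pass. Quasi-active membranes can
be band-pass (a hyperpolarization-activated current with a slow time
constant produces a resonance; the package asserts this on a constructed
example). The expansion point defaults to the model's equilibrium, solved
by damped Newton iteration on a fine finite-difference grid.

**Concentration coupling.** The pool model is
$d[\mathrm{ion}]/dt = -\gamma\, i_{\mathrm{ion}} - ([\mathrm{ion}] -
c_\infty)/\tau$, the minimal exponential-decay pool consistent with
adaptation phenomenology; $\gamma$ has units mM·µm²/(nA·ms) (per current
*density*). With `with_conc = TRUE` the linearization chains through the
pool: a concentration-gated state variable acquires the extra admittance
term
$(v_0-e_c)\,(\partial o/\partial y)\,(\partial y_\infty/\partial c)\,
(-\gamma\tau_c)\,(\partial i_{\mathrm{ion}}/\partial v)$ filtered by
$1/(1+i\omega\tau_y)$, $1/(1+i\omega\tau_c)$ and the carrying channels' own
Lorentzians. The exact form of this coupling is a design choice of this
package; its binding contract is behavioural and is checked in the tests:
the linearization *without* the pool predicts the overshoot of a small
step response, the one *with* the pool predicts the post-adaptation
steady-state amplitude, and the DC resistances differ accordingly.

## Impedances and kernels

Koch's recursion works on admittances. Sweep 1 (leaves → root) accumulates
the distal load of every cylinder, sealed at the tips; sweep 2 (root →
leaves) accumulates the proximal load, including the soma's lumped
admittance $Y_s(\omega) = A_s (g_{lin}(\omega) + i\omega c_m)$ and sibling
subtrees. A location splits its cylinder into two exact sub-cylinders, so
evaluation is continuous in space. Transfer impedances multiply the input
impedance by per-segment voltage attenuations
$1/(\cosh\gamma\Delta + z_c Y_{far}\sinh\gamma\Delta)$ along the unique
path. Reciprocity ($Z_{12} = Z_{21}$) and Hermitian symmetry in $\omega$
hold to rounding and are asserted as properties. Hyperbolic functions are
evaluated through `tanh` with saturation for large real parts, so long
electrotonic distances cannot overflow.

**Inverse transform.** Kernels are computed as
$k(t) = (2/\pi)\int_0^\infty \mathrm{Re}\,Z(i\omega)\cos(\omega t)\,
d\omega$ by trapezoidal quadrature on a hybrid grid: a linear section near
zero whose spacing adapts to the largest requested time
($\Delta\omega = 0.05/t_{max}$), plus a log-spaced tail up to
$3\times10^3$ rad/ms. For each $t$ the quadrature stops where the grid
ceases to resolve $\cos(\omega t)$ and closes with a two-term
integration-by-parts tail. Against a single-compartment RC closed form the
error is $\sim10^{-6}$ of the peak; the integral of the kernel reproduces
the DC resistance to well under 0.5%. For quasi-active trees a stability
check rejects expansion points with $\mathrm{Re}\,Z < 0$ anywhere on the
grid, since the inversion assumes a stable linearization.

## Separation of variables

For a passified tree the eigenvalue condition is propagated from the
sealed tips to the root. The characteristic quantity is kept as a
numerator/denominator pair $(N, D)$ with $Y = N/D$, updated per cylinder
via entire functions of $s$ ($\cosh\gamma L$ and $L\,\mathrm{sinhc}\,
\gamma L$ forms, which are regular even where $y_m(s) = 0$, i.e. at the
membrane time constant). The root function
$W(1/\tau) = Y_s D + N$ is therefore pole-free: every sign change is a
genuine eigenvalue. The search grid is uniform in $\sqrt{1/\tau}$ with at
least 50 points per expected mode (mode count estimated from the
accumulated electrotonic phase), bisection refines to $10^{-10}$ relative.

Two clustering hazards are handled explicitly. Nearly degenerate pairs
(electrotonically similar subtrees) can share one grid cell without a net
sign change; local minima of $|W|$ are recursively refined. Exactly
degenerate eigenvalues from perfect geometric symmetry (e.g. a
3/2-power-rule tree whose equivalent-cylinder mode vanishes at a
bifurcation, so a confined antisymmetric partner coexists) make $W$ touch
zero without crossing; a minimum that keeps shrinking relative to its
local scale at every refinement level is reported as a multiplicity-2
root. Spatial profiles are marched from the root as (value, axial current)
pairs through transfer matrices — current continuity along unbranched
chains avoids divisions, so interior mode zeros cost no precision — and
normalized by closed-form exponential integrals under the capacitance
inner product. Profiles of symmetry-confined modes (vanishing root
amplitude) cannot be anchored at the root; they are flagged with a
warning, and the finite-difference generalized eigenproblem
$G\phi = (1/\tau) C\phi$ is the authoritative oracle in the tests. The
default expansion stops at $\tau < 0.1$ ms or 100 modes.

## Reduction pipeline

Given $n$ user locations, `fit_model()`:

1. **extends** the location list with every bifurcation of the minimal
   spanning subtree joining at least two covered subtrees, and the soma;
   the first $n$ entries always equal the user's, in order, and each
   compartment stores the index of its location;
2. solves the full model's **equilibrium**;
3. fits **leak and couplings** by minimizing $\|Z G(\theta) - I\|_F$ over
   the passified resistance matrix — linear in $\theta$, closed form, and
   exactly invertible when the "full" model is itself a compartment model
   (the identity-recovery property, held to $10^{-8}$ and better in the
   tests). The objective is $\|ZG - I\|$ rather than $\|G - Z^{-1}\|$
   because it is linear in the parameters and better conditioned.
   Compartment adjacency is the nearest-neighbour tree induced by the
   locations on the morphology. Negative fitted conductances are allowed
   (with a warning) because clamping would destroy identity recovery; a
   `nonneg` flag switches to an active-set nonnegative fit;
4. fits each **channel** separately: for each holding potential (default
   $-90\ldots0$ mV in 15 mV steps plus the equilibrium, hard-capped at 16
   points) the full model is linearized with the bare leak plus that
   single channel, and the reduced counterpart is
   $G_h = G_{leak} + \mathrm{diag}(\bar g_i \lambda_c(0; v_h))$; all
   holdings enter one linear least-squares problem. Whether other
   channels should be frozen or absent during these fits is not decidable
   from first principles; the "bare leak + single channel" convention is
   chosen because it preserves identity recovery exactly. The final
   compartment leak is the passified-fit membrane conductance minus the
   frozen channel contribution;
5. fits **capacitances**: `local_tau` sets $ca_i = \tau_m(\xi_i)\,
   g_{mem,i}$; `eigenmode` additionally rescales all $ca_i$ by one common
   factor so the slowest reduced eigenvalue equals the full model's
   $\tau_0$ (a single global degree of freedom — the constraint fixes one
   number, and the local time constants are the natural initialization);
6. fits **concentration pools**: $\tau$ and $c_\infty$ are copied from the
   full model at each site, and the current-to-concentration factor is
   rescaled by the ratio of the full model's local carrying conductance to
   the fitted one, which makes the reduced concentration response match
   the full model's local response — exactly so for iso-potential models,
   which is the binding contract (the tests also hold a branched model to
   5% at subthreshold steady state);
7. places **leak reversals** from the compartment steady-state balance,
   iterated to self-consistency with the reduced pool's own equilibrium
   concentration, so the reduced equilibrium reproduces the full one (to
   $10^{-6}$ mV and better).

`plot_kernels()` compares passified full-model kernels (Fourier route)
with the reduction's (eigen decomposition of the reduced system) for all
$N(N+1)/2$ pairs and reports per-pair peak-relative deviations. For a
two-compartment reduction of a 1000 µm cable the somatic input kernel
agrees to within 10% of its peak after the first millisecond; the transfer
kernel misses the axial delay at early times (deviations up to ~30% of
peak below a few ms) — an inherent limit of two compartments, not of the
fit, and the reason the regression bound in the tests is 0.35.

## The finite-difference simulator

`discretize_fd()` places compartments at cylinder-interior grid centers
(spacing ≤ `dx_max` or a fraction of the local length constant), couples
adjacent centers by $g = \pi R^2/(r_a \Delta x)$ with series half-steps
across radius changes, lumps the soma, and inserts explicit zero-area
junction compartments at branch points so that all half-steps meet in a
single potential — without them the scheme loses its second order exactly
at bifurcations. Membrane area is conserved by construction. The observed
convergence order of the impedance matrix toward the analytical engine is
2 on every built-in morphology (the oracle interpolates between centers,
along the smooth diagonal for input resistances, because the off-diagonal
Green's function has a derivative kink at the source).

Integration is implicit: a backward-Euler voltage step (direct solve of
the tree-structured system) with staggered gating — state variables and
pool concentrations advance by exact exponential integration at frozen
voltage resp. frozen current. The scheme is unconditionally stable for
stiff channel models, first-order accurate in `dt` (verified by
self-convergence), with `dt = 0.025` ms as default. Synapses are
conductance-based double exponentials normalized so a unit spike reaches
peak `gmax` ($N = ((\tau_r/\tau_d)^{\tau_r/(\tau_d-\tau_r)} -
(\tau_r/\tau_d)^{\tau_d/(\tau_d-\tau_r)})^{-1}$); NMDA receptors carry the
standard sigmoidal magnesium block $1/(1 + 0.3\,[\mathrm{Mg}]\,
e^{-0.1 v})$ with $[\mathrm{Mg}] = 1$ mM, evaluated at the previous
voltage step (operator splitting, like the Ca-dependent gating). Poisson
input trains are generated reproducibly from a seed. Spike detection is an
upward threshold crossing with a 1 ms lockout.

## Synthetic models and what they probe

All validation inputs are generated in code:

* **sealed cable** (1000 µm, 1 µm radius, point root): every closed-form
  oracle — $z_c\coth\gamma L$, $z_c/\sinh\gamma L$, cosine modes,
  $\tau_k = \tau_m/(1+(k\pi\lambda/L)^2)$;
* **ball-and-stick** (10 µm soma, 21-node stick): the generic
  soma-plus-cable case for kernels, eigenmodes and reductions;
* **Y-tree** and **3/2-power-rule tree**: branch-point handling, Rall's
  equivalent cylinder (root impedance equal to 1 part in $10^{6}$ and
  better), and degenerate eigenmodes;
* **soma+AIS**: a 10 µm soma with a 50 µm axon initial segment carrying
  generic sigmoid-kinetics Na/K spiking channels, two Ca channels, a Ca
  pool and an SK-type Ca-gated K channel. The pool parameters
  ($\gamma = 10$ mM·µm²/(nA·ms), an effective ~0.5 µm submembrane shell;
  $\tau = 80$ ms; $c_\infty = 10^{-4}$ mM) were chosen once so that the
  model shows the canonical adaptation phenotype: without concentration
  dynamics ($[\mathrm{Ca}]$ clamped via $\gamma = 0$) a 0.3 nA step drives
  tonic firing; with the pool, Ca influx opens SK and firing stops after
  the onset response. The resting potentials of the two variants differ by
  a fraction of a millivolt, as the adaptation current is nearly silent at
  rest.

The passive preset is $R_m = 20$ kΩ·cm², $c_m = 1$ µF/cm², $r_a = 100$
Ω·cm, $e_L = -70$ mV, giving $\tau_m = 20$ ms and $\lambda = 1$ mm at 1 µm
radius — standard cortical-pyramidal order-of-magnitude values.

These fixtures are deliberately small and regular. They do not exercise
tapering diameters, reconstruction noise, thousands of sections, spines,
or realistic channel gradients; passing tests demonstrate the correctness
of the algorithms on the model class, not the fidelity of any particular
biological parameterization. Problem sizes in the test-suite were chosen
to keep every oracle comparison (finite differences at 1 µm, eigen
decompositions of ~10³-compartment systems, 600 ms simulations at 25 µs)
comfortably within an interactive workflow.

## Numerical choices and known limitations

* Units: the public interface uses NEURON-conventional units; internally
  everything is MΩ, µS, nF, nA, mV, ms, µm, mM, a system in which
  $µS\cdot mV = nA$ and no further constants appear.
* The printed form of the two-rate gating ODE is implemented with the
  conventional minus sign on the closing term, so that
  $y_\infty = \alpha/(\alpha+\beta)$.
* Sub-threshold, small-signal accuracy of the quasi-active engine is
  limited by the linearization itself, not the numerics: large-signal
  behaviour (spikes) is validated through the simulator only.
* Spatial profiles of symmetry-confined eigenmodes are approximated (see
  above); their time constants are exact.
* Waveform-level agreement of spike shapes between full and reduced
  models is not a goal; spike counts and timing are compared instead.
* The grading of location weights in `distribute_locations_random()` is
  by membrane area per unit length ($2\pi R$), i.e. uniform per area.
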