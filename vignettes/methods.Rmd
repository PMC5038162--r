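---
title: "Methods: a coupled reduced left ventricle and 1D systemic-artery model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coupled reduced left ventricle and 1D systemic-artery model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lvsa)
```

`lvsa` simulates ventricular-arterial coupling at desk scale: a
one-dimensional model of the 24 large systemic arteries with structured-tree
vascular beds, coupled during systole to a reduced-order contracting left
ventricle. This vignette describes the model, its assumptions, the numerical
choices, and what the synthetic test conditions do and do not establish about
real data.

## The arterial network

Each large artery is a tapered elastic tube carrying cross-sectional-area-
averaged flow. Mass and momentum conservation give

$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right) +
\frac{A}{\rho}\,\partial_x P = -\frac{2\pi\nu R}{\delta^*}\frac{Q}{A},$$

closed by the tube law
$P = P_0 + \tfrac{4}{3}\tfrac{Eh}{r_0}\left(1 - \sqrt{A_0/A}\right)$ with
$A_0 = \pi r_0^2$ the area at transmural pressure $P_0$ and the wall
stiffness varying with the unstressed radius as
$Eh/r_0 = k_1 e^{k_2 r_0} + k_3$
($k_1 = 2\times10^7$, $k_2 = -22.53$, $k_3 = 8.65\times10^5$ in CGS). The
wave speed implied by this law is $c^2 = (A/\rho)\,\partial P/\partial A =
\tfrac{2}{3\rho}(Eh/r_0)\sqrt{A_0/A}$ — the relation is sometimes printed
without the square root over the whole right-hand side, but only the square
root form is dimensionally a speed, so that is what `wave_speed()`
implements.

The friction term uses a boundary-layer width
$\delta^* = \sqrt{\nu\,t_{\mathrm{period}}/2\pi}$ (the oscillatory
boundary-layer estimate, about 0.8 mm at a 0.9 s period), configurable in
`tube_law_params()`.

The default network (`default_network()`) has 24 segments — the aorta with
its arch and abdominal sections, head and arm vessels, the coeliac group and
the leg vessels — with lengths, radii and bed root radii assembled from the
standard structured-tree systemic-artery literature; it is a synthetic
transcription, not a measured dataset. Within a segment the unstressed
radius tapers exponentially, $r_0(x) = r_{\mathrm{top}}
(r_{\mathrm{bottom}}/r_{\mathrm{top}})^{x/L}$, which keeps $Eh/r_0$ smooth.
A strict binary tree cannot have an even number of segments (full binary
trees have odd node counts), so the 24-segment network contains exactly one
series connection in the abdominal aorta; the solver treats a single-daughter
junction as pressure and flow continuity.

## Structured-tree vascular beds

Each terminal artery feeds an asymmetric structured tree: a parent of radius
$r$ bifurcates into daughters $\alpha r$ and $\beta r$, where
$\alpha = (1+\gamma^{-\xi/2})^{-1/\xi}$ and $\beta = \alpha/\sqrt{\gamma}$
follow from the radius exponent $\xi$ ($r_p^\xi = r_{d1}^\xi + r_{d2}^\xi$,
baseline $\xi = 2.76$) and the squared daughter-radius ratio $\gamma$.
$\gamma$ is stored internally as $(r_{d1}/r_{d2})^2 \ge 1$; configurations
may supply the literature's asymmetry ratio 0.41, which is normalised by
reciprocal. Bifurcation continues while $r \ge r_{\min} = 100\,\mu$m;
vessel lengths are $50\,r$. Lowering $\xi$ to 2.4 models rarefaction: every
bed loses vessels and gains resistance. When counting that reduction,
$\gamma$ is held fixed and only $\xi$ varies.

The bed's root impedance is computed per frequency from the linearised
(Womersley) oscillatory solution: each vessel is a lossy transmission line
with complex wave speed $c = \sqrt{A_0(1-F_{10})/(\rho C)}$, where
$F_{10}(w) = 2J_1(i^{3/2}w)/(i^{3/2}w\,J_0(i^{3/2}w))$ is the Womersley
friction function (evaluated with a Lentz continued fraction for the Bessel
ratio, stable at all Womersley numbers) and $C = 3A_0r_0/2Eh$ the linearised
tube-law compliance. Impedances combine leaf-to-root by the transmission-line
input-impedance formula with daughters in parallel; at zero frequency this
reduces exactly to the series/parallel Poiseuille resistance
$8\mu l/\pi r^4$, which the tests use as an independent oracle. Subtrees
with equal radii share impedance through memoisation on the
$(\alpha^i\beta^j)$ lattice — exact, because radii repeat exactly there.
The impulse response $z(t)$ is the inverse DFT of the Hermitian-extended
spectrum (the Nyquist bin forced real) and closes each terminal with the
periodic convolution $P - P_0 = \sum_k z(k\,\Delta t)\,Q(t-k\,\Delta t)\Delta t$.

**Closure below 100 um.** The trees resolve arteries down to $r_{\min}$
only; the arterioles and capillaries beyond them carry most of the total
peripheral resistance. Terminating the leaves with zero impedance would
leave the network's DC resistance at about 0.34 mmHg s/mL — an order of
magnitude below the physiological total — and push the operating point to
unphysiologically low transmural pressures. The package therefore attaches
a uniform constant impedance to every leaf, solved once (in
`default_config()`) so that the network's total DC resistance matches the
anchor *mean arterial pressure = 100 mmHg at the baseline cardiac output of
72.6 mL per 0.9 s beat*, with the external pressure $P_0 = 0$. The anchor
is a standard physiological value chosen a priori, not a fitted quantity.

## The reduced left ventricle

The ventricle is a thick-walled incompressible spherical shell.
Incompressibility maps each reference radius $R \in [R_i, R_o]$ to
$r = (r_i^3 + R^3 - R_i^3)^{1/3}$, and the cavity pressure is the
equilibrium integral
$P = \int_{r_i}^{r_o} 2\,(\sigma_{\theta\theta} - \sigma_{rr})\,\frac{dr}{r}.$

The passive stress difference comes from the Holzapfel-Ogden strain-energy
function evaluated for the equibiaxial shell state
($\lambda_\theta = \lambda_\phi = \lambda$, $\lambda_r = \lambda^{-2}$,
$I_1 = 2\lambda^2 + \lambda^{-4}$) with the fibre and sheet families
uniformly distributed in the tangent plane ($I_{4f} = I_{4s} = \lambda^2$,
tension-only). In this kinematics the fibre-sheet shear invariant vanishes,
so the $a_{fs}$ term carries no stress; it is retained in `ho_params()` so
that the stiffer-myocardium scenario scales the complete a-type set. The
passive stress is linear in the a-type constants, which makes the
end-diastolic calibration exact in one step.

The active stress is $T_0\,T(t)\,\max(0,\,1+\beta_L(\lambda-1))$ along the
in-plane fibres, where $T(t)$ is a normalised phenomenological twitch (the
product of rising and falling exponential saturations, peak scaled to one,
cosine-tapered to zero at the twitch end). This replaces the full
myofilament ODE chain: the scenario analysis depends on the contractility
scale $T_0$ and the twitch timing, both of which the phenomenological form
exposes directly. $\beta_L$ supplies a linear length dependence (a
Frank-Starling surrogate) so that a smaller end-diastolic volume lowers the
active tension, which is what makes the stiff-myocardium scenario depress
both stroke volume and peak tension. Its default, $\beta_L = 4.9$, is the
length-dependent activation slope used in the myofilament model family
that cell-to-organ ventricular simulations commonly inherit, and which this
chamber reduces. The value matters structurally: in a thick spherical
shell the geometric factor $2\ln(r_o/r_i)$ grows as the cavity shrinks, and
a weak length dependence ($\beta_L \approx 3$) cancels it almost exactly,
leaving an unphysiological, nearly flat end-systolic pressure-volume
relation; $\beta_L = 4.9$ restores a positive end-systolic elastance in the
physiological range (about 1.7 mmHg/mL here). A consequence worth knowing:
the reduced chamber's ventricular-arterial coupling ratio
$E_A/E_S$ comes out near 1.0 rather than ~0.7, because the shell's
end-systolic stiffness remains on the low side of normal while the
effective arterial elastance is normal.

**Geometry.** The default unloaded shell (`chamber_geometry()`) has a
cavity of ~100 mL and a wall of ~140 mL. The unloaded cavity volume may
look large, but it is what keeps the end-diastolic fibre stretch near
1.1-1.15 — the strain range the Holzapfel-Ogden exponents are calibrated
for. A 40 mL unloaded cavity would demand shell stretches around 1.5, where
the exponentials are so stiff that the passive curve degenerates into a
step and myocardial-stiffness scenarios lose their volume effect.
Calibration, not the default geometry, carries the quantitative burden.

## Coupling and the cardiac cycle

One period (0.9 s for every scenario) runs through a valve state machine:

1. **Isovolumetric contraction** — volume fixed at the end-diastolic volume
   (the passive volume at the fixed 8 mmHg end-diastolic pressure);
   activation rises until cavity pressure reaches the aortic-root pressure.
2. **Ejection** — at every arterial time step the interface flow $Q$ is the
   root of $P_{\mathrm{LV}}(V - \!\int\!Q\,dt,\,t) =
   P_{\mathrm{SA}}(Q)$: ventricular pressure falls and arterial inlet
   pressure rises with $Q$, so the crossing is unique and is found by
   bracketed root-finding (a guaranteed-convergent replacement for a damped
   fixed-point sweep). There is no transvalvular pressure drop.
3. **Isovolumetric relaxation** — begins when the solved interface flow
   reaches zero (valve closure); the twitch decays at fixed volume.
4. **Filling** — a prescribed smooth (smoothstep) volume ramp back to the
   end-diastolic volume, ending exactly at the period; there is no mitral
   valve or atrium in scope, so filling is kinematic, and the arterial
   network runs with zero inflow whenever the valve is shut.

The ventricle is quasi-static (pressure is an algebraic function of volume
and time), so the exchange imposes no stability limit of its own and is
solved on the arterial grid ($\Delta t = 0.9/8192\ \mathrm{s}$) — i.e. at
sub-steps of the nominal ventricular step, consistent with using finer
ventricular steps in systole. `interpolate_exchange()` provides the linear
resampling between grids where series at other rates are needed.

Runs are initialised by warm-starting the network at its DC operating point
(uniform mean pressure, per-bed Poiseuille flows, primed convolution
histories) followed by four periods of a prescribed inflow pulse
(`make_inflow()`: a $\sin^p$ pulse with exact peak, duration and stroke
volume). The warm start matters because the DC filling time constant of the
closed network (~$R_{\mathrm{tot}}C_{\mathrm{tot}}$, of order a second)
would otherwise survive four periods of initialisation. Coupled cycles then
repeat until the maximum relative probe-pressure difference between
consecutive cycles falls below 1% (`run_until_periodic()`), which the
baseline reaches by the third cycle.

## Numerics

* **Scheme** — two-step (Richtmyer) Lax-Wendroff on each segment, in
  conservative form with the taper term treated as a source; the friction
  source uses the local radius. Grids are sized per segment so the Courant
  number stays below 0.9 at the unstressed state with a velocity margin; a
  runtime guard aborts on CFL violation with the offending segment.
* **Boundaries** — ghost-cell closures that advance each boundary cell by
  exact mass balance (interior predictor flux on one face, trapezoidal
  boundary flow on the other) and solve the remaining unknown flows by
  Newton iteration on pressure continuity (junctions), the impedance
  convolution (terminals) or directly (inlet). Junction flow conservation
  and total blood-volume conservation hold to round-off by construction;
  pressure-continuity residuals converge below $10^{-11}$ relative.
* **Quadrature** — the shell equilibrium integral uses 64-point
  Gauss-Legendre (cached per geometry); the active term integrates in
  closed form. 64 points put the quadrature error far below $10^{-6}$
  relative for these smooth integrands.
* **Calibration** (`calibrate_baseline()`) — passive scale solved exactly
  (linearity); then secant iterations on $T_0$ against stroke volume and on
  a twitch time-scale against ejection duration, alternated up to three
  times, each candidate evaluated on the second coupled cycle from the same
  pre-initialised arterial snapshot. Tolerance 2% on both targets.
* **Ties and degenerate inputs** — waveform peak times resolve to the
  earliest attaining sample; constant series report peak = trough; indices
  with a zero baseline report `NA` rather than propagating infinities;
  stroke work uses a start-point-invariant loop (shoelace) integral.

## Scenarios and indices

`apply_case()` reproduces the pathological scenarios as parameter
multipliers on the calibrated baseline: arterial stiffening ($k_3 \times 2$
in the large arteries only — the beds keep their own wall law), rarefaction
($\xi: 2.76 \to 2.4$, beds rebuilt; the lumped sub-100 um compartment of
each bed keeps its aggregate resistance, i.e. the per-leaf impedance is
rescaled by the leaf-count ratio, so rarefaction acts through the resolved
trees and raises the total resistance by roughly a quarter rather than
multiplying the unresolved compartment as well), myocardial stiffening (a-type
constants $\times 2$, which lowers the end-diastolic volume at the fixed
8 mmHg), increased contractility ($T_0 \times 1.33$), and isolated-arterial
variants driven by the prescribed baseline inflow. Indices follow the
clinical definitions: stroke work is the pressure-volume loop area
(reported in cJ, 1 mmHg mL = 1.33322$\times 10^{-4}$ J); the end-systolic
point is the state at aortic-valve closure (the standard operational choice
where the loop corner is not otherwise defined); the effective arterial
elastance is end-systolic pressure over stroke volume; the end-systolic
elastance is the least-squares slope through the end-systolic points of the
baseline and the two afterload scenarios, which leave contractility
untouched. Stroke work as implemented includes the filling limb of the
loop (the full enclosed area); with kinematic filling at low passive
pressures this differs negligibly from the systolic-limb convention.

## What the synthetic conditions show — and what they do not

All inputs are generated in code: the network table, the inflow pulse, and
the scenario multipliers. Passing tests therefore establish internal
consistency (conservation, convergence, inverse relations, directional
scenario responses) and agreement with the published headline values under
*this* reduced geometry and *this* literature-derived parameter stand-in.
They do not establish patient-specific accuracy: the artery table is not
from the same subject as the ventricle; the sub-100 um periphery is a
lumped resistive closure rather than a resolved bed; the spherical shell
has no regional wall motion, no pericardium, and a kinematic diastole.
Quantities dominated by wave shape and timing (peak-pressure amplification,
flow-peak delays) are the most sensitive to the missing appendix-level
geometry and should be read as scaled-down reproductions, not predictions.

## Known limitations

* Systole-only coupling: no mitral valve, atrium, or pulmonary loop;
  filling is prescribed.
* The tube law is purely elastic; no viscoelasticity, curvature, gravity,
  or vessel collapse.
* One heart rate (0.9 s) across all scenarios; no baroreflex.
* The structured-tree small vessels are rigid-walled in their DC resistance
  and linearised in their oscillatory response; no autoregulation.
* Problem sizes used throughout (8192 steps per period, ~1800 spatial
  nodes, 3 coupled cycles after 4 initialisation periods) reproduce the
  study conditions at desk scale; the unit-test suite runs the same physics
  on coarser grids (1024 steps) and small fixture networks.
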