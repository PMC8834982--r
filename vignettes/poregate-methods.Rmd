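---
title: "poregate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poregate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

## Scope

poregate reproduces, at desk scale, the computational chain used to study
voltage gating in a β-barrel channel such as VDAC1: ion permeation under an
applied transmembrane voltage, crossing-event counting, current and
conductance estimation with bulk-diffusion renormalization, conducting-regime
classification with bifurcation detection, conformational analytics of the
barrel and its N-terminal segment, and a dual-boost accelerated-MD
exploration scheduler with cluster restarts. All inputs are synthetic: a
Brownian-dynamics generator supplies ion trajectories with known ground
truth, and a toy barrel/tail generator supplies conformational ensembles.
This vignette records the models, the tunable parameters, and the design
choices made where the procedure was genuinely open.

## The Brownian pore model

`simulate_pore_bd()` propagates charged point ions by overdamped Langevin
dynamics,

$$\Delta x = \frac{D}{k_BT}\,F\,\Delta t + \sqrt{2D\,\Delta t}\,\xi,$$

in a periodic box holding an impermeable slab of thickness $L_p$ pierced by
a cylindrical pore of radius $r$. Units are Å, ns, mV, and elementary
charges; diffusion coefficients are given in cm²/s and converted internally
(1 cm²/s = 10⁷ Å²/ns). Default geometry: $r = 5$ Å, $L_p = 30$ Å in a
64 × 64 × 48 Å box, 1 M KCl (85–90 ions at this volume), 298 K, ±40 mV.

Three deliberate departures from a naive "uniform field over the box"
picture make the simulator agree with its closed-form oracle:

* **The voltage drops across the membrane.** In an all-atom simulation a
  constant applied field plus the dielectric response of the electrolyte
  concentrates the potential drop across the membrane. A BD model has no
  electrostatics, so that outcome is imposed directly: ions feel the axial
  force $qE$ with $E = V/L_p$ only inside the slab. With a positive voltage
  the force on a cation points toward $-z$ (cations traverse downward,
  anions upward). The helper `field_from_voltage()` documents the
  constant-field convention $E = V/L$ used to report field strengths.
* **Laterally stirred reservoirs.** Every step, ions outside the slab
  receive fresh uniform $(x, y)$ positions; their axial motion stays fully
  physical. This removes the diffusion-limited lateral convergence toward
  the pore mouth — an access resistance that the cylinder conductance
  formula excludes, and which the buffer regions of grid-based
  grand-canonical BD codes are designed to suppress. Axial resupply runs
  over the whole box cross-section and is never limiting. Stirring is
  confined to the baths, so event detection (which only needs axial
  positions and in-pore radial positions) is unaffected.
* **Geometric obstruction.** Partial occlusion of the lumen is modelled as
  a blocked angular sector of area fraction $f$ spanning
  `obstruction_zrange` (default: the whole slab). A rejection *probability*
  was considered and discarded: diffusing ions re-attempt a blocked entry
  many times per ns, so any per-attempt rejection probability short of 1
  barely reduces the steady-state flux and the open-area law would fail.
  With the sector geometry the open cross-section is exactly
  $(1-f)\pi r^2$. Collisions resolve by specular reflection — axial off the
  slab faces, radial off the pore wall, angular off the sector boundaries —
  and a move that cannot be reflected consistently is rejected.

The independent oracle is the Nernst–Einstein cylinder conductance
implemented in `analytic_pore_conductance()`:

$$\kappa = \frac{e^2}{k_BT} N_A \sum_i c_i z_i^2 D_i, \qquad
  G = \kappa\,\frac{\pi r^2 (1-f)}{L_p},$$

about 3.9 nS for the default pore. The simulated conductance converges to
this value from below; the residual deficit is a wall boundary layer of
thickness proportional to the step length $\sqrt{2D\Delta t}$, about 7% at
$\Delta t = 5$ ps and 4% at 2.5 ps for the open pore. The acceptance suite
runs 1500 ns at $\Delta t = 5$ ps (≈2800 events, under a minute) and checks
agreement within 15%; the area-law test uses $\Delta t = 2.5$ ps, where the
blocked-sector ratios match $1-f$ within 10%. The time step must satisfy
$\sqrt{2D\Delta t} < r/2$; the constructor enforces this.

`simulate_bulk_bd()` generates membrane-free free diffusion with exact
Gaussian frame-to-frame increments; `estimate_diffusion_msd()` recovers $D$
from the ensemble- and origin-averaged MSD ($\mathrm{MSD} = 6D\tau$, lags up
to a quarter of the duration by default) after minimum-image unwrapping.
Pure drift makes the MSD quadratic in lag; since a straight-line fit to a
parabola still yields $R^2 \approx 0.94$, the linearity flag uses the
threshold $R^2 \ge 0.99$ and the log–log slope (1 for diffusion, 2 for
drift) is reported alongside.

## Crossing events and currents

`detect_crossings()` implements the event definition — an ion crossing the
channel centre — with a hysteresis state machine so that jitter at the
mid-plane is never double-counted: commitment planes sit at
`origin_z ± gate_halfwidth` (default 10 Å) and an event fires only when the
committed side flips, i.e. the ion has traversed the whole gate. The
mid-plane passage must occur within `pore_radius + margin` of the axis
(default margin 2 Å); a passage outside that radius resets the state
without an event, as does a periodic wrap ($|\Delta z| > L_z/2$ between
frames). Ions in flight at the start or end of a trajectory contribute no
event. The test suite checks this machine against an independently written
per-frame reference on scripted paths with double-backs and wraps.

`cumulative_charge()` builds
$q_\mathrm{tot}(t) = (+1)\,n_{K^+}(t) + (-1)\,n_{Cl^-}(t)$ with
direction-aware signed counts; each unit-valence event moves
$q_\mathrm{tot}$ by exactly ±1 e. `estimate_current()` regresses
$q_\mathrm{tot}$ on time over the frame grid (the grid choice is exposed:
event times are carried on the series), converts the slope with
1 e/ns = 160.2176634 pA, multiplies by the renormalization factor
$D_\mathrm{exp}/D_\mathrm{sim}$ (`renormalization_factor()`; 0.586 for the
reference coefficients 1.918 and 3.273 × 10⁻⁵ cm²/s), and reports
$\sigma = |I|/|V|$ in nS. Rounding happens only at report time: two
decimals for conductances, one for current ratios. The current ratio
$I_{Cl^-}/I_{K^+}$ uses plain direction-insensitive event counts, which is
what makes 529/238 come out as 2.2.

## Conducting regimes

`regime_fit()` is the package's central model: a charge series is either
one line (one conducting regime) or two independent line segments split at
a bifurcation time (an abrupt low↔high switch). Continuity at the change
point is deliberately not enforced — the two regimes are fitted "one before
and one after" the bifurcation.

Two statistical points deserve a record:

* **Where the change point is sought.** `fit_changepoint()` offers two
  exhaustive-search objectives. For series whose grid values carry
  independent jitter, two OLS lines on the levels are optimal
  (`"levels"`). A raw counting series, however, is a random walk around its
  trend: its level residuals are long-range correlated and localize the
  change point poorly, while its *increments* are exchangeable — so the
  mean-shift split on increments (`"increments"`) is the maximum-likelihood
  estimator there. The default `"auto"` picks by the lag-1 autocorrelation
  of the detrended increments (≈0 for a random walk, ≈−1/2 for level
  jitter). On the calibration fixture (slopes 0.8 → 1.9 e/ns at 270 ns,
  500 ns, 0.1 ns grid, noise SD 0.5 e per grid point) the recovered change
  point is exact on noise-free data, unbiased (−0.03 ± 0.05 ns over 100
  seeds), and within ±5 ns in 20/20 seeds. Under *random-walk* noise of the
  same per-step magnitude no estimator can do that: the MLE error has an
  exponential tail with scale $4\sigma^2/\Delta\mu^2 \approx 4$ ns, putting
  roughly a third of the estimates outside ±5 ns. The fixture therefore
  uses level jitter (`noise = "level"` in `synthetic_charge_series()`),
  and the random-walk variant remains available as `noise = "step"`.
* **How the model is selected.** `select_model()` compares BIC values
  computed on the increment residuals (fitted means derive from the
  segment slopes), charging the two-segment model two extra parameters.
  BIC on levels is meaningless for an integrated series — autocorrelated
  residuals would make the two-segment model always win. With the
  increment BIC, zero-trend random walks select the single model in 20/20
  calibration seeds while the two-slope fixture selects two segments in
  20/20.

`classify_state()` applies the stability thresholds: a single-regime fit is
*stable-low* when $\sigma \le 2.3$ nS and $R^2 \ge 0.99$, *open-like* when
its conductance is within 15% of the open reference (the 15% band is this
package's operationalization of "conductance equaling that of the open
state"); a two-segment fit is *bistable* when one segment falls in the
closed-state band (40–60% of the open conductance) and the other within
15% of the reference; everything else is *unstable*. The rolling-slope
bimodality of a bistable series (two well-separated slope clusters, no
intermediate plateau) is verified in the test suite with a two-cluster
separation test on 50 ns windows. `screen_conformers()` keeps conformers
strictly below 2.5 nS and reports the threshold as a truncated integer
percentage of the open reference (67% of 3.7 nS).

## Conformational analytics

Superposition is closed-form Kabsch (SVD with determinant correction); the
fit and scoring selections are independent, hydrogens never enter (the toy
ensembles carry none and the selections are role-based). With no explicit
reference, frames are aligned to the first frame, the mean is computed and
all frames are re-aligned to it — one iteration of mean-realignment,
simpler than full iterative Procrustes and sufficient for jittered
ensembles.

*Ellipticity* of the barrel is defined here — the source workflow never
wrote the formula down — as $\sqrt{\lambda_1/\lambda_2}$ of the 2D
covariance of barrel Cα positions projected on the plane normal to the pore
axis. It is exactly 1 for a circular section, $a/b$ for an ellipse sampled
on a uniform angular grid, and is invariant under rotation about the axis,
translation, and uniform scaling. Fewer than three points, or colinear
points, are an error.

*Residue z statistics* report mean and **population** standard deviation
(divide by $n$) of Cα axial positions relative to the pore centre, matching
error bars computed over the frames of a trajectory.

*PCA landscapes* pool flattened selection coordinates across conditions
(default selection: the tail segment; configurable), keep per-condition
projections, and flag zero-variance inputs as degenerate. The overlap
between two conditions is $\sum_b \min(p_A, p_B)$ over a common 2D
histogram of (PC1, PC2) — 1 for identical clouds, 0 for disjoint ones, and
$2\Phi(-1) \approx 0.317$ for unit Gaussians 2σ apart, which the tests
check against the analytic value within binning error.

*Clustering* is average-linkage agglomerative on the pairwise RMSD matrix
of the selection after common superposition (`stats::hclust`/`cutree`), cut
to exactly the requested number of clusters; each cluster is represented by
its medoid, ties resolving to the lowest frame index, making the whole
procedure deterministic. *Average structures* are coordinate-wise means
with a per-atom RMSF sidecar, since means of disordered tails can be
unphysical.

*Apparent sequence charge* is plain Henderson–Hasselbalch with an explicit,
pluggable pKa table (standard textbook values by default, N-terminus 9.0,
C-terminus 3.6). No ionic-strength or structure-based correction is
applied, and published apparent charges computed with unstated corrections
are not treated as ground truth.

## Dual-boost aMD and the exploration scheduler

The boost below a threshold energy is
$\Delta V = (E - V)^2/(\alpha + E - V)$, zero at and above $E$, bounded by
$E - V$, monotone decreasing in $V$; the dual-boost bias adds one term on
the total energy and one on the dihedral energy. Threshold energies scale
with system size as $E_p = E_{p,0} + \gamma_p n_\mathrm{atoms}$ and
$E_d = E_{d,0} + \gamma_d n_\mathrm{res} + \gamma_d' n_\mathrm{lipids}$
with $\gamma_p = 0.16$, $\gamma_d = 3.5$, $\gamma_d' = 30.0$ kcal/mol per
unit. The smoothing parameters $\alpha$ are not fixed by the reference
parameterization; the package defaults to the standard dual-boost
convention $\alpha_p = \gamma_p n_\mathrm{atoms}$,
$\alpha_d = \gamma_d n_\mathrm{res}/5$ (floored at 1 kcal/mol for toy
systems) and exposes both.

`toy_propagate()` integrates overdamped Langevin dynamics on analytic 1D
landscapes with the boosted force
$-\nabla(V + \Delta V) = -[\nabla V \cdot f_p + \nabla V_d (f_d - 1)]$,
$f = (\alpha/(\alpha + E - V))^2$ — strictly positive, so minima of $V$
stay minima of the boosted surface. Each landscape designates one term as
"dihedral-like" (for the well landscapes, the whole potential). Unbiased,
the propagator thermalizes to equipartition within 1% on a harmonic well;
with the dihedral threshold at the barrier top of a 6 kT double well, the
boost multiplies the barrier-crossing count by >30.

`run_exploration()` reproduces the multi-walker protocol: all walkers run a
fixed segment; all conformers generated so far are pooled (optionally
strided) and clustered into as many clusters as walkers; the representative
of cluster k — the medoid, clusters ordered by size then lowest member
index, a pairing the reference protocol leaves unspecified — restarts
walker k. Bookkeeping is exact:
20 walkers × 5 ns × 20 rounds = 2 μs, and 2000 ns saved every 0.1 ns =
20,000 frames. Every segment and clustering seed derives deterministically
from the master seed, so logs reproduce bit for bit; a failed segment
aborts the round but preserves the partial log, and `final_states` allows
continuation. On an asymmetric triple well (deep outer wells, shallow
middle) the restart scheme covers all three wells in fewer rounds than the
same walkers running uninterrupted (median 14 vs 28 over 10 seeds in the
test configuration) — restarts resurrect transient frontier states that
unrestarted walkers abandon.

## What the synthetic data do and do not emulate

The generators reproduce the *statistical structure* the analyses assume:
Ohmic voltage response, open-area scaling, direction-aware crossing events,
a counting-series charge record, diffusive bulk MSD, elliptic barrel
sections, tail placements (vertical along the wall, horizontal across the
pore middle, detached below), and boost-accelerated barrier crossing. They
do not emulate ion–ion interactions, electrostatic profiles or selectivity
physics (the anion/cation ratio of the BD pore is ≈1, not 2.2, because both
species see the same geometry), atomic force fields, explicit lipids, or
grand-canonical particle exchange (fixed N with stirred reservoirs
instead). Conclusions from passing tests are therefore about the
*analysis chain*, not about channel physics: the paper-scale trajectory
results (per-conformer conductances, bifurcation times of specific
conformers, landscape shapes) require the original all-atom trajectories,
which are not public, and are covered instead by the property-based checks
above.

## Problem sizes and determinism

The test and acceptance runs use: 1500 ns of pore BD at a 5 ps step
(≈2800 events) for the oracle-equivalence check; 500 ns at 2.5 ps per point
for the area law; 100 ns × 600 particles of bulk BD for the MSD; 20-seed
batches for change-point and model-selection calibration; 10⁵-step toy
propagations for the aMD properties. Everything is seeded: identical
(spec, seed) pairs give bit-identical trajectories, ensembles, logs and
reports, with the RNG state of the caller left untouched.

## Known limitations

* The BD conductance converges to the cylinder formula from below with a
  $\sqrt{\Delta t}$ wall-layer bias; runs at the default 5 ps step read
  ≈5–10% low. Halve the step when absolute accuracy matters more than
  speed.
* The selectivity ratio of the synthetic pore is ≈1 by construction; Table
  1-style ratios above 2 are inputs to the arithmetic, not outputs of the
  BD model.
* `fit_changepoint()` finds at most one bifurcation; multi-state
  segmentation is out of scope.
* The apparent-charge calculation is uncorrected Henderson–Hasselbalch;
  with the default table the M1–G11 tail of mVDAC1 comes out near 0, not
  at published values computed with unstated (likely ionic-strength or
  structure-corrected) pKas.
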