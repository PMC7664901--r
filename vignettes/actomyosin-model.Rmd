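---
title: "A bottom-up mechanokinetic model of actomyosin ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bottom-up mechanokinetic model of actomyosin ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xbridge)
```

## The model

`xbridge` simulates ensembles of myosin II motor heads interacting with an
actin filament, built entirely from single-molecule properties. Each head is
an independent Markov process over a seven-state ATPase cycle — detached
states MT (myosin·ATP) and MDP (myosin·ADP·Pi), and attached states AMDP_PP
(pre-power-stroke), AMDP_PiR (Pi release), AMD_L (low force), AMD_H (high
force) and AM (rigor) — coupled to the other heads only through the rigid
actin filament they share.

The mechanical coordinate is the strain `x`, the axial distance (nm) between
a head's anchor on the thick-filament side and the actin binding site, with
`x = 0` where the rigor (AM) free energy is minimal and filament shortening
carrying attached heads toward decreasing `x`. Every attached state `i` has
a free energy

`G_i(x) = g_i + E(x − x_i) / kBT`,

the basal chemical level `g_i` (kBT units) plus the elastic energy of the
cross-bridge spring stretched from that state's minimum position `x_i`. The
minima descend as the cycle proceeds, `x1 > x11 > x2 > 0` (defaults 8.0,
7.5, 1.0 nm), so the strokes AMDP_PP→AMDP_PiR (0.5 nm), AMD_L→AMD_H
(6.5 nm) and AMD_H→AM (1 nm) move the filament when they fire. The basal
levels are constructed so that one complete cycle dissipates exactly
`dG_ATP = 25` kBT, the free energy of MgATP turnover; the constructor
enforces this and the equilibrium constants around the cycle multiply to
`exp(25)`.

### Elasticity

Linear mode uses `E(s) = ks s²/2` with `ks = 2.8` pN/nm. Nonlinear mode
implements the behaviour seen in single-molecule experiments on myosin II
(Kaya–Higuchi type): full stiffness when stretched, buckling under
compression. The force law is

`f(s) = ks s` for `s ≥ 0`, `f(s) = ks w (exp(s/w) − 1)` for `s < 0`,

continuously differentiable at `s = 0`, with a bounded compressive force
`ks·w` (default buckling length `w = 2` nm, plateau 5.6 pN) and a
closed-form energy. Setting `w = Inf` reproduces the linear law bit-for-bit,
which the test suite asserts.

### Strain-dependent rates under exact detailed balance

Rate functional forms are not uniquely determined by equilibrium
thermodynamics, so the package makes the construction explicit and
configurable. Every reversible transition is parameterized by its rate `k0`
at a reference strain and a *split* `δ` — the fraction of the strain
dependence carried by the forward rate:

`k₊(x) = c exp(δ ΔG(x))`, `k₋(x) = c exp((δ − 1) ΔG(x))`,

with `ΔG(x) = G_from(x) − G_to(x)` and `c` fixed by `k₊(x_ref) = k0`. The
ratio is `exp(ΔG(x))` at every strain for any `δ`, so detailed balance is
exact by construction. Power strokes use `δ = 1` (the forward rate carries
the full strain dependence; the reverse rate is constant). Attachment uses
`δ = 1/2`: the attachment rate is then a Gaussian of width
`sqrt(2 kBT/ks) ≈ 1.7` nm around `x1`, and detachment of a badly strained
weakly bound head *accelerates* with strain (slip-bond behaviour) rather
than staying constant. The split changes no equilibrium and no steady-state
occupancy ratio — only kinetics — and the even split was chosen because a
strain-independent detachment rate left far-from-optimum heads trapped in
the low-force state for many seconds, which is neither physical nor
compatible with force transients that complete on the 100 ms scale.

Two further factors multiply the attachment *pair* symmetrically (both
directions equally, so detailed balance and all equilibria are again
untouched):

- **finite head reach**: a Gaussian factor of s.d. `attach_reach = 2` nm
  about the attachment optimum, encoding the limited axial range over which
  a tethered head can reach a binding site. This is the structural feature
  behind the model's power/force-rise trade-off (below).
- **rate caps**: no rate exceeds `rate_cap = 1e6` s⁻¹. Reversible pairs are
  capped by scaling both directions by the same factor, so the cap slows
  extreme-strain kinetics without ever violating detailed balance.

One-way steps — ATP-induced detachment of rigor heads at mM MgATP
(3000 s⁻¹) and, on the reverse side, nothing synthesized for it — are
modelled as irreversible constants, as is conventional when the reverse
flux is negligible under physiological nucleotide concentrations.

### Default rate constants

The packaged defaults (`inst/extdata/default_params.yaml`) are
literature-scale values for fast skeletal actomyosin near room temperature:
hydrolysis 100 s⁻¹ (equilibrium ~e^1.5), attachment 200 s⁻¹ at its optimum,
the first sub-stroke and Pi release 1000 s⁻¹, the main power stroke
50 s⁻¹ at the AMD_L minimum (strongly accelerating as strain decreases),
ADP release 1500 s⁻¹ at the AMD_H minimum (strain-gated: slow when the head
bears positive force), ATP-induced detachment 3000 s⁻¹. With
`kBT = 4` pN·nm these give an isometric force of ~1.1 pN per head (~7 pN per
attached cross-bridge at ~16% attachment), an unloaded velocity of ~2 µm/s
per half sarcomere, and maximum power at ~0.35 V_max — all in the ranges
established for fast muscle and motility assays at ~20–25 °C. They are the
package's own parameterization, not a transcription of any single published
table, and every value is configurable through `crossbridge_model()` or a
YAML file.

## The synthetic ensemble

The ensemble generator emulates a half sarcomere by its in-vitro-motility
approximation: one long actin filament with myosin-binding target zones
every `d = 36` nm (1 or 3 sites per zone, intra-zone separation 5.5 nm, the
actin monomer rise) and surface-adsorbed heads whose offsets to the nearest
zone centre are uniform over the repeat. A 20 µm filament carries 556 zones;
at 5000 active heads/µm² over a 30 nm band it is reached by 3000 heads
(150/µm), comparable to the ~147 heads per thin filament of a sarcomere
lattice (10 half thick filaments × 294 heads / 20 thin filaments).

Head offsets are *signed*, on [−18, +18) nm in 360 bins of 0.1 nm (heads sit
on both sides of a zone centre physically); an unsigned mode on [0, 18) nm
with 180 bins is provided for sensitivity checks. `random_binned` placement
draws bins uniformly at random (reproducibly under a seed);
`uniform_grid` places one head per bin — the large-ensemble limit. With
three sites per zone a head may occupy at most one site (states are
expanded per site), which resolves intra-zone competition by mutual
exclusion and is also the default normalization of the steady-state solver.

What the generator does *not* emulate: 3D lattice geometry, filament
compliance, azimuthal head positions, two-headed myosin molecules,
thin-filament regulation, or inter-sarcomere dynamics. Passing tests
therefore validate the 1D axial mechanokinetics, not those features of real
muscle. The "18 motors" of the small-ensemble experiments are treated as 18
independent single heads.

## Steady-state solver

At sliding velocity `v` every head's strain advances at `−v`, so the
stationary state solves the transport balance `−v ∂p/∂x = Qᵀ(x) p` over the
36 nm repeat. The solver marches semi-Lagrangian over a 0.1 nm grid (the
same resolution as the head-offset bins) with per-bin exact matrix
exponential propagators (rates evaluated at bin centres, probabilities at
bin edges). Detached heads wrap periodically at the core boundary
(x = −18 nm); attached heads dragged past it continue on an extended domain
down to −36 nm, and probability detaching there is reinjected one period
up. The one-period map is iterated to a fixed point (tolerance 1e−11); the
leaked attached probability at the bottom of the extension is tracked and is
≲1e−7 at all velocities of interest. At `v = 0` the algebraic flux balance
is solved independently at each strain by a direct linear solve — not as a
small-velocity limit, which would be stiff.

Isometric force, FV curves and power follow by weighting the attached-state
occupancies with the force law: `F = n_heads ⟨Σ p_i(x) f_i(x)⟩`. `V_max` is
located by root finding on `F(v)`, maximum power by golden-section search on
`F·v`, and the Hill hyperbola `(F + a)(v + b) = (F0 + a) b` is fitted by
Levenberg–Marquardt least squares. Halving the grid changes F0 and maximum
power by well under 0.5% (asserted in the tests).

## Monte Carlo engine

The Gillespie algorithm is exact for piecewise-constant propensities:
waiting times are exponential in the summed propensity of every possible
transition of every head, and events are selected proportionally. The three
modes differ in how the filament closes the mechanics:

- **zero/constant load** — after every event the filament position
  re-equilibrates so the summed cross-bridge force equals the external load
  (quasi-static mechanics: inertia and drag neglected, so propensities are
  constant between events and the simulation is exact). The force balance is
  a monotone 1-D root problem solved to 1e−9 pN by safeguarded Newton
  iteration. Zero-attachment episodes hold the position and are flagged.
  The trace records every event.
- **isometric** — the filament is fixed, heads are independent, and the
  trace is sampled on a regular grid (default 0.5–1 ms).
- **velocity clamp** — strain decreases deterministically at `v`; rates are
  taken from per-bin tables on the *same* 0.1 nm grid as the steady-state
  solver (piecewise-constant per bin, exact sampling within bins), so
  stochastic-deterministic comparisons are not limited by inconsistent
  discretisations.

The engine core is compiled (Rcpp); reference R implementations of the
propensity construction, a single Gillespie step and the filament
rebalancing are exported and the test suite asserts their agreement with the
compiled path. All randomness flows through R's own RNG, so `set.seed()`
and the `seed` arguments make every trajectory bit-reproducible.

## Analyses

**Steps and clusters.** In a zero-load record of a small ensemble every
stroke moves the filament, and because that changes the strain — hence the
rates — of every other attached head, strokes trigger one another.
`detect_steps()` emits every event-to-event displacement of ≥0.5 nm
(signed); the threshold sits below the smallest genuine sub-step (~0.5–1 nm)
and above numerical null moves. `cluster_steps()` groups them greedily into
0.4 ms windows. With 18 heads the typical record shows clusters of 2–4 steps
of ~1–7 nm, the signature of mechanically coordinated (but kinetically
independent) motors. Occasionally a seed places no head within attachment
reach and the record stalls — a real feature of very small ensembles.

**Work per step.** `mechanical_work(step, load)` converts a step against a
load to pN·nm and kBT and flags work exceeding the 25 kBT available from one
ATP (e.g. 4 nm × 30 pN = 120 pN·nm ≈ 30 kBT): such steps must be collective,
not single-motor events.

**Force rise.** `fit_force_rise()` fits `F(t) = F∞ − A exp(−kt)` by
Levenberg–Marquardt, optionally restricted to the upper half of the rise
(the range over which a single-exponential description of force development
is most defensible). The sweep experiment starts all heads detached (MDP),
the engine's canonical initial condition: starting all heads *attached* in
AMDP_PP at their resting offsets places most of them at strains they could
never reach by attachment, and their relaxation produces a large
non-exponential overshoot with no well-defined rise rate. The fitted rate is
measured over the rising phase (0.2 s); on longer windows the quasi-plateau
creeps slowly (~1 s⁻¹) toward the true stationary state as far-from-optimum
strains equilibrate, and that creep is not the rate of force development.

**Spearman correlation.** `spearman()` uses mid-ranks and computes the
two-sided p-value by full permutation enumeration for n ≤ 10 (e.g. perfect
correlation of 5 points gives p = 2/120 ≈ 0.0167 exactly), falling back to
the large-sample approximation above that. The enumeration is asserted
against a brute-force oracle and against `stats::cor.test`.

## The x1 sweep

`run_x1_sweep()` varies the pre-power-stroke minimum `x1` with `x11` tied to
`x1 − 0.5` nm, computing for each value the deterministic maximum power and
the force-rise rate from 4 independent isometric Monte Carlo replicates of
3000 heads (mean ± SEM, SD/√n). Increasing `x1` lengthens the distance over
which an attached head does positive work, so maximum power increases
strictly (Spearman r = 1, exact p = 0.0167 for 5 points). At the same time
the attachment optimum moves away from the strains at which the main stroke
is thermodynamically permitted (the stroke threshold moves by only ~0.1 nm
per nm of `x1` because the elastic cost steepens in step), so with finite
attachment reach, force development slows: the pooled (x1, rate) Spearman
correlation is ≈ −0.7. The default grid is 7.5–9.5 nm: below ~7.5 nm the
attachment optimum already lies inside the stroke-permissive range and the
rise rate saturates, so the trade-off is expressed on the outward side of
the default `x1 = 8` nm.

## Problem sizes and tolerances

The packaged experiments use a 0.1 nm strain grid (360 core + 180 extension
bins), fixed-point tolerance 1e−11, force-balance tolerance 1e−9 pN,
velocity root/power search tolerances of ~0.2% of V_max, 3000-head
ensembles for half-sarcomere quantities (isometric Monte Carlo runs of
2.5 s when comparing to the stationary solution, 0.2 s for rise-rate fits),
18 heads × 50 ms for step records, and 4–6 replicates where means ± SEM are
reported. These sizes keep every analysis in this vignette and the full
test suite within a few minutes on a single core while leaving Monte
Carlo standard errors at the few-percent level.

## Known limitations

Heads are single and independent; there is no inter-site slippage, no
thick-filament mechanosensing, no compliance in either filament, no
eccentric (lengthening) branch, and no explicit ATP/ADP/Pi concentration
dependence beyond what the rate constants encode. The stationary state at
strains far outside attachment reach equilibrates slowly (seconds); the
solver computes it exactly, but finite Monte Carlo runs approach it only as
closely as their duration allows — the packaged comparisons use durations
chosen so the residual is well inside the Monte Carlo standard error.
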