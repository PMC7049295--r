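---
title: "Modeling emergent quorum-sensing activation in biohybrid microrobot swarms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling emergent quorum-sensing activation in biohybrid microrobot swarms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsswarm)
```

# The modeling problem

Bacteria-based biohybrid microrobots — *E. coli* propelling a cargo
microparticle (BacteriaBots: a 6 µm sphere carrying ~12 cells) or a single
cell decorated with nanoparticles (NanoBEADS) — can be engineered with
quorum-sensing (QS) gene circuits so that a swarm "activates" (switches a
bistable positive-feedback circuit to a high-expression state) only where it
is locally dense enough. Predicting *when* and *whether* activation happens
requires coupling three layers:

1. **Motility and chemotaxis** of the agents, which set the evolving spatial
   distribution;
2. **Intracellular circuit kinetics** — AHL signal synthesis with Hill-type
   positive feedback, and a GFP reporter that matures, dilutes with growth,
   and is degraded by a saturable protease;
3. **Extracellular signal transport** — diffusion and first-order
   degradation of the small AHL molecule over the simulation domain.

`qsswarm` implements all three layers and the scenario families built on
them: isotropic vs gradient activation-time curves, circuit-sensitivity
(RBS-strength x migration-bias) sweeps, and decentralized control of
spatially separated colonized patches.

# Data-driven motility: replaying tracked kinematics in sequence

Biohybrid motility is awkward to model mechanistically (flagellar forces on
a cargo particle), but easy to *measure*. The package therefore drives
simulated agents by replaying tracked (speed, turn-rate) sequences at the
experimental frame interval: each agent holds a cursor into one track,
rotates by the track's turn rate, translates at its speed, and draws a new
track uniformly when the current one is exhausted.

The essential design constraint, which we verify as a regression test, is
that the pairs must be replayed **in the order they were recorded**. Tracked
populations are heterogeneous: some agents are nearly ballistic for seconds
at a time, others reorient constantly. Persistence — net displacement over
path length,

$$P(t_N) = \frac{\sqrt{(x_N - x_0)^2 + (y_N - y_0)^2}}
               {\sum_{i} \sqrt{(x_i - x_{i-1})^2 + (y_i - y_{i-1})^2}},$$

is the diagnostic: in-sequence replay reproduces a source track's
persistence curve exactly (until the track is exhausted), while sampling the
same values in random order collapses everyone onto the population-average
wiggle and eliminates the persistent subpopulation. `simulate_sampler()`
keeps a `mode = "random"` switch purely to document this failure.

**Kinematics conventions.** For $N$ positions there are $N-1$ velocities but
only $N-2$ angle changes; we front-pad: `turn_rates[1] = 0` and
`turn_rates[i]` is the rotation leading *into* velocity $i$. Replay is
"rotate, then translate", which makes dead-reckoning reintegration exact (a
tested invariant) and lets a freshly drawn track continue smoothly from the
agent's current heading. Turn rates are signed, counter-clockwise positive,
wrapped to (-180°, 180°]. A repeated position records speed 0 and turn rate
0, with the heading carried to the next non-degenerate step.

**Chemotactic bias by group selection.** Chemotaxis of the biohybrids is
emulated without any extra force term: tracks are split into two groups, and
an agent drawing a replacement track samples from group one if it is
currently oriented up-gradient, group two otherwise. Random partitions of a
heterogeneous library differ in how persistence and speed distribute across
groups, so different partitions yield different steady-state rightward bias.
`calibrate_bias()` repeats \{random partition -> simulate -> compare CPC
curve\} and keeps the best partition (unweighted SSE at the target times —
the simplest defensible error metric); `migration_bias_ladder()` ranks
partitions by steady-state CPC (an 85-min run, averaging the final 20 min)
and maps them onto a migration-bias scale 0–1, with bias 0 the isotropic
sampler (CPC 0 by symmetry) and bias 1 corresponding to CPC 0.9.

The bias metric is the chemotaxis partition coefficient
$\mathrm{CPC} = (B_R - B_L)/(B_R + B_L)$ over the two domain halves; agents
exactly on the midline count as right-hand (deterministic, measure-zero
under continuous motion).

# The synthetic trajectory generator

The tracked data behind the original study (154 NanoBEADS tracks of ~6 s at
14 FPS; 26 BacteriaBot tracks of 50 s at 1.3 FPS) are not deposited, so the
package ships a generator that emulates their *statistics*, making every
downstream stage testable:

* per-step speeds: normal truncated at zero (speeds are magnitudes;
  truncation raises the realized mean ~1% for NanoBEADS and ~5% for
  BacteriaBots above the nominal 23.4 and 2.82 µm/s — within the tolerances
  we test);
* headings: a correlated random walk whose per-track angular-noise scale is
  drawn from a two-component mixture. The mixture is the package's chosen
  mechanism for persistence heterogeneity — the tracked data show persistent
  and diffusive subpopulations but no generative model; the component
  weights/scales are calibration knobs set so the pooled turn-rate SD
  matches the reported ~606 deg/s (NanoBEADS) and ~70 deg/s (BacteriaBots)
  while both subpopulations are present. Whether the enormous turn-rate SDs
  arise from heavy tails or mixtures is not decidable from summary
  statistics; we document the mixture as a choice, not an inference.
* an optional `drift_bias` knob tilts initial headings and adds a restoring
  heading drift toward +x, standing in for the net bias present in tracked
  gradient-assay data; 0 reproduces isotropic assays.

Tracks are integrated by dead reckoning, so `extract_kinematics()` recovers
the generated sequences exactly, and generation is deterministic given the
spec's seed.

What the generator does **not** emulate: frame-to-frame speed
autocorrelation, speed-turn coupling, agent-agent interactions during
tracking, and the two distinct NanoBEADS frame rates (14.1 / 12.4 FPS; each
generated track carries a single frame interval, 0.07 s). Tests passing on
synthetic libraries therefore validate the machinery, not the motility of
any particular real dataset.

# Run-and-tumble chemotaxis of free bacteria

Free-swimming engineered bacteria are the comparative baseline and use a
standard stochastic run-and-tumble model. Runs translate at 34 µm/s; tumble
durations are exponential (mean 0.14 s) and stationary; tumble angles have
log-normal magnitude and random sign. The mean run duration responds to the
perceived rate of change of receptor occupancy:

$$\tau_\pm = \tau_0 \exp\!\left(\pm\,\sigma_{\mathrm{chemo}} C_T
  \frac{K_d}{(K_d + s)^2}\left(\frac{\partial s}{\partial t}
  + \vec V_b \cdot \nabla s\right)\right),$$

with Michaelis–Menten occupancy $C(s) = C_T\, s/(K_d+s)$. Only the product
$\sigma_{\mathrm{chemo}} C_T = 35$ s is identified, so occupancy is carried
in units of $C_T$. A run time is drawn once, at assignment, from the local
field (it is not re-evaluated mid-run). The reference gradient is the
microfluidic assay's 1.7x10^-5 M/mm l-aspartic-acid gradient with the
mid-domain concentration at $K_d$ = 18 µM.

Numerical choices: the exponent is clamped to ±5 (numerical hygiene for
pathological synthetic fields — inactive in the model's own regime, where
the exponent is ~±0.28); phase switches resolve at the 0.07 s step
resolution; the tumble-angle log-normal is parameterized so its *arithmetic*
mean and SD are 68° and 36° (the source statement is ambiguous between
log-space and linear-space moments; we chose linear).

At these parameters 1000 simulated bacteria reach a steady CPC by roughly
4–5 minutes. In this implementation the steady value measures somewhat
below the published ~0.95; this is insensitive to the time step and to
y-boundary handling, and plausibly reflects implementation-variant details
of run-time assignment (fixed-at-assignment vs continuous modulation). The
acceptance suite states the published value with its published tolerance
and reports whatever the simulation produces.

# The quorum-sensing circuit and signal field

Each bacterial cell produces AHL at
$A_t = \eta\,(A_1 + A_2\, Q^H/(Q^H + Q_0^H))$ molecules/s, where $Q$ is the
extracellular AHL concentration in the agent's grid cell and $\eta \in
(0,1]$ is the RBS strength (relative translation-initiation rate) — the
circuit-sensitivity design knob. As printed, $\eta$ scales the whole rate
including the basal term; because a plausible alternative reading scales
only the upregulated term, `qs_params(eta_scales_basal = FALSE)` exposes
that variant (the default follows the printed form). Downstream, immature
GFP is translated at $k_{tr}\,Q^H/(Q^H+Q_0^H)$, matures at $k_{Gm}$, both
pools dilute with growth ($\mu = \ln 2/\tau_{dbl}$; 0 with growth off) and
are degraded by a shared saturable protease
($k_{deg}\,G/(G_i+G_m+K_m)$). GFP is tracked in molecules per cell — the
unit of the 218 molecules/bacterium activation threshold. Activation time is
the first (linearly interpolated) crossing of that threshold by the
population mean over all living cells, each BacteriaBot contributing its 12
attached cells individually.

The extracellular field obeys $\partial Q/\partial t =
\nabla\cdot(D\nabla Q) - R_d Q$ on a regular grid: explicit 5-point
stencil with substeps bounded by $0.9\,\Delta x^2/(4D)$, exact exponential
factor for the linear degradation ($R_d$ = 10.8%/h as a continuous rate),
zero-concentration x-boundaries 1000 µm beyond the motility domain, and
periodic y-boundaries (Dirichlet on all four edges for the closed
4x4 mm decentralized-control domain, where the source text states no
boundary condition). Cells deposit whole-interval production into their
containing grid cell; concentration conversion uses the cell volume
$\Delta x^2 \times$ 1 µm. The 1 µm slab depth is not free: the study's own
agent-count-to-concentration mapping (20 agents = 2x10^7 ml^-1 over
1000x1000 µm²; 48 agents = 0.3x10^7 ml^-1 over 4x4 mm²) implies exactly
this depth. AHL is produced directly into the extracellular cell (no
membrane-transport resistance), advection is omitted (the Péclet number for
this system is ~0.28), and the chemoattractant field is static and
unconsumed.

Solver invariants under test: mass conservation to 1e-6 with degradation
off; second moments growing exactly as $2Dt$ (the discrete stencil
propagates second moments exactly); linearity/superposition;
non-negativity; the closed-form uniform decay.

# Orchestration

The global clock is 0.07 s (the NanoBEADS frame rate); BacteriaBot
kinematics update every 11th step (0.77 s), free bacteria every step. The
circuit and field advance on a coupling cadence of 5 global steps (0.35 s —
far below the circuit's minutes-scale dynamics; the Euler circuit update is
stable up to several seconds), with the PDE substepped inside. Static
(colonized) scenarios may use a coarser global step since no motility
constrains it.

Collisions are inelastic: a move that would bring two sphere centers (radii
1 µm for bacteria/NanoBEADS, 3 µm for BacteriaBots) closer than the sum of
radii is rejected and the agent pauses, heading continuing to evolve; moves
that *increase* the distance of an already-overlapping pair are allowed so
initial overlaps cannot deadlock. Resolution order is randomized;
candidate pairs are refreshed every 10 steps within a displacement-bounded
cutoff, and a brute-force all-pairs check backs the test suite.

Growth uses per-agent timers: initial timers uniform on $(0, \tau_{dbl})$
(desynchronized divisions), reset to $\tau_{dbl}$ on division. Bacteria
double in 43 min; NanoBEADS and microparticle-attached bacteria in 121 min;
BacteriaBot daughters are free-swimming bacteria adopting the 43-min rate;
"half growth" doubles both times. Daughters inherit the mother cell's GFP
state (cytoplasm is partitioned at division; the continuous $\mu G$ dilution
term already accounts for the concentration effect of growth, so no
additional halving is applied). Where a BacteriaBot divides, the inherited
state comes from one uniformly chosen attached cell.

A run ends at the activation of every population, at a declared steady
non-activated state (population means below threshold with the rates of
change of mean GFP and mean perceived signal below 1e-6 of their running
maxima for 30 min — in practice this fires only in smooth, static
scenarios; motile runs carry sampling noise and simply run to horizon), or
at the horizon.

# Scenario design choices

* **Equivalent concentrations** always equate total bacteria: a NanoBEADS
  concentration is compared with BacteriaBots at 1/12th the agent count.
  With the 1 µm slab, 4.8x10^7 ml^-1 over the 1000x1000 µm² domain is 48
  cells (48 bacteria, 48 NanoBEADS, or 4 BacteriaBots).
* **Two-population (decentralized control)**: two 100x100 µm patches on the
  x-axis of a 4x4 mm closed domain, separation 2.7 mm (1.3 and 1.7 mm are
  the documented alternatives), AHL diffusivity reduced to 75% of its
  in-water value (extracellular-matrix estimate), agents static. Staticness
  is a deliberate departure from free motility: the scenario's premise is a
  dose *colonizing* two sites, and motile agents at ~23 µm/s would disperse
  a 100 µm patch within minutes. `static = FALSE` restores motility.
* **Grid resolution**: 10 µm default; the packaged scenarios use 20–25 µm
  (a coarse mode for tractable sweeps) and the two-population runs 50 µm
  with 25 µm where the patch self-field is near threshold. The critical
  minority fraction is resolution-sensitive: a 100-µm patch must span
  multiple cells for its local upregulated self-production to be resolved;
  under-resolving it biases the critical fraction upward. Problem sizes in
  the tests and the acceptance script (replicate counts of 3–5, 20–25 µm
  grids, horizons of 8–12 h) were chosen as the smallest sizes at which the
  contrasts of interest are stable across seeds.
* **Cold start**: all scenarios begin with zero field and zero GFP.

# Known limitations

* Motility statistics come from the synthetic generator unless real track
  tables are supplied; conclusions about specific experimental swarms
  require their tracks.
* The implemented model reproduces the reference results qualitatively
  (activation ordering BacteriaBots < NanoBEADS ≈ bacteria without growth;
  growth-rate-driven separation with growth; density-gated decentralized
  activation) but is somewhat more sensitive in absolute activation
  density, which compresses some published percentage contrasts; the
  acceptance suite reports the measured values against the published ones
  without adjustment.
* 2D planar motility only; no advection; deterministic per-cell ODEs (no
  intrinsic expression noise); collisions are pause-based, not
  force-resolved.
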