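# qsswarm

Agent-based simulation of emergent quorum-sensing (QS) activation in
bacteria-based biohybrid microrobot swarms.

## The problem

Biohybrid microrobots — *E. coli* carrying engineered gene circuits,
assembled either as **BacteriaBots** (a 6 µm microparticle propelled by ~12
attached cells) or **NanoBEADS** (a single cell decorated with
nanoparticles) — can be programmed to "activate" (switch a bistable QS
circuit to a high-expression state) only where the swarm is locally dense
enough. Whether and when that happens depends jointly on motility and
chemotaxis (where the agents are), the QS circuit's kinetics (how fast
signal and reporter build up), and extracellular transport (how fast the
signal diffuses away and degrades). `qsswarm` couples all three so that
circuit designers can predict activation times, explore the
circuit-sensitivity design space, and test density-gated decentralized
control schemes before committing to wet-lab iterations.

The model has three parts:

* **Data-driven motility.** Simulated biohybrids replay tracked
  (speed, turn-rate) pairs *in the order they were recorded* at the
  experimental frame rate (0.07 s NanoBEADS, 0.77 s BacteriaBots), drawing a
  fresh track whenever one is exhausted. Chemotactic bias is produced by
  splitting the track library into two groups and sampling the group that
  matches the agent's up/down-gradient orientation; an iterative calibration
  (`calibrate_bias()`, `migration_bias_ladder()`) selects group partitions
  that reproduce a target chemotaxis partition coefficient
  CPC = (B_R − B_L)/(B_R + B_L). Because the original tracks are not
  deposited, a statistics-matched synthetic generator
  (`generate_library(preset_track_spec(...))`) stands in for them.
* **Run-and-tumble chemotaxis** for free-swimming bacteria (the comparative
  baseline): exponential runs with mean
  `tau = tau0 * exp(sigma_chemo*CT * Kd/(Kd+s)^2 * (ds/dt + V·grad s))`,
  stationary tumbles, log-normal tumble angles.
* **QS circuit + signal field.** Each cell produces AHL at
  `eta*(A1 + A2*Q^H/(Q^H+Q0^H))` molecules/s into its grid cell; immature
  GFP is translated under the same Hill term, matures, dilutes with growth
  and is degraded by a saturable protease; the extracellular field obeys
  `dQ/dt = div(D grad Q) − Rd*Q` (explicit stencil, periodic y, absorbing
  x-boundaries 1 mm beyond the 1000×1000 µm motility domain). Activation =
  population-mean mature GFP crossing 218 molecules/bacterium.

## Worked example

Forty-eight engineered bacteria (4.8×10⁷ ml⁻¹ equivalent) in a chemically
isotropic 1000×1000 µm² domain, no growth:

```r
library(qsswarm)

cfg <- scenario_config("isotropic", n_agents = c(bacteria = 48L),
                       duration = 6 * 3600, dx = 20, seed = 5)
res <- run_scenario(cfg)
res
#> <scenario_result: isotropic, activated after 94.2 min>
#>   population all: activated at 94.0 min
summary(res)
#> Scenario 'isotropic' (off growth): 191 records over 94.2 min, status activated
#>   final mean GFP: all=220.1 molecules/cell
#>   final mean perceived signal: all=11.9 nM
#>   final CPC: 0.042
```

The swarm sits below the circuit's upregulation threshold for over an hour
(perceived AHL creeping from 0 to ~1 nM against the 1.87 nM half-point),
then the positive feedback runs away and mean GFP crosses the 218
molecules/cell detection threshold at ~94 min. The same interface drives the
comparisons that matter for design: at the same total-bacteria
concentration, 4 BacteriaBots (12 cells each sharing one grid cell)
activate in ~51 min — the locally concentrated cells bootstrap the feedback
— while 48 dispersed NanoBEADS behave like free bacteria (~94 min).

Two-population decentralized control (a dose colonizing two sites 2.7 mm
apart):

```r
cfg2 <- scenario_config("two_population", n_agents = c(nanobeads = 48L),
                        split = c(44L, 4L), separation = 2700,
                        domain = c(4000, 4000), dx = 50, dt = 2,
                        couple_every = 1L, duration = 8 * 3600, seed = 8)
res2 <- run_scenario(cfg2)
res2$activation / 60  # minutes; NA = stable non-activated state
```

The densely colonized site activates within ~30 min; whether the sparse
site follows depends on its share of the dose — the density gate that makes
QS useful as a decentralized controller.

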