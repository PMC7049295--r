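# Default model parameters (chemotaxis + quorum-sensing circuit).
# Units are given per entry; these are the packaged defaults used by
# chemotaxis_params() and qs_params().
chemotaxis:
  tau0: 0.86          # s, mean run duration without a gradient
  tauT: 0.14          # s, mean tumble duration
  sigma_chemo_CT: 35  # s, chemotactic sensitivity x receptor count (fitted product)
  Kd: 18              # uM, receptor dissociation constant (l-aspartic acid)
  speed: 34.0         # um/s, free-swimming speed
  theta_mu: 68        # deg, mean |tumble angle|
  theta_sigma: 36     # deg, SD of |tumble angle|
quorum_sensing:
  A1: 3.19            # molecules/s, basal AHL synthesis rate per cell
  A2: 234             # molecules/s, upregulated AHL synthesis rate per cell
  H: 2.5              # Hill coefficient
  Q0: 1.87            # nM, AHL upregulation threshold
  ktr: 0.40           # molecules/s, max immature-GFP translation rate
  kGm: 3.02e-3        # 1/s, GFP maturation rate
  kdeg: 5.54          # molecules/s, max protease-mediated GFP degradation
  Km: 6650            # molecules/cell, half-max GFP level for degradation
  Dsignal: 490        # um^2/s, AHL diffusion coefficient in water
  Rd_per_h: 0.108     # 1/h, first-order AHL degradation rate
  gfp_threshold: 218  # molecules/bacterium, detection threshold for activation
  depth: 1            # um, slab thickness for count <-> concentration mapping
growth:
  tau_dbl_bacteria: 2580    # s (43 min), free-swimming doubling time
  tau_dbl_biohybrid: 7260   # s (121 min), NanoBEADS / attached-bacteria doubling
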