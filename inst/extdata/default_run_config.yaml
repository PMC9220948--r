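# Default run configuration: all three analysis stages at the package's
# default study conditions. Units are explicit in every key name.
bilayer:
  sigma_pN: 1        # line tension (overridden per row by the sweep)
  A_L_A2: 55         # area per lipid
  h_nm: 3.5          # dipole-plane separation between leaflets
  eps: 8             # bilayer dielectric constant near the dipoles
  delta_V_mV: 140    # ordered/disordered dipole-potential difference
  d_min_nm: 1.0      # dipole distance of closest approach
  A_tot_um2: 20      # total raft-covered area
sweep:
  sigma_min_pN: 0.1
  sigma_max_pN: 3
  n_sigma: 20
infer:
  sigma_true_pN: 1
  n_obs: 25
  noise_sd_log: 0.1
  n_boot: 200
  conf: 0.95
affinity:
  n_obs: 24
  kd_min_M: 1.0e-9
  kd_max_M: 1.0e-5
  slope_tcr: -20
  slope_stat5: 20
  noise_sd: 5
seed: 1
output_dir: results
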