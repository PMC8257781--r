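UNREGULATED:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.03
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
IFF:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.03
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
NF_IDEAL:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.0
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
NF_LEAKY:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.03
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
EQUALIZER:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.03
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
EQUALIZER_SPLIT:
  k_tx: 3.0
  k_tl: 4.0
  d_m: 0.5
  d_p: 0.03
  K_op: 150.0
  n_op: 4.0
  leak: 0.03
  K_dox: 1.5
  h_dox: 2.0
  R_tot: 350.0
  k_load: 1.0
  d_mi: 0.1
  k_on: 0.55
  k_off: 0.3
  k_cat: 30.0
  n_ts: 2.0
  stoich_tetr: 1.0
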