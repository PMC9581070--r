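# IL-33 feasibility case (asthma; SoA = lung).
# The alarmin IL-33 is synthesized at the SoA and distributes to plasma,
# where it is degraded and where the soluble decoy receptor sST2 (plasma-
# confined, as is its complex) competes with the drug for free IL-33.
# Baselines from reported tissue/serum levels converted at 18 kDa (IL-33)
# and 37 kDa (sST2): lung 11 pM, plasma 1.5 pM, sST2 27 pM.
name: il33
bodyweight_kg: 70
pk:
  VP_L: 3.2
  V2_L: 2.2
  Cl_L_per_day: 0.454
  Q_L_per_day: 0.252
  ka_per_day: 0.26
  F_fraction: 0.6
  mw_drug_kDa: 150
soa:
  VS_L: 0.3
  ratio: 0.3
target:
  TP0_nM: 0.0015
  TS0_nM: 0.011
  kdegTp_per_day: 4.2
  kdegTs_per_day: 0
  frac: 1
  Qtarget_L_per_day: 0.416
  mw_target_kDa: 18
binding:
  KD_nM: 0.01
  kon_per_nM_per_day: 86.4
  valence: bivalent
competitor:
  S0_nM: 0.027
  kon_per_nM_per_day: 358
  KD_nM: 0.026
  kdeg_S_per_day: 2.6
  kdeg_SC_per_day: 2.6
  mw_kDa: 37
regimens:
  - name: sc100_q4w
    route: sc
    dose_mg: 100
    interval_days: 28
    n_doses: 13
kd_grid_nM: [0.1, 0.01]
assumptions:
  - "lung interstitial volume VS = 0.3 L (shared lung-tissue assumption)"
  - "SoA:plasma drug ratio 0.30 (standard tissue assumption)"
  - "drug molecular weight assumed 150 kDa; SC ka = 0.26/day, F = 60%"
  - "competitor:target complex degraded at the competitor rate (2.6/day)"
notes:
  - "low expression and slow turnover make high neutralization feasible at ~10 pM affinity"
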