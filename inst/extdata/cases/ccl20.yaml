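# CCL20 affinity-requirement case (SoA = skin).
# Skin-homing chemokine assumed synthesized in skin only and eliminated in
# plasma only. Plasma baseline 30 pM (measured), skin tenfold higher;
# target half-life 15 min; plasma:skin drug concentration ratio 20%
# (measured); interstitial skin volume 1.125 L. The clinical antibody's
# affinity was 350 pM.
name: ccl20
bodyweight_kg: 70
pk:
  VP_L: 3.63
  V2_L: 3.19
  Cl_L_per_day: 0.475
  Q_L_per_day: 0.374
  ka_per_day: 0.26
  F_fraction: 0.6
  mw_drug_kDa: 150
soa:
  VS_L: 1.125
  ratio: 0.2
target:
  TP0_nM: 0.03
  TS0_nM: 0.3
  thalf_plasma_min: 15
  kdegTs_per_day: 0
  frac: 1
  Qtarget_L_per_day: 0.416
binding:
  KD_nM: 0.35
  kon_per_nM_per_day: 86.4
  valence: bivalent
regimens:
  - name: iv20mpk_single
    route: iv
    dose_mg_per_kg: 20
    n_doses: 1
    interval_days: 28
  - name: sc300_q2w
    route: sc
    dose_mg: 300
    interval_days: 14
    n_doses: 26
kd_grid_nM: [0.35, 0.035, 0.0035]
assumptions:
  - "SC absorption ka = 0.26/day and F = 60% are generic IgG assumptions (not reported for this antibody)"
  - "drug molecular weight assumed 150 kDa"
  - "target distributive clearance Qtarget = 0.416 L/day (exploratory default)"
  - "two-arm (bivalent) binding with per-site affinity"
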