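# IL-13 dose-projection case (asthma; SoA = lung).
# Retrospective projection for a clinical anti-IL-13 antibody. The
# antibody's population-PK constants are an EXTERNAL input (published
# separately, not shipped here): fixture_il13() requires a pk_parameters()
# block. Plasma IL-13 baselines 0.06 pM (healthy volunteers) / 0.12 pM
# (asthmatic), lung 0.03 pM / 0.4 pM; target half-life ~20 min; drug
# affinity 1 nM.
name: il13
bodyweight_kg: 70
pk: external
soa:
  VS_L: 0.3
  ratio: 0.3
target_healthy:
  TP0_nM: 6.0e-5
  TS0_nM: 3.0e-5
  thalf_plasma_min: 20
  thalf_soa_min: 20
  frac: 0.5
  Qtarget_L_per_day: 0.416
target_asthmatic:
  TP0_nM: 1.2e-4
  TS0_nM: 4.0e-4
  thalf_plasma_min: 20
  thalf_soa_min: 20
  frac: 0.5
  Qtarget_L_per_day: 0.416
binding:
  KD_nM: 1
  kon_per_nM_per_day: 86.4
  valence: bivalent
regimens:
  - name: sc2mpk_q1w_x2
    route: sc
    dose_mg_per_kg: 2
    interval_days: 7
    n_doses: 2
  - name: sc30mpk_q1w_x8
    route: sc
    dose_mg_per_kg: 30
    interval_days: 7
    n_doses: 8
kd_grid_nM: [1]
assumptions:
  - "clinical-antibody PK is an external input; none is shipped"
  - "synthesis split between plasma and lung unknown; frac = 0.5 with the same 20-min turnover in both compartments"
  - "lung interstitial volume VS = 0.3 L; SoA:plasma drug ratio 0.30"
  - "average bodyweight 70 kg for mg/kg dosing"
notes:
  - "reports total plasma target (free + drug-bound) alongside coverage to show complex-driven accumulation"
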