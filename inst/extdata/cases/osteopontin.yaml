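# Osteopontin feasibility case (rheumatoid arthritis).
# Abundant secreted plasma protein: serum baseline ~10 nM, half-life ~10 min
# (stable-isotope pulse-chase estimate). Plasma levels alone determine
# feasibility, so the site-of-action compartment is decoupled (ratio 0) and
# the target is plasma-only.
name: osteopontin
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
  ratio: 0
target:
  TP0_nM: 10
  TS0_nM: 0
  thalf_plasma_min: 10
  kdegTs_per_day: 0
  frac: 0
  Qtarget_L_per_day: 0
binding:
  KD_nM: 1
  kon_per_nM_per_day: 86.4
  valence: bivalent
regimens:
  - name: sc300_q1w
    route: sc
    dose_mg: 300
    interval_days: 7
    n_doses: 12
  - name: iv1000_q1w
    route: iv
    dose_mg: 1000
    interval_days: 7
    n_doses: 12
kd_grid_nM: [1, 0.1, 0.01]
assumptions:
  - "drug molecular weight assumed 150 kDa (whole IgG)"
  - "SC absorption ka = 0.26/day and F = 60% are generic IgG assumptions"
  - "two-arm (bivalent) binding with per-site affinity"
notes:
  - "high baseline and very fast turnover keep attainable coverage low at any affinity"
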