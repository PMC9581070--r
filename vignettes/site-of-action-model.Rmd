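---
title: "The site-of-action model: structure, parametrization and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The site-of-action model: structure, parametrization and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soamod)
```

## Why a site-of-action compartment

Classical two-compartment PK describes what an antibody does in plasma, but
antagonist antibodies against soluble ligands act wherever the disease
lives — skin, lung, joint. `soamod` extends the two-compartment model with a
third, disease-relevant compartment: the interstitial space of the target
tissue, the *site of action* (SoA). Free drug ($D_P$) distributes to a
non-specific peripheral compartment ($D_T$, volume $V_T$) and to the SoA
($D_S$, volume $V_S$); in plasma and at the SoA it binds its soluble target
($T_P$, $T_S$) reversibly to form complexes ($C_P$, $C_S$) which distribute
between plasma and the SoA and are eliminated in plasma only. The target is
synthesized (zero order, $k_{synP}$, $k_{synS}$), degraded (first order,
$k_{degTp}$, $k_{degTs}$) and exchanged between plasma and the SoA
($k_{psT}$, $k_{spT}$). The question the model answers is always some form
of: *given the drug's PK, its affinity, the dose, and what we measured about
the target (baselines and turnover), how much of the free target is
neutralized at the site of action, and for how long?*

The deliberate position of this model is between empirical PKPD and full
systems models: about ten ODEs, every parameter either measured, derived
from measurements by a steady-state argument, or a declared assumption. It
is a feasibility and requirements tool for early discovery — *right target,
right compound, right dose* — not a disease model.

## State, units, equations

Canonical units are nM, L, day, nmol; every species is a concentration in
its own compartment except the subcutaneous depot, which is an amount
(nmol). Inter-compartment fluxes carry volume ratios explicitly (e.g. the
SoA-to-plasma drug flux enters plasma as $k_{sp} D_S V_S/V_P$), so amounts
are conserved by construction. The monovalent (1:1) scheme uses mass-action
binding $k_{on} D\,T - k_{off} C$ with $k_{off} = k_{on} K_D$. With no
measured on-rate, `kon_default()` returns the generic antibody value
$10^6\,\mathrm{M^{-1}s^{-1}} = 86.4$ /nM/day; affinity engineering is then a
change in $k_{off}$ at fixed $k_{on}$, which is exactly how
`required_affinity()` varies $K_D$.

### Two-arm (bivalent) binding

An IgG has two Fab arms, and for a small soluble ligand both can be loaded.
The two-arm variant models step-wise binding with statistical factors: a
free antibody associates at $2k_{on}$ (two available arms), the single
complex associates again at $k_{on}$ and dissociates at $k_{off}$, and the
double complex dissociates at $2k_{off}$ (two occupied arms). The
double-complex conversion terms are the mass-conserving mirror images of the
single-complex ones, so binding fluxes cancel pairwise: closed systems
conserve drug ($D+C+C_2$) and target ($T+C+2C_2$) exactly, and the
equilibrium satisfies detailed balance
($C/(DT) = 2k_{on}/k_{off}$, $C_2/(CT) = k_{on}/(2k_{off})$), both verified
in the test suite against closed-form algebra.

Valence is a first-class switch (`binding_spec(..., valence =)`), and
**bivalent is the default**. This is a substantive choice, not a cosmetic
one: with one-arm binding each delivered antibody can at most remove one
target molecule, and for a fast-turnover tissue target the drug flux into
the tissue can then be the hard ceiling on coverage. Two arms double the
capture capacity per delivered antibody. The shipped case studies only
reproduce their published projections under two-arm binding; under the
one-arm scheme the skin-chemokine case caps below 90% coverage at *any*
affinity, which would contradict the published affinity requirement. The
one-arm model remains available and fully tested, and the two-arm model
reduces to it exactly when the second-arm association is switched off (a
property test).

### Competitor (decoy) ligand

Some targets are buffered by an endogenous soluble receptor (e.g. a shed
decoy) that competes with the drug for the free ligand. The competitor
scheme adds plasma-confined species $S$ (free competitor) and $SC$
(competitor:target complex): the drug now has to outcompete the decoy in
plasma. The scheme is defined for a target synthesized at the SoA only
(`frac = 1`) and degraded in plasma only (`kdegTs = 0`) — the configuration
of the lung-alarmin case — and other configurations are rejected rather
than silently mis-closed. Both valences combine with the competitor.

## Steady-state-preserving parametrization

Nothing in the rate set is free-floating: every derived rate comes from a
closure that preserves something measured.

**Drug distribution.** Adding the SoA must not distort the measured plasma
PK, and the average (equivalently AUC) total-drug concentration ratio
SoA:plasma must equal the measured or assumed `ratio` (default 0.30 for
non-brain, non-muscle tissue: a ~10% total-tissue:serum ratio corrected for
an interstitial fraction of ~1/3). Fixing the return rates
$k_{sp}=k_{tp}=Q/V_2$ gives

$$k_{ps} = \mathrm{ratio}\cdot k_{sp}\frac{V_S}{V_P},\qquad
  k_{pt} = \frac{Q}{V_P}-k_{ps},\qquad
  V_T = V_P\frac{k_{pt}}{k_{tp}} = V_2 - \mathrm{ratio}\cdot V_S.$$

so that $(k_{ps}+k_{pt})V_P = Q$ exactly: plasma kinetics are those of the
original two-compartment fit, which the tests verify against the analytic
biexponential solution to 0.1%. An over-large `ratio`·$V_S$ (relative to
$V_2$) makes $k_{pt}\le 0$ and is rejected with the offending inequality
named.

**Target turnover.** Given baselines ($T_{P0}$, $T_{S0}$), degradation
rates, the synthesis split `frac` (fraction of whole-body synthesis at the
SoA) and the fixed plasma-to-SoA rate $k_{psT}=Q_{target}/V_P$, the
synthesis rates and $k_{spT}$ are solved so the drug-free baseline is an
exact fixed point. Whole-body synthesis is $k_{synTot}=T_{P0}k_{degTp}V_P +
T_{S0}k_{degTs}V_S$ (nmol/day). The closure can demand a negative
$k_{spT}$ (e.g. fast SoA degradation with little SoA synthesis); this is an
error with advice (raise `frac`, lower $Q_{target}$, revisit baselines)
because silently clipping would break the fixed point. With a competitor the
closure changes: the plasma sink through complex degradation
($k_{deg,SC}\,SC_0$) must be resupplied, so
$k_{synS} = (k_{degTp}T_{P0}+k_{deg,SC}SC_0)V_P/V_S$ and
$SC_0 = k_{on,c}T_{P0}S_0/(k_{off,c}+k_{deg,SC})$, with competitor synthesis
$k_{syn,S} = k_{deg,S}S_0 + k_{deg,SC}SC_0$. The fixed-point property is
enforced as a test over 200 randomly generated scenarios (drift < 0.01%
over 50 drug-free days).

`Qtarget` defaults to 0.416 L/day, an exploratory-stage figure for soluble
protein distributive clearance into inflamed tissue; it is the least-known
quantity in the model and a standing candidate for `local_sensitivity()`.

## Dosing, solver, numerical choices

Doses are state discontinuities, not forcing functions: an IV bolus adds
$D_0/V_P$ to $D_P$; an SC dose adds $D_0 F$ to a first-order depot draining
at $k_a$, so the bolus is exact and the integrator restarts cleanly at each
event. Printed doses (mg or mg/kg with a bodyweight, default 70 kg) convert
at the drug's molecular weight (default 150 kDa for IgG). Turnover up to
~100/day against drug elimination ~0.1/day makes the system stiff;
integration uses `deSolve::lsoda` with rtol $10^{-8}$, atol $10^{-12}$ nM,
at which point halving the tolerances moves the reported coverage metrics by
well under 0.01 percentage points. The output grid samples 24 points/day
for two days after each dose (peaks), 4 points/day elsewhere, plus an
explicit pre-dose point before every dose (troughs). The solver reports the
pre-event state at an event time, so a dose at the grid start is folded into
the initial state instead (making $D_P(0)=D_0/V_P$ visible for an IV
bolus); later rows at dose times read as pre-dose values, which is what the
trough logic wants.

**Steady state** is declared when every monitored pre-dose trough changes by
less than 0.1% (relative) between successive doses, dosing capped at 52
weeks; hitting the cap sets a `converged = FALSE` flag with a warning rather
than failing, so sweeps can report partial results. Free-target species are
monitored by default; `monitor = "drug"` monitors total plasma drug instead,
which matters for PK-only diagnostics — with binding off, target troughs are
constant from the first dose while drug is still accumulating, and the
AUC-ratio check (AUC$_{SoA}$/AUC$_{plasma}$ = `ratio` ± 1%) must be taken at
*drug* steady state.

## Coverage analytics

Coverage (neutralization) is defined on **free** target,
$1 - T(t)/T_0$ — total target typically *rises* under treatment as
slowly-cleared complex accumulates, and the package reports
`total_target()` separately for exactly that reason. Summary statistics
(peak, trough, time above threshold) are computed over the converged
steady-state cycle when one is flagged; the trough — the pre-dose value, the
regimen's worst case — is the conservative statistic used for affinity
requirements. Coverage may transiently go below zero when a competitor
displaces target back into the free pool; such series are flagged, not
clipped.

`required_affinity()` bisects on $\log_{10} K_D$ over [1e-5, 1e3] nM for the
largest (weakest) $K_D$ whose steady-state statistic still meets the
threshold, to two significant figures — matching the precision at which
affinity requirements are quoted — after checking monotonicity at the
bracket ends; `"any"` and `"unachievable"` sentinels cover the trivial ends.
`coverage_sweep()` tabulates the same statistics along a $K_D$ or dose axis
with per-point failure capture, and `local_sensitivity()` reports
central-difference sensitivities $d\log(\mathrm{odds})/d\log p$ of trough
coverage (odds keep the measure informative near full coverage), recomputing
the closures for every perturbation so the steady-state constraints are
never violated mid-analysis.

## Case-study fixtures and their declared gaps

Four executable fixtures ship as YAML under `inst/extdata/cases/`, each
carrying an `assumptions` block that is surfaced on every run:

* **osteopontin** — abundant (10 nM) plasma protein with a 10-minute
  half-life; plasma-only degenerate configuration (SoA decoupled,
  `ratio = 0`). Its ~1000 nM/day synthesis flux dwarfs what any feasible
  regimen delivers, so coverage stays low and nearly affinity-independent —
  the "wrong target" archetype.
* **il33** — lung alarmin (11 pM lung, 1.5 pM plasma) with the soluble decoy
  sST2 (27 pM, $K_D$ 26 pM) competing in plasma; SoA-only synthesis,
  plasma-only degradation. Gap-filling: lung interstitial volume 0.3 L
  (shared lung assumption), ratio 0.30, generic SC absorption.
* **ccl20** — skin chemokine (30 pM plasma, 10× in skin, 15-min half-life),
  measured 20% plasma:skin ratio, 1.125 L skin interstitium. Gap-filling:
  the clinical antibody's SC `ka`/`F` are unreported, so the generic IgG
  values (0.26/day, 60%) are assumed — the affinity requirement inherits
  this uncertainty.
* **il13** — lung cytokine dose-projection case. The clinical antibody's
  population PK is published elsewhere and **not shipped**:
  `fixture_il13()` refuses to run without an externally supplied
  `pk_parameters()` block. The synthesis split between plasma and lung is
  unknown; the fixture assumes `frac = 0.5` with the same 20-minute
  turnover in both compartments. Conclusions from this fixture are
  therefore conditional on the supplied PK; the test suite exercises it
  with a clearly-labelled synthetic generic-IgG block.

## The random scenario generator

`random_scenario(seed)` draws log-uniform parameters inside declared
physiological ranges (volumes 2–5 L central / 1–5 L peripheral, clearances
0.1–1 L/day, baselines 1e-4–10 nM, half-lives 5 min–7 days, ratio 0.05–0.5,
$V_S$ 0.05–2 L, $K_D$ 1e-3–10 nM, `frac` uniform, valence randomized),
rejecting draws whose closure is infeasible. It emulates the *parameter
space* of mAb-vs-soluble-target programs, not real data: no measurement
noise, no inter-individual variability, no model misspecification. Passing
the property suite over this space shows the closures and conservation laws
hold wherever the model is defined — it does not validate the biology of
any particular program.

## Problem sizes and runtimes

The package's own test and acceptance workloads use: steady-state searches
capped at 52 weeks (13–52 doses depending on interval), 200 random
scenarios for the fixed-point property, a 26-point grid scan as the
bisection oracle, and bisection to 2 significant figures (~12 steady-state
simulations). These sizes keep any single analysis in the seconds-to-a-
minute range on one CPU while leaving the reported metrics
solver-converged.

## Known limitations

* Soluble targets only: no membrane targets, internalization, or
  target-mediated drug clearance beyond plasma complex elimination.
* The peripheral compartment carries free drug only (no target or complex
  there), and complexes are eliminated in plasma only.
* The `ratio`-based distribution assumes the new antibody distributes like
  previously measured ones; `kspT` from the closure can be
  non-physiologically fast when SoA baselines are small — sensitivity
  analysis is advised whenever target distribution matters.
* First-order SC absorption only; no infusions or delay compartments.
* The steady-state trough statistic is a convention; programs quoting
  average or sustained coverage will reach different affinity requirements
  (weaker, since trough is the worst case).
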