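#' @keywords internal
"_PACKAGE"

## Canonical internal units used throughout the package:
##   concentration nM, volume L, time day, amount nmol, molecular weight kDa.

stop_soa <- function(..., class = "soa_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (length(x) != 1L || !is.numeric(x)) {
    stop_soa(sprintf("'%s' must be a single numeric value", name),
             class = "soa_validation_error")
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    stop_soa(sprintf("'%s' must not be NA", name), class = "soa_validation_error")
  }
  bad_low <- if (strict_lower) x <= lower else x < lower
  if (bad_low || x > upper) {
    cmp <- if (strict_lower) ">" else ">="
    stop_soa(sprintf("'%s' = %g violates %s %g and <= %g", name, x, cmp, lower, upper),
             class = "soa_validation_error")
  }
  invisible(x)
}

#' Default antibody association rate constant
#'
#' Returns the generic antibody-antigen association rate of 1e6 M^-1 s^-1,
#' expressed in the model's canonical units (1/nM/day). It is used whenever a
#' measured on-rate is unavailable; affinity is then varied through the
#' off-rate, `koff = kon * KD`.
#'
#' @return Association rate constant in 1/nM/day (86.4).
#' @examples
#' kon_default() # 86.4
#' @export
kon_default <- function() {
  ## 1e6 / (M s) = 1e6 * 1e-9 / (nM s) * 86400 s/day
  1e6 * 1e-9 * 86400
}

#' Convert a half-life to a first-order rate constant
#'
#' @param t_half Half-life value.
#' @param unit Unit of `t_half`: `"day"`, `"hour"` or `"min"`.
#' @return First-order rate constant in 1/day.
#' @examples
#' kdeg_from_half_life(10, "min") # fast-turnover cytokine, ~99.8/day
#' @export
kdeg_from_half_life <- function(t_half, unit = c("day", "hour", "min")) {
  unit <- match.arg(unit)
  check_scalar(t_half, "t_half", lower = 0, strict_lower = TRUE)
  days <- switch(unit, day = t_half, hour = t_half / 24, min = t_half / 1440)
  log(2) / days
}

#' Antibody pharmacokinetic parameters
#'
#' Two-compartment mAb disposition constants plus first-order subcutaneous
#' absorption. `V2` is the peripheral volume estimated by the two-compartment
#' PK fit; the model's internal peripheral volume `VT` is derived from it so
#' that plasma PK is preserved when the site-of-action compartment is added.
#'
#' @param VP Central (plasma) volume of distribution (L).
#' @param V2 Peripheral volume from the two-compartment fit (L).
#' @param Cl Elimination clearance (L/day).
#' @param Q Distributive clearance (L/day).
#' @param ka First-order subcutaneous absorption rate (1/day); may be `NA`
#'   when only intravenous dosing is simulated.
#' @param F Subcutaneous bioavailability, a fraction in (0, 1].
#' @param mw_drug Drug molecular weight (kDa); 150 for a whole IgG.
#' @return An object of class `soa_pk`.
#' @examples
#' pk_parameters(VP = 3.2, V2 = 2.2, Cl = 0.454, Q = 0.252, ka = 0.26, F = 0.6)
#' @export
pk_parameters <- function(VP, V2, Cl, Q, ka = NA_real_, F = 1, mw_drug = 150) {
  check_scalar(VP, "VP", 0, strict_lower = TRUE)
  check_scalar(V2, "V2", 0, strict_lower = TRUE)
  check_scalar(Cl, "Cl", 0, strict_lower = TRUE)
  check_scalar(Q, "Q", 0, strict_lower = TRUE)
  check_scalar(ka, "ka", 0, strict_lower = TRUE, allow_na = TRUE)
  check_scalar(F, "F", 0, upper = 1, strict_lower = TRUE)
  check_scalar(mw_drug, "mw_drug", 0, strict_lower = TRUE)
  structure(list(VP = VP, V2 = V2, Cl = Cl, Q = Q, ka = as.numeric(ka),
                 F = F, mw_drug = mw_drug),
            class = "soa_pk")
}

#' Site-of-action geometry
#'
#' @param VS Interstitial volume of the site-of-action tissue (L).
#' @param ratio Steady-state SoA:plasma total-drug concentration ratio
#'   (dimensionless). The standard assumption for non-brain, non-muscle
#'   tissues is 0.30 (total-tissue:serum ratio of ~10% corrected for an
#'   interstitial fraction of ~1/3); a measured value should be used when
#'   available.
#' @return An object of class `soa_geometry`.
#' @export
soa_geometry <- function(VS, ratio = 0.30) {
  check_scalar(VS, "VS", 0, strict_lower = TRUE)
  check_scalar(ratio, "ratio", 0)
  structure(list(VS = VS, ratio = ratio), class = "soa_geometry")
}

#' Target baselines and turnover
#'
#' Baseline free-target concentrations and first-order degradation rates in
#' plasma and at the site of action, together with the synthesis split `frac`
#' (the fraction of whole-body target synthesis occurring at the SoA) and the
#' target distributive clearance `Qtarget`. Synthesis rates and the SoA-to-
#' plasma distribution rate are not inputs: they are derived so that the
#' drug-free baseline is an exact steady state (see [derive_target_rates()]).
#'
#' @param TP0 Baseline free target in plasma (nM).
#' @param TS0 Baseline free target at the SoA (nM); 0 for a plasma-only target.
#' @param kdegTp Plasma degradation rate (1/day).
#' @param kdegTs SoA degradation rate (1/day).
#' @param frac Fraction of total synthesis occurring at the SoA, in \[0, 1\].
#' @param Qtarget Target distributive clearance (L/day). The default 0.416
#'   corresponds to an exploratory-stage estimate of soluble-protein
#'   distributive clearance between plasma and inflamed tissue; set 0 for a
#'   plasma-only target.
#' @param mw_target Target molecular weight (kDa), used only for reporting and
#'   mass-to-molar conversions.
#' @return An object of class `soa_target`.
#' @export
target_spec <- function(TP0, TS0 = 0, kdegTp, kdegTs = 0, frac = 0,
                        Qtarget = 0.416, mw_target = NA_real_) {
  check_scalar(TP0, "TP0", 0)
  check_scalar(TS0, "TS0", 0)
  check_scalar(kdegTp, "kdegTp", 0)
  check_scalar(kdegTs, "kdegTs", 0)
  check_scalar(frac, "frac", 0, upper = 1)
  check_scalar(Qtarget, "Qtarget", 0)
  check_scalar(mw_target, "mw_target", 0, strict_lower = TRUE, allow_na = TRUE)
  structure(list(TP0 = TP0, TS0 = TS0, kdegTp = kdegTp, kdegTs = kdegTs,
                 frac = frac, Qtarget = Qtarget, mw_target = as.numeric(mw_target)),
            class = "soa_target")
}

#' Drug-target binding parameters
#'
#' @param KD Equilibrium dissociation constant (nM). For the two-arm model
#'   this is the per-site (microscopic) affinity.
#' @param kon Association rate constant (1/nM/day); defaults to
#'   [kon_default()]. The off-rate is derived as `koff = kon * KD`.
#' @param kelC Elimination rate of the drug:target complex in plasma (1/day);
#'   `NA` means "assume equal to the free-drug elimination rate `kel`", which
#'   is the standard soluble-target assumption.
#' @param valence `"bivalent"` for step-wise two-arm IgG binding (the default,
#'   since both Fab arms of an intact antibody can engage a small soluble
#'   ligand) or `"monovalent"` for single-step 1:1 binding.
#' @return An object of class `soa_binding` with derived `koff`.
#' @export
binding_spec <- function(KD, kon = kon_default(), kelC = NA_real_,
                         valence = c("bivalent", "monovalent")) {
  valence <- match.arg(valence)
  check_scalar(KD, "KD", 0)
  check_scalar(kon, "kon", 0)  # kon = 0 switches binding off (PK-only runs)
  check_scalar(kelC, "kelC", 0, allow_na = TRUE)
  structure(list(KD = KD, kon = kon, koff = kon * KD, kelC = as.numeric(kelC),
                 valence = valence),
            class = "soa_binding")
}

#' Endogenous competitor ligand in plasma
#'
#' Describes a soluble decoy/scavenger protein that competes with the drug
#' for free target in plasma (for example a shed receptor). The competitor
#' and its complex with the target are confined to plasma; the competitor's
#' synthesis rate and its baseline complex concentration are derived so that
#' the drug-free equilibrium is preserved (see [derive_rates()]).
#'
#' @param S0 Baseline free competitor concentration in plasma (nM).
#' @param kon Competitor-target association rate (1/nM/day).
#' @param KD Competitor-target dissociation constant (nM); `koff = kon * KD`.
#' @param kdeg_S First-order degradation of free competitor (1/day).
#' @param kdeg_SC First-order degradation of the competitor:target complex
#'   (1/day).
#' @param mw_competitor Competitor molecular weight (kDa), reporting only.
#' @return An object of class `soa_competitor` with derived `koff`.
#' @export
competitor_spec <- function(S0, kon, KD, kdeg_S, kdeg_SC,
                            mw_competitor = NA_real_) {
  check_scalar(S0, "S0", 0)
  check_scalar(kon, "kon", 0)
  check_scalar(KD, "KD", 0)
  check_scalar(kdeg_S, "kdeg_S", 0)
  check_scalar(kdeg_SC, "kdeg_SC", 0)
  check_scalar(mw_competitor, "mw_competitor", 0, strict_lower = TRUE, allow_na = TRUE)
  structure(list(S0 = S0, kon = kon, KD = KD, koff = kon * KD,
                 kdeg_S = kdeg_S, kdeg_SC = kdeg_SC,
                 mw_competitor = as.numeric(mw_competitor)),
            class = "soa_competitor")
}

#' Assemble a complete simulation scenario
#'
#' @param pk A [pk_parameters()] object.
#' @param soa A [soa_geometry()] object.
#' @param target A [target_spec()] object.
#' @param binding A [binding_spec()] object.
#' @param competitor Optional [competitor_spec()] object. Requires a target
#'   synthesized at the SoA only (`frac = 1`) and degraded in plasma only
#'   (`kdegTs = 0`); other configurations are rejected at rate derivation.
#' @param bodyweight Bodyweight (kg), used for mg/kg dosing.
#' @param name Scenario identifier carried into outputs.
#' @return An object of class `soa_scenario`.
#' @export
scenario <- function(pk, soa, target, binding, competitor = NULL,
                     bodyweight = 70, name = "scenario") {
  stopifnot(inherits(pk, "soa_pk"), inherits(soa, "soa_geometry"),
            inherits(target, "soa_target"), inherits(binding, "soa_binding"))
  if (!is.null(competitor)) stopifnot(inherits(competitor, "soa_competitor"))
  check_scalar(bodyweight, "bodyweight", 0, strict_lower = TRUE)
  structure(list(pk = pk, soa = soa, target = target, binding = binding,
                 competitor = competitor, bodyweight = bodyweight,
                 name = as.character(name)[1]),
            class = "soa_scenario")
}

#' @export
print.soa_scenario <- function(x, ...) {
  variant <- paste0(x$binding$valence,
                    if (!is.null(x$competitor)) "+competitor" else "")
  cat(sprintf("<soa_scenario '%s'> variant: %s\n", x$name, variant))
  cat(sprintf("  PK: VP=%g L V2=%g L Cl=%g L/d Q=%g L/d ka=%g/d F=%g\n",
              x$pk$VP, x$pk$V2, x$pk$Cl, x$pk$Q, x$pk$ka, x$pk$F))
  cat(sprintf("  SoA: VS=%g L ratio=%g\n", x$soa$VS, x$soa$ratio))
  cat(sprintf("  Target: TP0=%g nM TS0=%g nM kdegTp=%g/d kdegTs=%g/d frac=%g\n",
              x$target$TP0, x$target$TS0, x$target$kdegTp, x$target$kdegTs,
              x$target$frac))
  cat(sprintf("  Binding: KD=%g nM kon=%g/nM/d koff=%g/d\n",
              x$binding$KD, x$binding$kon, x$binding$koff))
  if (!is.null(x$competitor)) {
    cat(sprintf("  Competitor: S0=%g nM KD=%g nM\n",
                x$competitor$S0, x$competitor$KD))
  }
  invisible(x)
}

#' Replace the binding affinity of a scenario
#'
#' Returns a copy of `scn` with a new `KD`; the off-rate is recomputed at
#' fixed `kon` (the standard affinity-engineering assumption: maturation
#' changes the off-rate).
#'
#' @param scn A [scenario()] object.
#' @param KD New dissociation constant (nM).
#' @return A modified `soa_scenario`.
#' @export
set_affinity <- function(scn, KD) {
  stopifnot(inherits(scn, "soa_scenario"))
  scn$binding <- binding_spec(KD = KD, kon = scn$binding$kon,
                              kelC = scn$binding$kelC,
                              valence = scn$binding$valence)
  scn
}
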