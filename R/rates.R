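#' Derive drug distribution rate constants
#'
#' Computes the plasma/SoA/peripheral distribution rate constants of the drug
#' from the two-compartment PK parameters and the SoA geometry, under two
#' simultaneous constraints: the plasma PK of the two-compartment fit is
#' retained exactly, and the steady-state (equivalently, AUC) ratio of total
#' drug between the SoA and plasma equals `ratio`. The SoA-to-plasma and
#' peripheral-to-plasma rates are both fixed at `Q/V2`; the plasma-to-SoA
#' rate then follows from the ratio constraint and the plasma-to-peripheral
#' rate takes up the remainder of the distributional clearance so that
#' `(kps + kpt) * VP = Q` holds exactly. The internal peripheral volume
#' reduces to `VT = V2 - ratio * VS`.
#'
#' @param pk A [pk_parameters()] object.
#' @param soa A [soa_geometry()] object.
#' @return A list with elements `kps`, `ksp`, `kpt`, `ktp` (1/day), `VT` (L)
#'   and `kel` (1/day).
#' @examples
#' derive_drug_rates(pk_parameters(3.2, 2.2, 0.454, 0.252), soa_geometry(0.3))
#' @export
derive_drug_rates <- function(pk, soa) {
  stopifnot(inherits(pk, "soa_pk"), inherits(soa, "soa_geometry"))
  ksp <- pk$Q / pk$V2
  kps <- soa$ratio * ksp * soa$VS / pk$VP
  kpt <- pk$Q / pk$VP - kps
  if (kpt <= 0) {
    stop_soa(sprintf(
      "drug distribution closure failed: kpt = Q/VP - kps = %g <= 0; ",
      kpt), sprintf(
      "ratio*VS = %g must be smaller than V2 = %g",
      soa$ratio * soa$VS, pk$V2), class = "soa_parametrization_error")
  }
  VT <- pk$VP * kpt / ksp  # simplifies to V2 - ratio*VS
  if (VT <= 0) {
    stop_soa(sprintf("drug distribution closure failed: VT = %g <= 0", VT),
             class = "soa_parametrization_error")
  }
  list(kps = kps, ksp = ksp, kpt = kpt, ktp = ksp, VT = VT, kel = pk$Cl / pk$VP)
}

#' Derive target synthesis and distribution rates
#'
#' Closes the target sub-model around its measured baselines: given the
#' baseline concentrations, degradation rates, the synthesis split `frac`
#' and the fixed plasma-to-SoA distribution rate `kpsT = Qtarget / VP`, the
#' zero-order synthesis rates and the SoA-to-plasma distribution rate are
#' computed so that the drug-free baseline is an exact fixed point of the
#' target equations. Whole-body synthesis (nmol/day) is
#' `ksynTot = TP0 * kdegTp * VP + TS0 * kdegTs * VS`, of which a fraction
#' `frac` is produced at the SoA.
#'
#' A plasma-only target (`TS0 = 0` with `frac = 0` and `Qtarget = 0`)
#' degenerates to `ksynP = TP0 * kdegTp` with no SoA exchange.
#'
#' @param target A [target_spec()] object.
#' @param pk A [pk_parameters()] object.
#' @param soa A [soa_geometry()] object.
#' @return A list with `kpsT`, `kspT` (1/day), `ksynP`, `ksynS` (nM/day) and
#'   `ksynTot` (nmol/day).
#' @export
derive_target_rates <- function(target, pk, soa) {
  stopifnot(inherits(target, "soa_target"), inherits(pk, "soa_pk"),
            inherits(soa, "soa_geometry"))
  kpsT <- target$Qtarget / pk$VP
  ksynTot <- target$TP0 * target$kdegTp * pk$VP +
    target$TS0 * target$kdegTs * soa$VS
  if (target$TS0 <= 0) {
    if (target$frac > 0) {
      stop_soa("frac > 0 requires a positive SoA baseline TS0",
               class = "soa_parametrization_error")
    }
    if (kpsT > 0) {
      stop_soa("Qtarget > 0 requires a positive SoA baseline TS0 ",
               "(target would accumulate at the SoA with no return path)",
               class = "soa_parametrization_error")
    }
    return(list(kpsT = 0, kspT = 0, ksynP = target$TP0 * target$kdegTp,
                ksynS = 0, ksynTot = ksynTot))
  }
  ksynS <- target$frac * ksynTot / soa$VS
  ksynP <- (1 - target$frac) * ksynTot / pk$VP
  kspT <- target$frac * ksynTot / (target$TS0 * soa$VS) - target$kdegTs +
    target$TP0 * pk$VP / (target$TS0 * soa$VS) * kpsT
  if (kspT < 0) {
    stop_soa(sprintf(
      "target closure yields kspT = %g < 0; ", kspT),
      "raise frac, lower Qtarget/kpsT, or revisit the baselines ",
      "(the requested steady state is not reachable with non-negative rates)",
      class = "soa_parametrization_error")
  }
  list(kpsT = kpsT, kspT = kspT, ksynP = ksynP, ksynS = ksynS,
       ksynTot = ksynTot)
}

#' Derive the complete rate set of a scenario
#'
#' Combines [derive_drug_rates()] and [derive_target_rates()], resolves the
#' complex elimination rate (`kelC = kel` unless measured) and the complex
#' distribution rates (`kpsC = kps`, `kspC = ksp`), and, when a competitor is
#' present, replaces the target closure by the competitor-aware one: the
#' competitor scheme requires SoA-only target synthesis (`frac = 1`) and
#' plasma-only target degradation (`kdegTs = 0`). The baseline
#' competitor:target complex is
#' `SC0 = kon_c * TP0 * S0 / (koff_c + kdeg_SC)` and the SoA synthesis rate
#' absorbs the additional plasma sink through the complex,
#' `ksynS = (kdegTp * TP0 + kdeg_SC * SC0) * VP / VS`, so that all species
#' sit exactly at their drug-free baselines.
#'
#' @param scn A [scenario()] object.
#' @return An object of class `soa_rates`: a named list of all rate constants
#'   used by the ODE right-hand side.
#' @export
derive_rates <- function(scn) {
  stopifnot(inherits(scn, "soa_scenario"))
  drug <- derive_drug_rates(scn$pk, scn$soa)
  kelC <- if (is.na(scn$binding$kelC)) drug$kel else scn$binding$kelC
  rates <- c(drug, list(
    kpsC = drug$kps, kspC = drug$ksp, kelC = kelC,
    kon = scn$binding$kon, koff = scn$binding$koff,
    kdegTp = scn$target$kdegTp, kdegTs = scn$target$kdegTs))

  if (is.null(scn$competitor)) {
    rates <- c(rates, derive_target_rates(scn$target, scn$pk, scn$soa))
  } else {
    if (scn$target$frac != 1 || scn$target$kdegTs != 0) {
      stop_soa("the competitor scheme requires frac = 1 (SoA-only synthesis) ",
               "and kdegTs = 0 (plasma-only degradation)",
               class = "soa_configuration_error")
    }
    if (scn$target$TS0 <= 0) {
      stop_soa("the competitor scheme requires TS0 > 0",
               class = "soa_configuration_error")
    }
    cmp <- scn$competitor
    kpsT <- scn$target$Qtarget / scn$pk$VP
    SC0 <- cmp$kon * scn$target$TP0 * cmp$S0 / (cmp$koff + cmp$kdeg_SC)
    ksynS <- (scn$target$kdegTp * scn$target$TP0 + cmp$kdeg_SC * SC0) *
      scn$pk$VP / scn$soa$VS
    kspT <- (kpsT * scn$target$TP0 * scn$pk$VP / scn$soa$VS + ksynS) /
      scn$target$TS0
    ksyn_S <- cmp$kdeg_S * cmp$S0 + cmp$kdeg_SC * SC0
    rates <- c(rates, list(
      kpsT = kpsT, kspT = kspT, ksynP = 0, ksynS = ksynS,
      ksynTot = ksynS * scn$soa$VS,
      kon_c = cmp$kon, koff_c = cmp$koff, kdeg_S = cmp$kdeg_S,
      kdeg_SC = cmp$kdeg_SC, ksyn_S = ksyn_S, SC0 = SC0))
  }
  ## two-arm statistical factors: 2*kon for free-antibody association,
  ## 2*koff for double-complex dissociation; per-site rates otherwise
  rates$kon1 <- 2 * rates$kon
  rates$kon2 <- rates$kon
  rates$koff1 <- rates$koff
  rates$koff2 <- 2 * rates$koff
  structure(rates, class = "soa_rates")
}

#' Convert a printed dose to a molar amount
#'
#' @param dose_value Dose in mg, or mg/kg when `per_kg = TRUE`.
#' @param mw_drug Drug molecular weight (kDa).
#' @param bodyweight Bodyweight (kg); required for per-kg dosing.
#' @param per_kg Is `dose_value` a per-kilogram dose?
#' @return Dose amount in nmol (1 mg of a 150 kDa protein is 1000/150 nmol).
#' @examples
#' dose_to_amount(300, 150)                       # 2000 nmol
#' dose_to_amount(2, 150, bodyweight = 70, per_kg = TRUE) # 933.33 nmol
#' @export
dose_to_amount <- function(dose_value, mw_drug, bodyweight = NULL,
                           per_kg = FALSE) {
  check_scalar(dose_value, "dose_value", 0)
  check_scalar(mw_drug, "mw_drug", 0, strict_lower = TRUE)
  if (per_kg) {
    if (is.null(bodyweight) || is.na(bodyweight)) {
      stop_soa("bodyweight is required for mg/kg dosing",
               class = "soa_configuration_error")
    }
    check_scalar(bodyweight, "bodyweight", 0, strict_lower = TRUE)
    dose_value <- dose_value * bodyweight
  }
  ## 1 kDa = 1 mg/umol, so dose_mg / mw_kDa is umol
  dose_value / mw_drug * 1000
}
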