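## State-vector layouts. The depot is an amount (nmol); everything else is a
## concentration (nM) in its own compartment. Inter-compartment fluxes carry
## the volume ratios explicitly, so amounts (conc * volume) are conserved.

species_compartment <- c(
  Depot = "depot", DP = "plasma", DT = "peripheral", DS = "soa",
  CP = "plasma", CS = "soa", CP2 = "plasma", CS2 = "soa",
  TP = "plasma", TS = "soa", S = "plasma", SC = "plasma")

state_layout <- function(valence, competitor) {
  sp <- c("Depot", "DP", "DT", "DS", "CP", "CS")
  if (valence == "bivalent") sp <- c(sp, "CP2", "CS2")
  sp <- c(sp, "TP", "TS")
  if (competitor) sp <- c(sp, "S", "SC")
  sp
}

#' Build the ODE system for a scenario
#'
#' Assembles the state layout, initial (drug-free) state and right-hand-side
#' function for one of four model variants, chosen by the binding valence and
#' the presence of a competitor:
#'
#' * *monovalent*: single-step reversible 1:1 binding in plasma and at the
#'   SoA; drug, complex and target distribute between compartments; free drug
#'   additionally distributes to a peripheral compartment; complex is
#'   eliminated in plasma only. There is no binding in the peripheral
#'   compartment and no target or complex there.
#' * *bivalent*: step-wise two-arm binding with statistical factors - free
#'   antibody associates at `2*kon`, the double complex dissociates at
#'   `2*koff` - adding singly- and doubly-bound complex species. The
#'   double-complex conversion terms mirror the single-complex ones with
#'   opposite sign so that binding fluxes conserve both drug and target mass
#'   exactly.
#' * either valence `+competitor`: a plasma-confined endogenous ligand
#'   competes with the drug for free target in plasma.
#'
#' The drug-free initial state is an exact fixed point of the right-hand side
#' by construction of the rate closure.
#'
#' @param scn A [scenario()] object.
#' @param rates Optional pre-computed [derive_rates()] result; tests may pass
#'   a modified copy (e.g. with eliminations zeroed) to probe conservation
#'   laws.
#' @return An object of class `soa_model` with elements `variant`, `species`,
#'   `state0`, `rhs` (a `function(t, y, parms)` for [deSolve::ode()]),
#'   `rates` and `scenario`.
#' @export
soa_model <- function(scn, rates = NULL) {
  stopifnot(inherits(scn, "soa_scenario"))
  if (is.null(rates)) rates <- derive_rates(scn)
  has_cmp <- !is.null(scn$competitor)
  valence <- scn$binding$valence
  variant <- paste0(valence, if (has_cmp) "+competitor" else "")
  species <- state_layout(valence, has_cmp)

  rhs <- if (valence == "monovalent") {
    if (has_cmp) rhs_monovalent_competitor(scn, rates) else rhs_monovalent(scn, rates)
  } else {
    if (has_cmp) rhs_bivalent_competitor(scn, rates) else rhs_bivalent(scn, rates)
  }

  m <- structure(list(variant = variant, species = species,
                      compartments = species_compartment[species],
                      rhs = rhs, rates = rates, scenario = scn),
                 class = "soa_model")
  m$state0 <- initialize_state(m)
  m
}

#' Drug-free initial state of a model
#'
#' All drug species start at zero; free target starts at its measured
#' baselines and, when a competitor is present, the competitor starts at its
#' free baseline with the competitor:target complex at its equilibrium value
#' `SC0 = kon_c * TP0 * S0 / (koff_c + kdeg_SC)`. Dose administration is
#' handled as events by [simulate_regimen()], not in the initial state.
#'
#' @param model A [soa_model()] object.
#' @return Named numeric state vector (nM; depot in nmol).
#' @export
initialize_state <- function(model) {
  stopifnot(inherits(model, "soa_model"))
  y <- stats::setNames(numeric(length(model$species)), model$species)
  y["TP"] <- model$scenario$target$TP0
  y["TS"] <- model$scenario$target$TS0
  if ("S" %in% model$species) {
    y["S"] <- model$scenario$competitor$S0
    y["SC"] <- model$rates$SC0
  }
  y
}

#' @export
print.soa_model <- function(x, ...) {
  cat(sprintf("<soa_model '%s'> variant: %s, %d species: %s\n",
              x$scenario$name, x$variant, length(x$species),
              paste(x$species, collapse = " ")))
  invisible(x)
}

## --- right-hand sides ------------------------------------------------------
## Each builder returns a closure over plain scalar bindings (fast to
## evaluate under lsoda). State is indexed by position in the layout order.

rhs_monovalent <- function(scn, r) {
  VP <- scn$pk$VP; VS <- scn$soa$VS; VT <- r$VT
  ka <- if (is.na(scn$pk$ka)) 0 else scn$pk$ka
  kps <- r$kps; ksp <- r$ksp; kpt <- r$kpt; ktp <- r$ktp; kel <- r$kel
  kpsC <- r$kpsC; kspC <- r$kspC; kelC <- r$kelC
  kon <- r$kon; koff <- r$koff
  kpsT <- r$kpsT; kspT <- r$kspT; ksynP <- r$ksynP; ksynS <- r$ksynS
  kdegTp <- r$kdegTp; kdegTs <- r$kdegTs
  function(t, y, parms) {
    Depot <- y[1L]; DP <- y[2L]; DT <- y[3L]; DS <- y[4L]
    CP <- y[5L]; CS <- y[6L]; TP <- y[7L]; TS <- y[8L]
    bP <- kon * DP * TP
    bS <- kon * DS * TS
    list(c(
      -ka * Depot,
      ka * Depot / VP + ksp * DS * VS / VP + ktp * DT * VT / VP -
        kps * DP - kpt * DP + koff * CP - bP - kel * DP,
      kpt * DP * VP / VT - ktp * DT,
      kps * DP * VP / VS - ksp * DS + koff * CS - bS,
      kspC * CS * VS / VP - kpsC * CP + bP - koff * CP - kelC * CP,
      kpsC * CP * VP / VS - kspC * CS + bS - koff * CS,
      kspT * TS * VS / VP - kpsT * TP + koff * CP - bP + ksynP - kdegTp * TP,
      kpsT * TP * VP / VS - kspT * TS + koff * CS - bS + ksynS - kdegTs * TS))
  }
}

rhs_bivalent <- function(scn, r) {
  VP <- scn$pk$VP; VS <- scn$soa$VS; VT <- r$VT
  ka <- if (is.na(scn$pk$ka)) 0 else scn$pk$ka
  kps <- r$kps; ksp <- r$ksp; kpt <- r$kpt; ktp <- r$ktp; kel <- r$kel
  kpsC <- r$kpsC; kspC <- r$kspC; kelC <- r$kelC
  kon1 <- r$kon1; kon2 <- r$kon2; koff1 <- r$koff1; koff2 <- r$koff2
  kpsT <- r$kpsT; kspT <- r$kspT; ksynP <- r$ksynP; ksynS <- r$ksynS
  kdegTp <- r$kdegTp; kdegTs <- r$kdegTs
  function(t, y, parms) {
    Depot <- y[1L]; DP <- y[2L]; DT <- y[3L]; DS <- y[4L]
    CP <- y[5L]; CS <- y[6L]; CP2 <- y[7L]; CS2 <- y[8L]
    TP <- y[9L]; TS <- y[10L]
    b1P <- kon1 * DP * TP; b2P <- kon2 * CP * TP
    b1S <- kon1 * DS * TS; b2S <- kon2 * CS * TS
    list(c(
      -ka * Depot,
      ka * Depot / VP + ksp * DS * VS / VP + ktp * DT * VT / VP -
        kps * DP - kpt * DP + koff1 * CP - b1P - kel * DP,
      kpt * DP * VP / VT - ktp * DT,
      kps * DP * VP / VS - ksp * DS + koff1 * CS - b1S,
      kspC * CS * VS / VP - kpsC * CP + b1P - koff1 * CP -
        b2P + koff2 * CP2 - kelC * CP,
      kpsC * CP * VP / VS - kspC * CS + b1S - koff1 * CS - b2S + koff2 * CS2,
      kspC * CS2 * VS / VP - kpsC * CP2 + b2P - koff2 * CP2 - kelC * CP2,
      kpsC * CP2 * VP / VS - kspC * CS2 + b2S - koff2 * CS2,
      kspT * TS * VS / VP - kpsT * TP + koff1 * CP - b1P -
        b2P + koff2 * CP2 + ksynP - kdegTp * TP,
      kpsT * TP * VP / VS - kspT * TS + koff1 * CS - b1S -
        b2S + koff2 * CS2 + ksynS - kdegTs * TS))
  }
}

rhs_monovalent_competitor <- function(scn, r) {
  base <- rhs_monovalent(scn, r)
  kon_c <- r$kon_c; koff_c <- r$koff_c
  kdeg_S <- r$kdeg_S; kdeg_SC <- r$kdeg_SC; ksyn_S <- r$ksyn_S
  function(t, y, parms) {
    d <- base(t, y, parms)[[1L]]
    TP <- y[7L]; S <- y[9L]; SC <- y[10L]
    v_on <- kon_c * S * TP; v_off <- koff_c * SC
    d[7L] <- d[7L] - v_on + v_off
    list(c(d,
           ksyn_S - kdeg_S * S - v_on + v_off,
           v_on - v_off - kdeg_SC * SC))
  }
}

rhs_bivalent_competitor <- function(scn, r) {
  base <- rhs_bivalent(scn, r)
  kon_c <- r$kon_c; koff_c <- r$koff_c
  kdeg_S <- r$kdeg_S; kdeg_SC <- r$kdeg_SC; ksyn_S <- r$ksyn_S
  function(t, y, parms) {
    d <- base(t, y, parms)[[1L]]
    TP <- y[9L]; S <- y[11L]; SC <- y[12L]
    v_on <- kon_c * S * TP; v_off <- koff_c * SC
    d[9L] <- d[9L] - v_on + v_off
    list(c(d,
           ksyn_S - kdeg_S * S - v_on + v_off,
           v_on - v_off - kdeg_SC * SC))
  }
}

#' Total drug and total target accessors
#'
#' Helpers summing the species of a time-course matrix into totals: total
#' drug counts each antibody molecule once (free + singly + doubly bound);
#' total target counts bound ligand per binding site (the double complex
#' carries two target molecules).
#'
#' @param tc A `soa_timecourse` object.
#' @param compartment `"plasma"` or `"soa"`.
#' @return Numeric vector along the time grid (nM).
#' @export
total_drug <- function(tc, compartment = c("plasma", "soa")) {
  compartment <- match.arg(compartment)
  d <- tc$data
  if (compartment == "plasma") {
    out <- d$DP + d$CP
    if ("CP2" %in% names(d)) out <- out + d$CP2
  } else {
    out <- d$DS + d$CS
    if ("CS2" %in% names(d)) out <- out + d$CS2
  }
  out
}

#' @rdname total_drug
#' @export
total_target <- function(tc, compartment = c("plasma", "soa")) {
  compartment <- match.arg(compartment)
  d <- tc$data
  if (compartment == "plasma") {
    out <- d$TP + d$CP
    if ("CP2" %in% names(d)) out <- out + 2 * d$CP2
    if ("SC" %in% names(d)) out <- out + d$SC
  } else {
    out <- d$TS + d$CS
    if ("CS2" %in% names(d)) out <- out + 2 * d$CS2
  }
  out
}
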