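## Scenario configuration schema (YAML or JSON, same structure). All
## physical quantities carry explicit unit suffixes in their keys; unknown
## keys are rejected, and every default applied in place of an absent key is
## logged so that resolved runs are auditable.

check_keys <- function(lst, allowed, section) {
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown) > 0) {
    stop_soa(sprintf("unknown key(s) in '%s': %s (allowed: %s)", section,
                     paste(unknown, collapse = ", "),
                     paste(allowed, collapse = ", ")),
             class = "soa_config_error")
  }
}

need_key <- function(lst, key, section) {
  if (is.null(lst[[key]])) {
    stop_soa(sprintf("missing required key '%s' in '%s'", key, section),
             class = "soa_config_error")
  }
  lst[[key]]
}

## Each parser returns list(value = <spec object>, log = <character>,
## resolved = <named list of materialized keys>).

parse_pk_section <- function(lst) {
  check_keys(lst, c("VP_L", "V2_L", "Cl_L_per_day", "Q_L_per_day",
                    "ka_per_day", "F_fraction", "mw_drug_kDa"), "pk")
  log <- character(0)
  ka <- lst$ka_per_day
  if (is.null(ka)) ka <- NA_real_
  F <- lst$F_fraction
  if (is.null(F)) { F <- 1; log <- c(log, "pk.F_fraction defaulted to 1") }
  mw <- lst$mw_drug_kDa
  if (is.null(mw)) {
    mw <- 150
    log <- c(log, "pk.mw_drug_kDa defaulted to 150 (whole IgG)")
  }
  value <- pk_parameters(VP = need_key(lst, "VP_L", "pk"),
                         V2 = need_key(lst, "V2_L", "pk"),
                         Cl = need_key(lst, "Cl_L_per_day", "pk"),
                         Q = need_key(lst, "Q_L_per_day", "pk"),
                         ka = ka, F = F, mw_drug = mw)
  list(value = value, log = log,
       resolved = list(VP_L = value$VP, V2_L = value$V2,
                       Cl_L_per_day = value$Cl, Q_L_per_day = value$Q,
                       ka_per_day = value$ka, F_fraction = value$F,
                       mw_drug_kDa = value$mw_drug))
}

parse_soa_section <- function(lst) {
  check_keys(lst, c("VS_L", "ratio"), "soa")
  log <- character(0)
  ratio <- lst$ratio
  if (is.null(ratio)) {
    ratio <- 0.30
    log <- c(log, "soa.ratio defaulted to 0.30 (standard non-brain/non-muscle tissue)")
  }
  value <- soa_geometry(VS = need_key(lst, "VS_L", "soa"), ratio = ratio)
  list(value = value, log = log,
       resolved = list(VS_L = value$VS, ratio = value$ratio))
}

parse_target_section <- function(lst) {
  check_keys(lst, c("TP0_nM", "TS0_nM", "kdegTp_per_day", "kdegTs_per_day",
                    "thalf_plasma_min", "thalf_soa_min", "frac",
                    "Qtarget_L_per_day", "mw_target_kDa"), "target")
  log <- character(0)
  kdegTp <- lst$kdegTp_per_day
  if (!is.null(lst$thalf_plasma_min)) {
    if (!is.null(kdegTp)) {
      stop_soa("give either target.kdegTp_per_day or target.thalf_plasma_min, not both",
               class = "soa_config_error")
    }
    kdegTp <- kdeg_from_half_life(lst$thalf_plasma_min, "min")
  }
  if (is.null(kdegTp)) {
    stop_soa("missing target turnover: kdegTp_per_day or thalf_plasma_min",
             class = "soa_config_error")
  }
  kdegTs <- lst$kdegTs_per_day
  if (!is.null(lst$thalf_soa_min)) {
    if (!is.null(kdegTs)) {
      stop_soa("give either target.kdegTs_per_day or target.thalf_soa_min, not both",
               class = "soa_config_error")
    }
    kdegTs <- kdeg_from_half_life(lst$thalf_soa_min, "min")
  }
  if (is.null(kdegTs)) kdegTs <- 0
  TS0 <- lst$TS0_nM
  if (is.null(TS0)) TS0 <- 0
  frac <- lst$frac
  if (is.null(frac)) frac <- 0
  Qtarget <- lst$Qtarget_L_per_day
  if (is.null(Qtarget)) {
    Qtarget <- if (TS0 > 0) 0.416 else 0
    log <- c(log, sprintf("target.Qtarget_L_per_day defaulted to %g", Qtarget))
  }
  mw <- if (is.null(lst$mw_target_kDa)) NA_real_ else lst$mw_target_kDa
  value <- target_spec(TP0 = need_key(lst, "TP0_nM", "target"), TS0 = TS0,
                       kdegTp = kdegTp, kdegTs = kdegTs, frac = frac,
                       Qtarget = Qtarget, mw_target = mw)
  list(value = value, log = log,
       resolved = list(TP0_nM = value$TP0, TS0_nM = value$TS0,
                       kdegTp_per_day = value$kdegTp,
                       kdegTs_per_day = value$kdegTs, frac = value$frac,
                       Qtarget_L_per_day = value$Qtarget,
                       mw_target_kDa = value$mw_target))
}

parse_binding_section <- function(lst) {
  check_keys(lst, c("KD_nM", "kon_per_nM_per_day", "kelC_per_day", "valence"),
             "binding")
  log <- character(0)
  kon <- lst$kon_per_nM_per_day
  if (is.null(kon)) {
    kon <- kon_default()
    log <- c(log, "binding.kon_per_nM_per_day defaulted to 86.4 (1e6 /M/s)")
  }
  kelC <- lst$kelC_per_day
  if (is.null(kelC)) {
    kelC <- NA_real_
    log <- c(log, "binding.kelC_per_day defaulted to the drug elimination rate kel")
  }
  valence <- lst$valence
  if (is.null(valence)) {
    valence <- "bivalent"
    log <- c(log, "binding.valence defaulted to bivalent (two-arm IgG binding)")
  }
  value <- binding_spec(KD = need_key(lst, "KD_nM", "binding"), kon = kon,
                        kelC = kelC, valence = valence)
  list(value = value, log = log,
       resolved = list(KD_nM = value$KD, kon_per_nM_per_day = value$kon,
                       kelC_per_day = value$kelC, valence = value$valence))
}

parse_competitor_section <- function(lst) {
  check_keys(lst, c("S0_nM", "kon_per_nM_per_day", "KD_nM", "kdeg_S_per_day",
                    "kdeg_SC_per_day", "mw_kDa"), "competitor")
  mw <- if (is.null(lst$mw_kDa)) NA_real_ else lst$mw_kDa
  value <- competitor_spec(S0 = need_key(lst, "S0_nM", "competitor"),
                           kon = need_key(lst, "kon_per_nM_per_day", "competitor"),
                           KD = need_key(lst, "KD_nM", "competitor"),
                           kdeg_S = need_key(lst, "kdeg_S_per_day", "competitor"),
                           kdeg_SC = need_key(lst, "kdeg_SC_per_day", "competitor"),
                           mw_competitor = mw)
  list(value = value, log = character(0),
       resolved = list(S0_nM = value$S0, kon_per_nM_per_day = value$kon,
                       KD_nM = value$KD, kdeg_S_per_day = value$kdeg_S,
                       kdeg_SC_per_day = value$kdeg_SC,
                       mw_kDa = value$mw_competitor))
}

parse_regimen_section <- function(lst) {
  check_keys(lst, c("route", "dose_mg", "dose_mg_per_kg", "interval_days",
                    "n_doses", "start_day", "name"), "regimen")
  per_kg <- !is.null(lst[["dose_mg_per_kg"]])
  if (per_kg && !is.null(lst[["dose_mg"]])) {
    stop_soa("give either regimen.dose_mg or regimen.dose_mg_per_kg, not both",
             class = "soa_config_error")
  }
  amount <- if (per_kg) lst[["dose_mg_per_kg"]] else lst[["dose_mg"]]
  if (is.null(amount)) {
    stop_soa("missing dose: regimen.dose_mg or regimen.dose_mg_per_kg",
             class = "soa_config_error")
  }
  value <- dose_regimen(route = need_key(lst, "route", "regimen"),
                        amount = amount, per_kg = per_kg,
                        interval = if (is.null(lst$interval_days)) 7 else lst$interval_days,
                        n_doses = if (is.null(lst$n_doses)) 1 else lst$n_doses,
                        start = if (is.null(lst$start_day)) 0 else lst$start_day)
  resolved <- list(route = value$route, interval_days = value$interval,
                   n_doses = value$n_doses, start_day = value$start)
  resolved[[if (per_kg) "dose_mg_per_kg" else "dose_mg"]] <- value$amount
  list(value = value, log = character(0), resolved = resolved)
}

#' Read a scenario configuration file
#'
#' Reads a YAML or JSON scenario configuration (chosen by file extension),
#' validates it against the schema (unit-suffixed keys, unknown keys
#' rejected), applies documented defaults where keys are absent, and returns
#' the assembled scenario, regimen, an assumption log listing every applied
#' default, and the fully materialized ("resolved") configuration. Writing
#' the resolved configuration back out and re-reading it reproduces the same
#' scenario exactly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration.
#' @param overrides Optional character vector of `section.key=value`
#'   overrides, e.g. `"binding.KD_nM=0.0035"`.
#' @return A list with `scenario`, `regimen`, `assumptions`, `resolved` and
#'   `name`.
#' @export
read_scenario_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) {
    stop_soa(sprintf("configuration file not found: %s", path),
             class = "soa_config_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_soa("configuration must be a .yaml/.yml or .json file",
             class = "soa_config_error")
  }
  build_scenario_config(raw, overrides = overrides)
}

apply_overrides <- function(raw, overrides) {
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([^.=]+)\\.([^=]+)=(.*)$", ov))[[1]]
    if (length(m) != 4) {
      stop_soa(sprintf("malformed override '%s' (expected section.key=value)", ov),
               class = "soa_config_error")
    }
    val <- suppressWarnings(as.numeric(m[4]))
    if (is.na(val)) val <- m[4]
    raw[[m[2]]][[m[3]]] <- val
  }
  raw
}

#' @rdname read_scenario_config
#' @param raw A configuration given directly as a nested list.
#' @export
build_scenario_config <- function(raw, overrides = NULL) {
  if (!is.null(overrides)) raw <- apply_overrides(raw, overrides)
  check_keys(raw, c("name", "bodyweight_kg", "pk", "soa", "target", "binding",
                    "competitor", "regimen", "solver", "outputs"), "<top level>")
  name <- if (is.null(raw$name)) "config" else raw$name
  log <- character(0)
  pk <- parse_pk_section(need_key(raw, "pk", "<top level>"))
  soa <- parse_soa_section(need_key(raw, "soa", "<top level>"))
  target <- parse_target_section(need_key(raw, "target", "<top level>"))
  binding <- parse_binding_section(need_key(raw, "binding", "<top level>"))
  log <- c(log, pk$log, soa$log, target$log, binding$log)
  competitor <- NULL
  resolved <- list(name = name)
  bodyweight <- raw$bodyweight_kg
  if (is.null(bodyweight)) {
    bodyweight <- 70
    log <- c(log, "bodyweight_kg defaulted to 70")
  }
  resolved$bodyweight_kg <- bodyweight
  resolved$pk <- pk$resolved
  resolved$soa <- soa$resolved
  resolved$target <- target$resolved
  resolved$binding <- binding$resolved
  if (!is.null(raw$competitor)) {
    cmp <- parse_competitor_section(raw$competitor)
    competitor <- cmp$value
    resolved$competitor <- cmp$resolved
  }
  regimen <- NULL
  if (!is.null(raw$regimen)) {
    reg <- parse_regimen_section(raw$regimen)
    regimen <- reg$value
    resolved$regimen <- reg$resolved
  }
  if (!is.null(raw$solver)) {
    check_keys(raw$solver, c("rtol", "atol"), "solver")
    resolved$solver <- raw$solver
  }
  scn <- scenario(pk = pk$value, soa = soa$value, target = target$value,
                  binding = binding$value, competitor = competitor,
                  bodyweight = bodyweight, name = name)
  list(scenario = scn, regimen = regimen, assumptions = log,
       resolved = resolved, name = name)
}

#' Write the resolved configuration of a run
#'
#' @param cfg The list returned by [read_scenario_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_resolved_config <- function(cfg, path) {
  res <- cfg$resolved
  ## yaml cannot represent NA meaningfully for re-reading; drop NA leaves
  drop_na <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, drop_na)
      x[!vapply(x, is.null, logical(1))]
    } else if (length(x) == 1 && is.na(x)) NULL else x
  }
  yaml::write_yaml(drop_na(res), path)
  invisible(path)
}
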