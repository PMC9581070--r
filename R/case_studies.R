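## Executable case-study fixtures. Each fixture is built from a versioned
## YAML file shipped under inst/extdata/cases; gap-filling defaults (drug
## molecular weight, SC absorption where unreported, the lung interstitial
## volume reused across lung targets) are declared in the file's
## `assumptions` block and carried into the returned object so that runs
## remain auditable.

case_dir <- function() system.file("extdata", "cases", package = "soamod")

#' List the shipped case studies
#'
#' @return Character vector of case names.
#' @export
list_case_studies <- function() {
  sub("\\.yaml$", "", list.files(case_dir(), pattern = "\\.yaml$"))
}

#' Load a case study by name
#'
#' @param name One of [list_case_studies()]: `"osteopontin"` (plasma-only
#'   feasibility example, abundant fast-turnover target), `"il33"` (lung
#'   alarmin with a soluble decoy-receptor competitor in plasma), `"ccl20"`
#'   (skin chemokine, affinity-requirement example) or `"il13"` (lung
#'   cytokine dose-projection example; requires an externally supplied PK
#'   block).
#' @param ... Passed to the specific fixture function (e.g. `pk` and
#'   `population` for `"il13"`).
#' @return A `soa_case_study` object: list with `name`, `scenario`,
#'   `regimens` (named list of [dose_regimen()]), `kd_grid_nM` (the affinity
#'   grid studied), `assumptions` and `notes`.
#' @export
get_case_study <- function(name, ...) {
  switch(name,
         osteopontin = fixture_osteopontin(...),
         il33 = fixture_il33(...),
         ccl20 = fixture_ccl20(...),
         il13 = fixture_il13(...),
         stop_soa(sprintf("unknown case study '%s'", name),
                  class = "soa_configuration_error"))
}

#' @export
print.soa_case_study <- function(x, ...) {
  cat(sprintf("<soa_case_study '%s'> regimens: %s\n", x$name,
              paste(names(x$regimens), collapse = ", ")))
  for (a in x$assumptions) cat("  assumption:", a, "\n")
  invisible(x)
}

read_case_yaml <- function(name) {
  path <- file.path(case_dir(), paste0(name, ".yaml"))
  if (!file.exists(path)) {
    stop_soa(sprintf("case file not found: %s", path),
             class = "soa_configuration_error")
  }
  yaml::read_yaml(path)
}

parse_case_regimens <- function(lst) {
  regs <- lapply(lst, function(r) {
    ## [[ with exact names: $ would partial-match dose_mg to dose_mg_per_kg
    flat <- r[["dose_mg"]]
    dose_regimen(route = r[["route"]],
                 amount = if (!is.null(flat)) flat else r[["dose_mg_per_kg"]],
                 per_kg = is.null(flat),
                 interval = if (!is.null(r[["interval_days"]])) r[["interval_days"]] else 7,
                 n_doses = r[["n_doses"]],
                 start = if (!is.null(r[["start_day"]])) r[["start_day"]] else 0)
  })
  stats::setNames(regs, vapply(lst, `[[`, "", "name"))
}

build_case <- function(cfg, target, competitor = NULL, pk = NULL) {
  if (is.null(pk)) {
    pk <- parse_pk_section(cfg$pk)$value
  }
  soa <- parse_soa_section(cfg$soa)$value
  binding <- parse_binding_section(cfg$binding)$value
  scn <- scenario(pk = pk, soa = soa, target = target, binding = binding,
                  competitor = competitor,
                  bodyweight = if (!is.null(cfg$bodyweight_kg)) cfg$bodyweight_kg else 70,
                  name = cfg$name)
  structure(list(name = cfg$name, scenario = scn,
                 regimens = parse_case_regimens(cfg$regimens),
                 kd_grid_nM = unlist(cfg$kd_grid_nM),
                 assumptions = unlist(cfg$assumptions),
                 notes = unlist(cfg$notes)),
            class = "soa_case_study")
}

#' Osteopontin feasibility fixture
#'
#' Abundant plasma protein (baseline ~10 nM) with very fast turnover
#' (half-life ~10 min). Plasma levels alone suffice to judge feasibility, so
#' the fixture uses the degenerate plasma-only configuration (no SoA target,
#' no target distribution); the SoA compartment is decoupled from the drug
#' by `ratio = 0`.
#'
#' @return A `soa_case_study`.
#' @export
fixture_osteopontin <- function() {
  cfg <- read_case_yaml("osteopontin")
  target <- parse_target_section(cfg$target)$value
  build_case(cfg, target)
}

#' IL-33 feasibility fixture (lung, with sST2 competitor)
#'
#' The alarmin IL-33 is synthesized at the site of action (lung) and
#' distributes into plasma, where it is degraded and where the soluble decoy
#' receptor sST2 competes with the drug for free IL-33. The competitor and
#' its complex are plasma-confined.
#'
#' @return A `soa_case_study`.
#' @export
fixture_il33 <- function() {
  cfg <- read_case_yaml("il33")
  target <- parse_target_section(cfg$target)$value
  competitor <- parse_competitor_section(cfg$competitor)$value
  build_case(cfg, target, competitor = competitor)
}

#' CCL20 affinity-requirement fixture (skin)
#'
#' Skin-homing chemokine synthesized in the skin only and eliminated in
#' plasma only, with a measured plasma:skin drug concentration ratio of 20%
#' and skin baseline tenfold above the 30 pM plasma baseline.
#'
#' @return A `soa_case_study`.
#' @export
fixture_ccl20 <- function() {
  cfg <- read_case_yaml("ccl20")
  target <- parse_target_section(cfg$target)$value
  build_case(cfg, target)
}

#' IL-13 dose-projection fixture (lung)
#'
#' The anti-IL-13 retrospective example needs the clinical antibody's
#' population-PK constants, which are external inputs (they are not part of
#' this package's shipped data); supply them as a [pk_parameters()] object.
#' Plasma baselines are 0.06 pM (healthy) or 0.12 pM (asthmatic), lung
#' baselines 0.03 pM and 0.4 pM respectively, with a 20-minute half-life.
#'
#' @param pk A [pk_parameters()] object for the clinical antibody; an error
#'   is raised when missing.
#' @param population `"asthmatic"` (the population of the simulated trial)
#'   or `"healthy"`.
#' @return A `soa_case_study`.
#' @export
fixture_il13 <- function(pk = NULL, population = c("asthmatic", "healthy")) {
  population <- match.arg(population)
  cfg <- read_case_yaml("il13")
  if (is.null(pk)) {
    stop_soa("external input required: the IL-13 case needs a pk_parameters() ",
             "block for the clinical antibody (population-PK constants are ",
             "not shipped with the package)", class = "soa_configuration_error")
  }
  stopifnot(inherits(pk, "soa_pk"))
  tgt_cfg <- if (population == "asthmatic") cfg$target_asthmatic else cfg$target_healthy
  target <- parse_target_section(tgt_cfg)$value
  cs <- build_case(cfg, target, pk = pk)
  cs$population <- population
  cs
}

#' Draw a random, physiologically plausible scenario
#'
#' Samples log-uniformly within declared physiological ranges (central
#' volume 2-5 L, peripheral volume 1-5 L, clearances 0.1-1 L/day, plasma and
#' SoA baselines 1e-4 to 10 nM, half-lives 5 min to 7 days, SoA:plasma
#' ratio 0.05-0.5, SoA volume 0.05-2 L, KD 1e-3 to 10 nM) with `frac`
#' uniform on \[0, 1\] and the binding valence chosen at random. Draws whose
#' steady-state closure is infeasible (negative derived rates) are rejected
#' and redrawn, so every returned scenario parametrizes without error.
#' Reproducible by seed; the global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return A valid `soa_scenario`.
#' @export
random_scenario <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  runif_log <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  for (attempt in 1:1000) {
    pk <- pk_parameters(VP = runif_log(2, 5), V2 = runif_log(1, 5),
                        Cl = runif_log(0.1, 1), Q = runif_log(0.1, 1),
                        ka = 0.26, F = 0.6)
    soa <- soa_geometry(VS = runif_log(0.05, 2), ratio = runif_log(0.05, 0.5))
    target <- target_spec(
      TP0 = runif_log(1e-4, 10), TS0 = runif_log(1e-4, 10),
      kdegTp = kdeg_from_half_life(runif_log(5 / 1440, 7), "day"),
      kdegTs = kdeg_from_half_life(runif_log(5 / 1440, 7), "day"),
      frac = stats::runif(1))
    binding <- binding_spec(
      KD = runif_log(1e-3, 10),
      valence = sample(c("monovalent", "bivalent"), 1))
    scn <- scenario(pk, soa, target, binding,
                    name = sprintf("random-%d", seed))
    ok <- tryCatch({ derive_rates(scn); TRUE },
                   soa_parametrization_error = function(e) FALSE)
    if (ok) return(scn)
  }
  stop_soa("rejection sampling failed to find a valid scenario",
           class = "soa_error")
}
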