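## Coverage ("neutralization") is defined on FREE target: 1 - T(t)/T0.
## Total-target accumulation is reported separately via total_target().

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

window_idx <- function(tc, window) {
  which(tc$data$time >= window[1] - 1e-9 & tc$data$time <= window[2] + 1e-9)
}

#' Free-target coverage of a time course
#'
#' Coverage (neutralization) at time t is `1 - T(t)/T0` on the free target
#' of the requested compartment. Summary statistics (peak, trough, time
#' above a threshold) are computed over the steady-state cycle when the
#' time course carries one (see [simulate_to_steady_state()]), otherwise
#' over the whole course. The trough statistic is the coverage at the last
#' pre-dose time of the summary window; the peak is the maximum over it.
#'
#' Coverage can transiently go below zero when a competitor displaces target
#' back into the free pool; such series are flagged rather than clipped.
#'
#' @param tc A `soa_timecourse`.
#' @param compartment `"plasma"` or `"soa"`.
#' @param baseline Baseline free-target concentration (nM); defaults to the
#'   scenario baseline of the compartment. A zero baseline is an error.
#' @param threshold Coverage threshold for the time-above statistic.
#' @return An object of class `soa_coverage`: list with `series` (data.frame
#'   time, coverage), `summary` (peak, trough, time_above_days), `window`,
#'   `compartment`, `baseline` and a `negative` flag.
#' @export
coverage <- function(tc, compartment = c("plasma", "soa"), baseline = NULL,
                     threshold = 0.9) {
  stopifnot(inherits(tc, "soa_timecourse"))
  compartment <- match.arg(compartment)
  species <- if (compartment == "plasma") "TP" else "TS"
  if (!species %in% tc$species) {
    stop_soa(sprintf("species %s not present in this time course", species),
             class = "soa_configuration_error")
  }
  if (is.null(baseline)) baseline <- unname(tc$baselines[compartment])
  if (!is.numeric(baseline) || baseline <= 0) {
    stop_soa("coverage is undefined for a zero target baseline",
             class = "soa_configuration_error")
  }
  cov <- 1 - tc$data[[species]] / baseline
  window <- if (!is.null(tc$ss_cycle)) tc$ss_cycle else range(tc$data$time)
  i <- window_idx(tc, window)
  tw <- tc$data$time[i]
  cw <- cov[i]
  above <- cw >= threshold
  time_above <- if (any(above)) trapz(tw, as.numeric(above)) else 0
  structure(list(
    series = data.frame(time = tc$data$time, coverage = cov),
    summary = list(peak = max(cw), trough = cw[length(cw)],
                   time_above_days = time_above, threshold = threshold),
    window = window, compartment = compartment, baseline = baseline,
    negative = any(cov < -1e-9)),
    class = "soa_coverage")
}

#' @export
print.soa_coverage <- function(x, ...) {
  cat(sprintf(
    "<soa_coverage %s> peak %.1f%%, trough %.1f%%, %.1f d above %.0f%% (window [%g, %g])\n",
    x$compartment, 100 * x$summary$peak, 100 * x$summary$trough,
    x$summary$time_above_days, 100 * x$summary$threshold,
    x$window[1], x$window[2]))
  if (x$negative) cat("  note: coverage transiently negative (displacement)\n")
  invisible(x)
}

#' Steady-state AUC ratio of total drug, SoA over plasma
#'
#' Trapezoidal AUCs of total drug (free plus complexed, each antibody
#' counted once) over the steady-state dosing cycle. With binding switched
#' off this recovers the `ratio` parameter of the drug-distribution closure.
#'
#' @param tc A `soa_timecourse` carrying a steady-state cycle.
#' @return Dimensionless AUC ratio.
#' @export
auc_ratio <- function(tc) {
  stopifnot(inherits(tc, "soa_timecourse"))
  if (is.null(tc$ss_cycle)) {
    stop_soa("auc_ratio requires a steady-state cycle; ",
             "use simulate_to_steady_state()", class = "soa_configuration_error")
  }
  i <- window_idx(tc, tc$ss_cycle)
  t <- tc$data$time[i]
  auc_p <- trapz(t, total_drug(tc, "plasma")[i])
  if (auc_p == 0) {
    stop_soa("plasma drug AUC is zero", class = "soa_configuration_error")
  }
  trapz(t, total_drug(tc, "soa")[i]) / auc_p
}

ss_coverage_stat <- function(scn, regimen, statistic, compartment, ...) {
  tc <- simulate_to_steady_state(soa_model(scn), regimen, ...)
  cv <- coverage(tc, compartment)
  cv$summary[[statistic]]
}

#' Affinity required for a coverage threshold
#'
#' Finds, by bisection on log10(KD), the weakest (largest) dissociation
#' constant whose steady-state coverage statistic still meets `threshold`,
#' to two significant figures. The on-rate stays fixed while the off-rate
#' varies with KD, mirroring how affinity maturation is modeled. Coverage is
#' assumed monotone non-increasing in KD over the bracket; the bracket ends
#' are checked and a violation raises an error.
#'
#' @param scn A [scenario()] object.
#' @param regimen A [dose_regimen()].
#' @param threshold Coverage fraction to reach (e.g. 0.90).
#' @param statistic `"trough"` (conservative, default) or `"peak"`.
#' @param compartment `"soa"` or `"plasma"`; defaults to `"soa"` when the
#'   scenario has an SoA target baseline, else `"plasma"`.
#' @param bracket KD search bracket in nM (default 1e-5 to 1e3).
#' @param ... Passed to the steady-state simulation.
#' @return A list of class `soa_affinity`: `KD_nM`, `status` (`"ok"`,
#'   `"any"` when even the weakest bracket end meets the threshold or the
#'   threshold is not positive, `"unachievable"` when the tightest end
#'   fails), and `coverage` (confirmation statistic at the returned KD).
#' @export
required_affinity <- function(scn, regimen, threshold,
                              statistic = c("trough", "peak"),
                              compartment = NULL, bracket = c(1e-5, 1e3),
                              ...) {
  stopifnot(inherits(scn, "soa_scenario"))
  statistic <- match.arg(statistic)
  if (is.null(compartment)) {
    compartment <- if (scn$target$TS0 > 0) "soa" else "plasma"
  }
  eval_kd <- function(kd) {
    ss_coverage_stat(set_affinity(scn, kd), regimen, statistic, compartment, ...)
  }
  if (threshold <= 0) {
    return(structure(list(KD_nM = bracket[2], status = "any",
                          coverage = NA_real_, statistic = statistic,
                          threshold = threshold, compartment = compartment),
                     class = "soa_affinity"))
  }
  f_hi <- eval_kd(bracket[2])
  if (f_hi >= threshold) {
    return(structure(list(KD_nM = bracket[2], status = "any", coverage = f_hi,
                          statistic = statistic, threshold = threshold,
                          compartment = compartment),
                     class = "soa_affinity"))
  }
  f_lo <- eval_kd(bracket[1])
  if (f_lo < threshold) {
    return(structure(list(KD_nM = NA_real_, status = "unachievable",
                          coverage = f_lo, statistic = statistic,
                          threshold = threshold, compartment = compartment),
                     class = "soa_affinity"))
  }
  if (f_lo < f_hi) {
    stop_soa("coverage is not monotone non-increasing in KD across the ",
             "bracket; check the model configuration",
             class = "soa_configuration_error")
  }
  lo <- log10(bracket[1])  # meets threshold
  hi <- log10(bracket[2])  # fails threshold
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (eval_kd(10^mid) >= threshold) lo <- mid else hi <- mid
  }
  kd <- signif(10^lo, 2)
  cov_kd <- eval_kd(kd)
  if (cov_kd < threshold) {  # rounding pushed KD past the boundary
    kd <- signif(10^(lo - 0.01), 2)
    cov_kd <- eval_kd(kd)
  }
  structure(list(KD_nM = kd, status = "ok", coverage = cov_kd,
                 statistic = statistic, threshold = threshold,
                 compartment = compartment),
            class = "soa_affinity")
}

#' @export
print.soa_affinity <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "<soa_affinity> KD = %g nM (%g pM) gives %s %s coverage %.3f >= %.2f\n",
      x$KD_nM, 1000 * x$KD_nM, x$compartment, x$statistic, x$coverage,
      x$threshold))
  } else {
    cat(sprintf("<soa_affinity> status: %s (threshold %.3g, %s %s)\n",
                x$status, x$threshold, x$compartment, x$statistic))
  }
  invisible(x)
}

#' Coverage sweep over affinity or dose
#'
#' Runs one steady-state simulation per value of the chosen axis and
#' tabulates the coverage summary. Per-point failures are recorded in the
#' `status` column rather than aborting the sweep.
#'
#' @param scn A [scenario()] object.
#' @param regimen A [dose_regimen()].
#' @param axis `"KD"` (nM) or `"dose"` (same unit as the regimen amount).
#' @param values Positive finite axis values.
#' @param compartment `"soa"` or `"plasma"` (default as in
#'   [required_affinity()]).
#' @param threshold Threshold for the time-above statistic.
#' @param ... Passed to the steady-state simulation.
#' @return A data.frame with one row per value: `axis`, `value`, `peak`,
#'   `trough`, `time_above_days`, `converged`, `status`.
#' @export
coverage_sweep <- function(scn, regimen, axis = c("KD", "dose"), values,
                           compartment = NULL, threshold = 0.9, ...) {
  stopifnot(inherits(scn, "soa_scenario"))
  axis <- match.arg(axis)
  if (any(!is.finite(values)) ||
      (axis == "KD" && any(values <= 0)) || any(values < 0)) {
    stop_soa("sweep values must be finite and positive",
             class = "soa_validation_error")
  }
  if (is.null(compartment)) {
    compartment <- if (scn$target$TS0 > 0) "soa" else "plasma"
  }
  rows <- lapply(values, function(v) {
    res <- tryCatch({
      scn_v <- scn
      reg_v <- regimen
      if (axis == "KD") scn_v <- set_affinity(scn, v) else reg_v$amount <- v
      if (axis == "dose" && v == 0) {
        ## no drug: coverage identically zero, no steady-state search needed
        return(data.frame(axis = axis, value = v, peak = 0, trough = 0,
                          time_above_days = 0, converged = TRUE,
                          status = "ok"))
      }
      tc <- simulate_to_steady_state(soa_model(scn_v), reg_v, ...)
      cv <- coverage(tc, compartment, threshold = threshold)
      data.frame(axis = axis, value = v, peak = cv$summary$peak,
                 trough = cv$summary$trough,
                 time_above_days = cv$summary$time_above_days,
                 converged = tc$converged, status = "ok")
    }, error = function(e) {
      data.frame(axis = axis, value = v, peak = NA_real_, trough = NA_real_,
                 time_above_days = NA_real_, converged = NA,
                 status = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "monotone_in_value") <-
    all(diff(out$trough[order(out$value)]) * (if (axis == "KD") -1 else 1) >=
          -1e-6, na.rm = TRUE)
  out
}

## Scenario perturbation helper for sensitivity analysis. `param` addresses a
## scalar input by name; derived rates are recomputed from scratch.
perturb_scenario <- function(scn, regimen, param, factor) {
  reg <- regimen
  if (param == "dose") {
    reg$amount <- reg$amount * factor
    return(list(scn = scn, regimen = reg))
  }
  section <- c(VP = "pk", V2 = "pk", Cl = "pk", Q = "pk", ka = "pk", F = "pk",
               VS = "soa", ratio = "soa",
               TP0 = "target", TS0 = "target", kdegTp = "target",
               kdegTs = "target", frac = "target", Qtarget = "target",
               KD = "binding", kon = "binding", kelC = "binding",
               S0 = "competitor")[param]
  if (is.na(section)) {
    stop_soa(sprintf("unknown sensitivity parameter '%s'", param),
             class = "soa_validation_error")
  }
  if (section == "binding") {
    b <- scn$binding
    val <- b[[param]] * factor
    scn$binding <- binding_spec(
      KD = if (param == "KD") val else b$KD,
      kon = if (param == "kon") val else b$kon,
      kelC = if (param == "kelC") val else b$kelC,
      valence = b$valence)
  } else {
    scn[[section]][[param]] <- scn[[section]][[param]] * factor
    ## re-run the constructor checks
    scn[[section]] <- do.call(
      switch(section, pk = pk_parameters, soa = soa_geometry,
             target = target_spec, competitor = competitor_spec),
      unclass(scn[[section]])[setdiff(names(scn[[section]]),
                                      c("koff"))])
  }
  list(scn = scn, regimen = regimen)
}

#' Local sensitivity of trough coverage
#'
#' Central-difference sensitivities `d log(odds) / d log(p)` of the
#' steady-state trough coverage (expressed as odds `c/(1-c)` so that the
#' measure stays informative near full coverage) with respect to scalar
#' inputs. Each parameter requires two full re-parametrized simulations;
#' derived rates are recomputed for every perturbation, so the closure
#' constraints are honoured throughout.
#'
#' @param scn A [scenario()] object.
#' @param regimen A [dose_regimen()].
#' @param parameters Character vector of input names: any of `VP`, `V2`,
#'   `Cl`, `Q`, `ka`, `F`, `VS`, `ratio`, `TP0`, `TS0`, `kdegTp`, `kdegTs`,
#'   `frac`, `Qtarget`, `KD`, `kon`, `kelC`, `S0`, `dose`.
#' @param perturbation Relative perturbation, in (0, 0.5].
#' @param compartment Coverage compartment (default as in
#'   [required_affinity()]).
#' @param ... Passed to the steady-state simulation.
#' @return A data.frame with `parameter`, `sensitivity`, `status`; rows whose
#'   perturbed scenario is invalid are marked rather than fatal.
#' @export
local_sensitivity <- function(scn, regimen, parameters, perturbation = 0.05,
                              compartment = NULL, ...) {
  stopifnot(inherits(scn, "soa_scenario"))
  check_scalar(perturbation, "perturbation", 0, upper = 0.5,
               strict_lower = TRUE)
  if (is.null(compartment)) {
    compartment <- if (scn$target$TS0 > 0) "soa" else "plasma"
  }
  odds <- function(c) c / (1 - c)
  stat_of <- function(mod) {
    ss_coverage_stat(mod$scn, mod$regimen, "trough", compartment, ...)
  }
  rows <- lapply(parameters, function(p) {
    tryCatch({
      up <- stat_of(perturb_scenario(scn, regimen, p, 1 + perturbation))
      dn <- stat_of(perturb_scenario(scn, regimen, p, 1 - perturbation))
      s <- (log(odds(up)) - log(odds(dn))) /
        (log(1 + perturbation) - log(1 - perturbation))
      data.frame(parameter = p, sensitivity = s, status = "ok")
    }, error = function(e) {
      data.frame(parameter = p, sensitivity = NA_real_,
                 status = conditionMessage(e))
    })
  })
  do.call(rbind, rows)
}

#' Write a sweep or sensitivity table to CSV
#'
#' @param x A data.frame as returned by [coverage_sweep()] or
#'   [local_sensitivity()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
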