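#' Bundle-sheath leakiness time course
#'
#' Leakiness is the fraction of the CO2 delivered to the bundle sheath by
#' the C4 cycle that diffuses back to the mesophyll:
#' `phi = v_CO2_leak / v_PEPC`. It is reported as 0 where the PEPC flux is
#' below a floor (darkness), to avoid a 0/0 artefact.
#'
#' @param result a `c4_sim` tibble from [c4_simulate()] or [run_scenario()].
#' @param floor minimum PEPC flux (umol m-2 s-1) for phi to be reported.
#' @return tibble with `time_s` and `phi`.
#' @export
leakiness <- function(result, floor = 0.1) {
  stopifnot(all(c("time_s", "v_co2_leak", "v_pepc") %in% names(result)))
  tibble(time_s = result$time_s,
         phi = ifelse(result$v_pepc > floor,
                      result$v_co2_leak / result$v_pepc, 0))
}

#' Induction summary metrics
#'
#' Summarises a dark-to-light induction simulation: the time to reach 50%
#' of the steady-state net CO2 uptake (IT50, by linear interpolation), the
#' percentage reduction of the induction-average uptake relative to steady
#' state, the minimum intercellular CO2 after light-on and the intrinsic
#' water-use efficiency series A/gs. "Steady state" is the mean over the
#' final `steady_window_min` minutes.
#'
#' @param result a `c4_sim` covering the induction (light-on at t = 0).
#' @param steady_window_min width of the steady-state window (min).
#' @return list of class `c4_induction_metrics`: `it50_s`,
#'   `mean_a_reduction_pct`, `min_ci`, `a_steady`, and `iwue` (a tibble).
#' @export
induction_metrics <- function(result, steady_window_min = 5) {
  t <- result$time_s
  a <- result$A
  t_end <- t[length(t)]
  in_tail <- t >= t_end - steady_window_min * 60
  a_steady <- mean(a[in_tail])
  if (!is.finite(a_steady) || a_steady <= 0) {
    abort("no identifiable positive steady-state A",
          class = "c4dyn_domain_error")
  }
  half <- 0.5 * a_steady
  it50 <- if (a[1] >= half) 0 else {
    i <- which(a >= half)[1]
    if (is.na(i)) {
      abort("A never reaches 50% of its steady state",
            class = "c4dyn_domain_error")
    }
    # linear interpolation between the bracketing samples
    t[i - 1] + (half - a[i - 1]) / (a[i] - a[i - 1]) * (t[i] - t[i - 1])
  }
  mean_a <- mean(a[t >= 0])
  reduction <- 100 * (1 - mean_a / a_steady)
  structure(list(
    it50_s = it50,
    mean_a_reduction_pct = max(reduction, 0),
    min_ci = min(result$ci[t >= 0]),
    a_steady = a_steady,
    iwue = tibble(time_s = t, iwue = a / result$gs)
  ), class = "c4_induction_metrics")
}

#' @export
print.c4_induction_metrics <- function(x, ...) {
  cat("Induction metrics\n")
  cat(sprintf("  IT50             %.1f s\n", x$it50_s))
  cat(sprintf("  mean A reduction %.1f %%\n", x$mean_a_reduction_pct))
  cat(sprintf("  minimum Ci       %.1f umol mol-1\n", x$min_ci))
  cat(sprintf("  steady-state A   %.2f umol m-2 s-1\n", x$a_steady))
  invisible(x)
}

#' Time-resolved sensitivity coefficient of A to a species parameter
#'
#' Central-difference relative sensitivity: the parameter is perturbed by
#' +/-1% and the coefficient at each output time is
#' `(A+ - A-) / (0.02 A)`, where A is the unperturbed series. A value of 1
#' means a 1% change in the parameter changes A by 1%; 0 means no control.
#'
#' @param param name of a species-level parameter (e.g. `"pdrp"`,
#'   `"tau_rubisco"`, `"gs_ki"`).
#' @param params base parameter set from [c4_params()].
#' @param forcing forcing object (default induction step).
#' @param duration simulated time (s).
#' @param scenario regulation scenario (default: full model).
#' @param base_sim optional precomputed unperturbed simulation (reused
#'   across parameters).
#' @param rel_step relative perturbation (default 0.01).
#' @param ... passed to [c4_simulate()].
#' @return tibble with `time_s`, `sc` and `param`.
#' @export
sensitivity_coefficient <- function(param, params,
                                    forcing = forcing_induction(),
                                    duration = 1800,
                                    scenario = c4_scenario(6),
                                    base_sim = NULL, rel_step = 0.01, ...) {
  if (!param %in% names(params) || !is.numeric(params[[param]])) {
    abort(paste0("unknown or non-numeric parameter: ", param),
          class = "c4dyn_config_error")
  }
  perturbed <- function(mult) {
    sp <- params[c("species", "slope_bb", "intercept_bb", "gs_ki", "gs_kd",
                   "vpmax", "vcmax", "tau_rubisco", "f_vmpepc",
                   "f_vmrubisco", "pdrp", "rd")]
    sp[[param]] <- sp[[param]] * mult
    c4_params(sp, network = network_of(params))
  }
  init <- dark_adapt(params)
  if (is.null(base_sim)) {
    base_sim <- c4_simulate(params, forcing, duration, init = init,
                            scenario = scenario, pre_adapt = FALSE, ...)
  }
  run <- function(mult) {
    p <- perturbed(mult)
    c4_simulate(p, forcing, duration, init = dark_adapt(p),
                scenario = scenario, pre_adapt = FALSE, ...)
  }
  up <- run(1 + rel_step)
  dn <- run(1 - rel_step)
  sc <- (up$A - dn$A) / (2 * rel_step * base_sim$A)
  sc[abs(base_sim$A) < 1e-9] <- 0
  tibble(time_s = base_sim$time_s, sc = sc, param = param)
}

#' Time-resolved flux control coefficient of an enzyme
#'
#' The same central-difference formula as [sensitivity_coefficient()],
#' applied to the maximal activity (Vmax) of a single enzyme of the
#' network. A coefficient of 1 means full control of net CO2 uptake by
#' that step; 0 means none.
#'
#' @param enzyme one of `pepc, ppdk, mdh, me, mutase_enolase, rubisco,
#'   gapdh, sbpase, fbpase, prk`.
#' @inheritParams sensitivity_coefficient
#' @return tibble with `time_s`, `fcc` and `enzyme`.
#' @export
flux_control_coefficient <- function(enzyme, params,
                                     forcing = forcing_induction(),
                                     duration = 1800,
                                     scenario = c4_scenario(6),
                                     base_sim = NULL, rel_step = 0.01, ...) {
  allowed <- setdiff(ACTIVITY_NAMES, "atpase")
  if (!enzyme %in% allowed) {
    abort(paste0("unknown enzyme: ", enzyme, " (one of ",
                 paste(allowed, collapse = ", "), ")"),
          class = "c4dyn_config_error")
  }
  init <- dark_adapt(params)
  if (is.null(base_sim)) {
    base_sim <- c4_simulate(params, forcing, duration, init = init,
                            scenario = scenario, pre_adapt = FALSE, ...)
  }
  run <- function(mult) {
    p <- params
    p$vmax_mult <- setNames(mult, enzyme)
    c4_simulate(p, forcing, duration, init = init, scenario = scenario,
                pre_adapt = FALSE, ...)
  }
  up <- run(1 + rel_step)
  dn <- run(1 - rel_step)
  fcc <- (up$A - dn$A) / (2 * rel_step * base_sim$A)
  fcc[abs(base_sim$A) < 1e-9] <- 0
  tibble(time_s = base_sim$time_s, fcc = fcc, enzyme = enzyme)
}
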