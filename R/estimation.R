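# Parameter estimation from gas-exchange data.
#
# Every estimator is a round trip against the generators in this package:
# parameters used to produce noise-free synthetic data are recovered to
# numerical precision.

# accept either the instrument CSV dialect (A, Ci, Ca, PAR, Tleaf, RH) or
# lower-case names; returns a tibble with canonical lower-case columns
normalize_series <- function(x) {
  x <- as_tibble(x)
  map <- c(A = "a", Ci = "ci", Ca = "ca", PAR = "par", Tleaf = "tleaf",
           RH = "rh", gs = "gs", time_s = "time_s", ca_set = "ca_set",
           par_set = "par_set")
  for (nm in names(map)) {
    if (nm %in% names(x) && !(map[[nm]] %in% names(x))) {
      names(x)[names(x) == nm] <- map[[nm]]
    }
  }
  x
}

#' Enzyme-limited C4 A-Ci forward model
#'
#' Simplified enzyme-limited net assimilation for a C4 leaf at saturating
#' light: the minimum of the PEP-carboxylation-limited rate
#' `Vpmax Ci / (Ci + Kp) + gbs Ci - Rm` and the Rubisco-limited plateau
#' `Vcmax`, minus day respiration. Used for A-Ci curve fitting and for
#' fixture generation.
#'
#' @param ci intercellular CO2 (umol mol-1, ~ ubar).
#' @param vpmax,vcmax maximal PEPC and Rubisco activities (umol m-2 s-1).
#' @param rd day respiration (umol m-2 s-1); the mesophyll share is
#'   `rm = 0.5 rd`.
#' @param kp PEPC Michaelis constant for CO2 (ubar).
#' @param gbs bundle-sheath CO2 conductance (mol m-2 s-1).
#' @return net CO2 uptake (umol m-2 s-1).
#' @export
aci_forward <- function(ci, vpmax, vcmax, rd = 1, kp = 80, gbs = 0.003) {
  rm <- 0.5 * rd
  pmin(vpmax * ci / (ci + kp) + gbs * ci - rm, vcmax) - rd
}

#' Fit Vpmax and Vcmax to an A-Ci curve
#'
#' Nonlinear least squares of the enzyme-limited C4 model
#' ([aci_forward()]): Vpmax is identified by the initial-slope (PEP
#' carboxylation limited) region and Vcmax by the CO2-saturated plateau.
#' The curve must cover both regions.
#'
#' @param curve data frame with columns `Ci` (or `ci`) and `A` (or `a`);
#'   an optional `ca_set` column (the CO2 setpoint sequence) is used to
#'   delimit the two regions as in the measurement protocol.
#' @param rd day respiration used in the model (umol m-2 s-1).
#' @param kp,gbs model constants, see [aci_forward()].
#' @return object of class `c4_aci_fit` with elements `vpmax`, `vcmax`,
#'   their standard errors, `rss`, `n` and the `nls` fit.
#' @export
#' @examples
#' ci <- c(300, 220, 150, 90, 50, 28, 14, 7, 300, 450, 600, 900, 1100)
#' curve <- data.frame(Ci = ci, A = aci_forward(ci, 120, 60))
#' fit_aci(curve)
fit_aci <- function(curve, rd = 1, kp = 80, gbs = 0.003) {
  d <- normalize_series(curve)
  stopifnot(all(c("ci", "a") %in% names(d)))
  d <- d[is.finite(d$ci) & is.finite(d$a), ]
  slope_rows <- if ("ca_set" %in% names(d)) d$ca_set <= 120 else d$ci <= 100
  plateau_rows <- if ("ca_set" %in% names(d)) d$ca_set >= 800 else d$ci >= 500
  if (sum(slope_rows) < 3) {
    abort("A-Ci curve lacks an initial-slope (low CO2) region",
          class = "c4dyn_fit_error")
  }
  if (sum(plateau_rows) < 1) {
    abort("A-Ci curve lacks a CO2-saturated plateau region",
          class = "c4dyn_fit_error")
  }
  if (stats::cor(d$a, d$ci) < 0) {
    abort("A decreases with Ci; not an A-Ci response", class = "c4dyn_fit_error")
  }
  start <- list(
    vpmax = max((d$a[slope_rows] + rd) * (d$ci[slope_rows] + kp) /
                  pmax(d$ci[slope_rows], 1)),
    vcmax = max(d$a) + rd)
  fit <- minpack.lm::nlsLM(
    a ~ pmin(vpmax * ci / (ci + kp) + gbs * ci - 0.5 * rd, vcmax) - rd,
    data = d, start = start, lower = c(1, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vpmax = NA_real_, vcmax = NA_real_))
  structure(list(vpmax = unname(cf["vpmax"]), vcmax = unname(cf["vcmax"]),
                 se_vpmax = unname(se["vpmax"]), se_vcmax = unname(se["vcmax"]),
                 rss = sum(residuals(fit)^2), n = nrow(d), fit = fit),
            class = "c4_aci_fit")
}

#' @export
print.c4_aci_fit <- function(x, ...) {
  cat("C4 A-Ci fit (enzyme-limited)\n")
  cat(sprintf("  Vpmax = %.2f (se %.2g)  Vcmax = %.2f (se %.2g) umol m-2 s-1\n",
              x$vpmax, x$se_vpmax, x$vcmax, x$se_vcmax))
  invisible(x)
}

#' Fit Ball-Berry slope and intercept from an A-Q curve
#'
#' Ordinary least-squares regression of steady-state stomatal conductance
#' on the Ball-Berry index `A RH / Ca` across the light-response levels.
#'
#' @param curve data frame with columns `gs`, `A`, `RH`, `Ca` (case as in
#'   the instrument export, lower case accepted).
#' @return object of class `c4_bb_fit` with `slope_bb`, `intercept_bb`,
#'   standard errors, `r_squared`, `n` and the `lm` fit.
#' @export
fit_ball_berry <- function(curve) {
  d <- normalize_series(curve)
  stopifnot(all(c("gs", "a", "rh", "ca") %in% names(d)))
  if (nrow(d) < 2) {
    abort("Ball-Berry regression needs at least 2 points",
          class = "c4dyn_fit_error")
  }
  d$bb_index <- d$a * d$rh / d$ca
  fit <- lm(gs ~ bb_index, data = d)
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(slope_bb = unname(cf["bb_index"]),
                 intercept_bb = unname(cf["(Intercept)"]),
                 se_slope = unname(se["bb_index"]),
                 se_intercept = unname(se["(Intercept)"]),
                 r_squared = summary(fit)$r.squared, n = nrow(d), fit = fit),
            class = "c4_bb_fit")
}

#' @export
print.c4_bb_fit <- function(x, ...) {
  cat("Ball-Berry regression\n")
  cat(sprintf("  slope = %.3f (se %.2g)  intercept = %.4f (se %.2g)\n",
              x$slope_bb, x$se_slope, x$intercept_bb, x$se_intercept))
  cat(sprintf("  R^2 = %.4f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Rubisco activation time constant from the semilog induction slope
#'
#' The approach of A to its final steady state during induction is
#' exponential with the Rubisco activation time constant. `ln(A_f - A(t))`
#' is regressed on time over the 3-7 min window; `tau = -1/slope`. `A_f`
#' is the mean of the final `steady_window_min` minutes. Points where
#' `A_f - A <= 0` are dropped; if more than half of the window is dropped
#' the estimate is refused.
#'
#' @param series induction time series with columns `time_s` and `A`
#'   (10-s sampling, t = 0 at light-on).
#' @param window_min regression window, minutes after light-on.
#' @param steady_window_min width of the final-steady-state window (min).
#' @return list of class `c4_tau_fit`: `tau_min`, `r_squared`, `a_final`,
#'   `n_used`.
#' @export
estimate_tau_rubisco <- function(series, window_min = c(3, 7),
                                 steady_window_min = 5) {
  d <- normalize_series(series)
  stopifnot(all(c("time_s", "a") %in% names(d)))
  d <- d[d$time_s >= 0, ]
  t_end <- max(d$time_s)
  a_f <- mean(d$a[d$time_s >= t_end - steady_window_min * 60])
  win <- d[d$time_s >= window_min[1] * 60 & d$time_s <= window_min[2] * 60, ]
  if (nrow(win) < 4) {
    abort("induction series has too few points in the regression window",
          class = "c4dyn_fit_error")
  }
  diff_a <- a_f - win$a
  keep <- diff_a > 0
  if (mean(keep) < 0.5) {
    abort("A_f - A(t) non-positive over most of the window; tau unidentifiable",
          class = "c4dyn_fit_error")
  }
  t_min <- win$time_s[keep] / 60
  fit <- lm(log(diff_a[keep]) ~ t_min)
  slope <- coef(fit)[["t_min"]]
  if (slope >= 0) {
    abort("semilog slope is non-negative; no exponential approach",
          class = "c4dyn_fit_error")
  }
  structure(list(tau_min = -1 / slope,
                 r_squared = summary(fit)$r.squared,
                 a_final = a_f, n_used = sum(keep)),
            class = "c4_tau_fit")
}

#' @export
print.c4_tau_fit <- function(x, ...) {
  cat(sprintf("tau_Rubisco = %.3f min (R^2 %.4f, n = %d, A_f = %.2f)\n",
              x$tau_min, x$r_squared, x$n_used, x$a_final))
  invisible(x)
}

#' Dark respiration from the dark-adapted CO2 efflux
#'
#' `Rd = -mean(A)` over the dark tail of a gas-exchange record (at least
#' one minute of steady darkness). Positive A in darkness is physically
#' suspect and flagged with a warning.
#'
#' @param dark_tail data frame with column `A` (and optionally `time_s`)
#'   recorded in darkness.
#' @return list with `rd` (umol m-2 s-1), `se` and `n`.
#' @export
estimate_rd <- function(dark_tail) {
  d <- normalize_series(dark_tail)
  stopifnot("a" %in% names(d))
  if (nrow(d) < 6) {
    abort("dark tail too short (need >= 1 min of records)",
          class = "c4dyn_fit_error")
  }
  m <- mean(d$a)
  if (m > 0) {
    warn("positive net CO2 uptake in darkness; Rd estimate is suspect")
  }
  list(rd = -m, se = sd(d$a) / sqrt(nrow(d)), n = nrow(d))
}

#' Estimate PPDK regulatory protein content from early induction
#'
#' One-dimensional least squares over the PDRP content: the dynamic model
#' is simulated through the 1-3 min window of a dark-to-high-light
#' induction for candidate PDRP values and the sum of squared deviations
#' from the measured A is minimised by bracketed scalar minimisation.
#'
#' @param series induction series with `time_s` and `A`.
#' @param params species parameter set ([c4_params()]); all parameters
#'   other than PDRP are held fixed.
#' @param window_s fitting window (s after light-on), default 60-180.
#' @param bracket search bracket for PDRP (umol m-2).
#' @param model_fun optional function `f(pdrp)` returning a data frame
#'   `time_s`, `A` of model predictions covering the window; by default the
#'   dynamic model is simulated (one shared dark adaptation, since the
#'   dark-adapted state does not depend on the PDRP content).
#' @param n_grid grid size for the unimodality/flatness diagnostic.
#' @return list of class `c4_pdrp_fit`: `pdrp`, `objective`, `flat`
#'   (logical), `grid` (tibble of the scanned objective).
#' @export
estimate_pdrp <- function(series, params, window_s = c(60, 180),
                          bracket = c(0.005, 0.25), model_fun = NULL,
                          n_grid = 9) {
  d <- normalize_series(series)
  stopifnot(all(c("time_s", "a") %in% names(d)))
  win <- d[d$time_s >= window_s[1] & d$time_s <= window_s[2], ]
  if (nrow(win) < 4) {
    abort("too few points in the PDRP fitting window",
          class = "c4dyn_fit_error")
  }
  if (sd(win$a) < 1e-10) {
    abort("A has zero variance in the fitting window; PDRP unidentifiable",
          class = "c4dyn_degenerate_error")
  }
  if (is.null(model_fun)) {
    init <- dark_adapt(params)
    model_fun <- function(pdrp) {
      p <- c4_params(within_species(params, pdrp = pdrp),
                     network = network_of(params))
      sim <- c4_simulate(p, forcing_induction(), duration = window_s[2] + 20,
                         init = init, scenario = c4_scenario(6),
                         pre_adapt = FALSE, dt_out = 5)
      sim[, c("time_s", "A")]
    }
  }
  objective <- function(pdrp) {
    pred <- model_fun(pdrp)
    a_hat <- approx(pred$time_s, pred$A, xout = win$time_s, rule = 2)$y
    sum((a_hat - win$a)^2)
  }
  grid_x <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_grid))
  grid_y <- vapply(grid_x, objective, 0)
  opt <- optimize(objective, interval = bracket, tol = 1e-4)
  flat <- diff(range(grid_y)) < 1e-6 * max(grid_y, 1e-12)
  if (flat) {
    warn(paste0("PDRP objective is flat over the bracket [",
                bracket[1], ", ", bracket[2],
                "]; the estimate has a wide confidence interval"))
  }
  structure(list(pdrp = opt$minimum, objective = opt$objective, flat = flat,
                 grid = tibble(pdrp = grid_x, objective = grid_y)),
            class = "c4_pdrp_fit")
}

#' @export
print.c4_pdrp_fit <- function(x, ...) {
  cat(sprintf("[PDRP] = %.4f umol m-2 (SSE %.4g%s)\n", x$pdrp, x$objective,
              if (x$flat) ", FLAT objective" else ""))
  invisible(x)
}

# the network sections embedded in a c4_params object
network_of <- function(params) {
  params[names(c4dyn_env_schema_names())]
}

c4dyn_env_schema_names <- function() .network_schema

# rebuild the species-parameter list embedded in a c4_params object with
# field overrides
within_species <- function(params, ...) {
  sp <- params[c("species", "slope_bb", "intercept_bb", "gs_ki", "gs_kd",
                 "vpmax", "vcmax", "tau_rubisco", "f_vmpepc", "f_vmrubisco",
                 "pdrp", "rd")]
  dots <- list(...)
  for (nm in names(dots)) sp[[nm]] <- dots[[nm]]
  sp
}

#' Estimate the capacity scalars f_VmPEPC and f_VmRubisco
#'
#' The measured Vpmax and Vcmax relate to the model's theoretical maximal
#' PEPC and Rubisco activities through two scalars:
#' `Vmax_PEPC = Vpmax / f_VmPEPC` and `Vmax_Rubisco = Vcmax / f_VmRubisco`
#' (all other C4- and C3-cycle capacities scale along). Each scalar is
#' estimated by minimising the squared mismatch between model steady-state
#' A (simulated at the measured Ci, stomata bypassed) and measured A:
#' f_VmPEPC over the initial-slope points (CO2 setpoints 120-10
#' umol mol-1), f_VmRubisco over the CO2-saturated points (800-1500).
#'
#' @param curve A-Ci curve with columns `ca_set`, `Ci`, `A`.
#' @param params species parameter set providing Vpmax, Vcmax and all
#'   fixed inputs.
#' @param bounds search interval for both scalars.
#' @param n_pass alternating passes (the two scalars interact weakly).
#' @param sim_s steady-state simulation length per CO2 level (s).
#' @return list with `f_vmpepc`, `f_vmrubisco` and the per-region residual
#'   sums of squares.
#' @export
estimate_f_scalars <- function(curve, params, bounds = c(0.3, 1.5),
                               n_pass = 2, sim_s = 900) {
  d <- normalize_series(curve)
  stopifnot(all(c("ca_set", "ci", "a") %in% names(d)))
  slope_d <- d[d$ca_set <= 120 & d$ca_set >= 10, ]
  plat_d <- d[d$ca_set >= 800, ]
  if (nrow(slope_d) < 2 || nrow(plat_d) < 2) {
    abort("A-Ci curve must cover both the initial slope and the plateau",
          class = "c4dyn_fit_error")
  }
  f_p <- params$f_vmpepc
  f_c <- params$f_vmrubisco
  model_a <- function(f_p, f_c, ci_vec, gs_vec) {
    p <- c4_params(within_species(params, f_vmpepc = f_p, f_vmrubisco = f_c),
                    network = network_of(params))
    state <- NULL
    vapply(seq_along(ci_vec), function(i) {
      ss <- steady_state_a(p, ci_vec[i], init = state, duration = sim_s,
                           gs = gs_vec[i])
      state <<- ss$state
      ss$a
    }, 0)
  }
  gs_slope <- if ("gs" %in% names(slope_d)) slope_d$gs else rep(0.3, nrow(slope_d))
  gs_plat <- if ("gs" %in% names(plat_d)) plat_d$gs else rep(0.3, nrow(plat_d))
  obj_p <- function(f) sum((model_a(f, f_c, slope_d$ci, gs_slope) - slope_d$a)^2)
  obj_c <- function(f) sum((model_a(f_p, f, plat_d$ci, gs_plat) - plat_d$a)^2)
  for (i in seq_len(n_pass)) {
    f_p <- optimize(obj_p, interval = bounds, tol = 1e-3)$minimum
    f_c <- optimize(obj_c, interval = bounds, tol = 1e-3)$minimum
  }
  list(f_vmpepc = f_p, f_vmrubisco = f_c,
       rss_slope = obj_p(f_p), rss_plateau = obj_c(f_c))
}

#' Assemble a species parameter report
#'
#' Collects the individual estimates into one row in the layout of the
#' model's input-parameter table, with a pretty text rendering and CSV
#' export via [write.csv()].
#'
#' @param species species label.
#' @param bb a `c4_bb_fit`, `gs_open`/`gs_close` two `c4_gs_fit`s,
#'   `aci` a `c4_aci_fit`, `tau` a `c4_tau_fit`, `pdrp` a `c4_pdrp_fit`,
#'   `rd` the list from [estimate_rd()], `f` the list from
#'   [estimate_f_scalars()] (optional).
#' @return one-row tibble with the eleven input parameters.
#' @export
species_report <- function(species, bb, gs_open, gs_close, aci, tau, pdrp,
                           rd, f = NULL) {
  tibble(
    species = species,
    slope_bb = bb$slope_bb, intercept_bb = bb$intercept_bb,
    gs_ki = gs_open$k, gs_kd = gs_close$k,
    vpmax = aci$vpmax, vcmax = aci$vcmax,
    tau_rubisco = tau$tau_min,
    f_vmpepc = f$f_vmpepc %||% NA_real_,
    f_vmrubisco = f$f_vmrubisco %||% NA_real_,
    pdrp = pdrp$pdrp, rd = rd$rd)
}
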