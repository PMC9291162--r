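#' Steady-state Ball-Berry stomatal conductance
#'
#' Empirical steady-state stomatal conductance to water vapour:
#' `gs = slope * A * RH / Ca + intercept`, floored at the intercept
#' (residual conductance) when net assimilation is non-positive.
#'
#' @param a net CO2 uptake rate (umol m-2 s-1).
#' @param rh relative humidity at the leaf surface, fraction in `[0, 1]`.
#' @param ca CO2 mole fraction at the leaf surface (umol mol-1), > 0.
#' @param slope_bb,intercept_bb Ball-Berry slope (dimensionless) and
#'   intercept (mol m-2 s-1).
#' @return stomatal conductance to H2O, mol m-2 s-1.
#' @export
#' @examples
#' ball_berry_steady(30, 0.6, 400, 5.183, 0.036)
ball_berry_steady <- function(a, rh, ca, slope_bb, intercept_bb) {
  if (any(ca <= 0)) abort("Ca must be > 0", class = "c4dyn_domain_error")
  if (any(rh < 0 | rh > 1)) abort("RH must be in [0, 1]",
                                  class = "c4dyn_domain_error")
  slope_bb * pmax(a, 0) * rh / ca + intercept_bb
}

#' First-order stomatal conductance dynamics
#'
#' `d gs / dt = k (gs_steady - gs)` with asymmetric rate constants: the
#' opening constant `k_i` applies when the target exceeds the current
#' conductance, the closing constant `k_d` otherwise. Switching is
#' instantaneous at target crossings (no hysteresis band).
#'
#' @param gs current conductance (mol m-2 s-1).
#' @param gs_steady Ball-Berry target (mol m-2 s-1).
#' @param k_i,k_d opening and closing rate constants (min-1).
#' @return rate of change, mol m-2 s-1 min-1.
#' @export
gs_rate <- function(gs, gs_steady, k_i, k_d) {
  k <- ifelse(gs_steady > gs, k_i, k_d)
  k * (gs_steady - gs)
}

#' Fit stomatal kinetic constants from a conductance transient
#'
#' Fits the exponential relaxation `gs(t) = g0 + (gmax - g0) exp(-k t)`
#' (closing) or its mirrored form `gs(t) = gmax - (gmax - g0) exp(-k t)`
#' (opening; approach to `gmax`) to a measured conductance time series by
#' nonlinear least squares. The direction is detected from the fitted series
#' unless given.
#'
#' @param series data frame with columns `time_s` and `gs`.
#' @param direction `"auto"` (default), `"opening"` or `"closing"`.
#' @return object of class `c4_gs_fit`: a list with `g_max`, `g_0`, `k`
#'   (min-1), `direction`, `rss`, `n` and the underlying `nls` fit.
#'   [tidy()][generics::tidy] and [glance()] methods are provided.
#' @export
#' @examples
#' t <- seq(0, 1800, 10)
#' gs <- 0.05 + (0.3 - 0.05) * exp(-0.2 * t / 60)
#' fit_gs_kinetics(data.frame(time_s = t, gs = gs))
fit_gs_kinetics <- function(series, direction = c("auto", "opening", "closing")) {
  direction <- match.arg(direction)
  stopifnot(all(c("time_s", "gs") %in% names(series)))
  if (nrow(series) < 10) {
    abort("fit_gs_kinetics: need at least 10 points",
          class = "c4dyn_domain_error")
  }
  t_min <- (series$time_s - series$time_s[1]) / 60
  gs <- series$gs
  if (sd(gs) < 1e-10 * max(abs(gs), 1)) {
    abort("fit_gs_kinetics: constant series, rate constant unidentifiable",
          class = "c4dyn_degenerate_error")
  }
  if (direction == "auto") {
    direction <- if (gs[length(gs)] >= gs[1]) "opening" else "closing"
  }
  df <- data.frame(t = t_min, gs = gs)
  start <- list(g_max = max(gs), g_0 = min(gs),
                k = 3 / max(t_min))
  form <- if (direction == "closing") {
    gs ~ g_0 + (g_max - g_0) * exp(-k * t)
  } else {
    gs ~ g_max - (g_max - g_0) * exp(-k * t)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = c(0, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("fit_gs_kinetics: fit failed (", conditionMessage(e),
                   "); last guess g_max=", signif(start$g_max, 4),
                   " g_0=", signif(start$g_0, 4), " k=", signif(start$k, 4)),
            class = "c4dyn_fit_error")
    }
  )
  cf <- coef(fit)
  structure(
    list(g_max = unname(cf["g_max"]), g_0 = unname(cf["g_0"]),
         k = unname(cf["k"]), direction = direction,
         rss = sum(residuals(fit)^2), n = nrow(df), fit = fit),
    class = "c4_gs_fit")
}

#' @export
print.c4_gs_fit <- function(x, ...) {
  cat("Stomatal kinetics fit (", x$direction, ")\n", sep = "")
  cat(sprintf("  g_max = %.4f  g_0 = %.4f mol m-2 s-1\n", x$g_max, x$g_0))
  cat(sprintf("  k     = %.4f min-1   (RSS %.3g, n = %d)\n",
              x$k, x$rss, x$n))
  invisible(x)
}
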