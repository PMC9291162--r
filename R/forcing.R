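#' Environmental forcing time courses
#'
#' A forcing object is a tibble of piecewise-constant segments with columns
#' `t_start` (s), `par` (umol m-2 s-1), `tair` (deg C), `rh` (fraction),
#' `ca` (umol mol-1), `wind` (m s-1) and `pa` (kPa). Segment i applies from
#' `t_start[i]` to the start of the next segment.
#'
#' @param par,tair,rh,ca,wind,pa scalar values (recycled across segments) or
#'   vectors of the same length as `t_start`.
#' @param t_start segment start times (s), strictly increasing from 0.
#' @return tibble of class `c4_forcing`.
#' @export
#' @examples
#' c4_forcing(par = c(0, 1800), t_start = c(0, 60))
c4_forcing <- function(par, t_start = 0, tair = NULL, rh = NULL, ca = NULL,
                       wind = NULL, pa = NULL) {
  env <- network_defaults()$environment_defaults
  if (is.null(tair)) tair <- env$tair
  if (is.null(rh)) rh <- env$rh
  if (is.null(ca)) ca <- env$ca
  if (is.null(wind)) wind <- env$wind
  if (is.null(pa)) pa <- env$pa
  n <- length(t_start)
  if (n < 1 || t_start[1] != 0 || (n > 1 && any(diff(t_start) <= 0))) {
    abort("t_start must be strictly increasing and begin at 0",
          class = "c4dyn_domain_error")
  }
  out <- tibble(
    t_start = as.numeric(t_start),
    par = rep_len(par, n), tair = rep_len(tair, n), rh = rep_len(rh, n),
    ca = rep_len(ca, n), wind = rep_len(wind, n), pa = rep_len(pa, n))
  if (any(out$par < 0) || any(out$rh < 0 | out$rh > 1) || any(out$ca <= 0)) {
    abort("invalid forcing values (PAR >= 0, RH in [0,1], Ca > 0)",
          class = "c4dyn_domain_error")
  }
  class(out) <- c("c4_forcing", class(out))
  out
}

#' Dark-to-light induction forcing
#'
#' The standard induction protocol: darkness, then a step to high light.
#' Time 0 is light-on; dark adaptation is handled separately (see
#' [dark_adapt()]).
#'
#' @param par_on light intensity after the step (umol m-2 s-1).
#' @param ... environmental overrides passed to [c4_forcing()].
#' @export
forcing_induction <- function(par_on = 1800, ...) {
  c4_forcing(par = par_on, t_start = 0, ...)
}

#' Fluctuating-light forcing
#'
#' Three 30-min steps of high, low and high light
#' (1800, 200, 1800 umol m-2 s-1 by default), beginning at time 0 after
#' dark adaptation.
#'
#' @param par_levels light levels (umol m-2 s-1).
#' @param step_s duration of each step (s).
#' @param ... environmental overrides passed to [c4_forcing()].
#' @export
forcing_fluctuating <- function(par_levels = c(1800, 200, 1800),
                                step_s = 1800, ...) {
  c4_forcing(par = par_levels,
             t_start = step_s * (seq_along(par_levels) - 1), ...)
}

# lookup of the active segment at time t (piecewise constant, right-open)
forcing_at <- function(forcing, t) {
  i <- findInterval(t, forcing$t_start, rightmost.closed = FALSE)
  i[i < 1] <- 1L
  as.list(forcing[i, c("par", "tair", "rh", "ca", "wind", "pa")])
}
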