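#' Generate synthetic LI-6800-style gas-exchange data
#'
#' Forward-simulates the full dynamic model under one of the measurement
#' protocols and samples it at the logging interval with multiplicative
#' measurement noise, emulating an infra-red gas analyser export. The
#' generating ("ground truth") parameters are attached as the `truth`
#' attribute, for estimator recovery tests.
#'
#' Protocols (the printed measurement designs):
#' \describe{
#'   \item{induction}{30 min dark adaptation, optional dark lead-in rows,
#'     then a step to 1800 umol m-2 s-1 logged every 10 s for 30 min.}
#'   \item{aci}{CO2 setpoint sequence 400, 300, 200, 120, 70, 40, 20, 10,
#'     400, 400, 400, 600, 800, 1200, 1500 umol mol-1; one steady-state
#'     record per level.}
#'   \item{aq}{light sequence 2000, 1500, 1000, 500, 300, 200, 100, 50
#'     umol m-2 s-1; one steady-state record per level.}
#'   \item{fluctuating}{1800, 200, 1800 umol m-2 s-1 for 1800 s each,
#'     logged every 10 s.}
#' }
#'
#' @param protocol one of `"induction"`, `"aci"`, `"aq"`, `"fluctuating"`.
#' @param params species parameter set ([c4_params()]) used as ground
#'   truth.
#' @param sigma_a,sigma_gs relative (multiplicative Gaussian) noise on A
#'   and gs; defaults 0.02 and 0.05. Noise on gs is truncated to keep
#'   gs > 0.
#' @param seed integer seed; generation is reproducible given the seed.
#' @param dark_lead_s dark records before light-on for the induction
#'   protocol (s), logged at the same 10-s cadence with negative time.
#' @param log_dt logging interval (s).
#' @param level_s settling time per setpoint for the aci/aq protocols (s).
#' @return tibble of class `c4_gx` with columns `time_s, A, gs, Ci, Ca,
#'   PAR, Tleaf, RH` (plus `ca_set`/`par_set` for response curves), with
#'   attributes `truth` (the generating parameters) and `protocol`.
#' @export
#' @examples
#' \donttest{
#' gx <- generate_gas_exchange("induction", c4_params("maize"), seed = 1)
#' }
generate_gas_exchange <- function(protocol = c("induction", "aci", "aq",
                                               "fluctuating"),
                                  params, sigma_a = 0.02, sigma_gs = 0.05,
                                  seed = 1L, dark_lead_s = 60,
                                  log_dt = 10, level_s = 600) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(params, "c4_params"))
  if (sigma_a < 0 || sigma_gs < 0) {
    abort("noise sigmas must be >= 0", class = "c4dyn_domain_error")
  }
  env <- params$environment_defaults
  dark <- dark_adapt(params)

  base <- switch(protocol,
    induction = {
      dk <- c4_simulate(params, c4_forcing(par = 0), duration = dark_lead_s,
                        init = dark, pre_adapt = FALSE, dt_out = log_dt)
      # the dark lead is logged from the same dark-adapted state the light
      # simulation starts from (the state is at its dark steady point)
      lt <- c4_simulate(params, forcing_induction(), duration = 1800,
                        init = dark, pre_adapt = FALSE, dt_out = log_dt)
      dk_rows <- sim_to_gx(dk, env, par = 0)
      dk_rows$time_s <- dk_rows$time_s - dark_lead_s
      lt_rows <- sim_to_gx(lt, env, par = 1800)
      dplyr::bind_rows(dk_rows[-nrow(dk_rows), ], lt_rows)
    },
    fluctuating = {
      sim <- c4_simulate(params, forcing_fluctuating(), duration = 5400,
                         init = dark, pre_adapt = FALSE, dt_out = log_dt)
      out <- sim_to_gx(sim, env, par = NA_real_)
      out$PAR <- vapply(out$time_s, function(t) {
        forcing_at(forcing_fluctuating(), t)$par
      }, 0)
      out
    },
    aci = {
      ca_seq <- c(400, 300, 200, 120, 70, 40, 20, 10, 400, 400, 400, 600,
                  800, 1200, 1500)
      state <- open_stomata_start(params, dark)
      rows <- purrr::map(ca_seq, function(ca) {
        res <- settle_level(params, c4_forcing(par = 1800, ca = ca),
                            state, level_s)
        state <<- res$state
        tibble(time_s = NA_real_, ca_set = ca, A = res$last$A,
               gs = res$last$gs, Ci = res$last$ci, Ca = ca, PAR = 1800,
               Tleaf = res$last$tleaf, RH = env$rh)
      })
      out <- dplyr::bind_rows(rows)
      out$time_s <- seq_len(nrow(out)) * level_s
      out
    },
    aq = {
      par_seq <- c(2000, 1500, 1000, 500, 300, 200, 100, 50)
      state <- open_stomata_start(params, dark)
      rows <- purrr::map(par_seq, function(q) {
        res <- settle_level(params, c4_forcing(par = q), state, level_s)
        state <<- res$state
        tibble(time_s = NA_real_, par_set = q, A = res$last$A,
               gs = res$last$gs, Ci = res$last$ci, Ca = env$ca, PAR = q,
               Tleaf = res$last$tleaf, RH = env$rh)
      })
      out <- dplyr::bind_rows(rows)
      out$time_s <- seq_len(nrow(out)) * level_s
      out
    })

  out <- add_noise(base, sigma_a, sigma_gs, seed)
  attr(out, "truth") <- params
  attr(out, "protocol") <- protocol
  class(out) <- c("c4_gx", class(out))
  out
}

# convert a simulation tibble to the instrument column dialect
sim_to_gx <- function(sim, env, par) {
  tibble(time_s = sim$time_s, A = sim$A, gs = sim$gs, Ci = sim$ci,
         Ca = env$ca, PAR = par, Tleaf = sim$tleaf, RH = env$rh)
}

add_noise <- function(base, sigma_a, sigma_gs, seed) {
  set.seed(seed)
  out <- base
  if (sigma_a > 0) out$A <- out$A * (1 + rnorm(nrow(out), 0, sigma_a))
  if (sigma_gs > 0) {
    eps <- rnorm(nrow(out), 0, sigma_gs)
    eps <- pmax(eps, -0.9)  # truncate so gs stays positive
    out$gs <- out$gs * (1 + eps)
  }
  out
}

# run one response-curve level to its coupled steady state: the normal
# dynamics for the logging interval, then a stomatal-equilibration polish
# (the instrument operator waits until gs is steady before logging)
settle_level <- function(params, forcing, state, level_s) {
  sim <- c4_simulate(params, forcing, duration = level_s, init = state,
                     pre_adapt = FALSE, dt_out = level_s / 10)
  p_fast <- params
  p_fast$gs_ki <- 30
  p_fast$gs_kd <- 30
  polish <- c4_simulate(p_fast, forcing, duration = 900,
                        init = attr(sim, "final_state"),
                        pre_adapt = FALSE, dt_out = 90)
  list(last = polish[nrow(polish), ], state = attr(polish, "final_state"))
}

# light-adapted steady start for response-curve protocols: acclimate at
# 1800 umol m-2 s-1 / 400 ppm until A and gs are steady
open_stomata_start <- function(params, dark, duration = 2400) {
  sim <- c4_simulate(params, forcing_induction(), duration = duration,
                     init = dark, pre_adapt = FALSE, dt_out = 60)
  attr(sim, "final_state")
}
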