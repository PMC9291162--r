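#' Run a regulation scenario
#'
#' Simulates a dark-to-light induction (or any forcing) under one of the
#' six regulation scenarios. Enabled regulation components start from their
#' dark-adapted values and follow their ODEs; disabled components are held
#' fully light-activated from time zero. When stomatal dynamics are
#' disabled, the stomata are held open at the light-on steady-state
#' conductance, found by a pre-run in which gs tracks its Ball-Berry target
#' quasi-instantaneously.
#'
#' @param scenario scenario id (1-6) or a [c4_scenario()] object.
#' @param params model parameters, a species name, or `NULL` (the original
#'   parameter set).
#' @param forcing forcing object; default dark-to-1800 umol m-2 s-1 step.
#' @param duration simulated time (s).
#' @param init optional dark-adapted initial state (computed if missing).
#' @param ... passed to [c4_simulate()].
#' @return a `c4_sim` tibble (see [c4_simulate()]).
#' @export
#' @examples
#' \donttest{
#' sim <- run_scenario(1, "original", duration = 300)
#' }
run_scenario <- function(scenario, params = "original",
                         forcing = forcing_induction(), duration = 1800,
                         init = NULL, ...) {
  if (is.numeric(scenario)) scenario <- c4_scenario(scenario)
  if (!inherits(scenario, "c4_scenario")) {
    abort("scenario must be an id 1-6 or a c4_scenario object",
          class = "c4dyn_config_error")
  }
  if (is.character(params) || is.null(params)) {
    params <- c4_params(params %||% "original")
  }
  if (is.null(init)) init <- dark_adapt(params)

  if (!scenario$dynamic_stomata) {
    init[["gs"]] <- open_stomata_gs(params, forcing, scenario)
  }
  c4_simulate(params, forcing, duration, init = init, scenario = scenario,
              pre_adapt = FALSE, ...)
}

# steady-state stomatal conductance under the light-on forcing, obtained by
# letting gs track its Ball-Berry target with fast kinetics
open_stomata_gs <- function(params, forcing, scenario, duration = 2400) {
  p_fast <- params
  p_fast$gs_ki <- 60
  p_fast$gs_kd <- 60
  sc <- scenario
  sc$dynamic_stomata <- TRUE
  init <- light_steady_init(params)
  sim <- c4_simulate(p_fast, forcing, duration, init = init, scenario = sc,
                     pre_adapt = FALSE, dt_out = 60)
  # pin the conductance at the Ball-Berry value of the converged uptake
  last <- sim[nrow(sim), ]
  env <- forcing_at(attr(sim, "forcing"), last$time_s)
  ball_berry_steady(last$A, env$rh, env$ca, params$slope_bb,
                    params$intercept_bb)
}
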