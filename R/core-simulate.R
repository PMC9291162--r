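#' Regulation scenario flags
#'
#' The six regulation scenarios of the induction analysis. A disabled
#' component is held at its fully light-activated value from time zero; an
#' enabled component follows its differential equation from dark-adapted
#' initial values.
#'
#' \describe{
#'   \item{1}{no dynamic regulation (all enzymes active, stomata open)}
#'   \item{2}{dynamic PPDK (PDRP) only}
#'   \item{3}{dynamic Rubisco (Rca) only}
#'   \item{4}{dynamic PPDK + Rubisco}
#'   \item{5}{all light-regulated enzymes}
#'   \item{6}{all light-regulated enzymes + stomatal dynamics}
#' }
#'
#' @param id scenario id, 1-6.
#' @return list of class `c4_scenario` with logical flags `dynamic_ppdk`,
#'   `dynamic_rubisco`, `dynamic_other`, `dynamic_stomata`.
#' @export
c4_scenario <- function(id) {
  if (!id %in% 1:6) {
    abort(paste0("unknown scenario id: ", id), class = "c4dyn_config_error")
  }
  structure(list(
    id = id,
    dynamic_ppdk = id %in% c(2, 4, 5, 6),
    dynamic_rubisco = id %in% c(3, 4, 5, 6),
    dynamic_other = id %in% c(5, 6),
    dynamic_stomata = id == 6
  ), class = "c4_scenario")
}

# reference state: metabolites from the config, regulation states at
# plausible dark values (refined by dark_adapt)
init_state <- function(params) {
  met <- unlist(params$initial_state)[MET_NAMES]
  if (anyNA(met)) {
    abort("initial_state config is missing metabolites",
          class = "c4dyn_config_error")
  }
  la <- params$light_activation
  tot <- params$pools$ppdk_total
  c(met,
    e_ppdk = 0.1 * tot, ep_ppdk = 0.9 * tot,
    r_rub = 0.3,
    a_atpase = la$atpase$c_a, a_fbpase = la$fbpase$c_a,
    a_gapdh = la$gapdh$c_a, a_prk = la$prk$c_a, a_rca = la$rca$c_a,
    a_sbpase = la$sbpase$c_a, a_pepc = la$pepc$c_a,
    gs = params$intercept_bb,
    tleaf = params$environment_defaults$tair)[STATE_NAMES]
}

#' Dark adaptation pre-simulation
#'
#' Integrates the full dynamic model in darkness from the stored reference
#' state so that metabolite pools, enzyme activation states, PPDK
#' phosphorylation, stomatal conductance and leaf temperature settle to
#' their dark-adapted values. Used to initialise induction simulations.
#'
#' @param params model parameters from [c4_params()].
#' @param minutes dark duration (default 30, the measurement protocol).
#' @param init optional starting state (defaults to the reference state).
#' @return named state vector.
#' @export
dark_adapt <- function(params, minutes = 30, init = NULL) {
  if (is.null(init)) init <- init_state(params)
  sim <- c4_simulate(params, c4_forcing(par = 0), duration = minutes * 60,
                     init = init, scenario = c4_scenario(6),
                     pre_adapt = FALSE, dt_out = 30)
  attr(sim, "final_state")
}

#' Integrate the dynamic C4 photosynthesis model
#'
#' Solves the coupled stiff ODE system (metabolism, enzyme regulation,
#' stomata, leaf energy balance) under a piecewise-constant environmental
#' forcing with `deSolve::lsoda`. The output time grid includes every
#' forcing breakpoint.
#'
#' @param params model parameters from [c4_params()].
#' @param forcing forcing object from [c4_forcing()]; time 0 is the start
#'   of the simulation.
#' @param duration simulated time (s), > 0.
#' @param init named initial state vector; if `NULL` the model is first
#'   dark-adapted for `dark_minutes`.
#' @param scenario regulation scenario flags, see [c4_scenario()];
#'   default: the full model (scenario 6).
#' @param dt_out output grid spacing (s).
#' @param rtol,atol solver tolerances.
#' @param pre_adapt logical; run the dark pre-simulation when `init` is
#'   `NULL`.
#' @param dark_minutes dark-adaptation duration (min).
#' @return a tibble of class `c4_sim`: `time_s`, `A` (net CO2 uptake, the
#'   flux of CO2 through the stomata, umol m-2 s-1), `gs`, `ci`, `tleaf`,
#'   `phi` (bundle-sheath leakiness), effective activity columns `act_*`,
#'   every reaction flux `v_*` and every metabolite concentration. The
#'   final full state is attached as attribute `final_state`.
#' @export
#' @examples
#' \donttest{
#' p <- c4_params("maize")
#' sim <- c4_simulate(p, forcing_induction(), duration = 300)
#' head(sim[, c("time_s", "A", "gs", "ci", "phi")])
#' }
c4_simulate <- function(params, forcing, duration,
                        init = NULL, scenario = c4_scenario(6),
                        dt_out = NULL, rtol = NULL, atol = NULL,
                        pre_adapt = TRUE, dark_minutes = 30) {
  stopifnot(inherits(params, "c4_params"))
  if (duration <= 0) abort("duration must be > 0", class = "c4dyn_domain_error")
  sol <- params$solver
  if (is.null(dt_out)) dt_out <- sol$dt_out
  if (is.null(rtol)) rtol <- sol$rtol
  if (is.null(atol)) atol <- sol$atol
  if (is.null(init)) {
    init <- if (pre_adapt) dark_adapt(params, dark_minutes)
            else init_state(params)
  }
  init <- init[STATE_NAMES]
  if (anyNA(init)) abort("init is missing state entries",
                         class = "c4dyn_config_error")

  ctx <- make_rhs_context(params, scenario)
  times <- sort(unique(c(seq(0, duration, by = dt_out), duration,
                         forcing$t_start[forcing$t_start <= duration])))
  func <- function(t, y, parms) ctx$rhs(t, y, forcing)
  out <- deSolve::lsoda(y = init, times = times, func = func, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 20000)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    last <- out[nrow(out), ]
    abort(paste0("ODE solver failed (istate ", di$istate,
                 ") at t = ", signif(last[["time"]], 6),
                 " s; last accepted state attached"),
          class = "c4dyn_integration_error",
          last_time = last[["time"]], last_state = last)
  }
  res <- as_tibble(as.data.frame(out))
  names(res)[1] <- "time_s"

  # effective activities actually applied, given the scenario flags
  frac_ppdk <- if (scenario$dynamic_ppdk) {
    res$e_ppdk / (res$e_ppdk + res$ep_ppdk)
  } else rep(1, nrow(res))
  act_rub <- if (scenario$dynamic_rubisco) res$r_rub else rep(1, nrow(res))
  oth <- function(col) if (scenario$dynamic_other) res[[col]] else rep(1, nrow(res))

  tidy <- tibble(
    time_s = res$time_s,
    A = res$A, gs = res$gs, ci = res$ci, tleaf = res$tleaf, phi = res$phi,
    act_ppdk = frac_ppdk, act_rubisco = act_rub,
    act_pepc = oth("a_pepc"), act_atpase = oth("a_atpase"),
    act_fbpase = oth("a_fbpase"), act_gapdh = oth("a_gapdh"),
    act_prk = oth("a_prk"), act_rca = oth("a_rca"),
    act_sbpase = oth("a_sbpase"))
  tidy <- dplyr::bind_cols(tidy, res[, RXN_NAMES], res[, MET_NAMES],
                           res[, c("e_ppdk", "ep_ppdk", "r_rub")])
  attr(tidy, "final_state") <- {
    fs <- unlist(res[nrow(res), STATE_NAMES])
    names(fs) <- STATE_NAMES
    fs
  }
  attr(tidy, "params") <- params
  attr(tidy, "scenario") <- scenario
  attr(tidy, "forcing") <- forcing
  class(tidy) <- c("c4_sim", class(tidy))
  tidy
}

# light-adapted initial guess: regulation states at their light-on
# steady-state targets, metabolite pools at working values
light_steady_init <- function(params, par = 1800) {
  y <- init_state(params)
  la <- params$light_activation
  for (e in c("atpase", "fbpase", "gapdh", "prk", "rca", "sbpase", "pepc")) {
    y[[paste0("a_", e)]] <- steady_activation_fraction(par, la[[e]]$k_a,
                                                      la[[e]]$c_a)
  }
  rca_a <- params$rca_total * y[["a_rca"]]
  y[["r_rub"]] <- rca_a / (params$rubisco_activation$k_activase + rca_a)
  tot <- params$pools$ppdk_total
  y[["e_ppdk"]] <- 0.9 * tot
  y[["ep_ppdk"]] <- 0.1 * tot
  y[["gs"]] <- 0.3
  y
}

# steady-state A (and final state) at a clamped intercellular CO2;
# used by the capacity-scalar estimation
steady_state_a <- function(params, ci, init = NULL, duration = 600,
                           par = 1800, scenario = c4_scenario(5),
                           gs = NULL) {
  p <- params
  p$fixed_ci <- ci
  if (is.null(init)) init <- light_steady_init(p, par)
  if (!is.null(gs)) init[["gs"]] <- gs
  sim <- c4_simulate(p, c4_forcing(par = par), duration = duration,
                     init = init, scenario = scenario, pre_adapt = FALSE,
                     dt_out = duration / 50)
  n <- nrow(sim)
  tail_rows <- sim$time_s >= sim$time_s[n] - duration / 10
  list(a = mean(sim$A[tail_rows]), state = attr(sim, "final_state"))
}
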