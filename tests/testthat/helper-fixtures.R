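# Shared fixtures: everything is generated in code at test time.

# parameter sets are cheap to build but reused across files
fix_params <- local({
  cache <- list()
  function(species = "original", ...) {
    key <- paste(species, ..., sep = "_")
    if (is.null(cache[[key]])) cache[[key]] <<- c4_params(species, ...)
    cache[[key]]
  }
})

# dark-adapted state, cached per species (used by many simulation tests)
fix_dark <- local({
  cache <- list()
  function(species = "original") {
    if (is.null(cache[[species]])) {
      cache[[species]] <<- dark_adapt(fix_params(species))
    }
    cache[[species]]
  }
})

# closed-form stomatal opening/closing series (the fitting model itself)
make_gs_series <- function(g_max, g_0, k, direction = "closing",
                           dt = 10, t_end = 1800) {
  t <- seq(0, t_end, dt)
  gs <- if (direction == "closing") {
    g_0 + (g_max - g_0) * exp(-k * t / 60)
  } else {
    g_max - (g_max - g_0) * exp(-k * t / 60)
  }
  data.frame(time_s = t, gs = gs)
}

# closed-form exponential induction (A approaches A_f with time constant tau)
make_induction_series <- function(a_f = 35, a_0 = -2, tau_min = 5,
                                  dt = 10, t_end = 1800) {
  t <- seq(0, t_end, dt)
  data.frame(time_s = t, A = a_f - (a_f - a_0) * exp(-t / (tau_min * 60)))
}

# residual-free Ball-Berry line over the printed light-response design
make_bb_curve <- function(slope, intercept, rh = 0.65, ca = 400,
                          a = c(34, 31, 28, 25, 22, 18, 10, 3)) {
  data.frame(A = a, RH = rh, Ca = ca, gs = slope * a * rh / ca + intercept)
}

# enzyme activities, all fully active
full_activities <- function() {
  stats::setNames(as.list(rep(1, length(c4dyn:::ACTIVITY_NAMES))),
                  c4dyn:::ACTIVITY_NAMES)
}

# metabolite state from the configuration's dark reference values
reference_state <- function(params = fix_params()) {
  unlist(params$initial_state)[c4dyn:::MET_NAMES]
}
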