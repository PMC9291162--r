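test_that("the stoichiometry matrix conserves carbon in every internal step", {
  S <- c4dyn:::stoich_with_rd(0.5)
  carbon <- c4dyn:::CARBON_PER_MET[rownames(S)]
  dC <- as.vector(carbon %*% S)
  names(dC) <- colnames(S)
  # only the boundary steps move carbon across the network boundary (the
  # respiratory decay of C4 acids returns their carbon as CO2)
  boundary <- c(v_stomatal_co2_influx = 1, v_rd = 1, v_export = -3)
  for (rxn in colnames(S)) {
    expected <- if (rxn %in% names(boundary)) boundary[[rxn]] else 0
    expect_equal(dC[[rxn]], expected, info = rxn)
  }
})

test_that("reaction rates respect zero-activity, gradient and linear-scaling laws", {
  p <- fix_params()
  state <- reference_state(p)
  act <- full_activities()

  # zero light-activated activities stop every light-dependent enzymatic flux
  act0 <- act
  for (e in c("pepc", "rubisco", "gapdh", "fbpase", "sbpase", "prk",
              "atpase", "ppdk")) act0[[e]] <- 0
  env <- p$environment_defaults; env$par <- 1800
  v0 <- reaction_rates(state, act0, t_leaf = 25, params = p, env = env)
  v0 <- setNames(v0$flux, v0$reaction)
  for (rxn in c("v_pepc", "v_rubisco_c", "v_gapdh_m", "v_gapdh_b",
                "v_fbpase", "v_sbpase", "v_prk", "v_ppdk", "v_lr_b",
                "v_atps_m")) {
    expect_equal(v0[[rxn]], 0, info = rxn)
  }

  # no CO2 gradient, no plasmodesmatal leak
  st_eq <- state
  st_eq[["co2_b"]] <- st_eq[["co2_m"]]
  v_eq <- reaction_rates(st_eq, act, 25, p, env = env)
  expect_equal(v_eq$flux[v_eq$reaction == "v_co2_leak"], 0)
  # leak sign follows the gradient
  st_up <- state; st_up[["co2_b"]] <- st_up[["co2_m"]] + 0.01
  v_up <- reaction_rates(st_up, act, 25, p, env = env)
  expect_gt(v_up$flux[v_up$reaction == "v_co2_leak"], 0)

  # doubling every Vmax doubles every saturable enzymatic flux
  p2 <- p
  p2$vmax_mult <- setNames(rep(2, 8), c("pepc", "ppdk", "mdh", "me",
                                        "rubisco", "gapdh", "fbpase",
                                        "sbpase"))
  v1 <- reaction_rates(state, act, 25, p, env = env)
  v2 <- reaction_rates(state, act, 25, p2, env = env)
  for (rxn in c("v_pepc", "v_ppdk", "v_mdh", "v_me", "v_rubisco_c",
                "v_gapdh_m", "v_gapdh_b", "v_fbpase", "v_sbpase")) {
    expect_equal(v2$flux[v2$reaction == rxn],
                 2 * v1$flux[v1$reaction == rxn], info = rxn)
  }

  # a missing activity entry is a configuration error naming the enzyme
  expect_error(reaction_rates(state, act[-match("rubisco", names(act))],
                              25, p, env = env),
               regexp = "rubisco", class = "c4dyn_config_error")
})

test_that("all-zero fluxes give all-zero metabolite derivatives", {
  S <- c4dyn:::stoich_with_rd(0.5)
  expect_equal(as.vector(S %*% rep(0, ncol(S))),
               rep(0, nrow(S)))
})

test_that("a closed configuration conserves total network carbon", {
  # remove every boundary flux: no respiration, no export, no C4-acid
  # decay, and zero mesophyll conductance (no exchange with the atmosphere)
  net <- network_defaults()
  net$vmax$export <- 0
  net$vmax$pyr_decay <- 0
  net$vmax$oaa_decay <- 0
  net$conductances$gm <- 1e-12
  p2 <- c4_params("original", network = net, rd = 1e-12)
  p2$rd <- 0
  sim <- c4_simulate(p2, forcing_induction(), duration = 3600,
                     init = c4dyn:::light_steady_init(p2),
                     scenario = c4_scenario(1), pre_adapt = FALSE,
                     dt_out = 120, rtol = 1e-9, atol = 1e-12)
  vols <- c4dyn:::build_param_cache(p2)$vols
  carbon <- c4dyn:::CARBON_PER_MET
  tot <- apply(sim[, c4dyn:::MET_NAMES], 1, function(conc) {
    sum(conc * vols[c4dyn:::MET_NAMES] * carbon[c4dyn:::MET_NAMES]) * 1000
  })
  # relative drift below 1e-8 over the simulated hour
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
})

test_that("concentrations stay non-negative at every accepted step", {
  p <- fix_params("maize")
  sim <- c4_simulate(p, forcing_fluctuating(), duration = 5400,
                     init = fix_dark("maize"), pre_adapt = FALSE,
                     dt_out = 10)
  conc <- as.matrix(sim[, c4dyn:::MET_NAMES])
  expect_gt(min(conc), -1e-8)
})

test_that("leak flux sign always follows the bundle-sheath gradient", {
  p <- fix_params("maize")
  sim <- c4_simulate(p, forcing_induction(), duration = 1200,
                     init = fix_dark("maize"), pre_adapt = FALSE, dt_out = 5)
  grad <- sim$co2_b - sim$co2_m
  expect_true(all(sign(sim$v_co2_leak) == sign(grad) | grad == 0))
})

test_that("the steady state is independent of the initial metabolite pools", {
  p <- fix_params()
  y1 <- c4dyn:::light_steady_init(p)
  y2 <- y1
  # second initialisation: very different pool sizes
  for (m in c("pep_m", "pyr_m", "mal_m", "pga_m", "t3p_m", "mal_b",
              "pyr_b", "pga_b", "t3p_b", "rubp_b", "ru5p_b")) {
    y2[[m]] <- y1[[m]] * 3 + 0.5
  }
  y2[["hep_b"]] <- 15
  s1 <- c4_simulate(p, forcing_induction(), 2400, init = y1,
                    scenario = c4_scenario(1), pre_adapt = FALSE, dt_out = 60)
  s2 <- c4_simulate(p, forcing_induction(), 2400, init = y2,
                    scenario = c4_scenario(1), pre_adapt = FALSE, dt_out = 60)
  a1 <- mean(s1$A[s1$time_s >= 2100])
  a2 <- mean(s2$A[s2$time_s >= 2100])
  expect_lt(abs(a1 - a2) / a1, 0.01)
})

test_that("in constant darkness net CO2 uptake converges to -Rd", {
  p <- fix_params("sorghum")
  sim <- c4_simulate(p, c4_forcing(par = 0), duration = 5400,
                     init = c4dyn:::init_state(p),
                     pre_adapt = FALSE, dt_out = 120)
  # a small residual efflux from slow starch respiration remains
  expect_equal(sim$A[nrow(sim)], -p$rd, tolerance = 0.15)
})

test_that("steady-state stomatal influx balances fixation and respiration", {
  p <- fix_params()
  sim <- run_scenario(1, p, duration = 2400, init = fix_dark(), dt_out = 60)
  last <- sim[nrow(sim), ]
  # A = net carbon fixation (3 C per exported triose + acid decay) - Rd
  net_fix <- 3 * last$v_export + 3 * last$v_pyr_decay + 4 * last$v_oaa_decay
  expect_equal(last$A, net_fix - p$rd, tolerance = 0.01 * abs(last$A))
})

test_that("halving the solver tolerance leaves the trajectory unchanged", {
  p <- fix_params()
  s1 <- c4_simulate(p, forcing_induction(), 600, init = fix_dark(),
                    pre_adapt = FALSE, dt_out = 20, rtol = 1e-6, atol = 1e-9)
  s2 <- c4_simulate(p, forcing_induction(), 600, init = fix_dark(),
                    pre_adapt = FALSE, dt_out = 20, rtol = 1e-7, atol = 1e-10)
  expect_lt(max(abs(s1$A - s2$A)), 1e-3 * max(abs(s2$A)))
})

test_that("the network configuration is schema-validated", {
  cfg <- network_defaults()
  broken <- cfg
  broken$pdrp_kinetics$kcat_i <- NULL
  expect_error(c4dyn:::validate_network(broken), class = "c4dyn_config_error")
  broken2 <- cfg
  broken2$km$rub_co2 <- -1
  expect_error(c4dyn:::validate_network(broken2), class = "c4dyn_config_error")
  expect_silent(c4dyn:::validate_network(cfg))
})
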