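test_that("PDRP rates vanish without their phosphoryl substrates and scale with PDRP", {
  pk <- network_defaults()$pdrp_kinetics

  # no ADP -> no phosphorylation (inactivation); no EP -> no activation
  r0 <- pdrp_rates(pk, 0.006, e = 0.8, ep = 0.2, adp = 0, pyr = 1, pi = 10)
  expect_identical(r0$v_inact, 0)
  r1 <- pdrp_rates(pk, 0.006, e = 0.8, ep = 0, adp = 0.5, pyr = 1, pi = 10)
  expect_identical(r1$v_act, 0)

  # both rates are first order in PDRP content
  a <- pdrp_rates(pk, 0.004, e = 0.6, ep = 0.4, adp = 0.5, pyr = 1, pi = 10)
  b <- pdrp_rates(pk, 0.008, e = 0.6, ep = 0.4, adp = 0.5, pyr = 1, pi = 10)
  expect_equal(b$v_inact, 2 * a$v_inact)
  expect_equal(b$v_act, 2 * a$v_act)

  expect_error(pdrp_rates(pk, 0.004, e = -1, ep = 0.4, adp = 0.5,
                          pyr = 1, pi = 10),
               class = "c4dyn_domain_error")
})

test_that("total PPDK is conserved by the PDRP ODE pair in a full simulation", {
  p <- fix_params()
  sim <- c4_simulate(p, forcing_induction(), duration = 600,
                     init = fix_dark(), scenario = c4_scenario(6),
                     pre_adapt = FALSE, dt_out = 20)
  total <- sim$e_ppdk + sim$ep_ppdk
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-8)
})

test_that("Rca content is inversely proportional to the activation time constant", {
  expect_equal(rca_total_from_tau(216.9), 1.0)
  # per-species contents follow from the measured time constants
  expect_equal(rca_total_from_tau(3.881), 216.9 / 3.881, tolerance = 1e-12)
  expect_equal(round(rca_total_from_tau(3.881), 2), 55.89)
  expect_equal(round(rca_total_from_tau(9.714), 2), 22.33)
  expect_error(rca_total_from_tau(0), class = "c4dyn_domain_error")
})

test_that("target Rubisco activity saturates in active Rca and is monotone", {
  # darkness: no active activase, no activity
  expect_equal(rubisco_target_vmax(70, 50, a_rca = 0), 0)
  # half-saturation at Rca_A = K_activase by construction
  expect_equal(rubisco_target_vmax(70, 12.3, a_rca = 1), 35)
  # saturation limit
  expect_equal(rubisco_target_vmax(70, 1e9, a_rca = 1), 70, tolerance = 1e-6)
  # monotone in light (via a_rca) and in total Rca
  a <- seq(0, 1, 0.1)
  v <- rubisco_target_vmax(70, 40, a)
  expect_true(all(diff(v) >= 0))
  rtot <- seq(5, 80, 5)
  expect_true(all(diff(rubisco_target_vmax(70, rtot, 1)) > 0))
})

test_that("first-order activation follows the closed-form exponential", {
  expect_equal(first_order_activation(10, 10, 3), 0)
  # integrate numerically and compare with the exponential solution
  tau <- 2.5
  target <- 40
  f <- function(t, y, p) list(first_order_activation(y, target, tau))
  out <- deSolve::lsoda(c(v = 0), times = seq(0, 3 * tau, 0.01), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  v_at <- function(t) unname(out[which.min(abs(out[, "time"] - t)), "v"])
  expect_equal(v_at(tau), target * (1 - exp(-1)), tolerance = 1e-6)
  expect_equal(v_at(3 * tau), target * (1 - exp(-3)), tolerance = 1e-6)
  expect_error(first_order_activation(0, 1, 0), class = "c4dyn_domain_error")
})

test_that("light-activation fractions are clamped-linear in [c, 1]", {
  expect_equal(steady_activation_fraction(0, 0.003, 0.2), 0.2)
  expect_equal(steady_activation_fraction(1e5, 0.003, 0.2), 1)
  # exact clamp boundary
  k <- 0.003; c0 <- 0.2
  i_star <- (1 - c0) / k
  expect_equal(steady_activation_fraction(i_star, k, c0), 1)
  expect_lt(steady_activation_fraction(i_star - 1, k, c0), 1)
  # property: in [0, 1] for any light level
  i <- seq(0, 3000, 50)
  a <- steady_activation_fraction(i, k, c0)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("all temperature response forms equal 1 at 25 C and behave as stated", {
  temps <- network_defaults()$temperature
  for (tr in temps[c("pepc", "ppdk", "jmax", "rubisco", "q10_default")]) {
    expect_equal(temperature_scale(tr, 25), 1, tolerance = 1e-12)
  }
  # Q10 = 2 doubles per 10 C
  expect_equal(temperature_scale(list(form = "q10", q10 = 2), 35), 2)
  expect_equal(temperature_scale(list(form = "q10", q10 = 2), 15), 0.5)
  # the peaked form has an interior optimum and declines above it
  tr <- temps$pepc
  tt <- seq(5, 55, 0.5)
  f <- vapply(tt, function(x) temperature_scale(tr, x), 0)
  i_opt <- which.max(f)
  expect_gt(i_opt, 1)
  expect_lt(i_opt, length(tt))
  expect_true(all(diff(f[i_opt:length(tt)]) < 0))
  expect_error(temperature_scale(list(form = "bogus"), 25),
               class = "c4dyn_config_error")
})
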