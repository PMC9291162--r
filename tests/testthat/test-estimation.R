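# Estimator round trips: parameters that generated the data are recovered.

test_that("A-Ci fitting recovers generating Vpmax and Vcmax", {
  ci <- c(300, 220, 150, 90, 50, 28, 14, 7, 300, 450, 600, 900, 1100)
  curve <- data.frame(Ci = ci, A = aci_forward(ci, 120, 60, rd = 1))
  fit <- fit_aci(curve, rd = 1)
  expect_equal(fit$vpmax, 120, tolerance = 1e-6)
  expect_equal(fit$vcmax, 60, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  td <- tidy(fit)
  expect_setequal(td$term, c("vpmax", "vcmax"))

  # degenerate inputs fail with informative errors
  expect_error(fit_aci(data.frame(Ci = c(500, 700, 900),
                                  A = c(30, 31, 32)), rd = 1),
               regexp = "slope", class = "c4dyn_fit_error")
  expect_error(fit_aci(data.frame(Ci = c(10, 30, 60, 90, 120),
                                  A = c(5, 10, 15, 20, 25)), rd = 1),
               regexp = "plateau", class = "c4dyn_fit_error")
  nonsense <- data.frame(Ci = c(10, 40, 80, 150, 600, 900),
                         A = c(30, 25, 20, 15, 10, 5))
  expect_error(fit_aci(nonsense, rd = 1), class = "c4dyn_fit_error")
})

test_that("A-Ci recovery stays unbiased under measurement noise", {
  # 2% multiplicative noise on A, 100 replicates: bias < 3% on both
  set.seed(7)
  ci <- c(300, 220, 150, 90, 50, 28, 14, 7, 300, 300, 300, 450, 600, 900, 1100)
  a0 <- aci_forward(ci, 120, 60, rd = 1)
  est <- t(vapply(1:100, function(i) {
    curve <- data.frame(Ci = ci, A = a0 * (1 + rnorm(length(a0), 0, 0.02)))
    fit <- fit_aci(curve, rd = 1)
    c(fit$vpmax, fit$vcmax)
  }, c(0, 0)))
  expect_lt(abs(mean(est[, 1]) / 120 - 1), 0.03)
  expect_lt(abs(mean(est[, 2]) / 60 - 1), 0.03)
})

test_that("Ball-Berry regression is exact on residual-free data", {
  curve <- make_bb_curve(4.53, 0.020)
  fit <- fit_ball_berry(curve)
  expect_equal(fit$slope_bb, 4.53, tolerance = 1e-8)
  expect_equal(fit$intercept_bb, 0.020, tolerance = 1e-8)
  # two points: exact interpolation, zero residual
  fit2 <- fit_ball_berry(make_bb_curve(5.183, 0.036, a = c(30, 10)))
  expect_equal(fit2$slope_bb, 5.183, tolerance = 1e-8)
  expect_equal(sum(residuals(fit2$fit)^2), 0, tolerance = 1e-12)
  expect_error(fit_ball_berry(make_bb_curve(5, 0.02, a = 30)[0, ]),
               class = "c4dyn_fit_error")
})

test_that("tau_Rubisco estimation inverts the semilog slope exactly", {
  # pure exponential with tau = 5 min (long tail so A_f is the asymptote)
  s <- make_induction_series(a_f = 35, a_0 = -2, tau_min = 5, t_end = 3600)
  fit <- estimate_tau_rubisco(s)
  expect_equal(fit$tau_min, 5, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.9999)
  # slope -0.2 min-1 corresponds to tau = 5 min by definition
  expect_equal(-1 / (-0.2), 5)
  # invariance: adding a constant to A leaves tau unchanged
  s2 <- s
  s2$A <- s2$A + 7.3
  expect_equal(estimate_tau_rubisco(s2)$tau_min, fit$tau_min,
               tolerance = 1e-6)
  # degenerate: flat series has no identifiable approach
  flat <- data.frame(time_s = seq(0, 1800, 10), A = 20)
  expect_error(estimate_tau_rubisco(flat), class = "c4dyn_fit_error")
})

test_that("dark respiration is the mean dark efflux", {
  d <- data.frame(time_s = seq(-60, 0, 10), A = rep(-2.282, 7))
  expect_equal(estimate_rd(d)$rd, 2.282)
  # fluctuating dark record: mean with standard error ~ sd/sqrt(n)
  set.seed(11)
  d2 <- data.frame(A = -1 + rnorm(60, 0, 0.1))
  est <- estimate_rd(d2)
  expect_equal(est$rd, 1, tolerance = 3 * 0.1 / sqrt(60))
  # positive uptake in darkness is flagged
  expect_warning(estimate_rd(data.frame(A = rep(0.5, 10))),
                 regexp = "suspect")
  expect_error(estimate_rd(data.frame(A = -1)), class = "c4dyn_fit_error")
})

test_that("estimator suite recovers parameters within 5% median under stated noise", {
  # 2% multiplicative noise on A, 5% on gs; 50 replicates per estimator
  set.seed(101)
  n_rep <- 50

  # Ball-Berry
  base_bb <- make_bb_curve(5.183, 0.036)
  bb <- t(vapply(1:n_rep, function(i) {
    cc <- base_bb
    cc$A <- cc$A * (1 + rnorm(nrow(cc), 0, 0.02))
    cc$gs <- cc$gs * (1 + rnorm(nrow(cc), 0, 0.05))
    fit <- fit_ball_berry(cc)
    c(fit$slope_bb, fit$intercept_bb)
  }, c(0, 0)))
  expect_lt(abs(median(bb[, 1]) / 5.183 - 1), 0.05)

  # stomatal kinetics
  base_gs <- make_gs_series(0.3, 0.05, 0.2, "closing")
  ks <- vapply(1:n_rep, function(i) {
    cc <- base_gs
    cc$gs <- cc$gs * (1 + rnorm(nrow(cc), 0, 0.05))
    fit_gs_kinetics(cc, direction = "closing")$k
  }, 0)
  expect_lt(abs(median(ks) / 0.2 - 1), 0.05)

  # tau_Rubisco
  base_tau <- make_induction_series(35, -2, 5)
  taus <- vapply(1:n_rep, function(i) {
    cc <- base_tau
    cc$A <- cc$A * (1 + rnorm(nrow(cc), 0, 0.02))
    estimate_tau_rubisco(cc)$tau_min
  }, 0)
  expect_lt(abs(median(taus) / 5 - 1), 0.05)

  # Rd
  rds <- vapply(1:n_rep, function(i) {
    estimate_rd(data.frame(A = -2.282 * (1 + rnorm(12, 0, 0.02))))$rd
  }, 0)
  expect_lt(abs(median(rds) / 2.282 - 1), 0.05)

  # A-Ci
  ci <- c(300, 220, 150, 90, 50, 28, 14, 7, 300, 450, 600, 900, 1100)
  a0 <- aci_forward(ci, 124.1, 49.9, rd = 2.282)
  vp <- t(vapply(1:n_rep, function(i) {
    fit <- fit_aci(data.frame(Ci = ci,
                              A = a0 * (1 + rnorm(length(a0), 0, 0.02))),
                   rd = 2.282)
    c(fit$vpmax, fit$vcmax)
  }, c(0, 0)))
  expect_lt(abs(median(vp[, 1]) / 124.1 - 1), 0.05)
  expect_lt(abs(median(vp[, 2]) / 49.9 - 1), 0.05)
})

test_that("PDRP content is recovered from the early induction window", {
  p <- fix_params("maize")
  gx <- generate_gas_exchange("induction", p, sigma_a = 0, sigma_gs = 0,
                              seed = 1)
  fit <- estimate_pdrp(gx, p)
  expect_false(fit$flat)
  expect_equal(fit$pdrp, 0.058, tolerance = 0.02)
  # the objective is unimodal over a 10x bracket
  obj <- fit$grid$objective
  i_min <- which.min(obj)
  expect_true(all(diff(obj[seq_len(i_min)]) <= 0))
  expect_true(all(diff(obj[i_min:length(obj)]) >= 0))
  # degenerate window
  flat <- data.frame(time_s = seq(0, 300, 10), A = 5)
  expect_error(estimate_pdrp(flat, p), class = "c4dyn_degenerate_error")
})

test_that("PDRP recovery stays within 5% median under measurement noise", {
  p <- fix_params("maize")
  gx0 <- generate_gas_exchange("induction", p, sigma_a = 0, sigma_gs = 0,
                               seed = 1)
  win <- gx0[gx0$time_s >= 0 & gx0$time_s <= 220, ]
  # precompute the model response surface once (it does not depend on the
  # noise replicate), then fit each noisy replicate against it
  init <- dark_adapt(p)
  grid <- seq(0.03, 0.12, length.out = 13)
  t_out <- seq(60, 180, 10)
  resp <- vapply(grid, function(x) {
    p2 <- c4_params(c4dyn:::within_species(p, pdrp = x))
    sim <- c4_simulate(p2, forcing_induction(), 200, init = init,
                       pre_adapt = FALSE, dt_out = 5)
    approx(sim$time_s, sim$A, xout = t_out)$y
  }, numeric(length(t_out)))
  model_fun <- function(pdrp) {
    a_hat <- apply(resp, 1, function(row) spline(grid, row, xout = pdrp)$y)
    data.frame(time_s = t_out, A = a_hat)
  }
  set.seed(202)
  est <- vapply(1:50, function(i) {
    noisy <- win
    noisy$A <- noisy$A * (1 + rnorm(nrow(noisy), 0, 0.02))
    estimate_pdrp(noisy, p, bracket = c(0.03, 0.12),
                  model_fun = model_fun, n_grid = 5)$pdrp
  }, 0)
  expect_lt(abs(median(est) / 0.058 - 1), 0.05)
})

test_that("capacity scalars are recovered by the fixed-Ci least squares", {
  p <- fix_params("maize")
  aci <- generate_gas_exchange("aci", p, sigma_a = 0, sigma_gs = 0, seed = 1)
  f <- estimate_f_scalars(aci, p, sim_s = 600, n_pass = 1)
  # conditioned on measured Ci (the estimation route) rather than the Ca
  # setpoints (the generation route), recovery is close but not exact
  expect_equal(f$f_vmpepc, 0.72, tolerance = 0.03)
  expect_equal(f$f_vmrubisco, 0.67, tolerance = 0.03)
  expect_gt(f$f_vmpepc, 0.3)
  expect_lte(f$f_vmpepc, 1.5)
})
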