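# Constant input-sensitivity synthesis and the sensitivity-function algebra.

test_that("synthesis reproduces the deployed compensator coefficients", {
  d1 <- synthesize_constant_U(nominal_p1())
  expect_equal(signif(d1$C$num, 3), c(0.0350, 0.000496))
  expect_equal(d1$C$den, c(1, 0))
  expect_equal(d1$g0_prime, 1 / 28.57, tolerance = 1e-12)

  d2 <- synthesize_constant_U(nominal_p2())
  expect_equal(signif(d2$C$num, 3), c(0.0405, 0.00324, 0.0000574))
  expect_equal(length(d2$C$den), 3)
  expect_equal(d2$C$den[3], 0)                     # integrator pole exactly
  expect_equal(signif(d2$C$den[2], 3), 0.0801)     # s (s + h0')

  # unit plant 1/(s+1): C = (s+1)/s with unit input sensitivity
  du <- synthesize_constant_U(tf(1, c(1, 1)))
  expect_equal(du$g0_prime, 1)
  expect_tf_equal(du$C, tf(c(1, 1), c(1, 0)))
})

test_that("synthesis rejects invalid plants", {
  expect_error(synthesize_constant_U(tf(1, c(1, -0.1))), "unstable plant")
  expect_error(synthesize_constant_U(tf(c(1, 0), c(1, 1, 0.5))), "zero at origin")
  expect_error(synthesize_constant_U(tf(c(1, 1), c(1, 2))), "strictly proper")
})

test_that("closed forms agree coefficient-wise with the general synthesis", {
  d1 <- synthesize_constant_U(nominal_p1())
  c1 <- closed_form_first_order(28.57, 70.56)
  expect_tf_equal(d1$C, c1$C, tol = 1e-12)
  expect_tf_equal(d1$S, c1$S, tol = 1e-12)
  expect_tf_equal(d1$T, c1$T, tol = 1e-12)

  d2 <- synthesize_constant_U(nominal_p2())
  c2 <- closed_form_second_order(24.70, 18.60, 37.95)
  expect_tf_equal(d2$C, c2$C, tol = 1e-12)
  expect_tf_equal(d2$S, c2$S, tol = 1e-12)
  expect_tf_equal(d2$T, c2$T, tol = 1e-12)

  # integral action: zero steady-state error whatever the parameters
  expect_equal(tf_dcgain(c1$T), 1)
  expect_equal(tf_dcgain(c2$T), 1)
  expect_equal(tf_dcgain(c1$S), 0)
})

test_that("repeated-pole two-phase plant still yields a valid design", {
  tau <- 25
  d <- synthesize_constant_U(second_order_plant(20, tau, tau))
  expect_equal(d$H_prime, c(1, 2 / tau), tolerance = 1e-12)
  g <- generic_sensitivities(second_order_plant(20, tau, tau), d$C)
  expect_tf_equal(g$U, tf(1 / 20, 1), tol = 1e-6)
})

test_that("generic sensitivity oracle reduces to the pole-cancelled closed forms", {
  p2 <- nominal_p2()
  d2 <- synthesize_constant_U(p2)
  g <- generic_sensitivities(p2, d2$C)
  expect_tf_equal(g$U, tf(d2$g0_prime, 1), tol = 1e-6)
  expect_tf_equal(g$T, d2$T, tol = 1e-6)
  expect_tf_equal(g$S, d2$S, tol = 1e-6)
  # T2 poles are the open-loop plant poles (root accuracy is limited by the
  # multiple-root splitting of the uncancelled fraction, ~1e-5 relative)
  r <- sort(Re(polyroot(rev(g$T$den))))
  expect_equal(r, sort(c(-1 / 18.60, -1 / 37.95)), tolerance = 1e-4)

  p1 <- nominal_p1()
  u1 <- generic_sensitivities(p1, synthesize_constant_U(p1)$C)$U
  expect_tf_equal(u1, tf(1 / 28.57, 1), tol = 1e-6)

  # open loop: C = 0
  g0 <- generic_sensitivities(p2, tf(0, 1))
  expect_tf_equal(g0$S, tf(1, 1))
  expect_tf_equal(g0$T, tf(0, 1))
  expect_tf_equal(g0$U, tf(0, 1))
})

test_that("synthesis invariants hold over random stable plants", {
  set.seed(7)
  for (i in 1:200) {
    plant <- random_stable_plant(sample(1:4, 1))
    d <- synthesize_constant_U(plant)
    A <- plant$den
    # closed-loop characteristic polynomial AH + BG = A^2
    H <- poly_mul_(c(1, 0), d$H_prime)
    G <- d$g0_prime * A
    phi <- heartpace:::poly_add(poly_mul_(A, H), poly_mul_(plant$num, G))
    A2 <- poly_mul_(A, A)
    expect_lt(max(abs(phi - A2)), 1e-10 * max(abs(A2)))
    # flat input sensitivity at the value A(0)/B(0)
    g <- generic_sensitivities(plant, d$C)
    expect_equal(length(g$U$num), 1)
    expect_equal(g$U$num / d$g0_prime, 1, tolerance = 1e-6)
    # complementary relationships
    expect_equal(tf_dcgain(d$S), 0)
    expect_equal(tf_dcgain(d$T), 1, tolerance = 1e-9)
    expect_tf_equal(tf_minreal(tf_add(d$S, d$T)), tf(1, 1), tol = 1e-8)
  }
})

test_that("target response: critically damped double pole with requested rise time", {
  Tcl <- design_Tcl(150)
  # oracle: dense scan of the closed-form double-pole step response
  p_hat <- sqrt(Tcl$num)
  tg <- seq(0, 600, by = 0.01)
  y <- 1 - (1 + p_hat * tg) * exp(-p_hat * tg)
  t10 <- tg[which(y >= 0.1)[1]]; t90 <- tg[which(y >= 0.9)[1]]
  expect_equal(t90 - t10, 150, tolerance = 1e-3)
  expect_equal(p_hat, 0.02238, tolerance = 1e-3)
  expect_equal(tf_dcgain(Tcl), 1, tolerance = 1e-12)
  expect_equal(rise_time_10_90(Tcl), 150, tolerance = 0.5 / 150)
  # time scaling: doubling the rise time halves the pole
  expect_equal(sqrt(design_Tcl(300)$num) * 2, p_hat, tolerance = 1e-9)
})

test_that("prefilter inverts T_o up to the target response", {
  Tcl <- design_Tcl(150)
  for (plant in list(nominal_p1(), nominal_p2())) {
    d <- synthesize_constant_U(plant)
    pf <- design_prefilter(d$T, Tcl)
    expect_true(tf_is_proper(pf$C_pf))
    expect_tf_equal(tf_minreal(tf_mul(pf$C_pf, d$T)), Tcl, tol = 1e-9)
  }
  # first-order case in closed form: C_pf = tau (s + 1/tau) p^2/(s+p)^2
  d1 <- synthesize_constant_U(nominal_p1())
  pf1 <- design_prefilter(d1$T, Tcl)
  p <- sqrt(Tcl$num); tau <- 70.56
  manual <- tf(tau * p^2 * c(1, 1 / tau), poly_mul_(c(1, p), c(1, p)))
  expect_tf_equal(pf1$C_pf, manual, tol = 1e-9)
  # second-order case is biproper (relative degree 0)
  d2 <- synthesize_constant_U(nominal_p2())
  expect_equal(tf_rel_degree(design_prefilter(d2$T, Tcl)$C_pf), 0)
  # identity prefilter
  expect_tf_equal(design_prefilter(d2$T, d2$T)$C_pf, tf(1, 1))
  # non-minimum-phase T_o rejected
  expect_error(design_prefilter(tf(c(1, -0.1), c(1, 2, 1)), Tcl), "unstable prefilter")
  # T_cl slower roll-off than T_o rejected
  expect_error(design_prefilter(d2$T, tf(0.1, c(1, 0.1))), "improper")
})

test_that("HRV band edges are the conventional four frequencies", {
  e <- hrv_band_edges()
  expect_equal(unname(e), c(1 / 300, 0.04, 0.15, 0.4))
  expect_equal(unname(e[1]), 0.0033333, tolerance = 1e-4)
  expect_true(all(diff(e) > 0))
})

test_that("complementary sensitivities roll off at 20 and 40 dB per decade", {
  d1 <- synthesize_constant_U(nominal_p1())
  d2 <- synthesize_constant_U(nominal_p2())
  drop1 <- diff(-mag_db(freq_response(d1$T, c(1, 10))))
  drop2 <- diff(-mag_db(freq_response(d2$T, c(1, 10))))
  expect_equal(drop1, 20, tolerance = 0.1 / 20)
  expect_equal(drop2, 40, tolerance = 0.1 / 40)
})
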