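# Discretization, disturbance generation, cohorts and the closed-loop run.

test_that("Tustin discretization: integrator image, DC gain, frequency match", {
  f <- discretize_tustin(tf(1, c(1, 0)), Ts = 5)
  expect_equal(f$b, c(2.5, 2.5))
  expect_equal(f$a, c(1, -1))            # pole exactly at z = 1

  g <- tf(c(2, 0.3), c(1, 0.7, 0.1))
  fd <- discretize_tustin(g, Ts = 5)
  expect_equal(Re(heartpace:::poly_eval(fd$b, 1) / heartpace:::poly_eval(fd$a, 1)),
               tf_dcgain(g), tolerance = 1e-12)

  c1 <- synthesize_constant_U(nominal_p1())$C
  fc <- discretize_tustin(c1, Ts = 5)
  hc <- freq_response(c1, 0.001)
  hd <- heartpace:::discrete_freq_response(fc, 0.001)
  expect_equal(Mod(hd) / Mod(hc), 1, tolerance = 0.01)
  expect_error(discretize_tustin(tf(c(1, 0, 0), c(1, 1)), 5), "proper")
})

test_that("Tustin coefficients match signal::bilinear on a strictly proper filter", {
  skip_if_not_installed("signal")
  g <- tf(c(2, 0.3), c(1, 0.7, 0.1))
  ours <- discretize_tustin(g, Ts = 5)
  ref <- signal::bilinear(Sz = polyroot(rev(g$num)), Sp = polyroot(rev(g$den)),
                          Sg = g$num[1], T = 5)
  ref_b <- Re(ref$gain * heartpace:::poly_from_roots(ref$zero))
  ref_a <- Re(heartpace:::poly_from_roots(ref$pole))
  expect_equal(ours$b[-1] / ours$b[1], ref_b[-1] / ref_b[1], tolerance = 1e-9)
  expect_equal(ours$a, ref_a, tolerance = 1e-9)
  expect_equal(ours$b[1], Re(ref$gain), tolerance = 1e-9)
})

test_that("target heart rate follows the age prediction equation", {
  expect_equal(target_hr(30), 0.765 * 190)
  expect_lt(target_hr(57), target_hr(23))
  expect_error(target_hr(220))
})

test_that("HRV-like disturbance: scale, determinism, zero case", {
  expect_identical(gen_hrv_disturbance(100, sd = 0, seed = 3), numeric(100))
  a <- gen_hrv_disturbance(500, sd = 2, seed = 9)
  b <- gen_hrv_disturbance(500, sd = 2, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, gen_hrv_disturbance(500, sd = 2, seed = 10)))
  big <- gen_hrv_disturbance(1e6, sd = 2, cutoff_hz = 0.05, seed = 4)
  expect_equal(sd(big), 2, tolerance = 0.02)
  expect_equal(mean(big), 0, tolerance = 0.05)
})

test_that("cohort sampling: nominal centre, size, determinism", {
  c0 <- sample_cohort(5, seed = 2, cv = 0)
  expect_equal(c0$k2, rep(24.70, 5))
  expect_equal(c0$tau21, rep(18.60, 5))
  expect_equal(c0$tau22, rep(37.95, 5))
  expect_equal(nrow(sample_cohort(23, seed = 1)), 23)
  expect_identical(sample_cohort(8, seed = 5), sample_cohort(8, seed = 5))
  ch <- sample_cohort(1e4, seed = 3, cv = 0.2)
  expect_equal(mean(ch$k2), 24.70, tolerance = 0.02)
  expect_true(all(ch$tau21 <= ch$tau22))
  expect_true(all(ch$age >= 23 & ch$age <= 57))
  expect_true(all(ch$hr_rest >= 60 & ch$hr_rest <= 80))
})

test_that("matched nominal session: tracking, steady state, timing", {
  d2 <- synthesize_constant_U(nominal_p2())
  pf <- design_prefilter(d2$T, design_Tcl(150))
  ses <- simulate_session(quiet_truth(), d2, pf, protocol_spec())
  s <- ses$series
  expect_equal(nrow(s), 2100)
  # speed changes only at 5 s boundaries
  changes <- which(diff(s$speed_cmd_mps) != 0)
  expect_true(all(s$t_s[changes + 1] %% 5 == 0))
  # no noise: measured equals true heart rate exactly
  expect_identical(s$hr_meas_bpm, s$hr_true_bpm)
  # integral action: tiny steady-state error, exact steady-state speed
  expect_lt(max(abs(ses$control$err_bpm[ses$control$t_s > 600])), 0.01)
  expect_equal(tail(s$speed_cmd_mps, 1),
               (ses$target_hr_bpm - 70) / 24.70, tolerance = 1e-6)
  # evaluation-window RMSE against the nominal simulated response
  expect_lt(session_outcomes(ses, "trajectory")$rmse_bpm, 0.05)
  # determinism is bit-exact
  ses2 <- simulate_session(quiet_truth(), d2, pf, protocol_spec())
  expect_identical(ses$series, ses2$series)
})

test_that("plant propagation is exact zero-order-hold", {
  p2 <- nominal_p2()
  pd <- heartpace:::ss_zoh(heartpace:::tf_to_ss(p2), 1)
  x <- matrix(0, 2, 1); y <- numeric(400)
  for (k in 1:400) {
    y[k] <- as.numeric(pd$C %*% x)
    x <- pd$Ad %*% x + pd$Bd * 1          # unit speed step
  }
  cont <- step_response(p2, 0:399)$y
  expect_lt(max(abs(y - cont)), 1e-4)
})

test_that("refining the control interval converges to the continuous response", {
  d2 <- synthesize_constant_U(nominal_p2())
  pf <- design_prefilter(d2$T, design_Tcl(150))
  ses <- simulate_session(quiet_truth(), d2, pf, protocol_spec(control_Ts = 1))
  dev <- ses$series$hr_true_bpm - ses$series$hr_sim_bpm
  expect_lt(max(abs(dev)), 0.15)
})

test_that("saturation engages with anti-windup and the loop stays bounded", {
  d2 <- synthesize_constant_U(nominal_p2())
  pf <- design_prefilter(d2$T, design_Tcl(150))
  # steady state needs ~3 m/s; cap at 2 m/s
  ses <- simulate_session(quiet_truth(), d2, pf, protocol_spec(), u_max = 2)
  u <- ses$series$speed_cmd_mps
  expect_true(all(u <= 2 + 1e-12))
  expect_gt(mean(u == 2), 0.5)                     # saturated most of the run
  expect_lt(max(ses$series$hr_true_bpm), 145)      # cannot reach target
  expect_true(all(is.finite(ses$series$hr_true_bpm)))
  # release the cap within the same protocol: no residual windup blow-up
  expect_lt(max(abs(ses$control$err_bpm)) , 80)
})

test_that("paired experiment shares disturbance and noise across matched arms", {
  coh <- sample_cohort(2, seed = 21, cv = 0.2)
  out <- run_paired_experiment(coh, keep_sessions = TRUE)
  expect_equal(nrow(out), 4)
  expect_setequal(out$controller, c("C1", "C2"))
  for (pid in unique(out$participant_id)) {
    pair <- out[out$participant_id == pid, ]
    s1 <- pair$session[[1]]$series
    s2 <- pair$session[[2]]$series
    expect_identical(s1$disturbance_bpm, s2$disturbance_bpm)
    expect_identical(s1$noise_bpm, s2$noise_bpm)
  }
})
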