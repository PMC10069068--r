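test_that("the passive model obeys Ohm's law and rests at Vrest", {
  cc <- simulate_rc_sweeps(12, 62, -80, cc_protocol(steps = 0), noise_sd = 0)
  expect_true(all(abs(cc$response + 80) < 1e-9))
  cc2 <- simulate_rc_sweeps(12, 62, -80, cc_protocol(steps = -100),
                            noise_sd = 0)
  ss <- perivasc:::cc_step_table(cc2)
  expect_equal(ss$dv[ss$di == -100], -1.2, tolerance = 1e-3)  # I*Rm, mV
})

test_that("the fitted time constant matches Rm*Cm on clean sweeps", {
  cc <- simulate_rc_sweeps(12, 62, -71.5, cc_protocol(), noise_sd = 0)
  expect_equal(membrane_tau(cc), 12 * 62 * 1e-3, tolerance = 0.02)
})

test_that("resting potential averages zero-current baselines", {
  cc <- simulate_rc_sweeps(15, 50, -86.5, cc_protocol(), noise_sd = 0.2,
                           seed = 4)
  expect_equal(resting_potential(cc), -86.5, tolerance = 0.05)
  flat <- simulate_rc_sweeps(10, 50, -80, cc_protocol(steps = 0), noise_sd = 0)
  expect_equal(resting_potential(flat), -80)
  # two equal-length baselines at -80 and -82 average to -81
  two <- simulate_rc_sweeps(10, 50, -80, cc_protocol(steps = 0), noise_sd = 0)
  two$response <- cbind(two$response, two$response - 2)
  two$command <- cbind(two$command, two$command)
  expect_equal(resting_potential(two), -81)
  vc <- simulate_rc_sweeps(10, 50, -80, vc_protocol())
  expect_error(resting_potential(vc), "current-clamp")
})

test_that("input resistance is the slope of the linear steady-state range", {
  cc <- simulate_rc_sweeps(11.98, 62, -71.5, cc_protocol(), noise_sd = 0.1,
                           seed = 6)
  expect_equal(input_resistance(cc), 11.98, tolerance = 0.1)
  # perfectly ohmic: any subset gives the same slope
  cc0 <- simulate_rc_sweeps(20, 60, -80, cc_protocol(), noise_sd = 0)
  expect_equal(input_resistance(cc0), 20, tolerance = 1e-3)
  short <- simulate_rc_sweeps(20, 60, -80, cc_protocol(steps = c(-400, 400)),
                              noise_sd = 0)
  expect_error(input_resistance(short), "3")
})

test_that("saturating extreme steps are excluded by the linear-range screen", {
  cc <- simulate_rc_sweeps(10, 60, -80, cc_protocol(), noise_sd = 0)
  # clip the response of the largest hyperpolarizing step (saturation)
  cc$response[cc$response < -84] <- -84
  rin <- input_resistance(cc)
  expect_equal(rin, 10, tolerance = 0.01)
})

test_that("resting conductance is dI/dV for the -10 mV step", {
  vc <- simulate_rc_sweeps(1000 / 27, 60, -85, vc_protocol(holding = -85),
                           noise_sd = 0)
  expect_equal(resting_conductance(vc), 27, tolerance = 1e-3)
  vc2 <- simulate_rc_sweeps(10, 60, -85, vc_protocol(holding = -85),
                            noise_sd = 0)
  expect_equal(resting_conductance(vc2), 100, tolerance = 1e-3)
  no10 <- simulate_rc_sweeps(10, 60, -85,
                             vc_protocol(delta_mv = c(-30, -50), holding = -85))
  expect_error(resting_conductance(no10), "-10 mV")
})

test_that("steady-state I-V is linear for passive cells and flat without conductance", {
  vc <- simulate_rc_sweeps(1000 / 27, 62, -85, vc_protocol(holding = -85),
                           noise_sd = 0.5, seed = 9)
  iv <- steady_state_iv(vc)
  expect_gt(attr(iv, "r_squared"), 0.999)
  expect_equal(attr(iv, "slope_ns"), 27, tolerance = 0.02)
  # an onset window feels the capacitive transient, the terminal one does not
  iv_on <- steady_state_iv_window_check <- local({
    vc0 <- simulate_rc_sweeps(20, 100, -85, vc_protocol(holding = -85),
                              noise_sd = 0)
    on <- steady_state_iv(vc0, window = 1)  # includes the onset transient
    off <- steady_state_iv(vc0, window = 0.2)
    abs(attr(on, "slope_ns") - attr(off, "slope_ns"))
  })
  expect_gt(iv_on, 0.3)
  expect_error(steady_state_iv(vc, window = 1.5), "window")
})

test_that("junction-potential correction shifts voltages once and only once", {
  expect_equal(correct_ljp(-71.47), -86.47)
  expect_equal(correct_ljp(0, ljp = 0), 0)
  cc <- simulate_rc_sweeps(12, 62, -71.47, cc_protocol(), noise_sd = 0)
  vc <- simulate_rc_sweeps(12, 62, -71.47, vc_protocol(holding = -71.47),
                           noise_sd = 0)
  mp <- membrane_props(cc, vc)
  mpc <- correct_ljp(mp)
  expect_equal(mpc$vm, -86.47, tolerance = 0.01)
  expect_true(mpc$ljp_corrected)
  expect_error(correct_ljp(mpc), "already")
})

test_that("Nernst potentials reproduce the potassium equilibrium values", {
  out <- solution(c(K = 3), temperature = 306.15)
  std <- solution(c(K = 140), temperature = 306.15)
  mod <- solution(c(K = 135), temperature = 306.15)
  e_std <- nernst("K", std, out)
  e_mod <- nernst("K", mod, out)
  expect_equal(e_std, -101.39, tolerance = 0.005)
  expect_equal(e_mod, -100.42, tolerance = 0.01)
  expect_equal(e_std - e_mod, -0.96, tolerance = 0.01)
  expect_equal(nernst("K", std, std), 0)
  # antisymmetry under swapping compartments
  expect_equal(nernst("K", out, std), -e_std)
  expect_error(nernst("Na", std, out), "missing")
  expect_error(solution(c(K = -1)), "> 0")
})

test_that("membrane properties satisfy the conductance-resistance identity", {
  for (s in 1:5) {
    Rm <- runif(1, 5, 30)
    cc <- simulate_rc_sweeps(Rm, 60, -85, cc_protocol(), noise_sd = 0.1,
                             seed = s)
    vc <- simulate_rc_sweeps(Rm, 60, -85, vc_protocol(holding = -85),
                             noise_sd = 1, seed = s + 100)
    mp <- membrane_props(cc, vc)
    expect_equal(mp$gm * mp$rin, 1000, tolerance = 0.02)
  }
})

test_that("membrane-property PCA separates constructed clusters and not resamples", {
  set.seed(3)
  grp1 <- data.frame(vm = rnorm(15, -85, 1), gm = rnorm(15, 27, 2),
                     rin = rnorm(15, 12, 1), cm = rnorm(15, 60, 4))
  grp2 <- data.frame(vm = rnorm(15, -60, 1), gm = rnorm(15, 80, 2),
                     rin = rnorm(15, 40, 1), cm = rnorm(15, 20, 4))
  sep <- pca_membrane_props(rbind(grp1, grp2),
                            group = rep(c("a", "b"), each = 15))
  expect_false(sep$group_summary$overlapping)
  expect_gt(sep$group_summary$centroid_distance,
            sep$group_summary$within_spread)

  resample <- pca_membrane_props(rbind(grp1[1:7, ], grp1[8:14, ]),
                                 group = rep(c("a", "b"), each = 7))
  expect_true(resample$group_summary$overlapping)

  expect_equal(sum(sep$explained), 4)   # standardized-variable PCA
  cst <- grp1; cst$cm <- 5
  expect_error(pca_membrane_props(cst), "cm")
})
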