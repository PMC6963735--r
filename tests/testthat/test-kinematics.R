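test_that("tail and fin angles follow the two-DOF sinusoid model", {
  mc <- toy_case(theta_T = 3.44, theta_C = 0, phi = 0)
  expect_equal(tail_angle(mc, 0.25), 3.44)
  mc0 <- toy_case(theta_T = 0, theta_C = 0)
  expect_equal(tail_angle(mc0, seq(0, 1, by = 0.1)), rep(0, 11))

  mc2 <- toy_case(theta_T = 2.01, theta_C = 9.03, phi = 70, dT = 0.20)
  expect_equal(tail_angle(mc2, 0), 2.01 * sin(70 * pi / 180) + 0.20)

  mcf <- toy_case(theta_C = 12.90, phi = 0)
  expect_equal(fin_angle(mcf, 0.25), 12.90)
  mcf0 <- toy_case(theta_C = 0, dC = -1.2)
  expect_equal(fin_angle(mcf0, c(0, 0.3, 0.7)), rep(-1.2, 3))
  mcf2 <- toy_case(theta_C = 9.03, dC = -2.1)
  expect_equal(fin_angle(mcf2, 0), -2.1)
})

test_that("trailing-edge excursion evaluates the two-link geometry", {
  mc0 <- toy_case(theta_T = 0, theta_C = 0)
  expect_equal(trailing_edge_excursion(mc0, seq(0, 1, 0.05)), rep(0, 21))

  mc <- toy_case(theta_T = 3, theta_C = 5, phi = 0, LT = 0.05, c = 0.04)
  expect_equal(trailing_edge_excursion(mc, 0.25),
               0.05 * sin(3 * pi / 180) + 0.04 * sin(8 * pi / 180))

  # peak |a| on a 1000-point cycle matches a much denser brute-force search
  mc70 <- toy_case(theta_T = 3, theta_C = 5, phi = 70, LT = 0.05, c = 0.04)
  coarse <- max(abs(trailing_edge_excursion(mc70, seq(0, 1, length.out = 1001))))
  dense <- max(abs(trailing_edge_excursion(mc70, seq(0, 1, length.out = 2e5))))
  expect_equal(coarse, dense, tolerance = 1e-4)

  mc_na <- motion_case("g", theta_T_amp = 1, theta_C_amp = 1, phi = 0,
                       freq = 1, te_excursion_max = 0.01, freestream = 0.1)
  expect_error(trailing_edge_excursion(mc_na, 0), "tail_length")
})

test_that("misalignment offsets are excluded from the excursion by default", {
  mc <- toy_case(theta_T = 3, theta_C = 5, phi = 0, dT = 0.5, dC = -1)
  expect_equal(trailing_edge_excursion(mc, 0.1),
               trailing_edge_excursion(toy_case(theta_T = 3, theta_C = 5,
                                                phi = 0), 0.1))
  expect_false(isTRUE(all.equal(
    trailing_edge_excursion(mc, 0.1, include_misalignment = TRUE),
    trailing_edge_excursion(mc, 0.1))))
})

test_that("resultant amplitude/phase of summed sinusoids is exact", {
  r <- resultant_amplitude_phase(0.4, 0.6, 0)
  expect_equal(r$amplitude, 1.0)
  expect_equal(r$psi, 0)

  r2 <- resultant_amplitude_phase(1, 1, 90)
  expect_equal(r2$amplitude, sqrt(2))
  expect_equal(r2$psi, 45)

  # dense-grid oracle: peak and peak-time of the sampled sum
  amp_T <- 0.3; amp_C <- 1.0; phi <- 70
  t <- seq(0, 1, length.out = 2e5 + 1)
  s <- amp_T * sin(2 * pi * t + phi * pi / 180) + amp_C * sin(2 * pi * t)
  r3 <- resultant_amplitude_phase(amp_T, amp_C, phi)
  expect_equal(r3$amplitude, max(s), tolerance = 1e-8)
  t_peak <- t[which.max(s)]
  psi_oracle <- 90 - 360 * t_peak      # peak of sin(wt + psi) at wt = 90 - psi
  expect_equal(r3$psi, psi_oracle, tolerance = 1e-2)

  r0 <- resultant_amplitude_phase(0, 0, 30)
  expect_true(r0$degenerate)
  expect_equal(r0$amplitude, 0)
})

test_that("resultant amplitude obeys the triangle bound and phase limits", {
  set.seed(42)
  for (i in 1:25) {
    aT <- runif(1, 0, 2); aC <- runif(1, 0, 2); phi <- runif(1, 0, 359.99)
    r <- resultant_amplitude_phase(aT, aC, phi)
    expect_lte(r$amplitude, aT + aC + 1e-12)
    if (phi > 1 && phi < 359) expect_lt(r$amplitude, aT + aC)
  }
  expect_equal(resultant_amplitude_phase(1e-9, 1, 70)$psi, 0, tolerance = 1e-6)
  expect_equal(resultant_amplitude_phase(1, 1e-12, 70)$psi, 70,
               tolerance = 1e-9)
})

test_that("Strouhal and Reynolds numbers are the standard ratios", {
  mc1 <- motion_case(1, 0.24, 12.90, 0, 1, te_excursion_max = 0.0251,
                     freestream = 0.0815)
  expect_equal(round(strouhal(mc1), 3), 0.308)
  mc6 <- motion_case(6, 2.06, 9.12, 70, 1, te_excursion_max = 0.0240,
                     freestream = 0.0595)
  expect_equal(round(strouhal(mc6), 3), 0.403)
  mc0 <- motion_case(0, 0, 0, 0, 1, te_excursion_max = 0,
                     freestream = 0.1)
  expect_equal(strouhal(mc0), 0)

  mcr <- motion_case("r", 1, 1, 0, 1, te_excursion_max = 0.01,
                     freestream = 1, body_length = 1,
                     kinematic_viscosity = 1)
  expect_equal(reynolds(mcr), 1)
  mcr2 <- motion_case("r2", 1, 1, 0, 1, te_excursion_max = 0.01,
                      freestream = 0.0595, body_length = 0.286,
                      kinematic_viscosity = 1e-6)
  expect_equal(reynolds(mcr2), 0.0595 * 0.286 / 1e-6)  # ~1.70e4
  mcr3 <- mcr2; mcr3$freestream <- 2 * mcr2$freestream
  expect_equal(reynolds(mcr3), 2 * reynolds(mcr2))
  mc_no_geom <- motion_case("g", 1, 1, 0, 1, te_excursion_max = 0.01,
                            freestream = 0.1)
  expect_error(reynolds(mc_no_geom), "body_length")
})

test_that("fixed-frequency sinusoid fitting recovers its own model class", {
  t <- seq(0, 2, length.out = 51)
  y <- 12.9 * sin(2 * pi * t + 0.4) - 3.4
  fit <- fit_sinusoid_with_offset(angle_trace(t, y), freq = 1)
  expect_equal(fit$amplitude, 12.9, tolerance = 1e-9)
  expect_equal(fit$offset, -3.4, tolerance = 1e-9)
  expect_equal(fit$phase, 0.4 * 180 / pi, tolerance = 1e-7)
  expect_lt(fit$rms_residual, 1e-10)

  fitc <- fit_sinusoid_with_offset(angle_trace(t, rep(2.5, 51)), freq = 1)
  expect_equal(fitc$amplitude, 0, tolerance = 1e-10)
  expect_equal(fitc$offset, 2.5, tolerance = 1e-10)

  set.seed(7)
  tn <- seq(0, 4, length.out = 100)
  yn <- 12.9 * sin(2 * pi * tn) - 3.4 + rnorm(100, 0, 0.2)
  fitn <- fit_sinusoid_with_offset(angle_trace(tn, yn), freq = 1)
  tol <- 3 * 0.2 / sqrt(100)
  expect_lt(abs(fitn$amplitude - 12.9), tol)
  expect_lt(abs(fitn$offset + 3.4), tol)

  expect_error(fit_sinusoid_with_offset(angle_trace(t[1:4], y[1:4]), 1),
               "at least 5")
})

test_that("TE trace of a sinusoid has quadrature velocity and extrema", {
  # pure fin pitching, small angle: a(t) ~ c*sin(theta_C(t)) peaks at 0.25/0.75
  mc <- toy_case(theta_T = 0, theta_C = 5, phi = 0, LT = 0.05, c = 0.04)
  tr <- te_trace(mc, n_phases = 25)
  expect_equal(tr$extrema_phases, c(0.25, 0.75), tolerance = 1e-3)
  expect_equal(nrow(tr$intervals), 4)
  expect_true(all(tr$intervals$regime %in% c("accelerating", "decelerating")))

  # exact sinusoidal excursion series: centred-difference peak velocity is
  # 2 pi f A * sinc(2 pi / n)
  n <- 25; A <- 0.011
  ph <- (0:(n - 1)) / n
  tr2 <- te_trace_from_series(ph, A * sin(2 * pi * ph), period = 1)
  fd_factor <- sin(2 * pi / n) / (2 * pi / n)
  expect_equal(max(abs(tr2$velocity)), 2 * pi * A * fd_factor,
               tolerance = 1e-9)
  expect_equal(max(abs(tr2$velocity)), 2 * pi * A, tolerance = 0.015)
  # velocity leads excursion by a quarter cycle
  expect_equal(which.max(tr2$velocity) - which.max(tr2$excursion),
               -round(n / 4))
})

test_that("TE trace of the dwell waveform matches its analytic derivative", {
  n <- 50; A <- 0.012; df <- 0.2
  ph <- (0:(n - 1)) / n
  a <- dwell_waveform(ph, A, df)
  tr <- te_trace_from_series(ph, a, period = 1)
  van <- dwell_waveform_velocity(ph, A, df, period = 1)
  # warp kinks: phases within one bin of a slope discontinuity
  W <- df / 2
  kinks <- sort(c(0.25 + c(-1, 1) * W / 2, 0.75 + c(-1, 1) * W / 2))
  near_kink <- vapply(ph, function(p)
    any(abs(p - kinks) <= 1 / n + 1e-9), logical(1))
  expect_lt(max(abs(tr$velocity - van)[!near_kink]),
            0.02 * max(abs(van)))
  # velocity is identically zero in the dwell interior
  dwell <- abs(ph - 0.25) < W / 2 - 1e-9 | abs(ph - 0.75) < W / 2 - 1e-9
  expect_true(all(abs(van[dwell]) < 1e-14))
})

test_that("acceleration/deceleration intervals tile the cycle and alternate", {
  mc <- toy_case(theta_T = 0, theta_C = 5, phi = 0, LT = 0.05, c = 0.04)
  tr <- te_trace(mc, n_phases = 40)
  iv <- tr$intervals
  # tiles [0,1) modulo the cyclic wrap of the last interval
  expect_equal(sum(iv$end - iv$start), 1)
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_true(all(iv$regime[-1] != iv$regime[-nrow(iv)]))

  # degenerate all-zero velocity is flagged
  trz <- te_trace_from_series((0:9) / 10, rep(0, 10))
  expect_true(attr(trz$intervals, "degenerate"))
  expect_equal(trz$intervals$regime, "constant")
})

test_that("dwell-waveform speed segmentation matches a dense-grid oracle", {
  A <- 0.01; df <- 0.25; n <- 100
  ph <- (0:(n - 1)) / n
  tr <- te_trace_from_series(ph, dwell_waveform(ph, A, df))
  iv <- tr$intervals
  # oracle: sign changes of d|v|/dt from the analytic derivative on a
  # dense grid
  phd <- seq(0, 1, length.out = 2e4 + 1)[-(2e4 + 1)]
  spd <- abs(dwell_waveform_velocity(phd, A, df))
  ds <- diff(c(spd, spd[1]))
  oracle_bnd <- phd[which(sign(ds) != c(sign(ds[length(ds)]),
                                        sign(ds[-length(ds)])) &
                            sign(ds) != 0)]
  for (b in iv$start) {
    expect_lt(min(abs(c(b - oracle_bnd, b - oracle_bnd + 1,
                        b - oracle_bnd - 1))), 1.5 / n)
  }
})

test_that("excursion is periodic and odd-symmetric for phi in {0, 180}", {
  for (phi in c(0, 180)) {
    mc <- toy_case(theta_T = 2, theta_C = 6, phi = phi, LT = 0.05, c = 0.04)
    t <- seq(0, 1, length.out = 101)
    expect_equal(trailing_edge_excursion(mc, t),
                 trailing_edge_excursion(mc, t + 1), tolerance = 1e-12)
    expect_equal(trailing_edge_excursion(mc, t),
                 -trailing_edge_excursion(mc, t + 0.5), tolerance = 1e-12)
  }
})
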