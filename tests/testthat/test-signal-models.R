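# Frozen reference values were computed before the build with an
# independent 40-digit implementation of the same closed forms
# (mpmath): see the values' comments.

test_that("Bessel-derivative roots match the classical constants", {
  r <- bessel_j1prime_roots(3)
  expect_equal(r, c(1.84118378134066, 5.33144277352503, 8.53631636634629),
               tolerance = 1e-10)
})

test_that("GPD cylinder signal matches the high-precision oracle and its limits", {
  # R=1.25 um, D=0.6 um^2/ms, G=300 mT/m, delta=10.5 ms, Delta=16.9 ms
  s <- cylinder_perp_gpd(1.25e-6, 0.6e-9, 0.3, 10.5e-3, 16.9e-3)
  expect_equal(log(s), -0.03718642632092776, tolerance = 1e-6)

  expect_equal(cylinder_perp_gpd(1e-6, 0.6e-9, 0, 10e-3, 20e-3), 1)
  expect_gt(cylinder_perp_gpd(1e-9, 0.6e-9, 1.35, 8.6e-3, 13.6e-3), 0.9999)
  expect_error(cylinder_perp_gpd(-1e-6, 0.6e-9, 0.3, 5e-3, 10e-3), "positive")
  expect_error(cylinder_perp_gpd(1e-6, 0, 0.3, 5e-3, 10e-3), "positive")

  # monotone non-increasing in R at fixed acquisition
  rr <- seq(0.2, 3, by = 0.2) * 1e-6
  ss <- cylinder_perp_gpd(rr, 0.6e-9, 1.35, 8.6e-3, 13.6e-3)
  expect_true(all(diff(ss) <= 0))
  expect_true(all(ss > 0 & ss <= 1))

  # series truncation: across the dictionary grid extremes the default 20
  # roots sit within 1e-7 of a 60-root evaluation (slowest convergence is
  # the 6-um diameter against the 1.1-ms pulse, far below any noise floor)
  for (d in c(0.1e-6, 1e-6, 6e-6)) {
    for (sh in P5$shells) {
      s20 <- cylinder_perp_gpd(d / 2, 0.6e-9, sh$G, sh$delta, sh$Delta,
                               n_roots = 20L)
      s60 <- cylinder_perp_gpd(d / 2, 0.6e-9, sh$G, sh$delta, sh$Delta,
                               n_roots = 60L)
      expect_equal(s20, s60, tolerance = 1e-7)
    }
  }
})

test_that("wide-pulse closed form matches its oracle and the R^4 scaling", {
  s <- cylinder_perp_wide_pulse(1.25e-6, 0.6e-9, 0.3, 10.5e-3)
  expect_equal(log(s), -0.03572092491496640, tolerance = 1e-9)
  expect_equal(cylinder_perp_wide_pulse(0, 0.6e-9, 0.3, 10.5e-3), 1)

  # leading order: log-attenuation scales as R^4 when the R^2/D correction
  # is negligible relative to 2*delta
  R <- 0.3e-6; D <- 0.6e-9; delta <- 20e-3
  expect_lt((99 / 112) * R^2 / D / (2 * delta), 0.01)
  ratio <- log(cylinder_perp_wide_pulse(2 * R, D, 0.1, delta)) /
    log(cylinder_perp_wide_pulse(R, D, 0.1, delta))
  expect_equal(ratio, 16, tolerance = 0.02)
})

test_that("GPD and wide-pulse forms agree in the wide-pulse regime", {
  # D * delta / R^2 > 10 across the dictionary grid
  D <- 0.6e-9
  for (sh in list(P3$shells[[3]], P5$shells[[5]])) {
    for (d_um in c(0.5, 1, 2, 2.5)) {
      R <- d_um * 1e-6 / 2
      if (D * sh$delta / R^2 <= 10) next
      lg <- log(cylinder_perp_gpd(R, D, sh$G, sh$delta, sh$Delta))
      lw <- log(cylinder_perp_wide_pulse(R, D, sh$G, sh$delta))
      expect_lt(abs(lw - lg) / abs(lg), 0.05)
    }
  }
})

test_that("cylinder signal decomposes into parallel and perpendicular factors", {
  meas_at <- function(u) data.frame(shell = 1L, G = 0.3, delta = 5.6e-3,
                                    Delta = 12.1e-3, TE = 35e-3,
                                    ux = u[1], uy = u[2], uz = u[3],
                                    b = b_value(pgse_shell(1, 0.3, 5.6e-3, 12.1e-3, 35e-3)))
  p <- mmwmd_params(a = 2e-6, v_intra = 1, v_extra = 0, n = c(0, 0, 1))
  # parallel: pure Gaussian attenuation
  m <- meas_at(c(0, 0, 1))
  expect_equal(cylinder_signal(p, m), exp(-m$b * p$d_par), tolerance = 1e-12)
  # perpendicular: pure GPD factor
  m <- meas_at(c(1, 0, 0))
  expect_equal(cylinder_signal(p, m),
               cylinder_perp_gpd(1e-6, p$d_par, 0.3, 5.6e-3, 12.1e-3),
               tolerance = 1e-12)
  # 45 degrees: product of both, via explicit decomposition
  u <- c(1, 0, 1) / sqrt(2)
  m <- meas_at(u)
  G_par <- 0.3 / sqrt(2); G_perp <- 0.3 / sqrt(2)
  consts <- physical_constants()
  q_par <- consts$gamma * 5.6e-3 * G_par / (2 * pi)
  td <- 12.1e-3 - 5.6e-3 / 3
  expect_equal(cylinder_signal(p, m),
               exp(-(2 * pi * q_par)^2 * td * p$d_par) *
                 cylinder_perp_gpd(1e-6, p$d_par, G_perp, 5.6e-3, 12.1e-3),
               tolerance = 1e-12)
})

test_that("zeppelin follows the tortuosity model", {
  meas <- protocol_measurements(mini_protocol())
  # v_intra = 0: d_perp = d_par, isotropic Gaussian
  p0 <- mmwmd_params(a = 1e-6, v_intra = 0, v_extra = 1, n = c(1, 0, 0))
  expect_equal(zeppelin_signal(p0, meas), exp(-meas$b * p0$d_par),
               tolerance = 1e-12)
  # hand arithmetic: v_intra=0.7, v_extra=0.2 -> d_perp = 0.6*0.2/0.9
  p <- mmwmd_params(a = 1e-6, v_intra = 0.7, v_extra = 0.2, v_iso = 0.1,
                    n = c(0, 0, 1))
  d_perp <- 0.6e-9 * 0.2 / 0.9
  expect_equal(d_perp * 1e9, 0.13333333333, tolerance = 1e-9)
  m_perp <- meas[1, ]; m_perp$ux <- 1; m_perp$uy <- 0; m_perp$uz <- 0
  expect_equal(zeppelin_signal(p, m_perp), exp(-m_perp$b * d_perp),
               tolerance = 1e-12)
  p_bad <- mmwmd_params(a = 1e-6, v_intra = 0, v_extra = 0, v_iso = 1,
                        n = c(1, 0, 0))
  expect_error(zeppelin_signal(p_bad, meas), "positive")
})

test_that("ball and dot compartments behave as Gaussian and stationary pools", {
  meas <- protocol_measurements(mini_protocol(n_b0 = 2L))
  expect_equal(dot_signal(meas), rep(1, nrow(meas)))
  expect_equal(ball_signal(2e-9, meas[meas$G == 0, ]), rep(1, 2))
  # b = 3080 s/mm2 at d_iso = 2 um^2/ms -> exp(-6.16)
  m <- meas[1, ]; m$b <- 3080e6
  expect_equal(ball_signal(2e-9, m), exp(-6.16), tolerance = 1e-12)
})

test_that("composite MMWMD signal is the fraction-weighted compartment sum", {
  prot <- mini_protocol(n_b0 = 1L)
  meas <- protocol_measurements(prot)
  p_dot <- mmwmd_params(a = 1e-6, v_intra = 0, v_extra = 0, v_iso = 0,
                        v_dot = 1, n = c(1, 0, 0))
  expect_equal(mmwmd_signal(p_dot, prot), rep(1, nrow(meas)))

  p <- mmwmd_params(a = 2e-6, v_intra = 0.6, v_extra = 0.25, v_iso = 0.1,
                    v_dot = 0.05, n = c(0, 1, 0))
  manual <- 0.6 * cylinder_signal(p, meas) + 0.25 * zeppelin_signal(p, meas) +
    0.1 * ball_signal(p$d_iso, meas) + 0.05
  manual[meas$G == 0] <- 1
  expect_equal(mmwmd_signal(p, prot), manual, tolerance = 1e-12)
  expect_true(all(mmwmd_signal(p, prot) > 0 & mmwmd_signal(p, prot) <= 1))
})

test_that("the composite signal is rotation invariant", {
  prot <- mini_protocol()
  meas <- protocol_measurements(prot)
  p <- mmwmd_params(a = 2e-6, v_intra = 0.7, v_extra = 0.3, n = c(1, 0, 0))
  s0 <- mmwmd_signal(p, meas)
  # rotate fibre and all gradient directions by the same rotation
  th <- 0.7; ph <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  Rot <- Rx %*% Rz
  u_rot <- cbind(meas$ux, meas$uy, meas$uz) %*% t(Rot)
  meas2 <- meas; meas2$ux <- u_rot[, 1]; meas2$uy <- u_rot[, 2]; meas2$uz <- u_rot[, 3]
  p2 <- mmwmd_params(a = 2e-6, v_intra = 0.7, v_extra = 0.3,
                     n = as.numeric(Rot %*% c(1, 0, 0)))
  expect_equal(mmwmd_signal(p2, meas2), s0, tolerance = 1e-10)
})

test_that("parameter container rejects unphysical states", {
  expect_error(mmwmd_params(a = 2e-6, v_intra = 0.5, v_extra = 0.4),
               "sum to 1")
  expect_error(mmwmd_params(a = -1, v_intra = 0.5, v_extra = 0.5), "positive")
  expect_error(mmwmd_params(a = 2e-6, v_intra = 0.5, v_extra = 0.5,
                            n = c(1, 1, 0)), "unit")
})
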