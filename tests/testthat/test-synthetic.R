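orient_x <- c(1, 0, 0)

test_that("diameter sampling is seeded and matches the requested distribution", {
  spec <- substrate_spec(seed = 4L)
  expect_identical(sample_diameters(spec, 100)$diameters,
                   sample_diameters(spec, 100)$diameters)
  # default gamma preset reproduces the configured moments at n = 20000
  big <- sample_diameters(spec, 20000L)
  expect_lt(abs(mean(big$diameters) - 0.56), 0.01)
  expect_lt(abs(sd(big$diameters) - 0.27), 0.02)
  # discrete distribution: empirical frequencies track the weights
  dspec <- substrate_spec(diameter_dist = list(type = "discrete",
                                               values = c(0.5, 1, 2),
                                               weights = c(0.5, 0.3, 0.2)),
                          seed = 9L)
  d <- sample_diameters(dspec, 20000L)$diameters
  freq <- as.numeric(table(factor(d, levels = c(0.5, 1, 2)))) / length(d)
  expect_lt(max(abs(freq - c(0.5, 0.3, 0.2))), 0.02)
  expect_error(substrate_spec(diameter_dist = list(type = "gamma",
                                                   shape = -1, scale = 1)),
               "positive")
})

test_that("Watson sampling concentrates around the mean axis with kappa", {
  mu <- c(0, 0, 1)
  x_inf <- rwatson(50, mu, Inf)
  expect_true(all(abs(x_inf %*% mu) > 1 - 1e-12))
  x5 <- rwatson(4000, mu, 5, seed = 2L)
  x50 <- rwatson(4000, mu, 50, seed = 2L)
  expect_true(all(abs(sqrt(rowSums(x5^2)) - 1) < 1e-9))
  expect_gt(mean((x50 %*% mu)^2), mean((x5 %*% mu)^2))
  # axial symmetry: mean cos^2 to mu exceeds mean cos^2 to a perpendicular
  expect_gt(mean((x5 %*% mu)^2), mean((x5 %*% c(1, 0, 0))^2))
})

test_that("a degenerate substrate reproduces the analytic forward model", {
  spec <- substrate_spec(diameter_dist = list(type = "discrete", values = 2.5),
                         v_intra = 0.7, v_extra = 0.25, v_iso = 0.025,
                         v_dot = 0.025, orientation = orient_x,
                         watson_kappa = Inf, snr = Inf, n_axons = 50L,
                         seed = 11L)
  vox <- generate_voxel(spec, P5)
  pars <- mmwmd_params(a = 2.5e-6, v_intra = 0.7, v_extra = 0.25,
                       v_iso = 0.025, v_dot = 0.025, n = orient_x)
  expect_equal(vox$signal, mmwmd_signal(pars, P5), tolerance = 1e-12)
  expect_equal(vox$truth$alpha_wide, 2.5)
  # reproducible under seed
  expect_identical(vox$signal, generate_voxel(spec, P5)$signal)
})

test_that("the intra-axonal mixture is cross-section weighted", {
  prot <- mini_protocol()
  spec <- substrate_spec(diameter_dist = list(type = "discrete",
                                              values = c(1, 3)),
                         v_intra = 1, v_extra = 0, v_iso = 0, v_dot = 0,
                         orientation = orient_x, watson_kappa = Inf,
                         snr = Inf, n_axons = 400L, seed = 21L)
  vox <- generate_voxel(spec, prot)
  d <- vox$diameters$diameters
  n1 <- sum(d == 1); n3 <- sum(d == 3)
  w1 <- n1 * 1^2 / (n1 * 1^2 + n3 * 3^2)
  meas <- protocol_measurements(prot)
  s1 <- cylinder_signal(mmwmd_params(1e-6, 1, 0, n = orient_x), meas)
  s3 <- cylinder_signal(mmwmd_params(3e-6, 1, 0, n = orient_x), meas)
  expect_equal(vox$signal, w1 * s1 + (1 - w1) * s3, tolerance = 1e-10)
})

test_that("dispersion leaves a signature in the angular signal spread", {
  mk <- function(kappa) substrate_spec(
    diameter_dist = list(type = "discrete", values = 2),
    v_intra = 0.7, v_extra = 0.3, v_iso = 0, v_dot = 0,
    orientation = c(0, 0, 1), watson_kappa = kappa, snr = Inf,
    n_axons = 120L, seed = 31L)
  # all gradients exactly perpendicular to the mean fibre axis: an aligned
  # voxel is axially symmetric, so its signal is constant across these
  # directions; dispersion breaks the symmetry axon by axon
  phi <- 2 * pi * (0:23) / 24
  perp_prot <- pgse_protocol("perp", list(
    pgse_shell(24, 1350, 8.6, 13.6, 35, units = "scanner",
               directions = cbind(cos(phi), sin(phi), 0))))
  s_al <- generate_voxel(mk(Inf), perp_prot)$signal
  s_di <- generate_voxel(mk(5), perp_prot)$signal
  expect_lt(var(s_al), 1e-20)
  expect_gt(var(s_di), var(s_al))
})

test_that("ROI generation books signals against per-voxel ground truth", {
  spec <- substrate_spec(snr = 20, n_axons = 60L, seed = 5L)
  roi <- generate_roi(spec, mini_protocol(), 7L)
  expect_equal(dim(roi$signals), c(7L, n_measurements(mini_protocol())))
  expect_equal(nrow(roi$truth), 7L)
  expect_true(all(roi$truth$alpha_wide >= roi$truth$alpha_short))
  expect_true(all(roi$truth$alpha_wide > roi$truth$mean_diameter))
  # voxel matrix CSV round trip
  tmp <- tempfile(fileext = ".csv")
  write_voxel_csv(roi$signals, tmp)
  back <- read_voxel_csv(tmp)
  expect_equal(unname(back), unname(roi$signals), tolerance = 1e-12)
  unlink(tmp)
})

test_that("the fitted index tracks the tail-weighted truth end to end", {
  # noiseless aligned ROI with a spread distribution: the dictionary fit
  # should land within one grid step of the a^2-weighted truth index
  spec <- substrate_spec(diameter_dist = list(type = "discrete",
                                              values = c(2, 3),
                                              weights = c(0.5, 0.5)),
                         v_intra = 0.7, v_extra = 0.3, v_iso = 0, v_dot = 0,
                         orientation = orient_x, watson_kappa = Inf,
                         snr = Inf, n_axons = 400L, seed = 41L)
  vox <- generate_voxel(spec, P5)
  fit <- fit_voxel_dictionary(vox$signal, P5, orient_x,
                              snr = shell_snr(Inf, P5))
  expect_lt(abs(fit$alpha * 1e6 - vox$truth$alpha_wide), 0.35)
  # skewed distributions push the fitted index above the plain mean
  expect_gt(fit$alpha * 1e6, vox$truth$mean_diameter)
})
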