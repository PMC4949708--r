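#' Synthetic white-matter substrate specification
#'
#' Describes a voxel's tissue for simulation: an axon diameter
#' distribution, the four compartment fractions, diffusivities, fibre
#' orientation, optional Watson orientation dispersion, and per-shell SNR.
#' The default diameter distribution is a gamma density with mean 0.56 um
#' and SD 0.27 um, matching the whole-corpus-callosum moments of the
#' electron-microscopy population this package's simulations emulate; the
#' default fractions reflect a densely packed ex vivo tract (intra-axonal
#' water around 0.7).
#'
#' @param diameter_dist Either `list(type = "gamma", shape =, scale =)`
#'   (um) or `list(type = "discrete", values =, weights =)` (um).
#' @param v_intra,v_extra,v_iso,v_dot Volume fractions, sum to 1.
#' @param d_par,d_iso Diffusivities (m^2/s).
#' @param orientation Mean fibre orientation unit vector.
#' @param watson_kappa Watson concentration; `Inf` means perfectly aligned.
#' @param snr Per-shell SNR (recycled); `Inf` for noiseless.
#' @param n_axons Number of axons sampled per voxel.
#' @param seed Base RNG seed.
#' @return Object of class `substrate_spec`.
#' @export
substrate_spec <- function(diameter_dist = list(type = "gamma",
                                                shape = (0.56 / 0.27)^2,
                                                scale = 0.27^2 / 0.56),
                           v_intra = 0.7, v_extra = 0.2,
                           v_iso = 0.05, v_dot = 0.05,
                           d_par = 0.6e-9, d_iso = 2.0e-9,
                           orientation = c(1, 0, 0),
                           watson_kappa = Inf, snr = 20,
                           n_axons = 300L, seed = 1L) {
  v <- c(v_intra, v_extra, v_iso, v_dot)
  if (any(v < 0) || abs(sum(v) - 1) > 1e-9) stop("fractions must be in [0,1] and sum to 1")
  if (!is.infinite(watson_kappa) && watson_kappa <= 0)
    stop("watson_kappa must be positive or Inf")
  if (diameter_dist$type == "gamma" &&
      (diameter_dist$shape <= 0 || diameter_dist$scale <= 0))
    stop("gamma parameters must be positive")
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(diameter_dist = diameter_dist, v_intra = v_intra,
                 v_extra = v_extra, v_iso = v_iso, v_dot = v_dot,
                 d_par = d_par, d_iso = d_iso, orientation = orientation,
                 watson_kappa = watson_kappa, snr = snr,
                 n_axons = as.integer(n_axons), seed = seed),
            class = "substrate_spec")
}

#' Sample axon diameters from a substrate specification
#'
#' @param spec A [substrate_spec()].
#' @param n Number of diameters.
#' @param seed Seed (default: the spec's).
#' @return A [diameter_sample()] in micrometres.
#' @export
sample_diameters <- function(spec, n = spec$n_axons, seed = spec$seed) {
  if (n <= 0) stop("n must be positive")
  dd <- spec$diameter_dist
  draw <- function() {
    if (dd$type == "gamma") {
      rgamma(n, shape = dd$shape, scale = dd$scale)
    } else if (dd$type == "discrete") {
      w <- if (is.null(dd$weights)) rep(1, length(dd$values)) else dd$weights
      dd$values[sample.int(length(dd$values), n, replace = TRUE, prob = w)]
    } else stop("unknown diameter distribution type")
  }
  d <- withr::with_seed(seed, draw())
  diameter_sample(pmax(d, 1e-3), region_label = "synthetic")
}

#' Sample axis directions from a Watson distribution
#'
#' Axially symmetric bipolar Watson density proportional to
#' `exp(kappa * (mu . x)^2)`, sampled by numerical inversion of the
#' distribution of the polar cosine. `kappa = Inf` returns copies of `mu`.
#'
#' @param n Number of directions.
#' @param mu Mean axis (unit vector).
#' @param kappa Concentration parameter, > 0 or Inf.
#' @param seed Optional seed.
#' @return `n` x 3 matrix of unit vectors.
#' @export
rwatson <- function(n, mu, kappa, seed = NULL) {
  mu <- mu / sqrt(sum(mu^2))
  if (is.infinite(kappa)) return(matrix(mu, n, 3, byrow = TRUE))
  draw <- function() {
    tg <- seq(-1, 1, length.out = 4001)
    w <- exp(kappa * (tg^2 - 1))              # scaled to avoid overflow
    cdf <- cumsum(w) + seq_along(w) * 1e-12  # strictly increasing
    cdf <- cdf / cdf[length(cdf)]
    t <- approx(cdf, tg, xout = runif(n), rule = 2)$y
    phi <- runif(n, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - t^2))
    local_xyz <- cbind(st * cos(phi), st * sin(phi), t)
    # rotate local +z to mu
    ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
            mu[3] * e1[1] - mu[1] * e1[3],
            mu[1] * e1[2] - mu[2] * e1[1])
    local_xyz %*% rbind(e1, e2, mu)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate one synthetic voxel
#'
#' Forward-simulates a voxel's multi-shell signal: the intra-axonal signal
#' is the cross-section-weighted (a^2) mixture of restricted-cylinder
#' signals over the sampled diameters (voxel signal is volume-averaged
#' over spins, which is exactly why the tail-weighted diameter indices are
#' the right microscopy comparators); axon orientations are Watson-drawn
#' about the mean axis when `watson_kappa` is finite; extra-axonal
#' zeppelins follow the same sampled orientations; ball and dot are
#' isotropic. Rician noise is added per shell at the spec's SNR
#' (`sigma_q = 1/snr_q` relative to the unit b = 0 signal).
#'
#' @param spec A [substrate_spec()].
#' @param protocol A `pgse_protocol`.
#' @param seed Seed (default: the spec's).
#' @return List with `signal` (noisy vector), `noiseless`, `truth` (list:
#'   `alpha_wide`, `alpha_short`, `mean_diameter` in um, fractions,
#'   `orientation`, `watson_kappa`, `snr`), `diameters` (the
#'   `diameter_sample` drawn).
#' @export
generate_voxel <- function(spec, protocol, seed = spec$seed) {
  meas <- protocol_measurements(protocol)
  ds <- sample_diameters(spec, seed = seed)
  a_um <- ds$diameters
  axes <- rwatson(length(a_um), spec$orientation, spec$watson_kappa,
                  seed = seed + 1L)
  consts <- physical_constants()
  td <- meas$Delta - meas$delta / 3

  # per-axon cylinder signal, a^2 (cross-section) weighted
  w <- a_um^2 / sum(a_um^2)
  intra <- rep(0, nrow(meas))
  u <- cbind(meas$ux, meas$uy, meas$uz)
  for (i in seq_along(a_um)) {
    nvec <- axes[i, ]
    cospar <- as.numeric(u %*% nvec)
    G_par <- meas$G * cospar
    G_perp <- meas$G * sqrt(pmax(0, 1 - cospar^2))
    q_par <- consts$gamma * meas$delta * G_par / (2 * pi)
    s <- exp(-(2 * pi * q_par)^2 * td * spec$d_par) *
      cylinder_perp_gpd(a_um[i] * 1e-6 / 2, spec$d_par, G_perp,
                        meas$delta, meas$Delta, consts)
    intra <- intra + w[i] * s
  }

  # extra-axonal zeppelin, averaged over the same dispersed axes
  d_perp <- spec$d_par * spec$v_extra / (spec$v_intra + spec$v_extra)
  extra <- rep(0, nrow(meas))
  uniq <- if (is.infinite(spec$watson_kappa)) 1L else seq_along(a_um)
  for (i in uniq) {
    cospar2 <- as.numeric(u %*% axes[i, ])^2
    extra <- extra + exp(-meas$b * (d_perp + (spec$d_par - d_perp) * cospar2))
  }
  extra <- extra / length(uniq)

  noiseless <- spec$v_intra * intra + spec$v_extra * extra +
    spec$v_iso * exp(-meas$b * spec$d_iso) + spec$v_dot
  noiseless[meas$G == 0] <- 1

  snr_q <- rep_len(spec$snr, length(protocol$shells))
  sigma <- rep(0, nrow(meas))
  for (k in seq_along(protocol$shells))
    sigma[meas$shell == k] <- ifelse(is.infinite(snr_q[k]), 0, 1 / snr_q[k])
  signal <- if (all(sigma == 0)) noiseless else
    add_rician(noiseless, sigma, seed = seed + 2L)

  list(signal = signal, noiseless = noiseless,
       truth = list(alpha_wide = adi_wide(ds), alpha_short = adi_short(ds),
                    mean_diameter = mean(a_um), v_intra = spec$v_intra,
                    v_extra = spec$v_extra, v_iso = spec$v_iso,
                    v_dot = spec$v_dot, orientation = spec$orientation,
                    watson_kappa = spec$watson_kappa, snr = spec$snr),
       diameters = ds)
}

#' Generate a synthetic region of interest
#'
#' A batch of voxels (specs recycled across voxels, seeds offset per
#' voxel) for ROI-level sensitivity/stability experiments.
#'
#' @param spec_list A `substrate_spec` or list of them (recycled).
#' @param protocol A `pgse_protocol`.
#' @param n_voxels Number of voxels.
#' @return List with `signals` (n_voxels x n_measurements matrix) and
#'   `truth` (data.frame, one row per voxel).
#' @export
generate_roi <- function(spec_list, protocol, n_voxels) {
  if (inherits(spec_list, "substrate_spec")) spec_list <- list(spec_list)
  rows <- list(); sigs <- list()
  for (v in seq_len(n_voxels)) {
    spec <- spec_list[[(v - 1) %% length(spec_list) + 1]]
    vox <- generate_voxel(spec, protocol, seed = spec$seed + 1000L * v)
    sigs[[v]] <- vox$signal
    rows[[v]] <- data.frame(voxel = v,
                            alpha_wide = vox$truth$alpha_wide,
                            alpha_short = vox$truth$alpha_short,
                            mean_diameter = vox$truth$mean_diameter,
                            v_intra = spec$v_intra, v_extra = spec$v_extra,
                            v_iso = spec$v_iso, v_dot = spec$v_dot,
                            watson_kappa = spec$watson_kappa)
  }
  list(signals = do.call(rbind, sigs), truth = do.call(rbind, rows))
}

#' Read/write voxel signal matrices as CSV
#'
#' Plain CSV with one voxel per row, one measurement per column, in
#' protocol measurement order.
#'
#' @param x Matrix of signals (voxels x measurements).
#' @param path File path.
#' @return `read_voxel_csv` returns the matrix.
#' @export
write_voxel_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_voxel_csv
#' @export
read_voxel_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
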