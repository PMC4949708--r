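# Roots of J1'(x) = 0 for the Gaussian-phase-distribution cylinder series.
# Computed once at load by bisection on besselJ; the first root is the
# classical 1.8411838...
.gpd_roots_env <- new.env(parent = emptyenv())

#' Roots of the derivative of the first-order Bessel function
#'
#' Returns the first `n` positive roots of J1'(x) = 0, used in the
#' Gaussian-phase-distribution cylinder signal series. Roots are computed
#' numerically once and cached.
#'
#' @param n Number of roots (default 20).
#' @return Numeric vector of length `n`.
#' @export
bessel_j1prime_roots <- function(n = 20L) {
  key <- "roots"
  cached <- .gpd_roots_env[[key]]
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  f <- function(x) besselJ(x, 0) - besselJ(x, 2)  # 2 J1'(x)
  roots <- numeric(n)
  lo <- 1e-3
  for (k in seq_len(n)) {
    # roots are spaced by ~pi; bracket each one
    hi <- lo + 0.5
    while (f(lo) * f(hi) > 0) hi <- hi + 0.25
    roots[k] <- uniroot(f, c(lo, hi), tol = 1e-13)$root
    lo <- roots[k] + 2
  }
  .gpd_roots_env[[key]] <- roots
  roots
}

#' Perpendicular cylinder signal, Gaussian phase distribution
#'
#' Normalised PGSE signal from water restricted inside an impermeable
#' cylinder of radius `R`, gradient perpendicular to the cylinder axis,
#' using the Gaussian-phase-distribution closed form (a series over the
#' roots of J1'). Vectorised over `R` and over `G_perp`/`delta`/`Delta`
#' (lengths recycled).
#'
#' @param R Cylinder radius (m), > 0.
#' @param D Intra-cylinder diffusivity (m^2/s), > 0.
#' @param G_perp Perpendicular gradient magnitude (T/m).
#' @param delta,Delta Pulse duration and separation (s).
#' @param consts Physical constants.
#' @param n_roots Series truncation (default 20, ample for tissue-scale
#'   radii: the last term is checked to be negligible in the test suite).
#' @return Normalised signal in (0, 1].
#' @export
cylinder_perp_gpd <- function(R, D, G_perp, delta, Delta,
                              consts = physical_constants(), n_roots = 20L) {
  if (any(R <= 0)) stop("R must be positive")
  if (D <= 0) stop("D must be positive")
  n <- max(length(R), length(G_perp), length(delta), length(Delta))
  R <- rep_len(R, n); G_perp <- rep_len(G_perp, n)
  delta <- rep_len(delta, n); Delta <- rep_len(Delta, n)
  beta <- bessel_j1prime_roots(n_roots)
  # am = beta_m / R; outer over (measurement, root)
  am2 <- outer(1 / R^2, beta^2)            # am^2
  dam2 <- D * am2
  num <- 2 * dam2 * delta - 2 +
    2 * exp(-dam2 * delta) + 2 * exp(-dam2 * Delta) -
    exp(-dam2 * (Delta - delta)) - exp(-dam2 * (Delta + delta))
  den <- D^2 * am2^3 * (am2 * R^2 - 1)     # am^6 (am^2 R^2 - 1)
  lnS <- -2 * consts$gamma^2 * G_perp^2 * rowSums(num / den)
  exp(lnS)
}

#' Perpendicular cylinder signal, wide-pulse closed form
#'
#' Wide-pulse (long-delta) limit of the restricted-cylinder signal:
#' `ln S = -(R^4 gamma^2 G^2 / D) * (7/96) * (2 delta - (99/112) R^2 / D)`.
#' The attenuation scales as diameter to the fourth power, which is what
#' makes voxel-averaged measurements weight the large-diameter tail of the
#' axon distribution. Validity of the wide-pulse regime is the caller's
#' responsibility.
#'
#' @inheritParams cylinder_perp_gpd
#' @return Normalised signal.
#' @export
cylinder_perp_wide_pulse <- function(R, D, G_perp, delta,
                                     consts = physical_constants()) {
  if (any(R < 0)) stop("R must be non-negative")
  if (D <= 0) stop("D must be positive")
  lnS <- -(R^4 * consts$gamma^2 * G_perp^2 / D) * (7 / 96) *
    (2 * delta - (99 / 112) * R^2 / D)
  exp(lnS)
}

#' MMWMD tissue parameters
#'
#' State of the minimal model of white matter diffusion: all axons are
#' treated as parallel cylinders of one diameter `a` (the axon diameter
#' index), embedded in a tortuous extra-axonal compartment, with isotropic
#' (CSF-like) and stationary (trapped) water pools.
#'
#' @param a Axon diameter index (m).
#' @param v_intra,v_extra,v_iso,v_dot Volume fractions, must sum to 1.
#' @param d_par Parallel (intra/extra-axonal) diffusivity (m^2/s).
#' @param d_iso Isotropic compartment diffusivity (m^2/s); the ex vivo
#'   value is not well constrained, default 2.0e-9.
#' @param n Fibre orientation unit 3-vector.
#' @return An object of class `mmwmd_params`.
#' @export
mmwmd_params <- function(a, v_intra, v_extra, v_iso = 0, v_dot = 0,
                         d_par = 0.6e-9, d_iso = 2.0e-9, n = c(1, 0, 0)) {
  v <- c(v_intra, v_extra, v_iso, v_dot)
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) stop("fractions must lie in [0,1]")
  if (abs(sum(v) - 1) > 1e-9) stop("fractions must sum to 1")
  if (a <= 0) stop("a must be positive")
  if (d_par <= 0 || d_iso <= 0) stop("diffusivities must be positive")
  n <- as.numeric(n)
  if (abs(sqrt(sum(n^2)) - 1) > 1e-6) stop("n must be a unit vector")
  structure(list(a = a, v_intra = v_intra, v_extra = v_extra, v_iso = v_iso,
                 v_dot = v_dot, d_par = d_par, d_iso = d_iso, n = n),
            class = "mmwmd_params")
}

# split gradient vectors into components parallel/perpendicular to n
.decompose_G <- function(meas, n) {
  u <- cbind(meas$ux, meas$uy, meas$uz)
  cospar <- as.numeric(u %*% n)
  G_par <- meas$G * cospar
  G_perp <- meas$G * sqrt(pmax(0, 1 - cospar^2))
  list(G_par = G_par, G_perp = G_perp)
}

#' Intra-axonal cylinder signal for a set of measurements
#'
#' Decomposes each gradient into components parallel and perpendicular to
#' the fibre orientation; the parallel component contributes free Gaussian
#' attenuation at `d_par`, the perpendicular one the restricted GPD
#' cylinder signal.
#'
#' @param p An [mmwmd_params()] object.
#' @param meas Measurement table from [protocol_measurements()].
#' @return Normalised signal vector, one entry per measurement row.
#' @export
cylinder_signal <- function(p, meas) {
  g <- .decompose_G(meas, p$n)
  consts <- physical_constants()
  td <- meas$Delta - meas$delta / 3
  q_par <- consts$gamma * meas$delta * g$G_par / (2 * pi)
  s_par <- exp(-(2 * pi * q_par)^2 * td * p$d_par)
  s_perp <- cylinder_perp_gpd(p$a / 2, p$d_par, g$G_perp, meas$delta,
                              meas$Delta, consts)
  s_par * s_perp
}

#' Extra-axonal zeppelin signal
#'
#' Axially symmetric Gaussian compartment with perpendicular diffusivity
#' set by the tortuosity model
#' `d_perp = d_par * v_extra / (v_intra + v_extra)`.
#'
#' @inheritParams cylinder_signal
#' @return Normalised signal vector.
#' @export
zeppelin_signal <- function(p, meas) {
  if (p$v_intra + p$v_extra <= 0) stop("v_intra + v_extra must be positive")
  d_perp <- p$d_par * p$v_extra / (p$v_intra + p$v_extra)
  u <- cbind(meas$ux, meas$uy, meas$uz)
  cospar2 <- as.numeric(u %*% p$n)^2
  exp(-meas$b * (d_perp + (p$d_par - d_perp) * cospar2))
}

#' Isotropic ball signal
#' @param d_iso Isotropic diffusivity (m^2/s).
#' @param meas Measurement table.
#' @return `exp(-b * d_iso)` per measurement.
#' @export
ball_signal <- function(d_iso, meas) {
  exp(-meas$b * d_iso)
}

#' Stationary dot signal
#'
#' Water trapped inside small structures is stationary on the experiment's
#' time scale and contributes unattenuated signal at every b-value.
#'
#' @param meas Measurement table.
#' @return Vector of ones.
#' @export
dot_signal <- function(meas) {
  rep(1, nrow(meas))
}

#' Composite MMWMD signal for a protocol
#'
#' Volume-fraction-weighted sum of the four compartment signals, one entry
#' per measurement in protocol order (b = 0 entries are 1).
#'
#' @param p An [mmwmd_params()] object.
#' @param protocol A `pgse_protocol` or a measurement table.
#' @return Normalised signal vector.
#' @export
mmwmd_signal <- function(p, protocol) {
  meas <- if (inherits(protocol, "pgse_protocol"))
    protocol_measurements(protocol) else protocol
  s <- p$v_iso * ball_signal(p$d_iso, meas) + p$v_dot * dot_signal(meas)
  if (p$v_intra > 0) s <- s + p$v_intra * cylinder_signal(p, meas)
  if (p$v_extra > 0) s <- s + p$v_extra * zeppelin_signal(p, meas)
  s[meas$G == 0] <- 1
  s
}
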