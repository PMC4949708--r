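#' Add Rician noise to a noiseless signal vector
#'
#' Magnitude-MRI noise: each entry becomes
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ Normal(0, sigma^2)`.
#'
#' @param signal Noiseless signal vector.
#' @param sigma Noise standard deviation (on the same normalised scale as
#'   `signal`); may be a scalar or per-entry vector.
#' @param seed Optional integer seed for reproducibility (RNG state is
#'   restored afterwards).
#' @return Noisy signal vector.
#' @export
add_rician <- function(signal, sigma, seed = NULL) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  draw <- function() {
    n1 <- rnorm(length(signal), 0, sigma)
    n2 <- rnorm(length(signal), 0, sigma)
    sqrt((signal + n1)^2 + n2^2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-shell SNR estimate from a voxel's measurements
#'
#' The estimator is `SNR_q = mean(S_q) / sd(S_q)` over each shell's
#' diffusion-weighted signals. This conflates angular signal variation with
#' noise, so in anisotropic voxels it under-estimates the true SNR of the
#' measurement (equivalently over-estimates sigma); it is nevertheless the
#' convention the dictionary fitter is built around, because it requires no
#' repeated measurements.
#'
#' @param y Signal vector in protocol measurement order.
#' @param protocol The `pgse_protocol` describing `y`.
#' @return An object of class `shell_snr`: data.frame with columns `shell`,
#'   `mu`, `sd`, `snr`, `sigma` (`sigma = mu / snr = sd`), plus a logical
#'   `degenerate` flag for shells with zero variance (infinite SNR).
#' @export
estimate_snr <- function(y, protocol) {
  meas <- protocol_measurements(protocol)
  if (length(y) != nrow(meas)) stop("length(y) must equal measurement count")
  ks <- sort(unique(meas$shell[meas$shell > 0]))
  rows <- lapply(ks, function(k) {
    s <- y[meas$shell == k]
    if (length(s) < 2) stop("need at least 2 measurements per shell")
    mu <- mean(s); sdev <- sd(s)
    data.frame(shell = k, mu = mu, sd = sdev,
               snr = if (sdev > 0) mu / sdev else Inf,
               sigma = sdev, degenerate = sdev == 0)
  })
  structure(do.call(rbind, rows), class = c("shell_snr", "data.frame"))
}

#' Construct a per-shell SNR table from known values
#'
#' Used when the noise level is known (simulations) rather than estimated.
#' `sigma` is taken relative to the unit-normalised b = 0 signal:
#' `sigma_q = 1 / snr_q`.
#'
#' @param snr Vector of per-shell SNR values (recycled to the number of
#'   shells).
#' @param protocol The `pgse_protocol`.
#' @return A `shell_snr` object.
#' @export
shell_snr <- function(snr, protocol) {
  nq <- length(protocol$shells)
  snr <- rep_len(snr, nq)
  if (any(snr <= 0)) stop("SNR must be positive")
  structure(data.frame(shell = seq_len(nq), mu = NA_real_, sd = NA_real_,
                       snr = snr, sigma = 1 / snr, degenerate = FALSE),
            class = c("shell_snr", "data.frame"))
}

#' Mean of the Rice distribution and the Rician bias offset
#'
#' `rician_mean(S, sigma)` is the exact expectation of a Rice(S, sigma)
#' variable, computed from the Laguerre-function closed form with
#' exponentially scaled Bessel functions for numerical stability.
#' `rician_offset` is the upward bias `E[Rice(S, sigma)] - S` added to
#' dictionary atoms so that they live on the same (biased) scale as
#' magnitude data.
#'
#' @param S Noiseless signal value(s), >= 0.
#' @param sigma Noise SD, >= 0.
#' @return Numeric vector.
#' @export
rician_mean <- function(S, sigma) {
  if (any(S < 0)) stop("S must be non-negative")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  n <- max(length(S), length(sigma))
  S <- rep_len(S, n); sigma <- rep_len(sigma, n)
  out <- S
  t_all <- ifelse(sigma > 0, S^2 / (2 * sigma^2), Inf)
  # exact Laguerre form where the scaled Bessel functions are reliable
  pos <- sigma > 0 & t_all < 1e4
  if (any(pos)) {
    t <- t_all[pos]
    # E = sigma sqrt(pi/2) exp(-t/2) [(1+t) I0(t/2) + t I1(t/2)]
    i0 <- besselI(t / 2, 0, expon.scaled = TRUE)
    i1 <- besselI(t / 2, 1, expon.scaled = TRUE)
    out[pos] <- sigma[pos] * sqrt(pi / 2) * ((1 + t) * i0 + t * i1)
  }
  # high-SNR asymptotic branch (relative error O((sigma/S)^6))
  hi <- sigma > 0 & is.finite(S) & t_all >= 1e4
  if (any(hi)) {
    r <- sigma[hi]^2 / S[hi]^2
    out[hi] <- S[hi] * (1 + r / 2 - r^2 / 8)
  }
  out
}

#' @rdname rician_mean
#' @export
rician_offset <- function(S, sigma) {
  rician_mean(S, sigma) - rep_len(S, max(length(S), length(sigma)))
}
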