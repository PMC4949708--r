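#' Rician log-likelihood of a measured voxel given a model prediction
#'
#' Sum over measurements of the Rice log-density
#' `ln(y/sigma^2) - (y^2 + s^2)/(2 sigma^2) + ln I0(y s / sigma^2)`,
#' with the Bessel term evaluated in the log domain (exponentially scaled)
#' so large arguments do not overflow. Non-positive `y` entries are clamped
#' to a small positive boundary value where the density is evaluated.
#'
#' @param y Measured signal vector (magnitude data, > 0).
#' @param s Model-predicted noiseless signal vector.
#' @param sigma Noise SD, scalar or per-measurement vector, > 0.
#' @return Scalar log-likelihood.
#' @export
rician_loglik <- function(y, s, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  n <- length(y)
  s <- rep_len(s, n); sigma <- rep_len(sigma, n)
  y <- pmax(y, 1e-12)
  z <- y * s / sigma^2
  # scaled besselI underflows above ~1e5; switch to the asymptotic series
  log_i0 <- ifelse(z < 1e4,
                   log(besselI(pmin(z, 1e4), 0, expon.scaled = TRUE)) + z,
                   z - 0.5 * log(2 * pi * z) + log1p(1 / (8 * z)))
  sum(log(y / sigma^2) - (y^2 + s^2) / (2 * sigma^2) + log_i0)
}

# per-measurement sigma vector from a shell_snr table
.sigma_vector <- function(snr, meas) {
  sig <- rep(NA_real_, nrow(meas))
  for (k in seq_len(nrow(snr))) sig[meas$shell == snr$shell[k]] <- snr$sigma[k]
  sig[meas$shell == 0] <- min(snr$sigma)  # b0 rows, if present
  sig
}

# forward model + likelihood for a parameter vector on a fixed measurement
# table; theta = (a, v_intra, v_iso, v_dot), v_extra is the remainder
.mcmc_objective <- function(theta, y, meas, sigma, orientation, d_par, d_iso) {
  v_extra <- 1 - theta[2] - theta[3] - theta[4]
  if (v_extra < 0) return(-Inf)
  p <- mmwmd_params(a = theta[1], v_intra = theta[2], v_extra = v_extra,
                    v_iso = theta[3], v_dot = theta[4],
                    d_par = d_par, d_iso = d_iso, n = orientation)
  rician_loglik(y, mmwmd_signal(p, meas), sigma)
}

#' Default grid for the stage-1 search
#'
#' @param diameters Diameter candidates (m).
#' @param v_intra Intra-axonal fraction candidates.
#' @param v_iso Isotropic fraction candidates.
#' @param v_dot Stationary fraction candidates.
#' @return List of grid vectors.
#' @export
mcmc_grid_spec <- function(diameters = seq(0.5, 5.5, by = 0.5) * 1e-6,
                           v_intra = seq(0.2, 0.8, by = 0.1),
                           v_iso = c(0, 0.1),
                           v_dot = c(0, 0.1)) {
  list(diameters = diameters, v_intra = v_intra, v_iso = v_iso, v_dot = v_dot)
}

#' Stage 1: exhaustive grid search for the fitting start point
#'
#' Maximises the Rician likelihood over the Cartesian grid of diameter and
#' fractions (extra-axonal fraction is the unit-sum remainder; infeasible
#' combinations are skipped). Ties are broken toward the smallest diameter,
#' then lexicographically, so the result is deterministic.
#'
#' @param y Measured signal vector.
#' @param protocol A `pgse_protocol`.
#' @param orientation Fibre orientation unit vector.
#' @param snr A `shell_snr` (default: estimated from `y`).
#' @param grid_spec See [mcmc_grid_spec()].
#' @param d_par,d_iso Fixed diffusivities (m^2/s).
#' @return List with `theta` (a, v_intra, v_iso, v_dot), `v_extra`,
#'   `loglik`.
#' @export
grid_search <- function(y, protocol, orientation, snr = NULL,
                        grid_spec = mcmc_grid_spec(),
                        d_par = 0.6e-9, d_iso = 2.0e-9) {
  if (length(grid_spec$diameters) == 0) stop("empty grid")
  if (is.null(snr)) snr <- estimate_snr(y, protocol)
  meas <- protocol_measurements(protocol)
  sigma <- .sigma_vector(snr, meas)
  grid <- expand.grid(v_dot = grid_spec$v_dot, v_iso = grid_spec$v_iso,
                      v_intra = grid_spec$v_intra, a = grid_spec$diameters)
  # order so that the first maximum found is smallest-a then lexicographic
  grid <- grid[order(grid$a, grid$v_intra, grid$v_iso, grid$v_dot), ]
  best <- NULL; best_ll <- -Inf
  for (i in seq_len(nrow(grid))) {
    th <- c(grid$a[i], grid$v_intra[i], grid$v_iso[i], grid$v_dot[i])
    ll <- .mcmc_objective(th, y, meas, sigma, orientation, d_par, d_iso)
    if (ll > best_ll) { best_ll <- ll; best <- th }
  }
  if (is.null(best)) stop("no feasible grid point")
  list(theta = c(a = best[1], v_intra = best[2], v_iso = best[3],
                 v_dot = best[4]),
       v_extra = 1 - sum(best[2:4]), loglik = best_ll)
}

# bounded transform: a on log scale; fractions by stick-breaking logits
.theta_to_z <- function(theta) {
  v_intra <- theta[2]; v_iso <- theta[3]; v_dot <- theta[4]
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  z2 <- qlogis(clamp(v_intra))
  z3 <- qlogis(clamp(v_iso / max(1 - v_intra, 1e-6)))
  z4 <- qlogis(clamp(v_dot / max(1 - v_intra - v_iso, 1e-6)))
  c(log(theta[1]), z2, z3, z4)
}

.z_to_theta <- function(z) {
  v_intra <- plogis(z[2])
  v_iso <- (1 - v_intra) * plogis(z[3])
  v_dot <- (1 - v_intra - v_iso) * plogis(z[4])
  c(exp(z[1]), v_intra, v_iso, v_dot)
}

#' Stage 2: local refinement of the grid-search optimum
#'
#' Nelder-Mead ascent of the same Rician objective in a transformed space
#' (log diameter, stick-breaking logits for the fractions) that keeps all
#' parameters in bounds. The returned point never has a lower objective
#' than the start.
#'
#' @param start Output of [grid_search()] (or a compatible list with
#'   `theta`).
#' @inheritParams grid_search
#' @return List with `theta`, `v_extra`, `loglik`, `converged`.
#' @export
refine_descent <- function(start, y, protocol, orientation, snr = NULL,
                           d_par = 0.6e-9, d_iso = 2.0e-9) {
  if (is.null(snr)) snr <- estimate_snr(y, protocol)
  meas <- protocol_measurements(protocol)
  sigma <- .sigma_vector(snr, meas)
  obj <- function(z) {
    th <- .z_to_theta(z)
    -.mcmc_objective(th, y, meas, sigma, orientation, d_par, d_iso)
  }
  z0 <- .theta_to_z(start$theta)
  fit <- optim(z0, obj, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-10))
  ll_start <- .mcmc_objective(start$theta, y, meas, sigma, orientation,
                              d_par, d_iso)
  if (-fit$value >= ll_start) {
    theta <- unname(.z_to_theta(fit$par)); ll <- -fit$value
  } else {
    theta <- unname(start$theta); ll <- ll_start  # never worse than the start
  }
  list(theta = c(a = theta[1], v_intra = theta[2], v_iso = theta[3],
                 v_dot = theta[4]),
       v_extra = 1 - sum(theta[2:4]), loglik = ll,
       converged = fit$convergence == 0)
}

#' MCMC configuration
#'
#' @param n_iterations Retained Metropolis-Hastings iterations (default
#'   2000; the posterior summary is the mean over these).
#' @param burn_in Discarded initial iterations (default 0: the chain starts
#'   at the descent optimum).
#' @param proposal_sd_a Diameter proposal SD (m).
#' @param proposal_sd_v Fraction proposal SD (natural scale).
#' @param seed RNG seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 2000L, burn_in = 0L,
                        proposal_sd_a = 0.1e-6, proposal_sd_v = 0.02,
                        seed = 1L) {
  if (n_iterations <= 0) stop("n_iterations must be positive")
  if (proposal_sd_a <= 0 || proposal_sd_v <= 0)
    stop("proposal SDs must be positive")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 proposal_sd_a = proposal_sd_a,
                 proposal_sd_v = proposal_sd_v, seed = seed),
            class = "mcmc_config")
}

#' Stage 3: Rician Metropolis-Hastings over diameter and axonal fractions
#'
#' Starting from the refined optimum, samples the axon diameter index and
#' the intra-/extra-axonal volume fractions, holding the isotropic and
#' stationary fractions and the diffusivities fixed at their refined
#' values. Because the four fractions sum to one with `v_iso`, `v_dot`
#' fixed, the free coordinates are the diameter and the intra-axonal share
#' of the axonal water; proposals are Gaussian on the natural scale with
#' out-of-bounds proposals rejected. Estimates are means over the retained
#' iterations.
#'
#' @param refined Output of [refine_descent()].
#' @inheritParams grid_search
#' @param cfg An [mcmc_config()].
#' @return An object of class `posterior_summary`: list with `alpha_mean`,
#'   `alpha_sd` (m), `v_intra_mean`, `v_extra_mean`, `acceptance_rate`,
#'   `chain` (data.frame of retained samples), `failed` (TRUE when no
#'   proposal was ever accepted).
#' @export
run_mcmc <- function(refined, y, protocol, orientation, snr = NULL,
                     cfg = mcmc_config(), d_par = 0.6e-9, d_iso = 2.0e-9) {
  if (is.null(snr)) snr <- estimate_snr(y, protocol)
  meas <- protocol_measurements(protocol)
  sigma <- .sigma_vector(snr, meas)
  v_iso <- refined$theta[[3]]; v_dot <- refined$theta[[4]]
  v_ax <- 1 - v_iso - v_dot           # axonal (intra + extra) water share
  a_cur <- refined$theta[[1]]
  vi_cur <- refined$theta[[2]]
  ll_fun <- function(a, vi) {
    if (a <= 0.05e-6 || a > 10e-6 || vi < 0 || vi > v_ax) return(-Inf)
    .mcmc_objective(c(a, vi, v_iso, v_dot), y, meas, sigma, orientation,
                    d_par, d_iso)
  }
  ll_cur <- ll_fun(a_cur, vi_cur)
  n_tot <- cfg$burn_in + cfg$n_iterations
  run <- function() {
    chain_a <- numeric(cfg$n_iterations)
    chain_vi <- numeric(cfg$n_iterations)
    acc <- 0L
    a <- a_cur; vi <- vi_cur; ll <- ll_cur
    for (it in seq_len(n_tot)) {
      a_p <- a + rnorm(1, 0, cfg$proposal_sd_a)
      vi_p <- vi + rnorm(1, 0, cfg$proposal_sd_v)
      ll_p <- ll_fun(a_p, vi_p)
      if (is.finite(ll_p) && log(runif(1)) < ll_p - ll) {
        a <- a_p; vi <- vi_p; ll <- ll_p; acc <- acc + 1L
      }
      if (it > cfg$burn_in) {
        chain_a[it - cfg$burn_in] <- a
        chain_vi[it - cfg$burn_in] <- vi
      }
    }
    list(a = chain_a, vi = chain_vi, acc = acc)
  }
  res <- withr::with_seed(cfg$seed, run())
  chain <- data.frame(alpha = res$a, v_intra = res$vi,
                      v_extra = v_ax - res$vi)
  structure(list(alpha_mean = mean(chain$alpha), alpha_sd = sd(chain$alpha),
                 v_intra_mean = mean(chain$v_intra),
                 v_extra_mean = mean(chain$v_extra),
                 acceptance_rate = res$acc / n_tot, chain = chain,
                 failed = res$acc == 0L),
            class = "posterior_summary")
}

#' Three-stage fit of a single voxel (grid, descent, MCMC)
#'
#' @inheritParams grid_search
#' @param cfg An [mcmc_config()].
#' @return A `posterior_summary` with elements `grid`, `refined` attached.
#' @export
fit_voxel_mcmc <- function(y, protocol, orientation, snr = NULL,
                           grid_spec = mcmc_grid_spec(), cfg = mcmc_config(),
                           d_par = 0.6e-9, d_iso = 2.0e-9) {
  if (is.null(snr)) snr <- estimate_snr(y, protocol)
  g <- grid_search(y, protocol, orientation, snr, grid_spec, d_par, d_iso)
  r <- refine_descent(g, y, protocol, orientation, snr, d_par, d_iso)
  post <- run_mcmc(r, y, protocol, orientation, snr, cfg, d_par, d_iso)
  post$grid <- g; post$refined <- r
  post
}
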