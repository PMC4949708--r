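#' PGSE shell
#'
#' A shell is a set of diffusion-weighted measurements sharing gradient
#' magnitude and pulse timing, differing only in gradient direction.
#' Internal units are strict SI (T/m, s); `units = "scanner"` accepts the
#' usual console units (mT/m, ms).
#'
#' @param n_dirs Number of gradient directions.
#' @param G Gradient magnitude (T/m, or mT/m with `units = "scanner"`).
#' @param delta Gradient pulse duration (s, or ms).
#' @param Delta Pulse separation (s, or ms).
#' @param TE Echo time (s, or ms).
#' @param directions Optional `n_dirs` x 3 matrix of unit direction vectors.
#'   If omitted, a deterministic electrostatic-repulsion point set is used.
#' @param units `"SI"` (default) or `"scanner"` (mT/m and ms).
#' @return An object of class `pgse_shell`.
#' @export
pgse_shell <- function(n_dirs, G, delta, Delta, TE,
                       directions = NULL, units = c("SI", "scanner")) {
  units <- match.arg(units)
  if (units == "scanner") {
    G <- .mT_per_m(G); delta <- .ms(delta); Delta <- .ms(Delta); TE <- .ms(TE)
  }
  if (G < 0) stop("G must be non-negative")
  if (!(delta > 0 && delta < Delta)) stop("need 0 < delta < Delta")
  if (Delta > TE) stop("need Delta <= TE")
  if (n_dirs < 1) stop("n_dirs must be positive")
  if (is.null(directions)) {
    directions <- electrostatic_directions(n_dirs)
  } else {
    directions <- as.matrix(directions)
    if (nrow(directions) != n_dirs || ncol(directions) != 3)
      stop("directions must be an n_dirs x 3 matrix")
    nrm <- sqrt(rowSums(directions^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("direction vectors must be unit norm")
  }
  dimnames(directions) <- NULL
  structure(
    list(n_dirs = as.integer(n_dirs), G = G, delta = delta, Delta = Delta,
         TE = TE, directions = directions),
    class = "pgse_shell")
}

#' Multi-shell PGSE protocol
#'
#' @param name Label for the protocol.
#' @param shells List of [pgse_shell()] objects.
#' @param n_b0 Number of unweighted (b = 0) measurements (default 0).
#' @return An object of class `pgse_protocol`.
#' @export
pgse_protocol <- function(name, shells, n_b0 = 0L) {
  if (length(shells) == 0) stop("protocol needs at least one shell")
  stopifnot(all(vapply(shells, inherits, logical(1), "pgse_shell")))
  structure(list(name = name, shells = shells, n_b0 = as.integer(n_b0)),
            class = "pgse_protocol")
}

#' @export
print.pgse_protocol <- function(x, ...) {
  cat(sprintf("PGSE protocol '%s': %d shells, %d b0, %d measurements\n",
              x$name, length(x$shells), x$n_b0, n_measurements(x)))
  for (s in x$shells) {
    cat(sprintf("  n=%3d  |G|=%7.1f mT/m  delta=%5.1f ms  Delta=%5.1f ms  b=%8.0f s/mm2\n",
                s$n_dirs, s$G * 1e3, s$delta * 1e3, s$Delta * 1e3,
                b_value(s) * 1e-6))
  }
  invisible(x)
}

#' Total number of measurements in a protocol
#' @param p A `pgse_protocol`.
#' @return Integer count `n_b0 + sum(n_dirs)`.
#' @export
n_measurements <- function(p) {
  p$n_b0 + sum(vapply(p$shells, function(s) s$n_dirs, integer(1)))
}

#' Effective diffusion time of a shell
#'
#' `t_d = Delta - delta / 3`, the effective diffusion time of the PGSE
#' experiment.
#'
#' @param shell A `pgse_shell`.
#' @return Diffusion time in seconds.
#' @export
diffusion_time <- function(shell) {
  shell$Delta - shell$delta / 3
}

#' q-value of a shell
#'
#' `q = (2 pi)^-1 * gamma * delta * G`, the magnitude of the diffusion
#' wavevector in reciprocal metres.
#'
#' @param shell A `pgse_shell`.
#' @param consts Physical constants, see [physical_constants()].
#' @return q in m^-1.
#' @export
q_value <- function(shell, consts = physical_constants()) {
  consts$gamma * shell$delta * shell$G / (2 * pi)
}

#' b-value of a shell
#'
#' `b = (2 pi q)^2 * t_d` in s m^-2 (divide by 1e6 for s/mm^2).
#'
#' @inheritParams q_value
#' @return b in s m^-2.
#' @export
b_value <- function(shell, consts = physical_constants()) {
  (2 * pi * q_value(shell, consts))^2 * diffusion_time(shell)
}

#' Built-in optimised ex vivo protocols
#'
#' The two optimised ex vivo mouse-brain acquisition protocols used
#' throughout the package: a three-shell protocol with maximum gradient
#' 300 mT/m and a five-shell protocol reaching 1350 mT/m
#' (maximum b about 105,000 s/mm^2). Both comprise 360 diffusion-weighted
#' measurements at TE = 35 ms. `"four_shell"` is the five-shell protocol
#' with its highest-b shell removed and `"high_b_subset"` is the five-shell
#' protocol without its two lowest-b shells.
#'
#' @param name One of `"three_shell"`, `"five_shell"`, `"four_shell"`,
#'   `"high_b_subset"`.
#' @return A `pgse_protocol`.
#' @export
#' @examples
#' builtin_protocol("five_shell")
builtin_protocol <- function(name = c("three_shell", "five_shell",
                                      "four_shell", "high_b_subset")) {
  name <- match.arg(name)
  mk <- function(tbl, label) {
    shells <- lapply(seq_len(nrow(tbl)), function(i) {
      pgse_shell(tbl[i, 1], tbl[i, 2], tbl[i, 3], tbl[i, 4], 35,
                 units = "scanner")
    })
    pgse_protocol(label, shells, n_b0 = 0L)
  }
  three <- rbind(c(120, 300, 5.6, 12.1),
                 c(120, 220, 7.0, 20.4),
                 c(120, 300, 10.5, 16.9))
  five <- rbind(c(60, 1107, 1.1, 28.4),
                c(60, 1227, 2.3, 7.0),
                c(60, 464, 6.3, 23.0),
                c(60, 509, 5.6, 23.7),
                c(120, 1350, 8.6, 13.6))
  switch(name,
    three_shell = mk(three, "three_shell"),
    five_shell = mk(five, "five_shell"),
    four_shell = subset_protocol(mk(five, "five_shell"), 1:4, name = "four_shell"),
    high_b_subset = subset_protocol(mk(five, "five_shell"), 3:5,
                                    name = "high_b_subset"))
}

#' Keep a subset of a protocol's shells
#'
#' Used to generate reduced datasets, e.g. dropping the highest-b shell or
#' discarding the low-b shells to mitigate time-dependent extra-axonal
#' diffusion effects.
#'
#' @param p A `pgse_protocol`.
#' @param keep Integer indices of shells to retain (order preserved).
#' @param name Optional new label.
#' @return A `pgse_protocol` with only the kept shells.
#' @export
subset_protocol <- function(p, keep, name = NULL) {
  keep <- as.integer(keep)
  if (length(keep) == 0) stop("keep must be non-empty")
  if (any(keep < 1 | keep > length(p$shells))) stop("shell index out of range")
  pgse_protocol(if (is.null(name)) paste0(p$name, "_subset") else name,
                p$shells[keep], n_b0 = p$n_b0)
}

#' Deterministic electrostatic-repulsion direction set
#'
#' Generates `n` approximately uniformly spread unit vectors on the
#' hemisphere by starting from a Fibonacci spiral and relaxing pairwise
#' Coulomb forces between all antipodal pairs. Fully deterministic for a
#' given `n`.
#'
#' @param n Number of directions.
#' @param n_iter Relaxation iterations.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
electrostatic_directions <- function(n, n_iter = 80L) {
  # Fibonacci sphere start, folded to upper hemisphere
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - i / n           # z in (0, 1): hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  x <- cbind(r * cos(phi), r * sin(phi), z)
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  step <- 0.05
  for (it in seq_len(n_iter)) {
    gxx <- x %*% t(x)                       # cos angles
    f <- matrix(0, n, 3)
    # force from both u_j and -u_j: 1/d^2 along the difference vectors
    for (s in c(1, -1)) {
      d2 <- pmax(2 - 2 * s * gxx, 1e-12)    # |u_i - s u_j|^2
      w <- 1 / (d2 * sqrt(d2))              # 1/d^3: unit diff vec times 1/d^2
      diag(w) <- 0
      f <- f + (w %*% (-s * x)) + rowSums(w) * x
    }
    # project force onto tangent plane, take a damped step
    f <- f - rowSums(f * x) * x
    x <- x + step * f / max(1, max(abs(f)))
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' Per-measurement table of a protocol
#'
#' Expands a protocol into one row per measurement, b = 0 rows first, then
#' shells in order. This row order is the measurement-vector contract used
#' by all signal and fitting functions.
#'
#' @param p A `pgse_protocol`.
#' @return A data.frame with columns `shell` (0 for b0), `G`, `delta`,
#'   `Delta`, `TE`, `ux`, `uy`, `uz`, `b` (SI units).
#' @export
protocol_measurements <- function(p) {
  rows <- list()
  if (p$n_b0 > 0) {
    rows[[1]] <- data.frame(shell = 0L, G = 0,
                            delta = p$shells[[1]]$delta,
                            Delta = p$shells[[1]]$Delta,
                            TE = p$shells[[1]]$TE,
                            ux = 0, uy = 0, uz = 1, b = 0)[rep(1, p$n_b0), ]
  }
  for (k in seq_along(p$shells)) {
    s <- p$shells[[k]]
    rows[[length(rows) + 1]] <- data.frame(
      shell = k, G = s$G, delta = s$delta, Delta = s$Delta, TE = s$TE,
      ux = s$directions[, 1], uy = s$directions[, 2], uz = s$directions[, 3],
      b = b_value(s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
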