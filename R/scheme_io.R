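#' Write a protocol as a Camino STEJSKALTANNER scheme file
#'
#' One line per measurement: `x y z |G| Delta delta TE` in SI units, after
#' a `VERSION: STEJSKALTANNER` header. b = 0 measurements are written as
#' all-zero gradient lines.
#'
#' @param p A `pgse_protocol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(p, path) {
  meas <- protocol_measurements(p)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("VERSION: STEJSKALTANNER", con)
  for (i in seq_len(nrow(meas))) {
    if (meas$G[i] == 0) {
      writeLines(sprintf("%.10e %.10e %.10e %.10e %.10e %.10e %.10e",
                         0, 0, 0, 0, meas$Delta[i], meas$delta[i],
                         meas$TE[i]), con)
    } else {
      writeLines(sprintf("%.10e %.10e %.10e %.10e %.10e %.10e %.10e",
                         meas$ux[i], meas$uy[i], meas$uz[i], meas$G[i],
                         meas$Delta[i], meas$delta[i], meas$TE[i]), con)
    }
  }
  invisible(path)
}

#' Read a Camino STEJSKALTANNER scheme file
#'
#' Rows sharing gradient magnitude and timing are grouped into shells in
#' order of first appearance; zero-gradient rows become b = 0
#' measurements. Malformed lines raise an error naming the line number;
#' non-unit direction vectors are rejected.
#'
#' @param path Scheme file path.
#' @param name Protocol label.
#' @return A `pgse_protocol`.
#' @export
read_scheme <- function(path, name = basename(path)) {
  lines <- readLines(path)
  if (length(lines) == 0 || !grepl("STEJSKALTANNER", lines[1]))
    stop("not a STEJSKALTANNER scheme file: ", path)
  body <- lines[-1]
  body_idx <- which(nzchar(trimws(body)))
  rows <- matrix(NA_real_, length(body_idx), 7)
  for (j in seq_along(body_idx)) {
    i <- body_idx[j]
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(vals) != 7 || any(is.na(vals)))
      stop(sprintf("malformed scheme line %d in %s", i + 1, path))
    rows[j, ] <- vals
  }
  g <- rows[, 4]
  n_b0 <- sum(g == 0)
  dw <- rows[g > 0, , drop = FALSE]
  if (nrow(dw) == 0) stop("scheme contains no diffusion-weighted lines")
  nrm <- sqrt(rowSums(dw[, 1:3, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("scheme contains non-unit direction vectors")
  key <- apply(dw[, 4:7, drop = FALSE], 1, paste, collapse = "|")
  shells <- lapply(unique(key), function(k) {
    sub <- dw[key == k, , drop = FALSE]
    pgse_shell(nrow(sub), sub[1, 4], sub[1, 6], sub[1, 5], sub[1, 7],
               directions = sub[, 1:3, drop = FALSE])
  })
  pgse_protocol(name, shells, n_b0 = n_b0)
}

#' Write a protocol in FSL form (bval/bvec plus a timing sidecar)
#'
#' FSL bval (s/mm^2) and bvec files cannot encode the pulse timing, so a
#' YAML sidecar stores `delta`, `Delta`, `TE` (seconds) per shell, in
#' shell order.
#'
#' @param p A `pgse_protocol`.
#' @param basename_path Path prefix; writes `<prefix>.bval`,
#'   `<prefix>.bvec`, `<prefix>_timing.yaml`.
#' @return The prefix, invisibly.
#' @export
write_fsl <- function(p, basename_path) {
  meas <- protocol_measurements(p)
  bvals <- meas$b * 1e-6
  writeLines(paste(sprintf("%.6f", bvals), collapse = " "),
             paste0(basename_path, ".bval"))
  bvec <- rbind(ifelse(meas$G > 0, meas$ux, 0),
                ifelse(meas$G > 0, meas$uy, 0),
                ifelse(meas$G > 0, meas$uz, 0))
  writeLines(apply(bvec, 1, function(r)
    paste(sprintf("%.10f", r), collapse = " ")),
    paste0(basename_path, ".bvec"))
  timing <- list(shells = lapply(p$shells, function(s)
    list(delta = s$delta, Delta = s$Delta, TE = s$TE)))
  yaml::write_yaml(timing, paste0(basename_path, "_timing.yaml"))
  invisible(basename_path)
}

#' Read a protocol from FSL bval/bvec files and a timing sidecar
#'
#' Nonzero b-values are grouped into shells in order of first appearance;
#' the sidecar must list the same number of shells. Gradient magnitude is
#' reconstructed from `b = (gamma delta G)^2 t_d`.
#'
#' @param basename_path Path prefix used by [write_fsl()].
#' @param name Protocol label.
#' @return A `pgse_protocol`.
#' @export
read_fsl <- function(basename_path, name = basename(basename_path)) {
  bvals <- scan(paste0(basename_path, ".bval"), quiet = TRUE) * 1e6
  bvec <- as.matrix(utils::read.table(paste0(basename_path, ".bvec")))
  if (ncol(bvec) != length(bvals)) stop("bval/bvec length mismatch")
  timing <- yaml::read_yaml(paste0(basename_path, "_timing.yaml"))
  n_b0 <- sum(bvals == 0)
  dwi <- which(bvals > 0)
  key <- as.character(signif(bvals[dwi], 10))
  uk <- unique(key)
  if (length(uk) != length(timing$shells))
    stop("sidecar shell count does not match distinct b-values")
  consts <- physical_constants()
  shells <- lapply(seq_along(uk), function(k) {
    idx <- dwi[key == uk[k]]
    tm <- timing$shells[[k]]
    td <- tm$Delta - tm$delta / 3
    G <- sqrt(bvals[idx[1]] / td) / (consts$gamma * tm$delta)
    pgse_shell(length(idx), G, tm$delta, tm$Delta, tm$TE,
               directions = t(bvec[, idx, drop = FALSE]))
  })
  pgse_protocol(name, shells, n_b0 = n_b0)
}
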