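#' Diameter sample container
#'
#' A set of axon inner diameters (e.g. traced from electron microscopy),
#' with an optional region label.
#'
#' @param diameters Positive diameters, micrometres by convention (the
#'   indices are scale-equivariant, so any single unit works).
#' @param region_label Optional text label.
#' @return Object of class `diameter_sample`.
#' @export
diameter_sample <- function(diameters, region_label = "") {
  diameters <- as.numeric(diameters)
  if (length(diameters) == 0) stop("diameter sample must be non-empty")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be positive and finite")
  structure(list(diameters = diameters, region_label = region_label),
            class = "diameter_sample")
}

.diam <- function(s) if (inherits(s, "diameter_sample")) s$diameters else
  diameter_sample(s)$diameters

#' Axon diameter indices of a diameter distribution
#'
#' Tail-weighted summary statistics of the axon diameter distribution that
#' diffusion MRI is sensitive to. In the wide-pulse limit the measured
#' index is `(<a^6>/<a^2>)^(1/4)`; in the short-pulse limit it is
#' `(<a^4>/<a^2>)^(1/2)`, with `< >` the sample mean over axons. Both are
#' dominated by the large-diameter tail; `adi_wide >= adi_short` always,
#' with equality only when all diameters coincide.
#'
#' @param s A [diameter_sample()] or numeric vector of diameters.
#' @return The index, in the unit of the input diameters.
#' @export
adi_wide <- function(s) {
  a <- .diam(s)
  (mean(a^6) / mean(a^2))^(1 / 4)
}

#' @rdname adi_wide
#' @export
adi_short <- function(s) {
  a <- .diam(s)
  (mean(a^4) / mean(a^2))^(1 / 2)
}

#' Descriptive summary of a diameter sample
#'
#' One row of basic statistics in the format used for reporting
#' electron-microscopy axon populations, plus both axon diameter indices,
#' the mass of the distribution tail above 1 um, and a semilog histogram.
#'
#' @param s A [diameter_sample()] or numeric vector.
#' @param breaks Histogram breaks passed to [hist()].
#' @return List with `stats` (one-row data.frame: `region`, `n`, `mean`,
#'   `sd`, `min`, `max`, `median`, `alpha_wide`, `alpha_short`,
#'   `tail_mass_1um`) and `histogram` (data.frame `mid`, `count`,
#'   `log10_count`).
#' @export
summarize_diameters <- function(s, breaks = 30) {
  a <- .diam(s)
  lab <- if (inherits(s, "diameter_sample")) s$region_label else ""
  h <- hist(a, breaks = breaks, plot = FALSE)
  list(
    stats = data.frame(
      region = lab, n = length(a), mean = mean(a), sd = sd(a),
      min = min(a), max = max(a), median = median(a),
      alpha_wide = adi_wide(a), alpha_short = adi_short(a),
      tail_mass_1um = mean(a > 1)),
    histogram = data.frame(mid = h$mids, count = h$counts,
                           log10_count = log10(pmax(h$counts, 0.5))))
}

#' Sensitivity and stability of ROI-level index estimates
#'
#' Sensitivity is the absolute difference between the reference
#' (microscopy) index and the ROI mean of the MRI estimates,
#' `|alpha_EM - mean(alpha)|`; stability is the sample standard deviation
#' of the per-voxel estimates (1/(N-1) normalisation). Lower is better for
#' both.
#'
#' @param alpha_em Reference axon diameter index.
#' @param roi_estimates Per-voxel index estimates in the region.
#' @return List with `sensitivity`, `stability` (NA with a flag when fewer
#'   than two voxels), `n`.
#' @export
sensitivity_stability <- function(alpha_em, roi_estimates) {
  roi_estimates <- as.numeric(roi_estimates)
  if (length(roi_estimates) == 0) stop("roi_estimates must be non-empty")
  list(sensitivity = abs(alpha_em - mean(roi_estimates)),
       stability = if (length(roi_estimates) >= 2) sd(roi_estimates)
                   else NA_real_,
       stability_defined = length(roi_estimates) >= 2,
       n = length(roi_estimates))
}

#' Read a diameter sample from CSV
#'
#' One diameter per row; a `diameter` column is used when present (first
#' column otherwise), an optional `region` column splits the file into one
#' sample per region.
#'
#' @param path CSV file path.
#' @return A `diameter_sample`, or a named list of them when a region
#'   column is present.
#' @export
read_diameter_csv <- function(path) {
  df <- utils::read.csv(path)
  dcol <- if ("diameter" %in% names(df)) "diameter" else names(df)[1]
  if ("region" %in% names(df)) {
    sp <- split(df[[dcol]], df$region)
    lapply(names(sp), function(r) diameter_sample(sp[[r]], r)) |>
      stats::setNames(names(sp))
  } else {
    diameter_sample(df[[dcol]])
  }
}
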