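#' Physical constants for PGSE arithmetic
#'
#' Returns the constants used throughout the package. The only entry is the
#' proton gyromagnetic ratio, `gamma = 2 * pi * 42.57e6` rad s^-1 T^-1.
#'
#' @return A list with element `gamma` (rad s^-1 T^-1).
#' @export
#' @examples
#' physical_constants()$gamma / (2 * pi)  # 42.57 MHz/T
physical_constants <- function() {
  list(gamma = 2 * pi * 42.57e6)
}

# unit helpers: internal representation is strict SI
.mT_per_m <- function(x) x * 1e-3   # mT/m -> T/m
.ms <- function(x) x * 1e-3         # ms -> s
.um <- function(x) x * 1e-6         # um -> m
.um2_per_ms <- function(x) x * 1e-9 # um^2/ms -> m^2/s
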