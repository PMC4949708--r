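# shared fixtures, built in code

# cached built-in protocols (direction generation is deterministic but not free)
P3 <- builtin_protocol("three_shell")
P5 <- builtin_protocol("five_shell")

# a small synthetic protocol for fast tests: 2 shells x 12 directions
mini_protocol <- function(n_dirs = 12L, n_b0 = 0L) {
  pgse_protocol("mini",
                list(pgse_shell(n_dirs, 300, 5.6, 12.1, 35, units = "scanner"),
                     pgse_shell(n_dirs, 1350, 8.6, 13.6, 35, units = "scanner")),
                n_b0 = n_b0)
}

# noiseless aligned single-diameter voxel on the dictionary grid
ongrid_voxel <- function(a_um, v_intra, protocol = P5, orient = c(1, 0, 0)) {
  p <- mmwmd_params(a = a_um * 1e-6, v_intra = v_intra,
                    v_extra = 1 - v_intra, n = orient)
  mmwmd_signal(p, protocol)
}

NOISELESS_SNR <- function(protocol) shell_snr(Inf, protocol)
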