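# shared fixtures, built in code

# tiny fully-active layout with all four sub-areas (4 x 2, 8 units)
tiny_layout <- function() {
  sub <- matrix(rep(c("toe", "forefoot", "arch", "heel"), each = 2),
                4, 2, byrow = TRUE)
  build_layout(4, 2, matrix(TRUE, 4, 2), sub)
}

# 2 x 2 all-active layout used for hand-derived network cases
quad_layout <- function() {
  build_layout(2, 2, matrix(TRUE, 2, 2),
               matrix(c("heel", "heel", "toe", "toe"), 2, 2))
}

# independent oracle for the zero-potential readout: full-network nodal
# current balance. All line voltages are clamped (driven row at V_i, every
# other line at ground / virtual ground); the current the op-amp must sink
# at the selected column node follows from the complete Laplacian, and
# |V_out| = R_f * |I_col|.
oracle_zero_potential <- function(field, circuit, unit) {
  lay <- field$layout
  nr <- lay$n_rows; nc <- lay$n_cols
  G <- 1 / field$R
  G[!is.finite(G)] <- 0
  L <- rbind(cbind(diag(rowSums(G), nr), -G),
             cbind(-t(G), diag(colSums(G), nc)))
  v <- numeric(nr + nc)
  v[unit[1] + 1L] <- circuit$V_i
  I <- L %*% v
  abs(I[nr + unit[2] + 1L]) * circuit$R_f
}

# quick synthetic trial with controllable noise/jitter
quick_trial <- function(cadence = 60, n_cycles = 3, mode = "straight",
                        noise_sd = 0, jitter = 0, seed = 7,
                        baseline_s = 2, spread = 0) {
  lay <- default_insole_layout()
  circ <- readout_circuit()
  cfg <- synth_gait_config(cadence = cadence, n_cycles = n_cycles,
                           mode = mode, noise_sd = noise_sd,
                           timing_jitter_sd = jitter,
                           baseline_s = baseline_s, seed = seed)
  par <- sample_unit_params(lay, spread = spread, seed = seed)
  synth_gait_trial(cfg, lay, circ, par)
}

max_event_error_frames <- function(detected, truth, fs = 50) {
  max(sapply(c("HC", "FC", "HO", "TO"), function(e) {
    max(abs(detected[[paste0("t_", e)]] - truth[[paste0("t_", e)]])) * fs
  }))
}
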