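#' Readout circuit description
#'
#' Parameters of the scanning electronics: excitation voltage applied to the
#' selected row, the load/feedback resistor of the transimpedance amplifier,
#' ADC resolution and reference, and the frame sampling rate.
#'
#' @param V_i Excitation voltage in volts (default 3.3).
#' @param R_f Load/feedback resistance in ohms (default 10000).
#' @param adc_bits ADC resolution in bits (default 12, counts 0-4095).
#' @param adc_vref ADC reference voltage in volts (default 3.3).
#' @param fs Frame sampling rate in Hz (default 50).
#' @return An object of class `readout_circuit`.
#' @examples
#' readout_circuit()
#' @export
readout_circuit <- function(V_i = 3.3, R_f = 10000, adc_bits = 12,
                            adc_vref = 3.3, fs = 50) {
  stopifnot(V_i > 0, R_f > 0, adc_bits >= 1, adc_vref > 0, fs > 0)
  structure(list(V_i = V_i, R_f = R_f, adc_bits = as.integer(adc_bits),
                 adc_vref = adc_vref, fs = fs),
            class = "readout_circuit")
}

#' @export
print.readout_circuit <- function(x, ...) {
  cat(sprintf("<readout_circuit> V_i=%g V, R_f=%g ohm, %d-bit ADC @ %g V, fs=%g Hz\n",
              x$V_i, x$R_f, x$adc_bits, x$adc_vref, x$fs))
  invisible(x)
}

#' Per-crossing resistance state of the matrix
#'
#' @param layout A `sensor_layout`.
#' @param R Either a full `n_rows` x `n_cols` matrix of resistances in ohms,
#'   or a vector with one value per active unit (in the `layout$units`
#'   ordering). Inactive crossings are forced to open circuit (`Inf`).
#' @return An object of class `resistance_field` (list with `layout` and the
#'   resistance matrix `R`).
#' @export
resistance_field <- function(layout, R) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (is.matrix(R)) {
    if (!identical(dim(R), dim(layout$mask)))
      stop("resistance matrix dimensions must match the layout")
    Rm <- R
  } else {
    if (length(R) != n_units(layout))
      stop("need one resistance per active unit (", n_units(layout), ")")
    Rm <- matrix(Inf, layout$n_rows, layout$n_cols)
    Rm[cbind(layout$units$row + 1L, layout$units$col + 1L)] <- R
  }
  act <- Rm[layout$mask]
  if (any(!is.finite(act)) || any(act <= 0))
    stop("all active resistances must be finite and > 0")
  Rm[!layout$mask] <- Inf
  structure(list(layout = layout, R = Rm), class = "resistance_field")
}

check_unit_active <- function(field, unit) {
  r <- unit[1] + 1L; c <- unit[2] + 1L
  if (r < 1 || r > field$layout$n_rows || c < 1 || c > field$layout$n_cols ||
      !field$layout$mask[r, c])
    stop("unit (", unit[1], ",", unit[2], ") is not an active crossing")
  c(r, c)
}

#' Zero-potential scan of one sensing unit
#'
#' Simulates the crosstalk-free readout: the selected row is driven at `V_i`,
#' the selected column is held at the amplifier's virtual ground, and every
#' other row and column line is switched to ground. With all lines clamped,
#' the current entering the virtual-ground node is the sum over rows of
#' (row voltage) x (crossing conductance); only the driven row contributes,
#' so the output is independent of every other unit. The amplifier converts
#' that current through the feedback resistor, giving
#' `|V_out| = V_i * R_f / R_unit`.
#'
#' @param field A `resistance_field`.
#' @param circuit A `readout_circuit`.
#' @param unit Integer pair `c(row, col)`, 0-based.
#' @return Output voltage magnitude in volts.
#' @examples
#' lay <- build_layout(2, 2, matrix(TRUE, 2, 2),
#'                     matrix(c("heel","heel","toe","toe"), 2, 2))
#' f <- resistance_field(lay, rep(10000, 4))
#' simulate_zero_potential_vout(f, readout_circuit(), c(0, 0))  # 3.3 V
#' @export
simulate_zero_potential_vout <- function(field, circuit, unit) {
  rc <- check_unit_active(field, unit)
  nr <- field$layout$n_rows
  # clamped line voltages: driven row at V_i, everything else at 0
  v_rows <- rep(0, nr)
  v_rows[rc[1]] <- circuit$V_i
  G_col <- 1 / field$R[, rc[2]]           # open crossings contribute 0
  i_in <- sum(v_rows * G_col)             # current into the virtual ground
  abs(i_in * circuit$R_f)
}

#' Invert an output voltage to a unit resistance
#'
#' Applies the readout identity `R = (V_i / V_out) * R_f`, the quantitative
#' contract of the zero-potential scan.
#'
#' @param v_out Measured output voltage in volts (> 0).
#' @param circuit A `readout_circuit`.
#' @return Resistance in ohms.
#' @examples
#' invert_readout(3.3, readout_circuit())  # 10000
#' @export
invert_readout <- function(v_out, circuit) {
  if (any(v_out <= 0)) stop("v_out must be > 0: unit reads as open/unmeasurable")
  (circuit$V_i / v_out) * circuit$R_f
}

#' Naive (crosstalk-afflicted) scan of one sensing unit
#'
#' Simulates a scan without the zero-potential switching: the selected row is
#' driven at `V_i`, the selected column is read across the load resistor
#' `R_f` to ground, and all other row and column lines are left floating.
#' The full resistor network is solved by dense nodal analysis (Kirchhoff's
#' current law over the row and column nodes reachable from the driven row),
#' so sneak paths through neighbouring units contribute parallel conductance
#' and the apparent resistance `R_app = R_f * (V_i - V_out) / V_out`
#' underestimates the true unit resistance.
#'
#' @inheritParams simulate_zero_potential_vout
#' @return Output voltage (across `R_f`) in volts.
#' @export
simulate_naive_vout <- function(field, circuit, unit) {
  rc <- check_unit_active(field, unit)
  nr <- field$layout$n_rows; nc <- field$layout$n_cols
  G <- 1 / field$R                         # nr x nc branch conductances
  G[!is.finite(G)] <- 0

  # node numbering: rows 1..nr, columns nr+1..nr+nc
  sel_row <- rc[1]; sel_col_node <- nr + rc[2]

  # restrict to nodes reachable from the driven row through active units;
  # isolated floating islands would make the system singular and carry no
  # current anyway
  adj <- G > 0
  reach_r <- rep(FALSE, nr); reach_c <- rep(FALSE, nc)
  reach_r[sel_row] <- TRUE
  repeat {
    new_c <- (colSums(adj[reach_r, , drop = FALSE] > 0) > 0) & !reach_c
    reach_c <- reach_c | new_c
    new_r <- (rowSums(adj[, reach_c, drop = FALSE] > 0) > 0) & !reach_r
    if (!any(new_r) && !any(new_c)) break
    reach_r <- reach_r | new_r
  }
  # Laplacian over the bipartite row/column graph, assembled blockwise,
  # then restricted to reachable nodes; plus the load conductance to ground
  L_full <- rbind(cbind(diag(rowSums(G), nr), -G),
                  cbind(-t(G), diag(colSums(G), nc)))
  nodes <- c(which(reach_r), nr + which(reach_c))
  n <- length(nodes)
  pos <- integer(nr + nc); pos[nodes] <- seq_len(n)
  L <- L_full[nodes, nodes, drop = FALSE]
  pc <- pos[sel_col_node]
  L[pc, pc] <- L[pc, pc] + 1 / circuit$R_f

  # Dirichlet condition: driven row at V_i; solve for the free nodes
  pr <- pos[sel_row]
  free <- setdiff(seq_len(n), pr)
  if (!length(free)) stop("singular network: no conductive path from the driven row")
  b <- -L[free, pr] * circuit$V_i
  v <- tryCatch(solve(L[free, free, drop = FALSE], b),
                error = function(e) stop("singular network: open reading"))
  vf <- numeric(n); vf[pr] <- circuit$V_i; vf[free] <- v
  vf[pc]
}

#' Apparent resistance from a naive scan voltage
#'
#' @param v_out Voltage across the load resistor from [simulate_naive_vout()].
#' @param circuit A `readout_circuit`.
#' @return Apparent resistance in ohms (`R_f * (V_i - V_out) / V_out`).
#' @export
apparent_resistance <- function(v_out, circuit) {
  if (any(v_out <= 0)) stop("v_out must be > 0")
  circuit$R_f * (circuit$V_i - v_out) / v_out
}

#' Quantize a voltage to ADC counts
#'
#' Round-to-nearest (half up) with saturation at the range ends:
#' `floor(clip(v, 0, vref) / vref * (2^bits - 1) + 0.5)`.
#'
#' @param v Voltage(s), >= 0.
#' @param circuit A `readout_circuit`.
#' @return Integer count(s) in `[0, 2^adc_bits - 1]`.
#' @examples
#' adc_convert(c(0, 1.65, 3.3), readout_circuit())
#' @export
adc_convert <- function(v, circuit) {
  full <- 2^circuit$adc_bits - 1
  v <- pmin(pmax(v, 0), circuit$adc_vref)
  as.integer(floor(v / circuit$adc_vref * full + 0.5))
}

#' Scan a whole frame with the zero-potential method
#'
#' Iterates the zero-potential readout over every active unit of the layout
#' and quantizes each output voltage to ADC counts.
#'
#' @param field A `resistance_field` matching `layout`.
#' @param circuit A `readout_circuit`.
#' @param layout A `sensor_layout`.
#' @param t Timestamp in seconds attached to the frame.
#' @return A `pressure_frame`: list with `t` and integer `counts` named by
#'   unit id.
#' @export
scan_frame <- function(field, circuit, layout, t = 0) {
  stopifnot(identical(field$layout$mask, layout$mask))
  g <- 1 / field$R[cbind(layout$units$row + 1L, layout$units$col + 1L)]
  v <- abs(circuit$V_i * circuit$R_f * g)
  counts <- adc_convert(v, circuit)
  names(counts) <- layout$units$id
  structure(list(t = t, counts = counts), class = "pressure_frame")
}

#' Assemble a frame log
#'
#' @param t Numeric vector of timestamps (strictly increasing, uniform
#'   spacing `1/fs`).
#' @param counts Numeric matrix, one row per frame, one column per active
#'   unit (columns named by unit id).
#' @param fs Sampling rate in Hz.
#' @return An object of class `frame_log`.
#' @export
frame_log <- function(t, counts, fs) {
  stopifnot(length(t) == nrow(counts), fs > 0)
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs)
      stop("timestamps must increase uniformly at 1/fs")
  }
  structure(list(t = t, counts = counts, fs = fs), class = "frame_log")
}

#' @export
print.frame_log <- function(x, ...) {
  cat(sprintf("<frame_log> %d frames x %d units @ %g Hz (%.2f s)\n",
              length(x$t), ncol(x$counts), x$fs,
              if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}
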