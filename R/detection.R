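#' Register the zero offset from a baseline log
#'
#' @param baseline A `frame_log` captured with no external load.
#' @return Named numeric vector: per-unit mean counts.
#' @export
register_zero_offset <- function(baseline) {
  if (!length(baseline$t)) stop("empty baseline log")
  colMeans(baseline$counts)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Third-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase lag and unit DC gain. Applied
#' per sensing unit before sub-area averaging.
#'
#' @param x Numeric vector or matrix (one column per unit).
#' @param fs Sampling rate in Hz (must exceed `2 * cutoff`).
#' @param order Filter order (default 3).
#' @param cutoff Cut-off frequency in Hz (default 7).
#' @return Filtered data, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, order = 3, cutoff = 7) {
  if (fs <= 2 * cutoff) stop("fs must exceed twice the cut-off frequency")
  bf <- signal::butter(order, cutoff / (fs / 2))
  pad <- 3 * (max(length(bf$b), length(bf$a)) - 1) * 5
  if (NROW(x) <= pad) stop("series too short for zero-phase filtering")
  one <- function(col) {
    # odd-reflection padding suppresses start/end transients of the
    # forward-backward pass
    head_pad <- 2 * col[1] - col[(pad + 1):2]
    tail_pad <- 2 * col[length(col)] - col[(length(col) - 1):(length(col) - pad)]
    y <- signal::filtfilt(bf, c(head_pad, col, tail_pad))
    y[(pad + 1):(pad + length(col))]
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

#' Average offset-corrected unit outputs within plantar sub-areas
#'
#' For each sub-area the output is the plain mean over that area's active
#' units, which suppresses per-unit gain diversity.
#'
#' @param counts Numeric matrix of (filtered, offset-corrected) per-unit
#'   outputs, columns named by unit id in layout order.
#' @param layout A `sensor_layout`.
#' @param t Optional time vector (seconds) to carry along.
#' @return A data.frame of class `subarea_series` with columns `t`,
#'   `P_heel`, `P_arch`, `P_forefoot`, `P_toe`.
#' @export
subarea_average <- function(counts, layout, t = NULL) {
  subs <- c("heel", "arch", "forefoot", "toe")
  out <- lapply(subs, function(s) {
    sel <- layout$units$subarea == s
    if (!any(sel)) stop("empty sub-area: ", s)
    rowMeans(counts[, sel, drop = FALSE])
  })
  names(out) <- paste0("P_", subs)
  if (is.null(t)) t <- seq_len(NROW(counts))
  res <- data.frame(t = t, out)
  class(res) <- c("subarea_series", "data.frame")
  res
}

#' Segment a trial into single-stance cycle windows
#'
#' The total output (sum of the four sub-area averages) delimits stance
#' activity: an interval where the total stays below `thresh_frac` of the
#' trial maximum for at least `min_swing` seconds is a swing (or baseline)
#' gap, and each activity run between gaps is one stance. Windows are
#' padded by `pad` frames into the neighbouring gaps so the minima
#' bracketing each stance are available to the event search.
#'
#' @param s A `subarea_series`.
#' @param fs Sampling rate in Hz.
#' @param thresh_frac Activity threshold as a fraction of the trial maximum
#'   total output (default 0.05).
#' @param min_swing Minimum quiet-gap duration in seconds (default 0.15).
#' @param pad Window padding in frames (default 3).
#' @return Data.frame with `start` and `end` frame indices, one row per
#'   detected stance.
#' @export
segment_cycles <- function(s, fs, thresh_frac = 0.05, min_swing = 0.15,
                           pad = 3L) {
  total <- s$P_heel + s$P_arch + s$P_forefoot + s$P_toe
  thr <- thresh_frac * max(total)
  if (max(total) <= 0 || !any(total > thr)) stop("no activity found")
  active <- total > thr
  # close gaps shorter than min_swing (they belong to the same stance)
  r <- rle(active)
  short_gap <- !r$values & r$lengths < round(min_swing * fs)
  # never close leading/trailing gaps
  short_gap[c(1, length(r$values))] <- FALSE
  r$values[short_gap] <- TRUE
  active <- inverse.rle(r)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) stop("no activity found")
  w <- data.frame(start = starts[runs], end = ends[runs])
  # pad into the quiet gaps, clipped at midpoints between stances
  lo <- c(1, floor((w$end[-nrow(w)] + w$start[-1]) / 2) + 1)
  hi <- c(ceiling((w$end[-nrow(w)] + w$start[-1]) / 2), length(total))
  w$start <- pmax(w$start - pad, lo)
  w$end <- pmin(w$end + pad, hi)
  w
}

# robust noise scale of a window: spread of the quiet (near-floor) samples
.noise_scale <- function(x) {
  rng <- max(x) - min(x)
  if (rng <= 0) return(0)
  quiet <- x <= min(x) + 0.1 * rng
  if (sum(quiet) < 4) return(0)
  stats::mad(x[quiet])
}

# first local maximum at or after `from`, confirmed by a rise and fall of at
# least `delta` (plateaus collapse to their first frame)
.first_max <- function(x, from, to, delta) {
  cur_min <- x[from]; armed <- FALSE; cur_max <- -Inf; pos <- NA_integer_
  for (k in from:to) {
    if (!armed) {
      if (x[k] < cur_min) cur_min <- x[k]
      if (x[k] >= cur_min + delta) { armed <- TRUE; cur_max <- x[k]; pos <- k }
    } else {
      if (x[k] > cur_max) { cur_max <- x[k]; pos <- k }
      if (x[k] <= cur_max - delta) return(pos)
    }
  }
  NA_integer_
}

# turning-point minima of a segment: samples no higher than either
# neighbour, with plateaus contributing their first and last frames and
# segment edges treated as rising
.turning_minima <- function(seg) {
  n <- length(seg)
  if (n == 1) return(1L)
  le <- c(TRUE, seg[-1] <= seg[-n])        # not rising into the sample
  ri <- c(seg[-n] <= seg[-1], TRUE)        # not falling out of the sample
  lt <- c(TRUE, seg[-1] < seg[-n])
  rt <- c(seg[-n] < seg[-1], TRUE)
  which((le & rt) | (lt & ri))             # plateau start or plateau end
}

# local minimum immediately preceding `upto`: the nearest turning-point
# minimum before it that lies within `tie` of the segment floor (the
# tolerance absorbs noise and zero-phase filter ripple)
.last_min_before <- function(x, upto, lo, tie) {
  if (upto - 1 < lo) return(NA_integer_)
  seg <- x[lo:(upto - 1)]
  cand <- .turning_minima(seg)
  cand <- cand[seg[cand] <= min(seg) + tie]
  if (!length(cand)) return(NA_integer_)
  lo + cand[length(cand)] - 1L
}

# first local minimum strictly after `from`: the frame where the falling
# output reaches its floor plateau -- the moment the decrease ends and the
# (possibly delayed-response) increase can begin. The plateau is the band
# within `tie` of the segment minimum; its first frame is returned.
.first_min_after <- function(x, from, to, tie) {
  if (from + 1 > to) return(NA_integer_)
  seg <- x[(from + 1):to]
  cand <- which(seg <= min(seg) + tie)
  if (!length(cand)) return(NA_integer_)
  from + cand[1]
}

#' Detect the four gait events within one cycle window
#'
#' Implements the peak-heuristic search on the sub-area averages: the first
#' qualified peak of the heel output locates `t1`, and heel contact is the
#' minimum immediately before it; the first qualified peak of the forefoot
#' output locates `t2`, and forefoot contact is the minimum immediately
#' before it (constrained after heel contact); heel off is the first heel
#' minimum after forefoot contact; toe off is the first toe minimum after
#' heel off. Peaks qualify by a prominence of at least `delta_frac` of the
#' window's peak-to-peak range; minima searches tolerate noise and filter
#' ripple up to a few times the window's quiet-floor spread. Any missing
#' extremum yields `NA` for that event rather than a silently wrong time.
#'
#' @param s A `subarea_series`.
#' @param w One-row window (frame indices `start`, `end`).
#' @param fs Sampling rate in Hz.
#' @param delta_frac Peak prominence threshold as a fraction of the window
#'   range (default 0.05).
#' @return One-row data.frame: `t_HC`, `t_FC`, `t_HO`, `t_TO` (seconds, NA
#'   when not detected), the matching frame indices `i_HC` ... `i_TO`, and
#'   a `status` string (`"ok"` or the missing events).
#' @export
detect_events <- function(s, w, fs, delta_frac = 0.05) {
  a <- w$start[1]; b <- w$end[1]
  heel <- s$P_heel; fore <- s$P_forefoot; toe <- s$P_toe
  out <- data.frame(t_HC = NA_real_, t_FC = NA_real_, t_HO = NA_real_,
                    t_TO = NA_real_, i_HC = NA_integer_, i_FC = NA_integer_,
                    i_HO = NA_integer_, i_TO = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  miss <- character(0)

  # noise/ripple tolerances: `tie` qualifies dips near the floor for the
  # backward searches; `band` is the floor-plateau width for the forward
  # searches (wider, since the zero-phase filter rounds the descent corner)
  tie <- function(x) {
    rng <- max(x[a:b]) - min(x[a:b])
    max(4 * .noise_scale(x[a:b]), 1e-9 * rng)
  }
  band <- function(x) {
    rng <- max(x[a:b]) - min(x[a:b])
    max(4 * .noise_scale(x[a:b]), 0.01 * rng)
  }
  delta <- function(x) delta_frac * (max(x[a:b]) - min(x[a:b]))

  t1 <- .first_max(heel, a, b, delta(heel))
  i_HC <- if (is.na(t1)) NA_integer_ else .last_min_before(heel, t1, a, tie(heel))
  if (is.na(i_HC)) miss <- c(miss, "HC")

  t2 <- .first_max(fore, a, b, delta(fore))
  i_FC <- if (is.na(t2)) NA_integer_ else {
    lo <- if (!is.na(i_HC)) i_HC + 1L else a   # constraint t_HC < t_FC
    .last_min_before(fore, t2, lo, tie(fore))
  }
  if (is.na(i_FC)) miss <- c(miss, "FC")

  i_HO <- if (!is.na(i_FC)) .first_min_after(heel, i_FC, b, band(heel)) else NA_integer_
  if (is.na(i_HO)) miss <- c(miss, "HO")

  i_TO <- if (!is.na(i_HO)) .first_min_after(toe, i_HO, b, band(toe)) else NA_integer_
  if (is.na(i_TO)) miss <- c(miss, "TO")

  idx <- c(i_HC, i_FC, i_HO, i_TO)
  if (!anyNA(idx) && any(diff(idx) <= 0)) {
    miss <- c(miss, "ordering")
    idx <- rep(NA_integer_, 4)
  }
  out$i_HC <- idx[1]; out$i_FC <- idx[2]; out$i_HO <- idx[3]; out$i_TO <- idx[4]
  tt <- s$t[idx]
  out$t_HC <- tt[1]; out$t_FC <- tt[2]; out$t_HO <- tt[3]; out$t_TO <- tt[4]
  out$status <- if (length(miss)) paste("not detected:", paste(miss, collapse = ","))
                else "ok"
  out
}

#' Stance sub-phase durations from detected events
#'
#' Initial contact runs from heel contact to forefoot contact, flat foot
#' from forefoot contact to heel off, and push off from heel off to toe
#' off; the three durations telescope exactly to the stance duration.
#'
#' @param e One-row data.frame (or list) with `t_HC`, `t_FC`, `t_HO`, `t_TO`.
#' @return One-row data.frame with `T_IC`, `T_FF`, `T_PO` in seconds.
#' @export
phase_durations <- function(e) {
  tt <- c(e$t_HC, e$t_FC, e$t_HO, e$t_TO)
  if (anyNA(tt)) return(data.frame(T_IC = NA_real_, T_FF = NA_real_,
                                   T_PO = NA_real_))
  if (any(diff(tt) <= 0)) stop("events must be strictly ordered")
  data.frame(T_IC = e$t_FC - e$t_HC, T_FF = e$t_HO - e$t_FC,
             T_PO = e$t_TO - e$t_HO)
}

#' Run the full detection pipeline on a frame log
#'
#' Chains the preprocessing and detection stages: zero-offset subtraction,
#' per-unit zero-phase 7 Hz low-pass filtering, sub-area averaging, cycle
#' segmentation, per-cycle event detection and phase durations.
#'
#' @param frames A `frame_log`.
#' @param layout The matching `sensor_layout`.
#' @param offsets Per-unit offsets from [register_zero_offset()], or
#'   `NULL`. When `NULL` and `baseline_s > 0`, offsets are registered from
#'   the first `baseline_s` seconds of `frames`; with neither, zero offsets
#'   are assumed with a warning.
#' @param baseline_s Seconds of unloaded capture at the start of `frames`.
#' @param cutoff,order Low-pass filter settings (7 Hz, 3rd order).
#' @param thresh_frac,min_swing,pad Segmentation settings, see
#'   [segment_cycles()].
#' @param delta_frac Peak prominence threshold, see [detect_events()].
#' @return A list of class `gait_detection`: `events` (per-cycle data.frame
#'   with event times, phase durations and status), `series` (the
#'   `subarea_series`), and `windows`.
#' @export
detect_gait <- function(frames, layout, offsets = NULL, baseline_s = 0,
                        cutoff = 7, order = 3, thresh_frac = 0.05,
                        min_swing = 0.15, pad = 3L, delta_frac = 0.05) {
  fs <- frames$fs
  if (is.null(offsets)) {
    if (baseline_s > 0) {
      nb <- min(length(frames$t), round(baseline_s * fs))
      offsets <- colMeans(frames$counts[seq_len(nb), , drop = FALSE])
    } else {
      warning("no baseline available; assuming zero offsets")
      offsets <- rep(0, ncol(frames$counts))
    }
  }
  corrected <- sweep(frames$counts, 2, offsets)
  filtered <- lowpass_filter(corrected, fs, order = order, cutoff = cutoff)
  s <- subarea_average(filtered, layout, t = frames$t)
  w <- segment_cycles(s, fs, thresh_frac = thresh_frac,
                      min_swing = min_swing, pad = pad)
  # drop the leading baseline pseudo-gap window boundary case: windows fully
  # inside the baseline cannot occur since the baseline is quiet
  ev <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
    e <- detect_events(s, w[i, ], fs, delta_frac = delta_frac)
    cbind(cycle = i, e, phase_durations(e))
  }))
  structure(list(events = ev, series = s, windows = w, fs = fs),
            class = "gait_detection")
}

#' @export
print.gait_detection <- function(x, ...) {
  ok <- sum(x$events$status == "ok")
  cat(sprintf("<gait_detection> %d cycles, %d fully detected (%.1f%%)\n",
              nrow(x$events), ok, 100 * ok / max(1, nrow(x$events))))
  invisible(x)
}
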