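#' Reference gait events from a vertical GRF trace
#'
#' Applies the force-plate reference definitions: heel contact is the first
#' frame where the vertical force rises above the 10 N threshold, toe off
#' the first frame after loading where it falls back below, forefoot
#' contact the first local maximum of the loading curve and heel off the
#' second. Peaks qualify by the same prominence rule as the insole
#' detector. Every loading burst of at least `min_stance` seconds is
#' treated as one stance.
#'
#' @param grf Data.frame with columns `t` (uniform grid) and `Fz` (newtons).
#' @param threshold Contact threshold in newtons (default 10).
#' @param min_stance Minimum stance duration in seconds (default 0.2).
#' @param delta_frac Peak prominence threshold as a fraction of the trace
#'   range (default 0.05).
#' @return Data.frame with one row per stance: `cycle`, `t_HC`, `t_FC`,
#'   `t_HO`, `t_TO` (seconds).
#' @export
detect_reference_events <- function(grf, threshold = 10, min_stance = 0.2,
                                    delta_frac = 0.05) {
  t <- grf$t; Fz <- grf$Fz
  fs <- 1 / stats::median(diff(t))
  above <- Fz > threshold
  if (!any(above)) stop("no threshold crossing: GRF never exceeds ", threshold, " N")
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(min_stance * fs)
  if (!any(keep)) stop("no stance of at least ", min_stance, " s found")
  runs <- data.frame(start = starts[keep], end = ends[keep])
  delta <- delta_frac * (max(Fz) - min(Fz))
  out <- lapply(seq_len(nrow(runs)), function(i) {
    a <- runs$start[i]; b <- runs$end[i]
    if (b >= length(Fz) && Fz[b] > threshold)
      stop("GRF ends mid-stance: incomplete loading")
    p1 <- .first_max(Fz, a, b, delta)
    if (is.na(p1)) stop("no qualifying GRF peak in stance ", i)
    p2 <- if (p1 < b) .first_max(Fz, p1 + 1L, b, delta) else NA_integer_
    if (is.na(p2)) stop("second peak missing in stance ", i)
    data.frame(cycle = i, t_HC = t[a], t_FC = t[p1], t_HO = t[p2],
               t_TO = t[b + 1L])
  })
  do.call(rbind, out)
}

#' Signed and absolute timing error for one event
#'
#' `RD = t_shoe - t_ref` (positive = the shoe detection lags the
#' reference), `AD = |RD|`.
#'
#' @param t_shoe,t_ref Event times in seconds.
#' @return Data.frame with `RD` and `AD` in seconds.
#' @export
event_errors <- function(t_shoe, t_ref) {
  rd <- t_shoe - t_ref
  data.frame(RD = rd, AD = abs(rd))
}

#' Median of absolute differences
#'
#' @param ads Non-empty numeric vector of absolute differences.
#' @return The median (mean of the central pair for even lengths).
#' @export
median_error <- function(ads) {
  if (!length(ads)) stop("empty list of absolute differences")
  stats::median(ads)
}

#' Percentage difference relative to the reference stance duration
#'
#' @param ad Absolute difference in seconds.
#' @param t_st_ref Reference stance duration in seconds (> 0).
#' @return Percentage, `ad / t_st_ref * 100`.
#' @export
percent_difference <- function(ad, t_st_ref) {
  if (any(t_st_ref <= 0)) stop("reference stance duration must be > 0")
  ad / t_st_ref * 100
}

#' Evaluate shoe-detected events against the GRF reference
#'
#' Runs reference detection on the trial's GRF, pairs reference stances
#' with shoe-detected cycles by time overlap, and computes per-cycle RD/AD
#' for the four events and the three phase durations, plus the percentage
#' difference of each phase relative to the reference stance duration.
#' Cycles with missing detections are retained with `NA` errors and counted
#' against the detection rate.
#'
#' @param det A `gait_detection` from [detect_gait()] (or its `events`
#'   data.frame).
#' @param grf Data.frame `t`, `Fz` synchronized with the frame log.
#' @param ... Passed to [detect_reference_events()].
#' @return A list of class `gait_evaluation`: `records` (per-cycle errors,
#'   seconds), `reference` (the reference events), `fs`, and
#'   `detection_rate` (percent of reference stances with all events and
#'   phases detected).
#' @export
evaluate_trial <- function(det, grf, ...) {
  ev <- if (inherits(det, "gait_detection")) det$events else det
  fs <- if (inherits(det, "gait_detection")) det$fs else 1 / stats::median(diff(grf$t))
  ref <- detect_reference_events(grf, ...)
  events <- c("HC", "FC", "HO", "TO")
  phases <- c("IC", "FF", "PO")
  recs <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    # pair with the shoe cycle whose detected span overlaps this stance
    mid <- (r$t_HC + r$t_TO) / 2
    span_lo <- ifelse(is.na(ev$t_HC), ev$t_FC, ev$t_HC)
    cand <- which(!is.na(span_lo) & span_lo <= r$t_TO &
                    pmax(ev$t_TO, ev$t_HO, ev$t_FC, ev$t_HC, na.rm = TRUE) >= r$t_HC)
    j <- if (length(cand)) cand[which.min(abs(
      (ifelse(is.na(ev$t_HC[cand]), ev$t_FC[cand], ev$t_HC[cand])) - mid))]
      else NA_integer_
    out <- data.frame(cycle = i, t_st_ref = r$t_TO - r$t_HC)
    detected <- !is.na(j) && ev$status[j] == "ok"
    out$detected <- detected
    for (e in events) {
      rd <- if (detected) ev[[paste0("t_", e)]][j] - r[[paste0("t_", e)]] else NA_real_
      out[[paste0("RD_", e)]] <- rd
      out[[paste0("AD_", e)]] <- abs(rd)
    }
    ref_ph <- c(IC = r$t_FC - r$t_HC, FF = r$t_HO - r$t_FC, PO = r$t_TO - r$t_HO)
    shoe_ph <- if (detected)
      c(IC = ev$T_IC[j], FF = ev$T_FF[j], PO = ev$T_PO[j])
    else c(IC = NA_real_, FF = NA_real_, PO = NA_real_)
    for (p in phases) {
      rd <- shoe_ph[[p]] - ref_ph[[p]]
      out[[paste0("RD_", p)]] <- rd
      out[[paste0("AD_", p)]] <- abs(rd)
      out[[paste0("pD_", p)]] <- abs(rd) / out$t_st_ref * 100
    }
    out
  })
  records <- do.call(rbind, recs)
  structure(list(records = records, reference = ref, fs = fs,
                 detection_rate = 100 * mean(records$detected)),
            class = "gait_evaluation")
}

#' Summary table of detection errors
#'
#' Aggregates per-cycle records into one row per event (HC, FC, HO, TO)
#' and phase (IC, FF, PO): mean and sd of the absolute and signed
#' differences, in data frames and milliseconds, the median absolute error
#' (ME), the mean percentage difference for phases, and the overall
#' detection rate.
#'
#' @param eval_out A `gait_evaluation`, or a list of them (records are
#'   pooled).
#' @param fs Sampling rate used for the frame conversion (taken from the
#'   evaluation by default).
#' @return A data.frame with columns `item`, `kind`, `n`, `AD_frames`,
#'   `AD_sd_frames`, `AD_ms`, `RD_frames`, `RD_ms`, `ME_frames`, `ME_ms`,
#'   `pD_pct` and attribute `detection_rate`.
#' @export
summarize_errors <- function(eval_out, fs = NULL) {
  evs <- if (inherits(eval_out, "gait_evaluation")) list(eval_out) else eval_out
  records <- do.call(rbind, lapply(evs, `[[`, "records"))
  if (is.null(fs)) fs <- evs[[1]]$fs
  items <- c(HC = "event", FC = "event", HO = "event", TO = "event",
             IC = "phase", FF = "phase", PO = "phase")
  rows <- lapply(names(items), function(it) {
    ad <- records[[paste0("AD_", it)]]
    rd <- records[[paste0("RD_", it)]]
    ok <- !is.na(ad)
    data.frame(
      item = it, kind = items[[it]], n = sum(ok),
      AD_frames = mean(ad[ok]) * fs, AD_sd_frames = stats::sd(ad[ok]) * fs,
      AD_ms = mean(ad[ok]) * 1000,
      RD_frames = mean(rd[ok]) * fs, RD_ms = mean(rd[ok]) * 1000,
      ME_frames = median_error(ad[ok]) * fs, ME_ms = median_error(ad[ok]) * 1000,
      pD_pct = if (items[[it]] == "phase")
        mean(records[[paste0("pD_", it)]][ok]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "detection_rate") <- 100 * mean(records$detected)
  out
}

#' @export
print.gait_evaluation <- function(x, ...) {
  cat(sprintf("<gait_evaluation> %d reference stances, detection rate %.1f%%\n",
              nrow(x$records), x$detection_rate))
  print(summarize_errors(x), digits = 3)
  invisible(x)
}
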