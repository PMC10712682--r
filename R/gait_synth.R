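#' Configuration for synthetic gait trials
#'
#' Defaults emulate the walking protocol the system was designed around:
#' 50 Hz scanning, a ten-second unloaded capture before walking (used for
#' zero-offset registration), and cadences of 40/60/80 strides per minute
#' (slow/normal/fast). Within each cycle of duration `60/cadence` seconds
#' the ground-truth events fall at fixed fractions of the cycle: heel
#' contact at 0, forefoot contact at 8%, heel off at 40% and toe off at 62%
#' (the stance fraction). These fractions follow textbook gait norms and are
#' all configurable.
#'
#' @param cadence Strides per minute (default 60).
#' @param n_cycles Number of gait cycles to generate.
#' @param mode `"straight"` or `"turning"`. Turning emulates a left step
#'   turn: forefoot load shifts medially, stance lengthens by
#'   `turn_stance_stretch`, and timing jitter doubles.
#' @param event_fractions Named fractions of the cycle for `FC`, `HO`, `TO`
#'   (HC is the cycle origin); `TO` is the stance fraction.
#' @param peak_forces Named per-unit peak forces in newtons for
#'   `heel`, `forefoot`, `toe`, `arch` (per-unit plantar loading during
#'   walking is roughly 5-9.5 N on the loaded sub-areas).
#' @param noise_sd Additive post-ADC count noise sd (default 20).
#' @param timing_jitter_sd Cycle-to-cycle event timing jitter sd in seconds.
#' @param body_weight Body weight in newtons, scales the synthetic vGRF.
#' @param baseline_s Unloaded capture duration at the start of the trial, s.
#' @param toe_lead Seconds before heel off at which the toe starts loading.
#' @param turn_stance_stretch Relative stance lengthening in turning mode.
#' @param seed Integer seed driving all randomness in the trial.
#' @return A list of class `synth_gait_config`.
#' @export
synth_gait_config <- function(cadence = 60, n_cycles = 10, mode = "straight",
                              event_fractions = c(FC = 0.08, HO = 0.40, TO = 0.62),
                              peak_forces = c(heel = 9, forefoot = 8,
                                              toe = 6, arch = 2),
                              noise_sd = 20, timing_jitter_sd = 0.01,
                              body_weight = 620, baseline_s = 10,
                              toe_lead = 0.05, turn_stance_stretch = 0.05,
                              seed = 1L) {
  mode <- match.arg(mode, c("straight", "turning"))
  f <- event_fractions
  if (!(0 < f[["FC"]] && f[["FC"]] < f[["HO"]] && f[["HO"]] < f[["TO"]] &&
        f[["TO"]] <= 1))
    stop("event fractions must satisfy 0 < FC < HO < TO <= 1")
  stopifnot(n_cycles >= 1, cadence > 0, noise_sd >= 0, timing_jitter_sd >= 0,
            body_weight > 0, baseline_s >= 0, toe_lead > 0)
  structure(list(cadence = cadence, n_cycles = as.integer(n_cycles),
                 mode = mode, event_fractions = f, peak_forces = peak_forces,
                 noise_sd = noise_sd, timing_jitter_sd = timing_jitter_sd,
                 body_weight = body_weight, baseline_s = baseline_s,
                 toe_lead = toe_lead, turn_stance_stretch = turn_stance_stretch,
                 seed = as.integer(seed)),
            class = "synth_gait_config")
}

# ground-truth event schedule: one row per cycle. Event times are snapped
# to the scan clock (the system's temporal resolution), so the envelopes
# realize the recorded truth exactly at the sampled frames.
truth_schedule <- function(cfg, t0, fs) {
  T <- 60 / cfg$cadence
  f <- cfg$event_fractions
  if (cfg$mode == "turning") f <- f * (1 + cfg$turn_stance_stretch)
  jsd <- cfg$timing_jitter_sd * if (cfg$mode == "turning") 2 else 1
  n <- cfg$n_cycles
  starts <- t0 + (seq_len(n) - 1) * T
  j <- matrix(if (jsd > 0) stats::rnorm(4 * n, 0, jsd) else 0, n, 4)
  t_HC <- starts + j[, 1]
  t_FC <- pmax(starts + f[["FC"]] * T + j[, 2], t_HC + 0.06)
  t_HO <- pmax(starts + f[["HO"]] * T + j[, 3], t_FC + cfg$toe_lead + 0.06)
  t_TO <- pmin(pmax(starts + f[["TO"]] * T + j[, 4], t_HO + 0.08),
               starts + T - 0.18)   # keep a detectable swing gap
  snap <- function(x) round(x * fs) / fs
  data.frame(cycle = seq_len(n), t_HC = snap(t_HC), t_FC = snap(t_FC),
             t_HO = snap(t_HO), t_TO = snap(t_TO))
}

# smooth raised-cosine hump on [a, b], zero outside
hump <- function(t, a, b) {
  u <- (t - a) / (b - a)
  ifelse(u > 0 & u < 1, sin(pi * u)^2, 0)
}

#' Generate a full synthetic gait trial
#'
#' Builds per-unit force envelopes (heel loads from heel contact and unloads
#' by heel off; the forefoot loads from forefoot contact; the toe loads
#' shortly before heel off until toe off; the arch carries a small fraction
#' of the forefoot load), passes them through the sensing-unit creep
#' dynamics and the zero-potential readout to produce a scanned frame log,
#' synthesizes the synchronized vertical GRF from the same ground-truth
#' events, and records the truth exactly. The trial starts with
#' `baseline_s` seconds of unloaded frames for zero-offset registration.
#' All randomness (timing jitter, count noise) derives from `cfg$seed`.
#'
#' @param cfg A `synth_gait_config`.
#' @param layout A `sensor_layout` with all four sub-areas populated.
#' @param circuit A `readout_circuit` (its `fs` is the trial clock).
#' @param params Per-unit parameters from [sample_unit_params()].
#' @return A `synth_trial`: list with `frames` (a `frame_log`), `grf`
#'   (data.frame `t`, `Fz`), `truth` (per-cycle event times), `baseline_s`
#'   and `config`.
#' @export
synth_gait_trial <- function(cfg, layout = default_insole_layout(),
                             circuit = readout_circuit(),
                             params = sample_unit_params(layout, seed = cfg$seed)) {
  stopifnot(inherits(cfg, "synth_gait_config"))
  subs <- c("heel", "arch", "forefoot", "toe")
  if (!all(subs %in% layout$units$subarea))
    stop("layout must populate all four sub-areas")
  fs <- circuit$fs
  T <- 60 / cfg$cadence

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  t0 <- cfg$baseline_s + 0.4           # swing lead-in before the first cycle
  truth <- truth_schedule(cfg, t0, fs)
  t_end <- max(truth$t_TO) + 0.5
  t <- seq(0, t_end, by = 1 / fs)
  nt <- length(t)

  # sub-area force envelopes (per-unit newtons)
  pk <- cfg$peak_forces
  env <- matrix(0, nt, 4, dimnames = list(NULL, subs))
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    env[, "heel"] <- env[, "heel"] + pk[["heel"]] * hump(t, e$t_HC, e$t_HO)
    ff <- hump(t, e$t_FC, e$t_TO)
    env[, "forefoot"] <- env[, "forefoot"] + pk[["forefoot"]] * ff
    env[, "arch"] <- env[, "arch"] + pk[["arch"]] * ff
    env[, "toe"] <- env[, "toe"] +
      pk[["toe"]] * hump(t, e$t_HO - cfg$toe_lead, e$t_TO)
  }

  # creep dynamics applied per sub-area envelope; the dynamics are
  # homogeneous in amplitude, so per-unit scaling commutes with them
  nom <- params$nominal
  eff <- apply(env, 2, apply_creep_dynamics, p = nom, fs = fs)

  # spatial weighting within sub-areas: uniform for straight walking; the
  # turning emulation shifts forefoot load medially (low column indices)
  w <- rep(1, n_units(layout))
  if (cfg$mode == "turning") {
    ffu <- layout$units$subarea == "forefoot"
    colc <- layout$units$col[ffu]
    wt <- 1 - 0.6 * (colc - mean(colc)) / max(1, diff(range(colc)) / 2)
    w[ffu] <- wt / mean(wt)
  }

  sub_idx <- match(layout$units$subarea, subs)
  # frames x units effective drive, then the affine readout per unit
  E <- eff[, sub_idx, drop = FALSE] * rep(w, each = nt)
  V <- sweep(E, 2, params$gain, `*`)
  V <- sweep(V, 2, params$g0, `+`) * circuit$V_i * circuit$R_f
  full <- 2^circuit$adc_bits - 1
  counts <- floor(pmin(pmax(V, 0), circuit$adc_vref) / circuit$adc_vref * full + 0.5)
  if (cfg$noise_sd > 0)
    counts <- round(counts + matrix(stats::rnorm(length(counts), 0, cfg$noise_sd),
                                    nt, ncol(counts)))
  counts <- pmin(pmax(counts, 0), full)
  colnames(counts) <- layout$units$id

  grf <- synth_grf(truth, cfg, t)

  structure(list(frames = frame_log(t, counts, fs), grf = grf, truth = truth,
                 baseline_s = cfg$baseline_s, layout = layout,
                 circuit = circuit, config = cfg),
            class = "synth_trial")
}

#' @export
print.synth_trial <- function(x, ...) {
  cat(sprintf("<synth_trial> %d cycles @ %g strides/min (%s), %d frames @ %g Hz\n",
              nrow(x$truth), x$config$cadence, x$config$mode,
              length(x$frames$t), x$frames$fs))
  invisible(x)
}

#' Synthesize a vertical GRF trace from ground-truth events
#'
#' Constructs the classic double-hump stance profile per cycle: the force
#' rises from zero at heel contact to a first local maximum exactly at
#' forefoot contact, dips to a mid-stance valley, peaks again exactly at
#' heel off, and returns to zero at toe off. Peaks are ~1.1 x body weight
#' and the valley ~0.75 x, so the 10 N threshold crossings fall within one
#' frame of heel contact and toe off.
#'
#' @param truth Data.frame with per-cycle `t_HC`, `t_FC`, `t_HO`, `t_TO`.
#' @param cfg A `synth_gait_config` (for `body_weight`).
#' @param t Time grid in seconds.
#' @return Data.frame with columns `t` and `Fz` (newtons).
#' @export
synth_grf <- function(truth, cfg, t) {
  peak <- 1.1 * cfg$body_weight
  valley <- 0.75 * cfg$body_weight
  Fz <- numeric(length(t))
  for (i in seq_len(nrow(truth))) {
    e <- truth[i, ]
    stopifnot(e$t_HC < e$t_FC, e$t_FC < e$t_HO, e$t_HO < e$t_TO)
    seg <- t >= e$t_HC & t <= e$t_TO
    ts <- t[seg]
    f <- numeric(length(ts))
    a <- ts < e$t_FC
    f[a] <- peak * sin(pi / 2 * (ts[a] - e$t_HC) / (e$t_FC - e$t_HC))^2
    b <- ts >= e$t_FC & ts <= e$t_HO
    f[b] <- valley + (peak - valley) *
      cos(pi * (ts[b] - e$t_FC) / (e$t_HO - e$t_FC))^2
    cc <- ts > e$t_HO
    f[cc] <- peak * cos(pi / 2 * (ts[cc] - e$t_HO) / (e$t_TO - e$t_HO))^2
    Fz[seg] <- Fz[seg] + f
  }
  data.frame(t = t, Fz = Fz)
}

#' Capture an unloaded baseline frame log
#'
#' Emulates the zero-offset registration protocol: frames scanned with no
#' external load (baseline conductance only) plus count noise.
#'
#' @param layout A `sensor_layout`.
#' @param circuit A `readout_circuit`.
#' @param params Per-unit parameters from [sample_unit_params()].
#' @param duration Capture duration in seconds (default 10).
#' @param noise_sd Count noise sd (default 20; 0 for identical frames).
#' @param seed Seed for the noise.
#' @return A `frame_log`.
#' @export
capture_zero_offset <- function(layout, circuit, params, duration = 10,
                                noise_sd = 20, seed = 1L) {
  stopifnot(duration > 0)
  t <- seq(0, duration - 1 / circuit$fs, by = 1 / circuit$fs)
  v <- circuit$V_i * circuit$R_f * params$g0
  base <- adc_convert(v, circuit)
  counts <- matrix(rep(base, each = length(t)), length(t), n_units(layout))
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    counts <- pmin(pmax(round(counts + stats::rnorm(length(counts), 0, noise_sd)), 0),
                   2^circuit$adc_bits - 1)
  }
  colnames(counts) <- layout$units$id
  frame_log(t, counts, circuit$fs)
}
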