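#' Sensing-unit response parameters
#'
#' The force-sensitive film is modelled as a conductance that grows linearly
#' with the applied normal force, `G(F) = g0 + gain * F`, so the
#' zero-potential readout voltage `V_i * R_f * G(F)` is exactly affine in
#' force. The nominal gain is chosen so that a ~10 N load (the upper end of
#' per-unit plantar loading during walking) drives the readout near full
#' scale.
#'
#' The delayed post-unloading response is phenomenological. While a unit is
#' loaded, a creep state charges as `ds/dt = (kappa * F - s) / tau_charge`.
#' When the load is released after a *sustained* hold, the output does not
#' drop with the force: it continues from its pre-release level, keeps
#' rising for `creep_rise` seconds, then decays exponentially with
#' `creep_decay`. Releases after *brief* loads (one gait or bench cycle)
#' produce only a small residual bump: the transient amplitude is gated by
#' a squared-exponential function of the load episode duration with scale
#' `creep_latch`, and the stored charge itself recovers quickly
#' (`creep_recover`) between brief cycles, so cyclic output peaks stay
#' stationary.
#'
#' @param g0 Baseline (light-contact) conductance in siemens.
#' @param gain Conductance per newton (S/N).
#' @param creep_kappa Dimensionless creep drive (0 disables the delayed
#'   response entirely).
#' @param creep_tau_charge Charge accumulation time constant in seconds.
#' @param creep_rise Post-release rise duration in seconds (default 1.0).
#' @param creep_decay Post-release decay time constant in seconds.
#' @param creep_gamma Relative amplitude of the post-release rise at full
#'   charge maturity.
#' @param creep_latch Load-duration scale (s) above which a release behaves
#'   as "sustained" (full transient) rather than "brief" (small bump).
#' @param creep_recover Recovery time constant (s) of the stored charge
#'   between brief load cycles.
#' @param noise_sd Additive Gaussian noise sd, in ADC counts, applied after
#'   quantization.
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(g0 = 1e-6, gain = 1e-5,
                          creep_kappa = 1, creep_tau_charge = 20,
                          creep_rise = 1.0, creep_decay = 2.0,
                          creep_gamma = 0.5, creep_latch = 2.0,
                          creep_recover = 0.3, noise_sd = 20) {
  stopifnot(gain > 0, g0 >= 0, creep_kappa >= 0, creep_tau_charge > 0,
            creep_rise >= 0, creep_decay > 0, creep_latch > 0,
            creep_recover > 0, noise_sd >= 0)
  structure(list(g0 = g0, gain = gain, creep_kappa = creep_kappa,
                 creep_tau_charge = creep_tau_charge, creep_rise = creep_rise,
                 creep_decay = creep_decay, creep_gamma = creep_gamma,
                 creep_latch = creep_latch, creep_recover = creep_recover,
                 noise_sd = noise_sd),
            class = "sensor_params")
}

#' Draw per-unit parameter diversity
#'
#' Manufacturing variance makes the response of each sensing unit diverse.
#' Gains and baseline conductances are drawn from log-normal distributions
#' centred on the nominal values with the stated relative spread
#' (sd/mean). The draw is deterministic given `seed`.
#'
#' @param layout A `sensor_layout`.
#' @param nominal Nominal `sensor_params` (defaults from [sensor_params()]).
#' @param spread Relative spread (sd/mean) of the per-unit gains; 0 makes
#'   all units identical.
#' @param seed Integer seed.
#' @return A list of class `unit_params`: `gain` and `g0` vectors (one entry
#'   per active unit, named by unit id) plus the shared `nominal` parameters.
#' @export
sample_unit_params <- function(layout, nominal = sensor_params(),
                               spread = 0.2, seed = 1L) {
  stopifnot(spread >= 0)
  n <- n_units(layout)
  if (spread == 0) {
    gain <- rep(nominal$gain, n)
    g0 <- rep(nominal$g0, n)
  } else {
    sdlog <- sqrt(log(1 + spread^2))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    gain <- stats::rlnorm(n, log(nominal$gain) - sdlog^2 / 2, sdlog)
    g0 <- stats::rlnorm(n, log(nominal$g0) - sdlog^2 / 2, sdlog)
  }
  names(gain) <- names(g0) <- layout$units$id
  structure(list(gain = gain, g0 = g0, nominal = nominal),
            class = "unit_params")
}

# save/restore the global RNG state so seeded draws do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Resistance of a sensing unit under force
#'
#' `R(F) = 1 / (g0 + gain * F)`: conductance linear in force, so the
#' zero-potential readout voltage is affine-increasing in force with slope
#' `V_i * R_f * gain`.
#'
#' @param F Applied normal force in newtons (>= 0), vectorized.
#' @param p A `sensor_params` object, or a list with `g0` and `gain`.
#' @return Resistance in ohms.
#' @examples
#' resistance_from_force(9.9, sensor_params(g0 = 1e-6, gain = 1e-5))  # 10 kOhm
#' @export
resistance_from_force <- function(F, p) {
  if (any(F < 0)) stop("force must be >= 0")
  1 / (p$g0 + p$gain * F)
}

#' Apply the delayed-response (creep) dynamics to a force profile
#'
#' Returns the effective force-equivalent drive `e(t)`. While loaded,
#' `e = F + s` with the creep state `s` charging towards `kappa * F`. At an
#' unloading edge the load-episode duration gates the transient: after a
#' sustained hold the output continues from its pre-release level, rises
#' for `creep_rise` seconds and then decays with `creep_decay`; after a
#' brief cycle only a small residual bump remains and the stored charge
#' recovers with `creep_recover`, so cyclic loading shows no apparent
#' delayed response. With `creep_kappa = 0` the function is the identity.
#'
#' @param F Force samples in newtons on a uniform grid.
#' @param p A `sensor_params`.
#' @param fs Sampling rate in Hz.
#' @param f_thresh Load/unload threshold in newtons (default 0.05, the
#'   bench tester's entry force).
#' @return Numeric vector `e(t)`, same length as `F`.
#' @export
apply_creep_dynamics <- function(F, p, fs, f_thresh = 0.05) {
  stopifnot(fs > 0, all(F >= 0))
  if (p$creep_kappa == 0) return(F)   # creep disabled: identity
  n <- length(F)
  dt <- 1 / fs
  e <- numeric(n)
  s <- 0          # stored creep charge
  base <- 0       # transient base level at the last release
  rise <- 0       # additional rise amplitude of the transient
  u <- Inf        # time since last unloading edge
  t_on <- NA_real_  # start time of the current load episode
  peak_ep <- 0
  loaded_prev <- FALSE
  for (k in seq_len(n)) {
    loaded <- F[k] > f_thresh
    if (loaded) {
      if (!loaded_prev) { t_on <- (k - 1) * dt; peak_ep <- 0; u <- Inf }
      peak_ep <- max(peak_ep, F[k])
      s <- s + dt * (p$creep_kappa * F[k] - s) / p$creep_tau_charge
      e[k] <- F[k] + s
    } else {
      if (loaded_prev && s > 0) {
        L <- (k - 1) * dt - t_on                       # episode duration
        gate <- 1 - exp(-(L / p$creep_latch)^2)        # brief vs sustained
        maturity <- min(1, s / (p$creep_kappa * max(peak_ep, f_thresh)))
        base <- gate * e[k - 1]
        rise <- base * p$creep_gamma * maturity
        u <- 0
      }
      if (is.finite(u)) {
        if (u < p$creep_rise && p$creep_rise > 0) {
          # smooth half-cosine rise peaking at u = creep_rise
          e[k] <- base + rise * sin(pi * u / (2 * p$creep_rise))^2
        } else {
          e[k] <- (base + rise) * exp(-(u - p$creep_rise) / p$creep_decay)
        }
        u <- u + dt
        s <- s * exp(-dt / p$creep_recover)   # stored charge recovers
      } else {
        e[k] <- 0
      }
    }
    loaded_prev <- loaded
  }
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cyclic bench-test force profile
#'
#' Emulates the motorized reciprocating tester: raised-cosine load cycles
#' with period `60/rpm` seconds and the stated peak force. The contact dwell
#' (non-zero force) per cycle follows the bench protocol at its three speed
#' levels (1.25 s at 40 rpm, 1 s at 60 rpm, 0.75 s at 80 rpm) and defaults
#' to half the period at other speeds.
#'
#' @param rpm Reciprocating motions per minute, in the tester's 2-200 range.
#' @param peak_force Peak applied force in newtons (default 9.8).
#' @param duration Total profile duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param dwell_fraction Fraction of each period under load (overrides the
#'   protocol default).
#' @return A data.frame with columns `t` (s) and `F` (N).
#' @examples
#' fp <- cyclic_bench_trace(60, 9.8, duration = 5, fs = 50)
#' max(fp$F)
#' @export
cyclic_bench_trace <- function(rpm, peak_force = 9.8, duration = 10,
                               fs = 50, dwell_fraction = NULL) {
  if (rpm < 2 || rpm > 200) stop("rpm outside the tester's 2-200 range")
  stopifnot(duration > 0, peak_force >= 0)
  period <- 60 / rpm
  if (is.null(dwell_fraction)) {
    proto <- c(`40` = 1.25, `60` = 1.0, `80` = 0.75)
    key <- as.character(rpm)
    dwell_fraction <- if (key %in% names(proto)) proto[[key]] / period else 0.5
  }
  stopifnot(dwell_fraction > 0, dwell_fraction <= 1)
  dwell <- dwell_fraction * period
  t <- seq(0, duration, by = 1 / fs)
  phase <- t %% period
  F <- ifelse(phase < dwell, peak_force * sin(pi * phase / dwell)^2, 0)
  data.frame(t = t, F = F)
}

#' Simulate a bench characterization run for one unit
#'
#' Drives a single sensing unit with a force profile through the creep
#' dynamics, the resistance law and the zero-potential readout, producing
#' the traces a bench test would log.
#'
#' @param fp Data.frame with `t` and `F` columns (uniform grid).
#' @param p A `sensor_params` (per-unit `g0`/`gain` may be supplied via a
#'   list with those fields plus the creep fields).
#' @param circuit A `readout_circuit`.
#' @param seed Seed for the additive count noise (`NULL` for noiseless).
#' @return Data.frame with columns `t`, `F`, `e` (effective drive, N),
#'   `V_out` (V) and `count`.
#' @export
bench_run <- function(fp, p = sensor_params(), circuit = readout_circuit(),
                      seed = NULL) {
  fs <- 1 / stats::median(diff(fp$t))
  e <- apply_creep_dynamics(fp$F, p, fs)
  v <- circuit$V_i * circuit$R_f * (p$g0 + p$gain * e)
  count <- adc_convert(v, circuit)
  if (!is.null(seed) && p$noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    count <- pmin(pmax(round(count + stats::rnorm(length(count), 0, p$noise_sd)), 0),
                  2^circuit$adc_bits - 1)
  }
  data.frame(t = fp$t, F = fp$F, e = e, V_out = v, count = count)
}
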