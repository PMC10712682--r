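test_that("zero-offset registration averages the baseline", {
  lay <- tiny_layout()
  counts <- matrix(100, 10, 8, dimnames = list(NULL, lay$units$id))
  log <- frame_log(seq(0, 0.18, by = 0.02), counts, 50)
  expect_equal(unname(register_zero_offset(log)), rep(100, 8))
  expect_error(register_zero_offset(frame_log(numeric(0),
                                              counts[0, , drop = FALSE], 50)),
               "empty")
  # subtracting the offset from the baseline itself leaves ~0 residual
  resid <- sweep(log$counts, 2, register_zero_offset(log))
  expect_equal(max(abs(resid)), 0)
})

test_that("low-pass filter has unit DC gain, zero phase, and the expected rolloff", {
  fs <- 50
  expect_equal(lowpass_filter(rep(5, 200), fs), rep(5, 200), tolerance = 1e-8)

  # symmetric pulse: argmax unchanged by zero-phase filtering
  x <- c(rep(0, 90), sin(seq(0, pi, length.out = 21))^2, rep(0, 90))
  expect_equal(which.max(lowpass_filter(x, fs)), which.max(x))

  t <- seq(0, 20, by = 1 / fs)
  mid <- t > 5 & t < 15
  amp <- function(f) {
    y <- lowpass_filter(sin(2 * pi * f * t), fs)
    max(abs(y[mid]))
  }
  expect_gt(amp(1), 0.99)    # passband
  expect_lt(amp(20), 0.10)   # stopband
  expect_error(lowpass_filter(rep(0, 100), fs = 10), "twice the cut-off")
})

test_that("sub-area averages equal the per-area unit means", {
  lay <- tiny_layout()
  set.seed(2)
  counts <- matrix(runif(40 * 8, 0, 4000), 40, 8,
                   dimnames = list(NULL, lay$units$id))
  s <- subarea_average(counts, lay)
  for (area in c("heel", "arch", "forefoot", "toe")) {
    sel <- lay$units$subarea == area
    expect_equal(s[[paste0("P_", area)]],
                 rowMeans(counts[, sel, drop = FALSE]))
  }
  counts2 <- matrix(c(100, 200), 1, 2)
  lay2 <- build_layout(1, 2, matrix(TRUE, 1, 2),
                       matrix(c("heel", "heel"), 1, 2))
  expect_error(subarea_average(counts2, lay2), "empty sub-area")
})

test_that("cycle segmentation finds one window per stance", {
  tr <- quick_trial(n_cycles = 5, noise_sd = 20, seed = 3)
  det <- detect_gait(tr$frames, tr$layout, baseline_s = tr$baseline_s)
  expect_equal(nrow(det$windows), 5)
  expect_true(all(det$windows$start < det$windows$end))

  flat <- data.frame(t = seq(0, 1, by = 0.02),
                     P_heel = 0, P_arch = 0, P_forefoot = 0, P_toe = 0)
  expect_error(segment_cycles(flat, 50), "no activity")

  burst <- flat
  burst$P_heel <- c(rep(0, 15), sin(seq(0, pi, length.out = 11))^2 * 100,
                    rep(0, 25))
  expect_equal(nrow(segment_cycles(burst, 50)), 1)
})

test_that("event search follows the hand-traced extremum logic", {
  # heel rises to its first peak at frame 3 (0-based), HC at the preceding
  # minimum, frame 0
  heel <- c(0, 1, 3, 5, 3, 1, 0.5, 1, 0.5, 0)
  s <- data.frame(t = seq(0, by = 0.02, length.out = 10),
                  P_heel = heel, P_arch = 0, P_forefoot = 0, P_toe = 0)
  w <- data.frame(start = 1L, end = 10L)
  ev <- detect_events(s, w, fs = 50)
  expect_equal(ev$i_HC, 1L)        # frame 0 -> t = 0
  expect_equal(ev$t_HC, 0)
  expect_match(ev$status, "FC")    # flat forefoot: not silently wrong

  flat <- s; flat$P_heel <- 1
  ev2 <- detect_events(flat, w, fs = 50)
  expect_true(is.na(ev2$t_HC))
  expect_match(ev2$status, "HC")
})

test_that("noiseless trials are recovered to within one frame at all cadences", {
  for (cad in c(40, 60, 80)) {
    tr <- quick_trial(cadence = cad, n_cycles = 3)
    det <- detect_gait(tr$frames, tr$layout, baseline_s = tr$baseline_s)
    expect_true(all(det$events$status == "ok"))
    expect_lte(max_event_error_frames(det$events, tr$truth), 1 + 1e-6)
  }
})

test_that("detection works from heel-off creep cues and without them", {
  # the delayed response makes the heel output rise again after heel off;
  # the first-minimum rule must locate HO with the creep transient present
  # (default) and with creep disabled (flat floor after the descent)
  tr <- quick_trial(n_cycles = 2)
  lay <- tr$layout
  circ <- readout_circuit()
  cfg <- synth_gait_config(cadence = 60, n_cycles = 2, noise_sd = 0,
                           timing_jitter_sd = 0, baseline_s = 2, seed = 7)
  par_nc <- sample_unit_params(lay, nominal = sensor_params(creep_kappa = 0),
                               spread = 0, seed = 7)
  tr_nc <- synth_gait_trial(cfg, lay, circ, par_nc)
  for (trial in list(tr, tr_nc)) {
    det <- detect_gait(trial$frames, lay, baseline_s = trial$baseline_s)
    expect_true(all(det$events$status == "ok"))
    expect_lte(max_event_error_frames(det$events, trial$truth), 1 + 1e-6)
  }
})

test_that("phase durations telescope exactly and reject disorder", {
  e <- list(t_HC = 0.10, t_FC = 0.22, t_HO = 0.58, t_TO = 0.82)
  d <- phase_durations(e)
  expect_equal(unlist(d), c(T_IC = 0.12, T_FF = 0.36, T_PO = 0.24))
  expect_equal(d$T_IC + d$T_FF + d$T_PO, e$t_TO - e$t_HC)
  expect_error(phase_durations(list(t_HC = 0.5, t_FC = 0.2, t_HO = 0.6,
                                    t_TO = 0.8)),
               "ordered")

  # property sweep: all durations positive on detected synthetic cycles
  tr <- quick_trial(n_cycles = 4, noise_sd = 20, jitter = 0.01, seed = 21)
  det <- detect_gait(tr$frames, tr$layout, baseline_s = tr$baseline_s)
  ok <- det$events[det$events$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$T_IC > 0 & ok$T_FF > 0 & ok$T_PO > 0))
  expect_equal(ok$T_IC + ok$T_FF + ok$T_PO, ok$t_TO - ok$t_HC)
})

test_that("the pipeline is deterministic for identical input logs", {
  tr <- quick_trial(n_cycles = 3, noise_sd = 20, seed = 31)
  d1 <- detect_gait(tr$frames, tr$layout, baseline_s = tr$baseline_s)
  d2 <- detect_gait(tr$frames, tr$layout, baseline_s = tr$baseline_s)
  expect_identical(d1$events, d2$events)
})
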