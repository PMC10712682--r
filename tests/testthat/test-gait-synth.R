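test_that("config validation enforces event ordering", {
  expect_error(synth_gait_config(event_fractions = c(FC = 0.5, HO = 0.4, TO = 0.62)),
               "FC < HO < TO")
  expect_s3_class(synth_gait_config(), "synth_gait_config")
})

test_that("trials realize the configured cadence and exact ground truth", {
  tr <- quick_trial(cadence = 60, n_cycles = 2)
  T <- diff(tr$truth$t_HC)
  expect_equal(T, 1.0, tolerance = 1e-9)
  # defaults: FC/HO/TO at 8/40/62% of the cycle (snapped to the 50 Hz grid)
  expect_equal(tr$truth$t_FC - tr$truth$t_HC, rep(0.08, 2))
  expect_equal(tr$truth$t_HO - tr$truth$t_HC, rep(0.40, 2))
  expect_equal(tr$truth$t_TO - tr$truth$t_HC, rep(0.62, 2))

  tr40 <- quick_trial(cadence = 40, n_cycles = 2)
  expect_equal(diff(tr40$truth$t_HC), 1.5, tolerance = 1e-9)
})

test_that("trials are deterministic given the seed", {
  a <- quick_trial(noise_sd = 20, jitter = 0.01, seed = 12)
  b <- quick_trial(noise_sd = 20, jitter = 0.01, seed = 12)
  expect_identical(a$frames$counts, b$frames$counts)
  expect_identical(a$truth, b$truth)
  c <- quick_trial(noise_sd = 20, jitter = 0.01, seed = 13)
  expect_false(identical(a$frames$counts, c$frames$counts))
})

test_that("sub-area loading follows the stance sequence in noiseless trials", {
  tr <- quick_trial(n_cycles = 3)
  lay <- tr$layout
  s <- subarea_average(sweep(tr$frames$counts, 2,
                             colMeans(tr$frames$counts[1:50, ])),
                       lay, t = tr$frames$t)
  for (i in seq_len(3)) {
    e <- tr$truth[i, ]
    win <- s$t >= e$t_HC - 0.1 & s$t <= e$t_TO + 0.1
    t_win <- s$t[win]
    expect_lt(t_win[which.max(s$P_heel[win])], t_win[which.max(s$P_forefoot[win])])
    expect_lt(t_win[which.max(s$P_forefoot[win])], t_win[which.max(s$P_toe[win])])
  }
})

test_that("synthetic vGRF satisfies the reference-event construction", {
  tr <- quick_trial(n_cycles = 3)
  grf <- tr$grf
  fs <- 50
  expect_true(all(grf$Fz >= 0))
  expect_equal(max(grf$Fz), 1.1 * tr$config$body_weight, tolerance = 1e-6)
  for (i in seq_len(3)) {
    e <- tr$truth[i, ]
    # swing is unloaded
    expect_true(all(grf$Fz[grf$t < e$t_HC - 1 / fs & grf$t > e$t_HC - 0.3] == 0))
    expect_true(all(grf$Fz[grf$t > e$t_TO + 1 / fs & grf$t < e$t_TO + 0.3] == 0))
    # 10 N crossings within one frame of HC / TO
    up <- grf$t[which(grf$Fz > 10 & grf$t >= e$t_HC - 0.1)[1]]
    expect_lte(abs(up - e$t_HC), 1 / fs + 1e-9)
    loaded <- which(grf$Fz > 10 & grf$t >= e$t_HC & grf$t <= e$t_TO + 0.1)
    down <- grf$t[loaded[length(loaded)] + 1]
    expect_lte(abs(down - e$t_TO), 1 / fs + 1e-9)
    # humps peak at FC and HO
    seg <- grf[grf$t >= e$t_HC & grf$t <= e$t_HO - 0.05, ]
    expect_lte(abs(seg$t[which.max(seg$Fz)] - e$t_FC), 1 / fs + 1e-9)
    seg2 <- grf[grf$t >= e$t_FC + 0.05 & grf$t <= e$t_TO, ]
    expect_lte(abs(seg2$t[which.max(seg2$Fz)] - e$t_HO), 1 / fs + 1e-9)
  }
})

test_that("zero-offset capture reflects baseline conductance plus noise", {
  lay <- tiny_layout()
  circ <- readout_circuit()
  par <- sample_unit_params(lay, spread = 0, seed = 1)
  quiet <- capture_zero_offset(lay, circ, par, duration = 2, noise_sd = 0)
  expect_equal(length(quiet$t), 100)  # 2 s at 50 Hz
  expect_true(all(apply(quiet$counts, 2, function(x) all(x == x[1]))))
  expect_equal(unname(quiet$counts[1, ]),
               rep(adc_convert(circ$V_i * circ$R_f * par$g0[1], circ), 8))

  noisy <- capture_zero_offset(lay, circ, par, duration = 10, noise_sd = 20,
                               seed = 2)
  base <- adc_convert(circ$V_i * circ$R_f * par$g0[1], circ)
  se <- 20 / sqrt(500)
  expect_true(all(abs(colMeans(noisy$counts) - base) < 4 * se))
})

test_that("turning mode keeps truth ordering and shifts forefoot load medially", {
  tr_s <- quick_trial(mode = "straight", n_cycles = 2, seed = 4)
  tr_t <- quick_trial(mode = "turning", n_cycles = 2, seed = 4)
  with(tr_t$truth, expect_true(all(t_HC < t_FC & t_FC < t_HO & t_HO < t_TO)))
  # stance lengthened by the configured stretch
  expect_gt(mean(tr_t$truth$t_TO - tr_t$truth$t_HC),
            mean(tr_s$truth$t_TO - tr_s$truth$t_HC))
  # medial (low-column) forefoot units carry more load than lateral ones
  lay <- tr_t$layout
  ff <- lay$units$subarea == "forefoot"
  tot <- colSums(tr_t$frames$counts[, ff])
  cols <- lay$units$col[ff]
  expect_gt(mean(tot[cols < 4]), mean(tot[cols >= 4]))
})
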