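circ <- readout_circuit()

test_that("zero-potential readout matches the voltage-divider identity", {
  lay <- quad_layout()
  f <- resistance_field(lay, rep(10000, 4))
  expect_equal(simulate_zero_potential_vout(f, circ, c(0, 0)), 3.3)
  f2 <- resistance_field(lay, c(20000, 10000, 10000, 10000))
  expect_equal(simulate_zero_potential_vout(f2, circ, c(0, 0)), 1.65)
  expect_error(simulate_zero_potential_vout(f2, circ, c(5, 0)), "not an active")
})

test_that("zero-potential scan agrees with the full nodal oracle and isolates units", {
  lay <- default_insole_layout()
  set.seed(42)
  R <- runif(n_units(lay), 1e3, 1e5)
  f <- resistance_field(lay, R)
  idx <- seq(1, n_units(lay), by = 7)   # spot-check a spread of units
  for (u in idx) {
    unit <- c(lay$units$row[u], lay$units$col[u])
    v <- simulate_zero_potential_vout(f, circ, unit)
    expect_equal(v, oracle_zero_potential(f, circ, unit), tolerance = 1e-12)
    expect_equal(v, circ$V_i * circ$R_f / R[u], tolerance = 1e-12)
  }
  # perturbing any non-selected unit leaves the reading unchanged
  R2 <- R; R2[50] <- R2[50] * 10
  f2 <- resistance_field(lay, R2)
  unit1 <- c(lay$units$row[1], lay$units$col[1])
  expect_equal(simulate_zero_potential_vout(f2, circ, unit1),
               simulate_zero_potential_vout(f, circ, unit1),
               tolerance = 1e-12)
})

test_that("invert_readout implements R = (V_i / V_out) * R_f", {
  expect_equal(invert_readout(3.3, circ), 10000)
  expect_equal(invert_readout(1.65, circ), 20000)
  expect_error(invert_readout(0, circ), "open")
  # composition recovers the field
  lay <- tiny_layout()
  R <- c(5e3, 1e4, 2e4, 4e4, 8e4, 1.6e5, 3.2e5, 6.4e5)
  f <- resistance_field(lay, R)
  rec <- sapply(seq_len(8), function(u) {
    invert_readout(simulate_zero_potential_vout(
      f, circ, c(lay$units$row[u], lay$units$col[u])), circ)
  })
  expect_equal(rec, R, tolerance = 1e-12)
})

test_that("naive scan reproduces hand-derived sneak-path cases", {
  # lone unit: plain voltage divider, no parasitic loop
  lay1 <- build_layout(2, 2, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
                       matrix(c("heel", NA, NA, NA), 2, 2))
  f1 <- resistance_field(lay1, 20000)
  v1 <- simulate_naive_vout(f1, circ, c(0, 0))
  expect_equal(v1, circ$V_i * circ$R_f / (20000 + circ$R_f))
  expect_equal(apparent_resistance(v1, circ), 20000, tolerance = 1e-12)

  # 2x2 uniform 10 kOhm: sneak path R12+R22+R21 = 30 kOhm in parallel
  f4 <- resistance_field(quad_layout(), rep(10000, 4))
  v4 <- simulate_naive_vout(f4, circ, c(0, 0))
  expect_equal(apparent_resistance(v4, circ), 7500, tolerance = 1e-9)
})

test_that("naive apparent resistance never exceeds the true resistance", {
  lay <- quad_layout()
  set.seed(11)
  for (i in 1:25) {
    R <- runif(4, 1e3, 1e5)
    f <- resistance_field(lay, R)
    for (u in 1:4) {
      unit <- c(lay$units$row[u], lay$units$col[u])
      ra <- apparent_resistance(simulate_naive_vout(f, circ, unit), circ)
      expect_lte(ra, R[u] * (1 + 1e-12))
      expect_lt(ra, R[u])  # a closed sneak loop always exists here
    }
  }
})

test_that("ADC conversion rounds half up, saturates, and is monotone", {
  expect_equal(adc_convert(3.3, circ), 4095L)
  expect_equal(adc_convert(0, circ), 0L)
  expect_equal(adc_convert(1.65, circ), 2048L)  # 2047.5 rounds up
  expect_equal(adc_convert(5, circ), 4095L)     # saturation above vref
  v <- seq(-0.5, 4, by = 0.01)
  counts <- adc_convert(v, circ)
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts >= 0 & counts <= 4095))
})

test_that("scan_frame composes readout and quantization per unit", {
  lay <- tiny_layout()
  f_unif <- resistance_field(lay, rep(circ$R_f, 8))
  fr <- scan_frame(f_unif, circ, lay, t = 0.5)
  expect_true(all(fr$counts == 4095L))
  expect_equal(fr$t, 0.5)

  f_open <- resistance_field(lay, rep(1e9, 8))
  expect_true(all(scan_frame(f_open, circ, lay)$counts == 0L))

  set.seed(3)
  R <- runif(8, 5e3, 5e5)
  f_mix <- resistance_field(lay, R)
  fr_mix <- scan_frame(f_mix, circ, lay)
  manual <- sapply(seq_len(8), function(u) {
    adc_convert(simulate_zero_potential_vout(
      f_mix, circ, c(lay$units$row[u], lay$units$col[u])), circ)
  })
  expect_equal(unname(fr_mix$counts), manual)
})

test_that("readout inversion survives quantization to within one LSB", {
  lay <- tiny_layout()
  set.seed(8)
  R <- runif(8, 1.2e4, 2e5)   # keeps V_out inside the ADC range
  f <- resistance_field(lay, R)
  lsb <- circ$adc_vref / (2^circ$adc_bits - 1)
  for (u in seq_len(8)) {
    v <- simulate_zero_potential_vout(f, circ, c(lay$units$row[u], lay$units$col[u]))
    vq <- adc_convert(v, circ) * lsb
    expect_lt(abs(vq - v), lsb)
    expect_lt(abs(invert_readout(vq, circ) - R[u]),
              abs(invert_readout(v - lsb, circ) - R[u]) + 1e-9)
  }
})
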