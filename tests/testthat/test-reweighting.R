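.mk_table <- function(...) {
  tb <- data.frame(...)
  class(tb) <- c("colvar_table", "data.frame")
  tb
}

test_that("frame weights implement the discard rule and the bias exponential", {
  tb <- .mk_table(time = 1:10, cv_x = 1:10, opes_main = rep(0, 10))
  w <- frame_weights(tb, discard_fraction = 0)
  expect_equal(w, rep(0.1, 10))
  w2 <- frame_weights(tb, discard_fraction = 0.1)
  expect_equal(w2[1], 0)
  expect_true(all(w2[-1] > 0))
  expect_equal(sum(w2), 1)
  # V = (0, kBT ln 2) -> weights 1/3, 2/3
  tb2 <- .mk_table(time = 1:2, cv_x = c(0, 1),
                   opes_main = c(0, kB * 300 * log(2)))
  expect_equal(frame_weights(tb2, discard_fraction = 0,
                             temperature = 300), c(1, 2) / 3)
  expect_error(frame_weights(tb[, 1:2]), "opes_main")
  expect_error(frame_weights(tb, discard_fraction = 1), "discard_fraction")
})

test_that("weighted FES has exact bin identities and matches the oracle", {
  # two equally populated bins -> deltaF = 0
  tb <- .mk_table(time = 1:100, cv_x = rep(c(0.25, 0.75), 50))
  w <- rep(1 / 100, 100)
  f <- weighted_fes(tb, w, bins = c(0, 0.5, 1), temperature = 300)
  expect_equal(f$F[1], f$F[2])
  # counts 100 vs 50 -> kBT ln 2 = 1.729 kJ/mol
  tb2 <- .mk_table(time = 1:150, cv_x = c(rep(0.25, 100), rep(0.75, 50)))
  f2 <- weighted_fes(tb2, rep(1 / 150, 150), bins = c(0, 0.5, 1),
                     temperature = 300)
  expect_equal(f2$F[2] - f2$F[1], 1.7289, tolerance = 1e-4)
  expect_equal(min(f2$F, na.rm = TRUE), 0)
  # empty bins are NA, not zero
  f3 <- weighted_fes(tb2, rep(1 / 150, 150), bins = c(0, 0.5, 1, 1.5),
                     temperature = 300)
  expect_true(is.na(f3$F[3]))
  expect_error(weighted_fes(tb2, rep(1 / 150, 150), bins = c(0, 1, 2)),
               "fewer than 2")
  # unbiased harmonic samples reproduce the quadrature FES within noise
  h2 <- make_system("harmonic_2d", k = 2.494)
  run <- run_unbiased(h2, n_steps = 1e6, seed = 17, record_stride = 10)
  tb4 <- run$tables[[1]]
  w4 <- rep(1 / nrow(tb4), nrow(tb4))
  f4 <- weighted_fes(tb4, w4, bins = seq(-2, 2, 0.25), temperature = 300)
  theory <- 0.5 * 2.494 * f4$cv^2
  ok <- !is.na(f4$F) & abs(f4$cv) < 1.6
  expect_lt(max(abs((f4$F - min(f4$F[ok]))[ok] -
                      (theory[ok] - min(theory[ok])))), 0.5)
})

test_that("basin delta-F has exact ratio identities and block errors", {
  tb <- .mk_table(time = 1:100, cv_x = rep(c(-1, 1), 50))
  w <- rep(1 / 100, 100)
  est <- delta_f(tb, w, c(-2, 0), c(0, 2), temperature = 300)
  expect_equal(est$value, 0)
  # sum_A w = 2 sum_B w -> -kBT ln 2 (pattern interleaved so every block
  # sees both basins)
  tb2 <- .mk_table(time = 1:150, cv_x = rep(c(-1, -1, 1), 50))
  w2 <- rep(1 / 150, 150)
  est2 <- delta_f(tb2, w2, c(-2, 0), c(0, 2), temperature = 300)
  expect_equal(est2$value, -kB * 300 * log(2))
  expect_equal(est2$value, -1.7289, tolerance = 1e-4)
  expect_equal(est2$stderr, 0)
  # scaling all weights leaves the ratio unchanged
  est3 <- delta_f(tb2, w2 * 7, c(-2, 0), c(0, 2), temperature = 300)
  expect_equal(est3$value, est2$value)
  expect_error(delta_f(tb2, w2, c(-2, 0), c(5, 6), temperature = 300),
               "basin B")
  expect_error(delta_f(tb2, w2, c(-2, 1), c(0, 2), temperature = 300),
               "overlap")
})

test_that("block standard errors reduce to the textbook SEM", {
  expect_equal(block_stderr(c(1, 2, 3), n_blocks = 3), sd(1:3) / sqrt(3))
  expect_equal(block_stderr(c(1, 2, 3), n_blocks = 3), 0.5774, tolerance = 1e-4)
  expect_equal(block_stderr(rep(4, 30), n_blocks = 10), 0)
  # permutation of whole blocks leaves the SEM unchanged
  v <- rep(c(1, 2, 3), each = 5)
  expect_equal(block_stderr(v, n_blocks = 3),
               block_stderr(rep(c(3, 1, 2), each = 5), n_blocks = 3))
  expect_error(block_stderr(1:5, n_blocks = 10), "fewer frames")
  expect_error(block_stderr(1:5, n_blocks = 1), "n_blocks")
})

test_that("delta-F from FES bins matches delta-F from raw weights", {
  run <- hb_batch()[[1]]
  tb <- run$tables[[1]]
  w <- frame_weights(tb)
  b <- hb_basins()
  raw <- delta_f(tb, w, b$a, b$b)$value
  f <- weighted_fes(tb, w, bins = seq(-2, 2, 0.05))
  kbt <- kB * 300
  inA <- f$cv >= b$a[1] & f$cv < b$a[2] & !is.na(f$F)
  inB <- f$cv >= b$b[1] & f$cv < b$b[2] & !is.na(f$F)
  binned <- -kbt * log(sum(exp(-f$F[inA] / kbt)) / sum(exp(-f$F[inB] / kbt)))
  expect_equal(binned, raw, tolerance = 0.02)
})

test_that("Van't Hoff fits recover exact lines and the printed identity", {
  Ts <- c(300, 320, 340, 360)
  ft <- vant_hoff_fit(Ts, 10 - 0.05 * Ts)
  expect_equal(ft$deltaH, 10)
  expect_equal(ft$deltaS, 0.05)
  expect_equal(ft$T_melt, 200)
  expect_equal(ft$residuals, rep(0, 4), tolerance = 1e-10)
  # folding-type estimates: dH = -32.2 kJ/mol with -T dS = 27.0 at 340 K
  dS <- -27.0 / 340
  ft2 <- vant_hoff_fit(Ts, -32.2 - Ts * dS, T_ref = 340)
  expect_equal(ft2$T_melt, -32.2 / dS)
  expect_equal(ft2$T_melt, 405.5, tolerance = 1e-3)
  expect_equal(ft2$minusTdS_at_ref, 27.0, tolerance = 1e-10)
  # reordering points leaves the fit unchanged
  o <- c(3, 1, 4, 2)
  ft3 <- vant_hoff_fit(Ts[o], (10 - 0.05 * Ts)[o])
  expect_equal(ft3$deltaH, ft$deltaH)
  expect_equal(ft3$deltaS, ft$deltaS)
  # degenerate slope flags an undefined melting temperature
  ft4 <- vant_hoff_fit(Ts, rep(5, 4))
  expect_true(is.na(ft4$T_melt))
  expect_true(ft4$degenerate_slope)
  expect_error(vant_hoff_fit(c(300, 300), c(1, 2)), "singular")
})

test_that("deltaF(T) from a multithermal replica tracks the per-T oracle", {
  run <- hb_batch()[[2]]
  tb <- run$tables[[7]]  # replica 6 carries MultiThermal with T_max 500 K
  attr(tb, "T_range") <- c(300, 500)
  b <- hb_basins()
  Ts <- c(320, 360, 400, 440, 480)
  dft <- deltaF_vs_temperature(tb, b$a, b$b, Ts)
  for (k in seq_along(Ts)) {
    oracle <- quadrature_delta_f(hb_system(), "x", b$a, b$b, T = Ts[k])
    expect_lt(abs(dft$deltaF[k] - oracle), 3 * dft$stderr[k])
  }
  # weights at every target temperature sum to one
  for (Tp in Ts)
    expect_equal(sum(reweight_to_temperature(tb, Tp, T0 = 300)), 1)
  # a degenerate single-T grid reduces to the plain estimator
  run1 <- run_multithermal(make_system("harmonic_2d", k = 2.494),
                           t_max = 300, n_T = 1, n_steps = 5e4, seed = 2)
  tb1 <- run1$tables[[1]]
  w1 <- reweight_to_temperature(tb1, 300, T0 = 300)
  w2 <- frame_weights(tb1, mode = "total")
  expect_equal(w1, w2)
})

test_that("convergence reports shrink onto the oracle across seeds", {
  runs <- hb_batch()
  b <- hb_basins()
  rep2 <- convergence_report(runs[1:2], b$a, b$b,
                             checkpoints = c(2000, 4000))
  expect_true(all(rep2$sd >= 0))
  # identical runs give zero spread
  same <- convergence_report(list(runs[[1]], runs[[1]]), b$a, b$b,
                             checkpoints = 4000)
  expect_equal(same$sd, 0)
  # final-time mean over the 5-seed batch lands within 0.5 kBT of the oracle
  rep5 <- convergence_report(runs, b$a, b$b, checkpoints = 4000)
  expect_lt(abs(rep5$mean - hb_oracle()), 0.5 * kB * 300)
})
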