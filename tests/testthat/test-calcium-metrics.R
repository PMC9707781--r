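test_that("the d-prime metric recovers injected sinusoids with the right sign", {
  tr <- synth_flicker_trace(5, noise_sigma = 0, drift = 0, seed = 1)
  m <- fourier_response(tr, 0.15)
  expect_gt(m$snr, 20)
  expect_equal(m$response_sign, "ON")
  troff <- synth_flicker_trace(5, phase_rad = pi, noise_sigma = 0.3, seed = 2)
  moff <- fourier_response(troff, 0.15)
  expect_lt(moff$snr, -2)
  expect_equal(moff$response_sign, "OFF")
})

test_that("the d-prime formula matches an independent windowed-spectrum oracle", {
  tr <- synth_flicker_trace(3, noise_sigma = 1, drift = 0.05, seed = 7)
  m <- fourier_response(tr, 0.15)
  # independent transcription: Hann window, DFT by explicit sum at a few bins
  x <- tr$value - mean(tr$value)
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  dt <- tr$time_s[2] - tr$time_s[1]
  amp_at <- function(f_hz) {
    k <- round(f_hz * n * dt)
    Mod(sum(x * w * exp(-2i * pi * k * (seq_len(n) - 1) / n)))
  }
  freqs <- (0:(n - 1)) / (n * dt)
  band <- freqs[freqs >= 0.32 & freqs <= 1.08 & freqs <= 1 / (2 * dt)]
  amps <- vapply(band, amp_at, numeric(1))
  k_sig <- freqs[which.min(abs(freqs - 0.15))]
  snr_direct <- (amp_at(k_sig) - mean(amps)) / stats::sd(amps)
  expect_equal(abs(m$snr), abs(snr_direct), tolerance = 1e-6)
})

test_that("trace preconditions for the d-prime metric are enforced", {
  short <- tibble::tibble(time_s = seq(0, 5, by = 0.1),
                          value = rnorm(51))
  expect_error(fourier_response(short, 0.15), "2 stimulus cycles")
  tr <- synth_flicker_trace(1, seed = 1)
  expect_error(fourier_response(tr, 0.5), "below the noise band")
})

test_that("pure-noise traces give a calibrated, roughly zero-mean metric", {
  snrs <- vapply(1:300, function(s) {
    fourier_response(synth_flicker_trace(0, noise_sigma = 1, seed = 1000 + s),
                     0.15)$snr
  }, numeric(1))
  expect_gt(mean(snrs), -0.2)
  expect_lt(mean(snrs), 0.2)
  expect_lt(mean(abs(snrs) >= 2), 0.12)
})

test_that("the metric increases monotonically with response amplitude", {
  ladder <- c(0.5, 1, 2, 4)
  means <- vapply(ladder, function(a) {
    mean(vapply(1:30, function(s) {
      abs(fourier_response(
        synth_flicker_trace(a, noise_sigma = 1, seed = 2000 + s), 0.15)$snr)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("delta-F/F and its propagated error follow the stated formulas", {
  out <- delta_f_over_f(100, 150, 200)
  expect_equal(out$dff, 0.25)
  expect_equal(delta_f_over_f(100, 100, 200)$dff, 0)
  out2 <- delta_f_over_f(100, 150, 200, var_background = 100,
                         var_signal = 100, var_reference = 0)
  expect_equal(out2$dff_sem, sqrt(200 / 40000))
  expect_equal(round(out2$dff_sem, 4), 0.0707)
  expect_error(delta_f_over_f(1, 2, 0), "positive")
})

test_that("the propagated sem matches Monte-Carlo propagation", {
  set.seed(10)
  B <- 100; S <- 150; S17 <- 200
  vB <- 16; vS <- 25; vS17 <- 36
  draws <- (rnorm(1e5, S, sqrt(vS)) - rnorm(1e5, B, sqrt(vB))) /
    rnorm(1e5, S17, sqrt(vS17))
  sem <- delta_f_over_f(B, S, S17, vB, vS, vS17)$dff_sem
  expect_equal(sem, stats::sd(draws), tolerance = 0.02)
})

test_that("cone weights are modulation-normalized with unit absolute sum", {
  w <- cone_weight_vector(c(8, -6, 0), c(0.24, 0.33, 0.92))
  raw <- c(8 / 0.24, -6 / 0.33, 0)
  expect_equal(unlist(w), raw / sum(abs(raw)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(round(w$wL, 3), 0.647)
  expect_equal(round(w$wM, 3), -0.353)
  expect_equal(abs(w$wL) + abs(w$wM) + abs(w$wS), 1)
  w2 <- cone_weight_vector(c(0, 4, 0), c(0.24, 0.33, 0.92))
  expect_equal(unlist(w2), c(wL = 0, wM = 1, wS = 0))
  expect_error(cone_weight_vector(c(0, 0, 0), c(1, 1, 1)), "undefined")
  expect_error(cone_weight_vector(c(1, 1, 1), c(0.2, 0, 0.9)), "positive")
})

test_that("the classification rule set covers the functional groups", {
  expect_equal(classify_cell(c(L = 5, M = -5, S = 0.5))$group, "L-M opponent")
  expect_equal(classify_cell(c(L = -4, M = 6, S = 0))$group, "M-L opponent")
  expect_equal(classify_cell(c(L = 1, M = -1.5, S = 0.5))$group,
               "unresponsive")
  expect_equal(classify_cell(c(L = 0.2, M = 0.1, S = 4))$group, "S-ON")
  expect_equal(classify_cell(c(L = 0.2, M = 0.1, S = -4))$group, "S-OFF")
  expect_equal(classify_cell(c(L = 5, M = -5, S = 3))$group, "mixed L-M S")
  expect_equal(classify_cell(c(LM = 4, S = 0.3, lum = 1))$group,
               "L-M opponent")
  expect_equal(classify_cell(c(LM = -4, S = 0.3))$group, "M-L opponent")
  expect_equal(classify_cell(c(LM = 0.5, S = 0.3, lum = 6))$group,
               "luminance-ON")
  expect_equal(classify_cell(c(LM = 0.5, S = 0.3, lum = -6))$group,
               "luminance-OFF")
  # same-sign L and M responses pattern with luminance cells
  expect_equal(classify_cell(c(L = 4, M = 5, S = 0, lum = 6))$group,
               "luminance-ON")
  expect_error(classify_cell(c(foo = 3)), "recognized")
})

test_that("classify_cells maps a metrics table to groups per cell", {
  metrics <- tibble::tibble(
    cell_id = rep(c("a", "b"), each = 3),
    stimulus = rep(c("L", "M", "S"), 2),
    snr = c(5, -4, 0.3, 1, 0.5, 4.4))
  out <- classify_cells(metrics)
  expect_equal(out$group[out$cell_id == "a"], "L-M opponent")
  expect_equal(out$group[out$cell_id == "b"], "S-ON")
})

test_that("epoch means use the first-10-s background and last-10-s signal", {
  tr <- tibble::tibble(time_s = seq(0, 60, by = 0.25),
                       value = c(rep(10, 60), rep(30, 181)))
  em <- epoch_means(tr, stim_onset_s = 15, stim_end_s = 60)
  expect_equal(em$background_mean, 10)
  expect_equal(em$signal_mean, 30)
})
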