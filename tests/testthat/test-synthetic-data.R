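test_that("flicker traces are seed-deterministic and metric-consistent", {
  t1 <- synth_flicker_trace(3, seed = 4)
  t2 <- synth_flicker_trace(3, seed = 4)
  expect_identical(t1, t2)
  clean <- synth_flicker_trace(2.5, noise_sigma = 0, drift = 0, seed = 1)
  fit <- fit_sinusoid(clean$time_s, clean$value, 0.15)
  expect_equal(fit$amplitude, 2.5, tolerance = 1e-3)
  expect_error(synth_flicker_trace(1, stim_freq_hz = 10, rate_hz = 16),
               "twice")
})

test_that("null traces rarely exceed the significance cutoff", {
  hits <- vapply(1:100, function(s) {
    abs(fourier_response(synth_flicker_trace(0, noise_sigma = 1,
                                             seed = 3000 + s), 0.15)$snr) >= 2
  }, logical(1))
  expect_gte(mean(!hits), 0.90)
})

test_that("synthetic STF datasets reduce to the model STF at zero noise", {
  ctx <- test_context()
  truth <- test_truth_single()
  ds <- synth_stf_dataset(truth, ctx, sessions = 3, noise_frac = 0, seed = 1)
  expect_equal(ds$averaged$dff, ds$truth_stf$amplitude, tolerance = 1e-12)
  expect_equal(max(abs(ds$averaged$sem)), 0)
  # round trip: fitting a zero-noise dataset recovers the truth
  fit <- fit_stf(ds$averaged, ctx, "single-cone",
                 candidate_positions = matrix(truth$center_deg, 1),
                 n_starts = 32, seed = 6)
  expect_lt(abs(fit$kc - truth$kc) / truth$kc, 0.10)
  expect_lt(abs(fit$ks - truth$ks) / truth$ks, 0.10)
  expect_lt(abs(fit$rs_deg - truth$rs_deg) / truth$rs_deg, 0.05)
})

test_that("offset corruption produces negative minima that correction removes", {
  ctx <- test_context()
  truth <- test_truth_single()
  ds <- synth_stf_dataset(truth, ctx, sessions = 2, noise_frac = 0.02,
                          offset = 0.5, seed = 2)
  expect_lt(min(ds$averaged$dff), 0)
  corrected <- offset_correct(ds$averaged)
  expect_equal(min(corrected$dff), 0)
  expect_true(attr(corrected, "offset_applied"))
})

test_that("the achromatic-midget simulation matches its binomial oracle", {
  sim <- achromatic_midget_sim(n_repeats = 500, seed = 3)
  ana <- achromatic_analytic()
  expect_lt(abs(sim$true_fraction - ana$true_fraction), 4 * sim$se_true)
  expect_lt(abs(sim$thresholded_fraction - ana$thresholded_fraction),
            4 * sim$se_thresholded)
  expect_true(all(sim$per_repeat$thresholded_fraction >=
                    sim$per_repeat$true_fraction))
  expect_true(all(sim$per_repeat$true_fraction >= 0 &
                    sim$per_repeat$thresholded_fraction <= 1))
})

test_that("a one-class mosaic is always achromatic", {
  sim <- achromatic_midget_sim(n_cones = 400, fractions = c(1, 0, 0),
                               n_repeats = 5, seed = 1)
  expect_equal(sim$true_fraction, 1)
  expect_equal(sim$thresholded_fraction, 1)
  ana <- achromatic_analytic(c(1, 0, 0))
  expect_equal(ana$true_fraction, 1)
  expect_error(achromatic_midget_sim(fractions = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("the analytic achromatic fractions evaluate the closed forms", {
  ana <- achromatic_analytic(c(0.5, 0.5, 0))
  expect_equal(ana$true_fraction, 2 * 0.5^7)
  expect_equal(ana$true_fraction, 0.015625)
  ana2 <- achromatic_analytic()
  expect_equal(ana2$thresholded_fraction,
               sum(c(0.48, 0.48, 0.04) * (c(0.48, 0.48, 0.04)^6 +
                 6 * c(0.48, 0.48, 0.04)^5 * (1 - c(0.48, 0.48, 0.04)))))
  expect_lt(abs(ana2$thresholded_fraction - 0.088), 0.001)
})

test_that("the hex disk lattice wires interior cones to 6 true neighbors", {
  lat <- foveastf:::hex_disk_lattice(400)
  expect_equal(nrow(lat$coords), 400)
  expect_equal(ncol(lat$neighbors), 6)
  # every neighbor is at unit lattice distance
  for (k in seq_len(6)) {
    d <- sqrt(rowSums((lat$coords[lat$neighbors[, k], , drop = FALSE] -
                         lat$coords[lat$interior, , drop = FALSE])^2))
    expect_equal(d, rep(1, length(lat$interior)), tolerance = 1e-9)
  }
})

test_that("fixture bundles are byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- fixture_bundle(d1, seed = 3)
  p2 <- fixture_bundle(d2, seed = 3)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  # fixture mosaic satisfies the mosaic invariants
  mos <- read_mosaic(p1[["mosaic"]])
  expect_true(all(mos$class %in% c("L", "M", "S")))
  expect_equal(mos$aperture_um, aperture_radius(mos$diameter_um))
  # wavefront file round-trips into a pupil spec
  ps <- read_wavefront(p1[["wavefront"]])
  expect_equal(ps$diameter_mm, 6.7)
  expect_equal(ps$zernike$coeff_um[1], round(defocus_to_zernike(0.067, 6.7), 6))
})

test_that("measured STF tables round-trip through TSV", {
  ctx <- test_context()
  ds <- synth_stf_dataset(test_truth_single(), ctx, sessions = 2,
                          noise_frac = 0.1, seed = 8)
  tbl <- dplyr::mutate(ds$sessions, cell_id = "c1", .before = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stf(tbl, path)
  back <- read_stf(path)
  expect_equal(back$dff, tbl$dff, tolerance = 1e-12)
  expect_equal(back$session, tbl$session)
})
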