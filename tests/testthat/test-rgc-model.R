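test_that("uniform backgrounds excite equal-eccentricity cones equally", {
  mos <- test_mosaic()
  spec <- grating_spec(extent_deg = 0.4)
  bg <- make_background(spec)
  exc <- compute_excitations(bg, test_optics(0.067), mos)
  expect_true(all(exc$E >= 0))
  expect_true(all(exc$E0 > 0))
  # same class, similar eccentricity -> near-equal excitation
  ecc <- sqrt(mos$x_deg^2 + mos$y_deg^2)
  sel <- which(mos$class == "L" & abs(ecc - 0.05) < 0.003)
  expect_gt(length(sel), 2)
  expect_lt(diff(range(exc$E0[sel])) / mean(exc$E0[sel]), 0.02)
})

test_that("a mosaic outside the scene support is rejected", {
  mos <- test_mosaic()     # 0.3 deg extent
  spec <- grating_spec(extent_deg = 0.1)
  expect_error(compute_excitations(make_background(spec), test_optics(0), mos),
               "outside")
})

test_that("modulations are (E - E0) / E0 with a positive-background guard", {
  exc <- structure(list(E = matrix(c(3, 6, 2, 4), 2),
                        E0 = c(2, 4), times_ms = c(1, 2),
                        frame_duration_ms = 1, mosaic = NULL),
                   class = "cone_excitations")
  mods <- excitations_to_modulations(exc)
  expect_equal(mods$R, matrix(c(0.5, 0.5, 0, 0), 2))
  exc$E0 <- c(2, 0)
  expect_error(excitations_to_modulations(exc), "positive")
})

test_that("DoG weights follow the displayed center/surround formulas", {
  mos <- test_mosaic()
  w <- build_rf_weights(mos, kc = 2, ks = 0.5, rs_deg = 0.05,
                        scenario = "single-cone")
  expect_equal(sum(w$wc > 0), 1)
  expect_equal(max(w$wc), 2)
  # surround at the center cone distance ~0: Ws ~ ks; at d = rs: ks/e
  j <- which.max(w$wc)
  d <- sqrt((mos$x_deg - w$center_deg[1])^2 + (mos$y_deg - w$center_deg[2])^2)
  expect_equal(w$ws[j], 0.5 * exp(-(d[j] / 0.05)^2))
  expect_equal(w$ws, 0.5 * exp(-(d / 0.05)^2))
  wm <- build_rf_weights(mos, kc = 1, ks = 0.2, rc_deg = 0.02, rs_deg = 0.06,
                         center_position = c(0.01, 0), scenario = "multi-cone",
                         recenter = FALSE)
  dm <- sqrt((mos$x_deg - 0.01)^2 + mos$y_deg^2)
  expect_equal(wm$wc, 1 * exp(-(dm / 0.02)^2))
  expect_error(build_rf_weights(mos, kc = -1, ks = 0, rs_deg = 0.05),
               ">= 0")
})

test_that("cone masks exclude masked cones from pooling", {
  mos <- test_mosaic()
  mask <- mos$class != "S"
  w <- build_rf_weights(mos, kc = 1, ks = 0.3, rs_deg = 0.06,
                        scenario = "single-cone", cone_mask = mask)
  expect_true(all(w$ws[mos$class == "S"] == 0))
})

test_that("RGC pooling is the weighted center-minus-surround sum", {
  mods <- structure(list(R = rbind(sin(1:10), sin(1:10)),
                         times_ms = 1:10, mosaic = NULL),
                    class = "cone_modulations")
  w <- structure(list(wc = c(1, 0), ws = c(0.25, 0.25)),
                 class = "rf_weights")
  resp <- rgc_response(mods, w)
  expect_equal(resp$response, 0.5 * sin(1:10))
  w2 <- structure(list(wc = c(0.3, 0.3), ws = c(0.3, 0.3)),
                  class = "rf_weights")
  expect_equal(rgc_response(mods, w2)$response, rep(0, 10))
  w3 <- structure(list(wc = 1, ws = 0), class = "rf_weights")
  expect_error(rgc_response(mods, w3), "different numbers")
})

test_that("fixed-frequency sinusoid fitting recovers amplitude and offset", {
  t <- (seq_len(17) - 0.5) / 25.3
  fit <- fit_sinusoid(t, 0.5 * sin(2 * pi * 6 * t), 6)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit_sinusoid(t, rep(0, 17), 6)$amplitude, 0)
  fit2 <- fit_sinusoid(t, 0.3 * sin(2 * pi * 6 * t) + 0.05, 6)
  expect_equal(fit2$amplitude, 0.3, tolerance = 1e-3)
  expect_equal(fit2$offset, 0.05, tolerance = 1e-3)
  fit3 <- fit_sinusoid(t, 0.4 * sin(2 * pi * 6 * t - 1.1), 6)
  expect_equal(fit3$phase_rad, 1.1, tolerance = 1e-6)
  expect_error(fit_sinusoid(t[1:2], c(0, 1), 6), "3 samples")
})

test_that("pooled STF equals the pooled per-cone quadratures (linearity)", {
  ctx <- test_context()
  w <- test_truth_single()
  stf <- compute_model_stf(w, ctx)
  # explicit route: full forward model + rgc_response + fit_sinusoid
  spec <- ctx$spec_template
  spec$spatial_frequency_cpd <- ctx$frequencies[5]
  scene <- make_grating_sequence(spec)
  exc <- compute_excitations(scene, ctx$optics, ctx$mosaic)
  mods <- excitations_to_modulations(exc)
  resp <- rgc_response(mods, w)
  fit <- fit_sinusoid(resp$time_ms / 1000, resp$response, 6)
  expect_equal(stf$amplitude[5], fit$amplitude, tolerance = 1e-10)
  expect_equal(stf$phase_rad[5], fit$phase_rad, tolerance = 1e-8)
})

test_that("contrast scales the model STF linearly and vanishes at zero", {
  mos <- test_mosaic()
  ot <- test_optics(0.067)
  f <- c(6, 20, 40)
  ctx1 <- stf_model_context(mos, ot, frequencies = f,
                            spec_template = grating_spec(contrast = 1))
  ctx_half <- stf_model_context(mos, ot, frequencies = f,
                                spec_template = grating_spec(contrast = 0.5))
  ctx0 <- stf_model_context(mos, ot, frequencies = f,
                            spec_template = grating_spec(contrast = 0))
  w <- test_truth_single()
  a1 <- compute_model_stf(w, ctx1)$amplitude
  expect_equal(compute_model_stf(w, ctx_half)$amplitude, a1 / 2,
               tolerance = 1e-6)
  expect_equal(compute_model_stf(w, ctx0)$amplitude, rep(0, 3),
               tolerance = 1e-9 * max(a1))
})

test_that("a balanced DoG cancels toward zero frequency", {
  mos <- test_mosaic()
  # kc*rc^2 = ks*rs^2: center and surround integrals match, so the response
  # must vanish as the grating approaches uniformity
  ctx <- stf_model_context(mos, test_optics(0.067),
                           frequencies = c(0.5, 5, 20))
  # balance on the mosaic: equal center and surround integrated weight
  # (effective densities differ slightly because density falls with
  # eccentricity)
  ks_bal <- 1 * (0.03 / 0.06)^2 *
    effective_density(mos, c(0, 0), 0.03) /
    effective_density(mos, c(0, 0), 0.06)
  w <- build_rf_weights(mos, kc = 1, ks = ks_bal, rc_deg = 0.03,
                        rs_deg = 0.06, scenario = "multi-cone",
                        recenter = FALSE)
  stf <- compute_model_stf(w, ctx)
  expect_lt(stf$amplitude[1], 0.05 * stf$amplitude[2])
})

test_that("full pipeline matches the analytic DoG x MTF x aperture oracle", {
  ctx <- test_context()
  mos <- ctx$mosaic
  ot <- ctx$optics
  upd <- attr(mos, "um_per_deg")
  set.seed(99)
  for (i in 1:4) {
    kc <- stats::runif(1, 0.5, 3)
    ks <- stats::runif(1, 0.05, 0.3)
    rc <- stats::runif(1, 0.015, 0.03)
    rs <- stats::runif(1, 0.04, 0.065)
    w <- build_rf_weights(mos, kc, ks, rc, rs, scenario = "multi-cone",
                          recenter = FALSE)
    stf <- compute_model_stf(w, ctx)
    ana <- analytic_stf_oracle(ctx$frequencies, w, mos, ot)
    expect_lt(max(abs(stf$amplitude - ana)) / max(ana), 0.05)
  }
})
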