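test_that("boost factor is the stated linear ramp with clamping", {
  expect_equal(boost_factor(4.7), 0.1)
  expect_equal(boost_factor(49), 1.0)
  expect_equal(boost_factor(26.85), 0.55)
  expect_equal(boost_factor(60), 1.0)
  expect_equal(boost_factor(0), 0.1)
})

test_that("offset correction shifts negative-going STFs to zero minimum", {
  m <- tibble::tibble(freq_cpd = 1:3, dff = c(-0.1, 0.5, 1.0), sem = 0.1)
  out <- offset_correct(m)
  expect_equal(out$dff, c(0, 0.6, 1.1))
  expect_true(attr(out, "offset_applied"))
  m2 <- tibble::tibble(freq_cpd = 1:3, dff = c(0.1, 0.5, 1.0), sem = 0.1)
  expect_equal(offset_correct(m2)$dff, m2$dff)
  expect_false(attr(offset_correct(m2), "offset_applied"))
  m3 <- tibble::tibble(freq_cpd = 1:3, dff = rep(-0.2, 3), sem = 0.1)
  expect_equal(offset_correct(m3)$dff, rep(0, 3))
})

test_that("the weighted RMSE implements the displayed formula exactly", {
  m <- tibble::tibble(freq_cpd = c(4.7, 49), dff = c(0, 0),
                      sem = c(0.1, 0.2))
  model <- c(0.2, 0.1)
  expect_equal(as.numeric(stf_objective(model, m)),
               sqrt(0.5 * (0.1 / 0.1 * 0.04 + 1.0 / 0.2 * 0.01)))
  expect_equal(as.numeric(stf_objective(model, m)), sqrt(0.045))
  expect_equal(as.numeric(stf_objective(m$dff, m)), 0)
  # doubling all sem scales rmse by 1/sqrt(2)
  m2 <- dplyr::mutate(m, sem = sem * 2)
  expect_equal(as.numeric(stf_objective(model, m2)),
               as.numeric(stf_objective(model, m)) / sqrt(2))
  # random-input conformance against a direct transcription
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:14, 1)
    mm <- tibble::tibble(freq_cpd = sort(stats::runif(n, 4, 49)),
                         dff = stats::rnorm(n), sem = stats::runif(n, 0.05, 0.3))
    mod <- stats::rnorm(n)
    direct <- sqrt(sum(boost_factor(mm$freq_cpd) / mm$sem *
                         (mod - mm$dff)^2) / n)
    expect_equal(as.numeric(stf_objective(mod, mm)), direct,
                 tolerance = 1e-12)
  }
})

test_that("zero standard errors are floored, not divided by", {
  m <- tibble::tibble(freq_cpd = c(5, 10, 20, 30, 40, 49),
                      dff = c(1, 2, 3, 2, 1, 0.5), sem = 0)
  val <- stf_objective(rep(0, 6), m)
  expect_true(is.finite(val))
  expect_true(attr(val, "eps_floored"))
})

test_that("noise-free multi-cone STFs are recovered within tight tolerances", {
  ctx <- test_context()
  truth <- list(kc = 2, ks = 0.4, rc = 0.02, rs = 0.06)
  w <- build_rf_weights(ctx$mosaic, truth$kc, truth$ks, truth$rc, truth$rs,
                        center_position = c(0.005, -0.003),
                        scenario = "multi-cone", recenter = FALSE)
  meas <- noise_free_measured(w, ctx)
  fit <- fit_stf(meas, ctx, "multi-cone",
                 candidate_positions = matrix(w$center_deg, 1),
                 n_starts = 48, seed = 5)
  expect_lt(abs(fit$rc_deg - truth$rc) / truth$rc, 0.05)
  expect_lt(abs(fit$rs_deg - truth$rs) / truth$rs, 0.05)
  expect_lt(abs(fit$kc - truth$kc) / truth$kc, 0.10)
  expect_lt(abs(fit$ks - truth$ks) / truth$ks, 0.10)
})

test_that("fits are deterministic given the seed", {
  ctx <- test_context()
  w <- test_truth_single()
  meas <- noise_free_measured(w, ctx)
  f1 <- fit_stf(meas, ctx, "single-cone",
                candidate_positions = matrix(0, 1, 2), n_starts = 16, seed = 2)
  f2 <- fit_stf(meas, ctx, "single-cone",
                candidate_positions = matrix(0, 1, 2), n_starts = 16, seed = 2)
  expect_identical(glance(f1), glance(f2))
  expect_identical(tidy(f1), tidy(f2))
})

test_that("fitting requires enough frequencies and matching grids", {
  ctx <- test_context()
  short <- tibble::tibble(freq_cpd = ctx$frequencies[1:4], dff = 1:4 / 4,
                          sem = 0.1)
  expect_error(fit_stf(short, ctx), "at least 6")
  off_grid <- tibble::tibble(freq_cpd = seq(5, 45, length.out = 8),
                             dff = 1, sem = 0.1)
  expect_error(fit_stf(off_grid, ctx), "not in the model context")
})

test_that("derived statistics are the three DoG ratios", {
  st <- derived_stats(kc = 1, ks = 0.1, rc_deg = 0.02, rs_deg = 0.08)
  expect_equal(st$rc_over_rs, 0.25)
  expect_equal(st$ks_over_kc, 0.1)
  expect_equal(st$integrated_ratio, 1.6)
  st0 <- derived_stats(kc = 1, ks = 0, rc_deg = 0.02, rs_deg = 0.08)
  expect_equal(st0$ks_over_kc, 0)
  expect_equal(st0$integrated_ratio, 0)
  st1 <- derived_stats(kc = 1, ks = 1, rc_deg = 0.05, rs_deg = 0.05)
  expect_equal(unlist(st1), c(rc_over_rs = 1, ks_over_kc = 1,
                              integrated_ratio = 1))
  expect_error(derived_stats(kc = 0, ks = 1, rc_deg = 0.02, rs_deg = 0.08),
               "undefined")
})

test_that("cross-validation is symmetric for identical sessions", {
  ctx <- test_context()
  w <- test_truth_single()
  stf <- compute_model_stf(w, ctx)
  one <- tibble::tibble(freq_cpd = stf$freq_cpd, dff = stf$amplitude,
                        sem = 0.05)
  two <- dplyr::bind_rows(dplyr::mutate(one, session = 1),
                          dplyr::mutate(one, session = 2))
  cv <- crossvalidate_stf(two, ctx, "single-cone",
                          candidate_positions = matrix(0, 1, 2),
                          n_starts = 8, seed = 1)
  expect_equal(nrow(cv), 4)
  expect_equal(cv$rmse[cv$in_sample], cv$rmse[!cv$in_sample],
               tolerance = 1e-9)
  expect_error(crossvalidate_stf(dplyr::mutate(one, session = 1), ctx),
               "2 sessions")
})

test_that("out-of-sample error exceeds in-sample error in expectation", {
  ctx <- test_context()
  truth <- test_truth_single()
  diffs <- vapply(1:50, function(s) {
    ds <- synth_stf_dataset(truth, ctx, sessions = 2, noise_frac = 0.10,
                            seed = 100 + s)
    per <- ds$sessions
    cv <- crossvalidate_stf(per, ctx, "single-cone",
                            candidate_positions = matrix(0, 1, 2),
                            n_starts = 6, seed = s)
    mean(cv$rmse[!cv$in_sample]) - mean(cv$rmse[cv$in_sample])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.7)
})

test_that("session labels only permute the pair scores", {
  ctx <- test_context()
  truth <- test_truth_single()
  ds <- synth_stf_dataset(truth, ctx, sessions = 2, noise_frac = 0.1,
                          seed = 9)
  per <- ds$sessions
  cv1 <- crossvalidate_stf(per, ctx, "single-cone",
                           candidate_positions = matrix(0, 1, 2),
                           n_starts = 6, seed = 1)
  per2 <- dplyr::mutate(per, session = 3 - session)
  cv2 <- crossvalidate_stf(per2, ctx, "single-cone",
                           candidate_positions = matrix(0, 1, 2),
                           n_starts = 6, seed = 1)
  expect_equal(sort(cv1$rmse), sort(cv2$rmse), tolerance = 1e-9)
})

test_that("aperture projection through optics follows Gaussian convolution", {
  expect_equal(project_aperture_to_visual_space(0.01, gaussian_optics(0)),
               0.01)
  r <- 0.01; rho <- 0.02
  proj <- project_aperture_to_visual_space(r, gaussian_optics(rho))
  expect_equal(proj, sqrt(r^2 + rho^2), tolerance = 0.01)
  # blur cannot shrink the aperture
  ot <- test_optics(0.067)
  expect_gte(project_aperture_to_visual_space(0.003, ot), 0.003)
})

test_that("the descriptive DoG fit reproduces a pure DoG curve", {
  f <- default_stf_frequencies()
  kc <- 800; ks <- 40; rc <- 0.015; rs <- 0.06
  amp <- abs(kc * pi * rc^2 * exp(-(pi * rc * f)^2) -
               ks * pi * rs^2 * exp(-(pi * rs * f)^2))
  fit <- fit_descriptive_dog(f, amp, n_starts = 64, seed = 2)
  expect_lt(max(abs(fit$fitted - amp)) / max(amp), 0.02)
})
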