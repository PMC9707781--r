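#' High-spatial-frequency boost factor
#'
#' Linear weighting from 0.1 at 4.7 c/deg to 1.0 at 49 c/deg, clamped
#' outside; emphasizes the high-frequency measurements that are most
#' informative about the RF center.
#'
#' @param freq_cpd Spatial frequency, c/deg.
#' @return Boost values in `[0.1, 1]`.
#' @examples
#' boost_factor(c(4.7, 26.85, 49, 60))
#' @export
boost_factor <- function(freq_cpd) {
  b <- 0.1 + (freq_cpd - 4.7) / (49 - 4.7) * 0.9
  pmin(pmax(b, 0.1), 1.0)
}

#' Offset-correct a measured STF
#'
#' If any response value is negative (interpreted as overestimated
#' background fluorescence), the minimum is subtracted from all values so the
#' minimum maps to zero; otherwise the data are unchanged. The applied flag
#' is recorded in attribute `offset_applied`.
#'
#' @param measured A tibble with at least columns `freq_cpd`, `dff`
#'   (and optionally `sem`).
#' @return The corrected tibble with attribute `offset_applied`.
#' @export
offset_correct <- function(measured) {
  out <- measured
  applied <- any(measured$dff < 0)
  if (applied) out$dff <- measured$dff - min(measured$dff)
  attr(out, "offset_applied") <- applied
  out
}

#' Weighted RMSE between a model and a measured STF
#'
#' Implements `sqrt(1/N * sum(beta(w)/eps(w) * (STFm - STFdff)^2))` with
#' `beta` the boost factor and `eps` the per-frequency standard error.
#' Standard errors are floored at `eps_floor_frac * max(|dff|)` to avoid
#' infinite weights; flooring is reported via attribute `eps_floored`.
#'
#' @param model_amplitude Model STF values at the measured frequencies.
#' @param measured Tibble with `freq_cpd`, `dff`, `sem`.
#' @param eps_floor_frac Floor for `sem` as a fraction of `max(abs(dff))`.
#' @return The RMSE (numeric scalar, attribute `eps_floored` logical).
#' @export
stf_objective <- function(model_amplitude, measured,
                          eps_floor_frac = 1e-3) {
  eps <- measured$sem
  floor_val <- eps_floor_frac * max(abs(measured$dff))
  floored <- any(eps < floor_val)
  eps <- pmax(eps, floor_val)
  b <- boost_factor(measured$freq_cpd)
  res <- model_amplitude - measured$dff
  out <- sqrt(mean(b / eps * res^2))
  attr(out, "eps_floored") <- floored
  out
}

# weighted SSE pieces reused by the optimizer: w = beta/eps, 1/N inside
objective_weights <- function(measured, eps_floor_frac = 1e-3) {
  eps <- pmax(measured$sem, eps_floor_frac * max(abs(measured$dff)))
  boost_factor(measured$freq_cpd) / eps / nrow(measured)
}

#' Fit a DoG cone-pooling model to a measured STF
#'
#' Multi-start bounded minimization of the weighted RMSE over the DoG
#' parameters (`kc`, `ks`, `rs` and, in the multi-cone scenario, `rc`), at
#' one or more candidate RF center positions within the mosaic; the best
#' (position, start) by RMSE wins, ties broken by first found. Parameters
#' are optimized in log10 space within bounds (`kc`, `ks` up to 1e4;
#' `rc`, `rs` from a quarter of the cone spacing to 1 deg); starts are drawn
#' log-uniform within the bounds from a seeded generator. Offset correction
#' ([offset_correct()]) is applied before fitting.
#'
#' @param measured Tibble with `freq_cpd`, `dff`, `sem` for one cell (one
#'   session or session-averaged); frequencies must match the context grid.
#' @param context An [stf_model_context()] (fixes mosaic, optics/defocus and
#'   stimulus).
#' @param scenario `"single-cone"` or `"multi-cone"`.
#' @param candidate_positions A two-column matrix/data frame of candidate
#'   center positions in degrees, or `NULL` for the default 9-point grid
#'   spanning a 40-um square centered on the mosaic.
#' @param n_starts Number of optimizer starts per candidate position
#'   (default 512).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param eps_floor_frac Standard-error floor (see [stf_objective()]).
#' @return An object of class `stf_fit`: list with `kc`, `ks`, `rc_deg`,
#'   `rs_deg`, `rmse`, `scenario`, `defocus_D`, `center_deg`, `weights`
#'   (an `rf_weights`), `model_stf`, `measured` (offset-corrected),
#'   `offset_applied`, `n_starts`, `seed`.
#' @export
fit_stf <- function(measured, context, scenario = c("single-cone", "multi-cone"),
                    candidate_positions = NULL, n_starts = 512, seed = 1,
                    eps_floor_frac = 1e-3) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(context, "stf_model_context"))
  if (nrow(measured) < 6) {
    stop("need at least 6 measured frequencies.", call. = FALSE)
  }
  ord <- match_frequencies(measured$freq_cpd, context$frequencies)
  measured <- offset_correct(measured)
  offset_applied <- attr(measured, "offset_applied")
  wts <- objective_weights(measured, eps_floor_frac)
  zeta <- context$zeta[, ord, drop = FALSE]
  mosaic <- context$mosaic
  upd <- attr(mosaic, "um_per_deg")
  if (is.null(candidate_positions)) {
    g <- c(-20, 0, 20) / upd
    candidate_positions <- as.matrix(expand.grid(x = g, y = g))
  }
  candidate_positions <- as.matrix(candidate_positions)
  spacing_deg <- mosaic_hex_spacing(mosaic) / upd
  lb_r <- 0.25 * spacing_deg
  bounds <- param_bounds(scenario, lb_r)

  best <- NULL
  withr_seed(seed, {
    starts <- matrix(stats::runif(n_starts * nrow(bounds)), n_starts)
    starts <- sweep(sweep(starts, 2, bounds[, 2] - bounds[, 1], "*"),
                    2, bounds[, 1], "+")     # log10-uniform within bounds
    for (p in seq_len(nrow(candidate_positions))) {
      pos <- candidate_positions[p, ]
      obj <- make_position_objective(zeta, mosaic, pos, scenario,
                                     measured$dff, wts)
      for (s in seq_len(n_starts)) {
        fit <- try(stats::optim(starts[s, ], obj$fn, method = "L-BFGS-B",
                                lower = bounds[, 1], upper = bounds[, 2],
                                control = list(factr = 1e4, maxit = 200)),
                   silent = TRUE)
        if (inherits(fit, "try-error")) next
        if (is.null(best) || fit$value < best$value - 1e-12) {
          best <- list(value = fit$value, par = fit$par, pos = pos,
                       obj = obj)
        }
      }
    }
  })
  if (is.null(best)) stop("optimizer failed at every start.", call. = FALSE)
  par <- 10^best$par
  kc <- par[1]; ks <- par[2]
  rc <- if (scenario == "multi-cone") par[3] else NA_real_
  rs <- par[length(par)]
  # the multi-cone amplitude is invariant under swapping center and
  # surround; report the conventional labeling (rc <= rs)
  if (scenario == "multi-cone" && rc > rs) {
    tmp <- c(kc, rc); kc <- ks; rc <- rs; ks <- tmp[1]; rs <- tmp[2]
  }
  weights <- build_rf_weights(mosaic, kc, ks,
                              rc_deg = if (scenario == "multi-cone") rc else NULL,
                              rs_deg = rs, center_position = best$pos,
                              scenario = scenario, recenter = FALSE)
  model <- compute_model_stf(weights, context)
  j_center <- which.max(weights$wc)
  structure(
    list(kc = kc, ks = ks, rc_deg = rc, rs_deg = rs,
         rmse = sqrt(best$value), scenario = scenario,
         defocus_D = context_defocus(context),
         center_deg = weights$center_deg, weights = weights,
         center_aperture_deg = mosaic$aperture_um[j_center] / upd,
         model_stf = model, measured = measured,
         offset_applied = offset_applied, n_starts = n_starts, seed = seed),
    class = "stf_fit"
  )
}

# bounds in log10 space, rows: kc, ks, (rc), rs
param_bounds <- function(scenario, lb_r) {
  kb <- c(-4, 4)
  rb <- log10(c(lb_r, 1))
  if (scenario == "multi-cone") {
    rbind(kc = kb, ks = kb, rc = rb, rs = rb)
  } else {
    rbind(kc = kb, ks = kb, rs = rb)
  }
}

# squared-objective closure for one candidate position; parameters in log10
make_position_objective <- function(zeta, mosaic, pos, scenario, dff, wts) {
  d2 <- (mosaic$x_deg - pos[1])^2 + (mosaic$y_deg - pos[2])^2
  if (scenario == "single-cone") {
    j <- which.min(d2)
    zc_center <- zeta[j, ]
    fn <- function(par) {
      kc <- 10^par[1]; ks <- 10^par[2]; rs <- 10^par[3]
      zs <- crossprod(exp(-d2 / rs^2), zeta)[1, ]
      amp <- Mod(kc * zc_center - ks * zs)
      sum(wts * (amp - dff)^2)
    }
  } else {
    fn <- function(par) {
      kc <- 10^par[1]; ks <- 10^par[2]; rc <- 10^par[3]; rs <- 10^par[4]
      zc <- crossprod(exp(-d2 / rc^2), zeta)[1, ]
      zs <- crossprod(exp(-d2 / rs^2), zeta)[1, ]
      amp <- Mod(kc * zc - ks * zs)
      sum(wts * (amp - dff)^2)
    }
  }
  list(fn = fn, d2 = d2)
}

match_frequencies <- function(freq, grid) {
  ord <- vapply(freq, function(f) {
    i <- which.min(abs(grid - f))
    if (abs(grid[i] - f) > 1e-6 * max(1, f)) {
      stop(sprintf("measured frequency %.3f c/deg not in the model context",
                   f), call. = FALSE)
    }
    i
  }, integer(1))
  ord
}

context_defocus <- function(context) {
  op <- context$optics
  if (!is.null(op$pupil)) op$pupil$defocus_D else NA_real_
}

#' Sweep fitting scenarios and residual defocus values
#'
#' Runs [fit_stf()] for every combination of scenario and defocus context
#' and tabulates the minimized RMSE; the per-scenario argmin over defocus is
#' attached as attribute `argmin`.
#'
#' @param measured Measured STF tibble (see [fit_stf()]).
#' @param contexts Named list of [stf_model_context()] objects, one per
#'   defocus value (names ignored; defocus is read from each context).
#' @param scenarios Character vector of scenarios to fit.
#' @param ... Passed to [fit_stf()].
#' @return Tibble `scenario`, `defocus_D`, `rmse`, `kc`, `ks`, `rc_deg`,
#'   `rs_deg` with attributes `argmin` (tibble) and `fits` (list).
#' @export
scenario_sweep <- function(measured, contexts,
                           scenarios = c("single-cone", "multi-cone"), ...) {
  if (length(contexts) == 0) stop("empty defocus grid.", call. = FALSE)
  grid <- tidyr::expand_grid(scenario = scenarios,
                             ctx_i = seq_along(contexts))
  fits <- purrr::pmap(grid, function(scenario, ctx_i) {
    fit_stf(measured, contexts[[ctx_i]], scenario = scenario, ...)
  })
  out <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(scenario = f$scenario, defocus_D = f$defocus_D,
                   rmse = f$rmse, kc = f$kc, ks = f$ks,
                   rc_deg = f$rc_deg, rs_deg = f$rs_deg)
  })
  argmin <- out |>
    dplyr::group_by(.data$scenario) |>
    dplyr::slice_min(.data$rmse, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  attr(out, "argmin") <- argmin
  attr(out, "fits") <- fits
  out
}

#' Cross-validate STF fits across recording sessions
#'
#' For every ordered pair of sessions the model is fitted to the training
#' session and the weighted RMSE is evaluated on the test session
#' (in-sample when train == test).
#'
#' @param measured_by_session Tibble with columns `session`, `freq_cpd`,
#'   `dff`, `sem` (>= 2 sessions).
#' @param context An [stf_model_context()].
#' @param scenario Scenario to fit.
#' @param ... Passed to [fit_stf()].
#' @return Tibble `train_session`, `test_session`, `rmse`, `in_sample`.
#' @export
crossvalidate_stf <- function(measured_by_session, context,
                              scenario = "single-cone", ...) {
  sessions <- unique(measured_by_session$session)
  if (length(sessions) < 2) stop("need at least 2 sessions.", call. = FALSE)
  fits <- purrr::map(sessions, function(s) {
    fit_stf(dplyr::filter(measured_by_session, .data$session == s),
            context, scenario = scenario, ...)
  })
  names(fits) <- as.character(sessions)
  purrr::map_dfr(sessions, function(tr) {
    fit <- fits[[as.character(tr)]]
    purrr::map_dfr(sessions, function(te) {
      test <- dplyr::filter(measured_by_session, .data$session == te)
      test <- offset_correct(test)
      ord <- match_frequencies(test$freq_cpd, context$frequencies)
      amp <- fit$model_stf$amplitude[ord]
      tibble::tibble(train_session = tr, test_session = te,
                     rmse = as.numeric(stf_objective(amp, test)),
                     in_sample = tr == te)
    })
  })
}

#' Derived DoG population statistics
#'
#' The three ratios summarized across cells: `rc/rs`, `ks/kc` and the
#' integrated surround-to-center sensitivity ratio `(ks/kc) * (rs/rc)^2`.
#' For single-cone fits the equivalent center radius is the Gaussian
#' aperture characteristic radius of the center cone.
#'
#' @param fit An `stf_fit`, or explicit `kc`, `ks`, `rc_deg`, `rs_deg`.
#' @param kc,ks,rc_deg,rs_deg Used when `fit` is `NULL`.
#' @return Tibble `rc_over_rs`, `ks_over_kc`, `integrated_ratio`.
#' @export
derived_stats <- function(fit = NULL, kc = NULL, ks = NULL, rc_deg = NULL,
                          rs_deg = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "stf_fit"))
    kc <- fit$kc; ks <- fit$ks; rs_deg <- fit$rs_deg
    rc_deg <- if (fit$scenario == "single-cone" || is.na(fit$rc_deg)) {
      fit$center_aperture_deg
    } else {
      fit$rc_deg
    }
  }
  if (is.null(kc) || kc <= 0 || is.null(rc_deg) || rc_deg <= 0) {
    stop("undefined ratios: kc and rc must be positive.", call. = FALSE)
  }
  if (rs_deg <= 0) stop("`rs_deg` must be positive.", call. = FALSE)
  tibble::tibble(
    rc_over_rs = rc_deg / rs_deg,
    ks_over_kc = ks / kc,
    integrated_ratio = (ks / kc) * (rs_deg / rc_deg)^2
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict the STF under physiological optics
#'
#' Recomputes the forward STF of a fitted cell with the adaptive-optics
#' stimulation optics replaced by the supplied physiological optics (e.g. a
#' measured wavefront at a 2.5 mm natural pupil, or Gaussian-blur reference
#' optics) driving a 100% contrast achromatic grating, then fits a simple
#' unweighted descriptive DoG curve to the predicted STF, as is standard for
#' in vivo measurements taken through the eye's optics.
#'
#' @param fit An `stf_fit`.
#' @param physio_optics An `optical_transfer` for the physiological eye.
#' @param context The [stf_model_context()] used for the original fit (gives
#'   mosaic, frequencies, stimulus geometry).
#' @param media Optional [ocular_media()].
#' @param n_starts Starts for the descriptive DoG fit.
#' @param seed Seed for the descriptive fit starts.
#' @return A list of class `physio_stf`: `stf` (tibble `freq_cpd`,
#'   `amplitude`), `dog_fit` (tibble `kc`, `ks`, `rc_deg`, `rs_deg`, `sse`),
#'   `dog_curve` (fitted values), `aoslo_stf` (the fitted-model STF under
#'   stimulation optics).
#' @export
predict_physiological_stf <- function(fit, physio_optics, context,
                                      media = NULL, n_starts = 64, seed = 1) {
  stopifnot(inherits(fit, "stf_fit"))
  spec <- context$spec_template
  spec$contrast <- 1
  spec$spectrum <- "flat"
  physio_ctx <- stf_model_context(context$mosaic, physio_optics,
                                  frequencies = context$frequencies,
                                  spec_template = spec, media = media)
  pred <- compute_model_stf(fit$weights, physio_ctx)
  dog <- fit_descriptive_dog(pred$freq_cpd, pred$amplitude,
                             n_starts = n_starts, seed = seed)
  structure(
    list(stf = pred, dog_fit = dog$par, dog_curve = dog$fitted,
         aoslo_stf = fit$model_stf),
    class = "physio_stf"
  )
}

#' Fit a simple descriptive DoG curve to an STF
#'
#' Unweighted least squares of
#' `|kc*pi*rc^2*exp(-(pi*rc*w)^2) - ks*pi*rs^2*exp(-(pi*rs*w)^2)|`
#' to amplitude data; multi-start in log10 parameter space.
#'
#' @param freq_cpd,amplitude STF samples.
#' @param n_starts,seed Multi-start control.
#' @return List with `par` (tibble `kc`, `ks`, `rc_deg`, `rs_deg`, `sse`)
#'   and `fitted` values.
#' @export
fit_descriptive_dog <- function(freq_cpd, amplitude, n_starts = 64, seed = 1) {
  dogv <- function(p, f) {
    abs(p[1] * pi * p[3]^2 * exp(-(pi * p[3] * f)^2) -
          p[2] * pi * p[4]^2 * exp(-(pi * p[4] * f)^2))
  }
  fn <- function(lp) {
    p <- 10^lp
    sum((dogv(p, freq_cpd) - amplitude)^2)
  }
  lb <- c(-4, -4, log10(0.002), log10(0.002))
  ub <- c(6, 6, 0, 0)
  best <- NULL
  withr_seed(seed, {
    for (s in seq_len(n_starts)) {
      st <- stats::runif(4, lb, ub)
      fit <- try(stats::optim(st, fn, method = "L-BFGS-B", lower = lb,
                              upper = ub, control = list(factr = 1e4)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  if (is.null(best)) stop("descriptive DoG fit failed.", call. = FALSE)
  p <- 10^best$par
  list(par = tibble::tibble(kc = p[1], ks = p[2], rc_deg = p[3],
                            rs_deg = p[4], sse = best$value),
       fitted = dogv(p, freq_cpd))
}

#' Project a cone aperture into visual space through the optics
#'
#' Convolves a Gaussian aperture of the given characteristic radius with the
#' PSF and fits a 2-D Gaussian to the result; the fitted characteristic
#' radius is the visual-space aperture size. For Gaussian-blur optics the
#' closed form is `sqrt(r^2 + rho^2)`.
#'
#' @param aperture_radius_deg Aperture characteristic radius, deg.
#' @param optics An `optical_transfer`.
#' @return Visual-space characteristic radius in degrees.
#' @export
project_aperture_to_visual_space <- function(aperture_radius_deg, optics) {
  stopifnot(inherits(optics, "optical_transfer"))
  if (optics$kind == "delta") return(aperture_radius_deg)
  psf <- optics$psf
  p <- optics$pixel_deg
  n <- nrow(psf)
  ax <- (seq_len(n) - (n + 1 + (n %% 2 == 0)) / 2) * p
  r2 <- outer(ax^2, ax^2, "+")
  ap <- exp(-r2 / aperture_radius_deg^2)
  ap <- ap / sum(ap)
  conv <- Re(stats::fft(stats::fft(Matrix_ishift(psf)) *
                          stats::fft(Matrix_ishift(ap)), inverse = TRUE)) / n^2
  conv <- Matrix_shift(conv)
  conv <- pmax(conv, 0)
  # init from second moments: for exp(-r^2/rho^2), E[x^2 + y^2] = rho^2
  rho0 <- sqrt(max(sum(conv * r2) / sum(conv), 1e-12))
  obj <- function(lp) {
    rho <- exp(lp[2]); a <- exp(lp[1])
    sum((a * exp(-r2 / rho^2) - conv)^2)
  }
  fit <- stats::optim(c(log(max(conv)), log(rho0)), obj, method = "BFGS")
  if (fit$convergence != 0 && fit$value > obj(c(log(max(conv)), log(rho0)))) {
    stop("2-D Gaussian fit to the projected aperture failed.", call. = FALSE)
  }
  exp(fit$par[2])
}
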