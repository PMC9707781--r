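#' Compute cone excitations from a scene sequence
#'
#' For each frame, the retinal irradiance (scene attenuated by the lens) is
#' blurred by the optical PSF, spectrally weighted by each cone's effective
#' quantal efficiency (class fundamental times macular transmittance at the
#' cone's eccentricity), spatially integrated over the cone's Gaussian
#' entrance aperture, and integrated over the frame duration. No Poisson
#' noise and no eye-motion jitter are added: the measurements being modeled
#' were taken under anesthesia with stabilized stimuli.
#'
#' Because every scene in scope has a space-independent spectrum, the
#' wavelength integral factors into a per-cone spectral gain times the
#' spatial integral; aperture integration is performed by convolving the
#' blurred frame with the aperture Gaussian (cones grouped by aperture
#' radius) and interpolating at the cone positions.
#'
#' @param scene A `scene_sequence` from [make_grating_sequence()].
#' @param optics An `optical_transfer` from [compute_psf_mtf()] or
#'   [gaussian_optics()].
#' @param mosaic A `cone_mosaic`.
#' @param media An [ocular_media()]; `NULL` for a transparent eye.
#' @param fundamentals Named list of cone fundamentals (`L`, `M`, `S`);
#'   default [macaque_fundamentals()] on the scene wavelength grid.
#' @return Object of class `cone_excitations`: list with `E` (matrix cone x
#'   frame, expected excitation events), `E0` (background excitation per
#'   cone), `times_ms`, `frame_duration_ms`, `mosaic`.
#' @export
compute_excitations <- function(scene, optics, mosaic, media = NULL,
                                fundamentals = NULL) {
  stopifnot(inherits(scene, "scene_sequence"), inherits(mosaic, "cone_mosaic"))
  ext <- scene$pixel_deg * nrow(scene$frames[[1]])
  if (nrow(mosaic) > 0 &&
      (max(abs(mosaic$x_deg)) > ext / 2 || max(abs(mosaic$y_deg)) > ext / 2)) {
    stop("mosaic extends outside the scene support.", call. = FALSE)
  }
  if (is.null(fundamentals)) {
    fundamentals <- macaque_fundamentals(wavelength_nm = scene$wavelength_nm)
  }
  gains <- cone_spectral_gains(scene, mosaic, media, fundamentals)
  spatial <- cone_spatial_samples(scene, optics, mosaic)
  E <- spatial * gains * scene$frame_duration_ms
  bg <- matrix(scene$mean_level, nrow(scene$frames[[1]]), ncol(scene$frames[[1]]))
  E0 <- as.numeric(sample_blurred_at_cones(bg, scene$pixel_deg, optics, mosaic)) *
    gains * scene$frame_duration_ms
  structure(
    list(E = E, E0 = E0, times_ms = scene$times_ms,
         frame_duration_ms = scene$frame_duration_ms, mosaic = mosaic),
    class = "cone_excitations"
  )
}

# per-cone spectral gain: sum over wavelength of profile * lens * macular *
# class fundamental, times the aperture collecting area (pi * r_ap^2).
cone_spectral_gains <- function(scene, mosaic, media, fundamentals) {
  wl <- scene$wavelength_nm
  lens <- if (is.null(media)) rep(1, length(wl)) else media$lens_transmittance
  ecc <- sqrt(mosaic$x_deg^2 + mosaic$y_deg^2)
  # macular transmittance per cone (wavelength x cone)
  mac <- if (is.null(media)) {
    matrix(1, length(wl), nrow(mosaic))
  } else {
    media$macular_transmittance(ecc)
  }
  fmat <- vapply(fundamentals, function(f) f$sensitivity,
                 numeric(length(wl)))   # wavelength x class
  cls <- as.character(mosaic$class)
  base <- scene$spectral_profile * lens
  gains <- vapply(seq_len(nrow(mosaic)), function(j) {
    sum(base * mac[, j] * fmat[, cls[j]])
  }, numeric(1))
  upd <- attr(mosaic, "um_per_deg")
  gains * pi * (mosaic$aperture_um / upd)^2
}

# blur every frame by the optics + aperture and sample at cone positions;
# returns matrix cone x frame of mean irradiance seen through the aperture.
cone_spatial_samples <- function(scene, optics, mosaic) {
  n_fr <- length(scene$frames)
  out <- matrix(0, nrow(mosaic), n_fr)
  plan <- make_blur_plan(nrow(scene$frames[[1]]), scene$pixel_deg, optics,
                         mosaic)
  for (k in seq_len(n_fr)) {
    out[, k] <- apply_blur_plan(plan, scene$frames[[k]], mosaic)
  }
  out
}

# Precompute everything reusable across frames for one (grid, optics, mosaic)
# combination: the padded-grid optics kernel FFT and the per-aperture-group
# Gaussian transfer functions. Aperture radii are grouped in 0.05-um bins.
make_blur_plan <- function(n, pixel_deg, optics, mosaic) {
  upd <- attr(mosaic, "um_per_deg")
  pad <- 2^ceiling(log2(n * 1.5))
  kern <- psf_on_raster(optics, pixel_deg)
  K <- embed_kernel_fft(kern, pad)
  freq <- c(0:(pad / 2), -((pad / 2 - 1):1)) / (pad * pixel_deg)
  fr2 <- outer(freq^2, freq^2, "+")
  ap_groups <- round(mosaic$aperture_um / 0.05) * 0.05
  groups <- lapply(unique(ap_groups), function(ap) {
    rho_deg <- ap / upd
    list(idx = which(ap_groups == ap),
         G = K * exp(-pi^2 * rho_deg^2 * fr2))
  })
  list(n = n, pad = pad, i0 = floor((pad - n) / 2), pixel_deg = pixel_deg,
       groups = groups)
}

# Convolve one frame with PSF + aperture Gaussian per group in frequency
# space (padding with the frame edge level) and bilinearly interpolate at
# cone positions.
apply_blur_plan <- function(plan, frame, mosaic) {
  if (nrow(mosaic) == 0) return(numeric(0))
  n <- plan$n; pad <- plan$pad; i0 <- plan$i0
  padded <- matrix(mean(frame[c(1, n), ]), pad, pad)
  padded[i0 + seq_len(n), i0 + seq_len(n)] <- frame
  FF <- stats::fft(padded)
  vals <- numeric(nrow(mosaic))
  for (g in plan$groups) {
    blurred <- Re(stats::fft(FF * g$G, inverse = TRUE)) / pad^2
    vals[g$idx] <- bilinear_sample(
      blurred, plan$pixel_deg, pad, i0 + (n + 1) / 2,
      mosaic$x_deg[g$idx], mosaic$y_deg[g$idx])
  }
  vals
}

sample_blurred_at_cones <- function(frame, pixel_deg, optics, mosaic) {
  plan <- make_blur_plan(nrow(frame), pixel_deg, optics, mosaic)
  apply_blur_plan(plan, frame, mosaic)
}

# FFT of a centered odd-sized kernel embedded in a pad x pad grid
embed_kernel_fft <- function(kern, pad) {
  m <- nrow(kern)
  big <- matrix(0, pad, pad)
  h <- (m - 1) / 2
  ix <- ((-h:h) %% pad) + 1
  big[ix, ix] <- kern
  stats::fft(big)
}

# bilinear interpolation on the padded grid; rows index y, cols x, scene
# centered at fractional index `center`
bilinear_sample <- function(img, pixel_deg, pad, center, x_deg, y_deg) {
  ry <- y_deg / pixel_deg + center
  rx <- x_deg / pixel_deg + center
  iy <- floor(ry); ix <- floor(rx)
  fy <- ry - iy; fx <- rx - ix
  idx <- function(a, b) img[cbind(a, b)]
  idx(iy, ix) * (1 - fy) * (1 - fx) +
    idx(iy + 1, ix) * fy * (1 - fx) +
    idx(iy, ix + 1) * (1 - fy) * fx +
    idx(iy + 1, ix + 1) * fy * fx
}

#' Convert cone excitations to contrast modulations
#'
#' `R = (E - E0) / E0` per cone: the background excitation is subtracted and
#' divided out, capturing the down-regulation of stimulus-driven excitation
#' by the adapted background rate.
#'
#' @param excitations A `cone_excitations` object.
#' @return Object of class `cone_modulations`: list with `R` (cone x frame),
#'   `times_ms`, `mosaic`.
#' @export
excitations_to_modulations <- function(excitations) {
  stopifnot(inherits(excitations, "cone_excitations"))
  if (any(excitations$E0 <= 0)) {
    stop("background excitation must be positive for every cone.",
         call. = FALSE)
  }
  R <- sweep(excitations$E, 1, excitations$E0, "-")
  R <- sweep(R, 1, excitations$E0, "/")
  structure(list(R = R, times_ms = excitations$times_ms,
                 mosaic = excitations$mosaic),
            class = "cone_modulations")
}

#' Build DoG cone-pooling weights on a mosaic
#'
#' Center weights follow `kc * exp(-(d_j/rc)^2)` in the multi-cone scenario
#' or place `kc` on the single cone nearest `center_position` in the
#' single-cone scenario; surround weights are `ks * exp(-(d_j/rs)^2)`.
#' Distances `d_j` are measured from the RF center position: the snapped
#' nearest cone (single-cone) or the weight-centroid of the center cones
#' (multi-cone; the centroid definition is applied by one iteration of
#' re-centering).
#'
#' @param mosaic A `cone_mosaic`.
#' @param kc,ks Center and surround peak sensitivities (>= 0).
#' @param rc_deg,rs_deg Center and surround characteristic radii, deg
#'   (`rc_deg` is ignored in the single-cone scenario).
#' @param center_position Numeric `c(x, y)` in degrees.
#' @param scenario `"single-cone"` or `"multi-cone"`.
#' @param cone_mask Optional logical vector: cones allowed to contribute
#'   (e.g. to exclude S cones); masked cones get zero weight.
#' @param recenter Multi-cone scenario only: apply one re-centering
#'   iteration (weights rebuilt around the weight centroid). Fitting uses
#'   `FALSE` so candidate positions stay fixed.
#' @return Object of class `rf_weights`: list with `wc`, `ws` (per-cone
#'   weights), `kc`, `ks`, `rc_deg`, `rs_deg`, `center_deg`, `scenario`.
#' @export
build_rf_weights <- function(mosaic, kc, ks, rc_deg = NULL, rs_deg,
                             center_position = c(0, 0),
                             scenario = c("single-cone", "multi-cone"),
                             cone_mask = NULL, recenter = TRUE) {
  scenario <- match.arg(scenario)
  if (nrow(mosaic) == 0) stop("empty mosaic.", call. = FALSE)
  if (kc < 0 || ks < 0) stop("`kc`, `ks` must be >= 0.", call. = FALSE)
  if (rs_deg <= 0) stop("`rs_deg` must be > 0.", call. = FALSE)
  mask <- if (is.null(cone_mask)) rep(TRUE, nrow(mosaic)) else cone_mask
  d2 <- (mosaic$x_deg - center_position[1])^2 +
    (mosaic$y_deg - center_position[2])^2
  if (scenario == "single-cone") {
    j <- which(mask)[which.min(d2[mask])]
    wc <- numeric(nrow(mosaic))
    wc[j] <- kc
    center <- c(mosaic$x_deg[j], mosaic$y_deg[j])
  } else {
    if (is.null(rc_deg) || rc_deg <= 0) {
      stop("`rc_deg` must be > 0 for the multi-cone scenario.", call. = FALSE)
    }
    wc <- kc * exp(-d2 / rc_deg^2) * mask
    # one re-centering iteration: centroid of the center-driving cones
    if (recenter && sum(wc) > 0) {
      center <- c(sum(wc * mosaic$x_deg), sum(wc * mosaic$y_deg)) / sum(wc)
      d2 <- (mosaic$x_deg - center[1])^2 + (mosaic$y_deg - center[2])^2
      wc <- kc * exp(-d2 / rc_deg^2) * mask
    } else {
      center <- center_position
    }
  }
  d2s <- (mosaic$x_deg - center[1])^2 + (mosaic$y_deg - center[2])^2
  ws <- ks * exp(-d2s / rs_deg^2) * mask
  structure(
    list(wc = wc, ws = ws, kc = kc, ks = ks,
         rc_deg = if (scenario == "single-cone") NA_real_ else rc_deg,
         rs_deg = rs_deg, center_deg = center, scenario = scenario),
    class = "rf_weights"
  )
}

#' Pool cone modulations into an RGC response
#'
#' `RGC(t) = sum_j Wc_j R_j(t) - sum_j Ws_j R_j(t)`; no temporal filtering
#' and no center-surround delay.
#'
#' @param modulations A `cone_modulations` object.
#' @param weights An `rf_weights` object built on the same mosaic.
#' @return Tibble with `time_ms`, `response`.
#' @export
rgc_response <- function(modulations, weights) {
  stopifnot(inherits(modulations, "cone_modulations"),
            inherits(weights, "rf_weights"))
  if (length(weights$wc) != nrow(modulations$R)) {
    stop("weights and modulations index different numbers of cones.",
         call. = FALSE)
  }
  net <- weights$wc - weights$ws
  tibble::tibble(time_ms = modulations$times_ms,
                 response = as.numeric(net %*% modulations$R))
}

#' Least-squares sinusoid fit at a fixed frequency
#'
#' Fits `A * sin(2*pi*f*t - theta) + offset` by linear least squares on the
#' sine/cosine quadratures; `f` is fixed, not fitted. The amplitude is
#' non-negative with `theta` adjusted modulo `2*pi`.
#'
#' @param time_s Sample timestamps in seconds.
#' @param values Response samples.
#' @param freq_hz Fixed frequency in Hz.
#' @return A list with `amplitude`, `phase_rad` (in `[0, 2*pi)`), `offset`.
#' @export
fit_sinusoid <- function(time_s, values, freq_hz) {
  if (length(values) < 3) stop("need at least 3 samples.", call. = FALSE)
  s <- sin(2 * pi * freq_hz * time_s)
  cc <- cos(2 * pi * freq_hz * time_s)
  co <- stats::lm.fit(cbind(s = s, c = cc, o = 1), values)$coefficients
  # a*sin + b*cos = A*sin(x - theta) with A = sqrt(a^2+b^2),
  # theta = atan2(-b, a)
  A <- sqrt(co[["s"]]^2 + co[["c"]]^2)
  theta <- atan2(-co[["c"]], co[["s"]]) %% (2 * pi)
  list(amplitude = A, phase_rad = theta, offset = co[["o"]])
}

#' Compute a model spatial transfer function
#'
#' Runs the full forward chain per spatial frequency (scene, optics, cone
#' excitations, contrast conversion, DoG pooling, fixed-frequency sinusoid
#' fit) and returns the fitted amplitude `A(omega)` and phase per frequency.
#' When a precomputed [stf_model_context()] is supplied the per-cone
#' responses are reused, which is exactly equivalent (the model is linear
#' in the weights and the sinusoid fit is linear least squares).
#'
#' @param weights An `rf_weights` built on the context's mosaic.
#' @param context An [stf_model_context()].
#' @return A tibble `freq_cpd`, `amplitude`, `phase_rad` of class
#'   `model_stf`.
#' @export
compute_model_stf <- function(weights, context) {
  stopifnot(inherits(context, "stf_model_context"),
            inherits(weights, "rf_weights"))
  net <- weights$wc - weights$ws
  zc <- net %*% context$zeta               # complex quadratures per frequency
  amp <- Mod(zc)[1, ]
  # zeta = a + i*b with series ~ a*sin + b*cos = A*sin(x - theta)
  ph <- atan2(-Im(zc)[1, ], Re(zc)[1, ]) %% (2 * pi)
  out <- tibble::tibble(freq_cpd = context$frequencies,
                        amplitude = amp, phase_rad = ph)
  class(out) <- c("model_stf", class(out))
  out
}

#' Precompute per-cone frequency responses for STF modeling
#'
#' Runs the image-based forward model once per spatial frequency: drifting
#' grating scenes are blurred by the optics, converted to cone contrast
#' modulations, and each cone's temporal trace is reduced to a complex
#' quadrature amplitude at the drift frequency via the linear sinusoid fit.
#' DoG model STFs for any pooling weights then follow by linear combination
#' ([compute_model_stf()]), which makes the multi-start fit tractable.
#'
#' @param mosaic A `cone_mosaic`.
#' @param optics An `optical_transfer`.
#' @param frequencies Spatial frequencies in c/deg; default 14 log-spaced
#'   values over 4-49 c/deg (the measured design is not published).
#' @param spec_template A [grating_spec()] providing all non-frequency
#'   stimulus parameters.
#' @param media Optional [ocular_media()].
#' @return Object of class `stf_model_context`: list with `zeta` (complex
#'   matrix cone x frequency: per-cone quadrature amplitude of `R_j(t)`),
#'   `frequencies`, `mosaic`, `optics`, `spec_template`.
#' @export
stf_model_context <- function(mosaic, optics,
                              frequencies = default_stf_frequencies(),
                              spec_template = grating_spec(),
                              media = NULL) {
  zeta <- matrix(0 + 0i, nrow(mosaic), length(frequencies))
  for (i in seq_along(frequencies)) {
    spec <- spec_template
    spec$spatial_frequency_cpd <- frequencies[i]
    scene <- make_grating_sequence(spec)
    exc <- compute_excitations(scene, optics, mosaic, media)
    mods <- excitations_to_modulations(exc)
    t_s <- mods$times_ms / 1000
    s <- sin(2 * pi * spec$temporal_frequency_hz * t_s)
    cc <- cos(2 * pi * spec$temporal_frequency_hz * t_s)
    X <- cbind(s, cc, 1)
    coefs <- qr.coef(qr(X), t(mods$R))   # 3 x ncone
    zeta[, i] <- complex(real = coefs[1, ], imaginary = coefs[2, ])
  }
  structure(
    list(zeta = zeta, frequencies = frequencies, mosaic = mosaic,
         optics = optics, spec_template = spec_template),
    class = "stf_model_context"
  )
}

#' Default spatial frequency grid for STF work
#'
#' 14 log-spaced frequencies over 4-49 c/deg.
#' @return Numeric vector of frequencies in c/deg.
#' @export
default_stf_frequencies <- function() {
  exp(seq(log(4), log(49), length.out = 14))
}

#' Closed-form DoG x optics x aperture STF amplitude
#'
#' Analytic oracle for the image-based pipeline: for Gaussian center and
#' surround pooling over a mosaic of effective density `rho` (cones per
#' square degree), an optical MTF `M(omega)` and Gaussian cone apertures of
#' characteristic radius `r_ap`, the drifting-grating response amplitude is
#' `contrast * M(w) * exp(-(pi*r_ap*w)^2) * |kc*pi*rc^2*exp(-(pi*rc*w)^2) -
#' ks*pi*rs^2*exp(-(pi*rs*w)^2)| * rho` (the single-cone center contributes
#' `kc` without the density or center-Gaussian factor).
#'
#' @param freq_cpd Frequencies, c/deg.
#' @param kc,ks,rc_deg,rs_deg DoG parameters.
#' @param optics An `optical_transfer` (its radial MTF is used), or `NULL`
#'   for unity MTF.
#' @param aperture_deg Cone aperture characteristic radius, deg.
#' @param density_deg2 Effective cone density, cones per deg^2 (used for the
#'   surround and, in the multi-cone scenario, the center); see
#'   [effective_density()].
#' @param contrast Grating contrast.
#' @param scenario `"multi-cone"` or `"single-cone"`.
#' @param density_center_deg2 Optional separate density for the center term.
#' @return Amplitude values (same scale as [compute_model_stf()]).
#' @export
analytic_dog_stf <- function(freq_cpd, kc, ks, rc_deg, rs_deg, optics = NULL,
                             aperture_deg = 0, density_deg2 = 1, contrast = 1,
                             scenario = c("multi-cone", "single-cone"),
                             density_center_deg2 = density_deg2) {
  scenario <- match.arg(scenario)
  M <- if (is.null(optics)) rep(1, length(freq_cpd)) else mtf_at(optics, freq_cpd)
  apM <- exp(-(pi * aperture_deg * freq_cpd)^2)
  ctr <- if (scenario == "multi-cone") {
    density_center_deg2 * kc * pi * rc_deg^2 * exp(-(pi * rc_deg * freq_cpd)^2)
  } else {
    rep(kc, length(freq_cpd))
  }
  sur <- density_deg2 * ks * pi * rs_deg^2 * exp(-(pi * rs_deg * freq_cpd)^2)
  contrast * M * apM * abs(ctr - sur)
}

#' Moment-matched analytic STF prediction on a mosaic
#'
#' Evaluates the closed-form DoG x optics-MTF x aperture-MTF product with
#' the Gaussian center/surround parameters moment-matched to the actual
#' cone mosaic: the effective radius of each mechanism is the square root of
#' its weighted mean squared cone distance and the effective density is set
#' so the zero-frequency (integrated) weight matches the discrete sum.
#' On a homogeneous mosaic these reduce to the nominal values; on an
#' eccentricity-dependent mosaic they absorb the first-order effect of
#' density inhomogeneity, which the plain continuum formula misses.
#'
#' @param freq_cpd Frequencies, c/deg.
#' @param weights An `rf_weights` (provides parameters, scenario, center).
#' @param mosaic The `cone_mosaic` the weights were built on.
#' @param optics An `optical_transfer` or `NULL`.
#' @param contrast Grating contrast.
#' @return Amplitude values comparable with [compute_model_stf()].
#' @export
analytic_stf_oracle <- function(freq_cpd, weights, mosaic, optics = NULL,
                                contrast = 1) {
  stopifnot(inherits(weights, "rf_weights"))
  upd <- attr(mosaic, "um_per_deg")
  ctr <- weights$center_deg
  d2 <- (mosaic$x_deg - ctr[1])^2 + (mosaic$y_deg - ctr[2])^2
  eff <- function(r) {
    g <- exp(-d2 / r^2)
    r_eff <- sqrt(sum(g * d2) / sum(g))
    rho_eff <- sum(g) / (pi * r_eff^2)
    list(r = r_eff, rho = rho_eff)
  }
  M <- if (is.null(optics)) rep(1, length(freq_cpd)) else mtf_at(optics, freq_cpd)
  ap <- exp(-(pi * mean(mosaic$aperture_um) / upd * freq_cpd)^2)
  s <- eff(weights$rs_deg)
  sur <- s$rho * weights$ks * pi * s$r^2 * exp(-(pi * s$r * freq_cpd)^2)
  cen <- if (weights$scenario == "single-cone") {
    rep(weights$kc, length(freq_cpd))
  } else {
    cc <- eff(weights$rc_deg)
    cc$rho * weights$kc * pi * cc$r^2 * exp(-(pi * cc$r * freq_cpd)^2)
  }
  contrast * M * ap * abs(cen - sur)
}

#' Gaussian-weighted effective cone density around a point
#'
#' The quadrature-weight density `sum_j exp(-d_j^2 / r^2) / (pi r^2)` in
#' cones per square degree: the constant by which a discrete Gaussian-pooled
#' sum over the mosaic approximates the continuum integral. Used to set the
#' density factor of the analytic STF oracle.
#'
#' @param mosaic A `cone_mosaic`.
#' @param center `c(x, y)` in degrees.
#' @param radius_deg Gaussian characteristic radius of the pooling, deg.
#' @return Density in cones per deg^2.
#' @export
effective_density <- function(mosaic, center = c(0, 0), radius_deg) {
  d2 <- (mosaic$x_deg - center[1])^2 + (mosaic$y_deg - center[2])^2
  sum(exp(-d2 / radius_deg^2)) / (pi * radius_deg^2)
}
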