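#' Drifting-grating stimulus specification
#'
#' Defaults reproduce the adaptive-optics stimulation conditions: a
#' monochromatic (561 nm, 5 nm FWHM) horizontally-oriented sinusoidal grating
#' at 100% contrast drifting at 6 Hz, displayed at 25.3 Hz for 666 ms
#' (4 cycles) over a 0.7 deg field with 0.005 deg pixels and a mean retinal
#' irradiance of 1.29 mW/cm^2. Horizontal orientation means the bars vary
#' along y (the grating drifts vertically).
#'
#' @param spatial_frequency_cpd Spatial frequency in c/deg.
#' @param temporal_frequency_hz Drift temporal frequency in Hz.
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param peak_wavelength_nm,fwhm_nm Gaussian spectral profile of the beam.
#' @param mean_irradiance Mean retinal irradiance, mW/cm^2.
#' @param extent_deg Square field width, deg.
#' @param pixel_deg Pixel size, deg.
#' @param refresh_hz Display refresh rate, Hz.
#' @param duration_ms Stimulus duration, ms.
#' @param spectrum Either `"gaussian"` (monochromatic beam) or `"flat"`
#'   (achromatic, equal radiance across the wavelength grid).
#' @param wavelength_nm Wavelength sampling grid, nm.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(spatial_frequency_cpd = 10,
                         temporal_frequency_hz = 6,
                         contrast = 1.0,
                         peak_wavelength_nm = 561, fwhm_nm = 5,
                         mean_irradiance = 1.29,
                         extent_deg = 0.7, pixel_deg = 0.005,
                         refresh_hz = 25.3, duration_ms = 666,
                         spectrum = c("gaussian", "flat"),
                         wavelength_nm = seq(400, 700, by = 5)) {
  spectrum <- match.arg(spectrum)
  if (contrast < 0 || contrast > 1) {
    stop("`contrast` must lie in [0, 1].", call. = FALSE)
  }
  structure(
    list(spatial_frequency_cpd = spatial_frequency_cpd,
         temporal_frequency_hz = temporal_frequency_hz,
         contrast = contrast,
         peak_wavelength_nm = peak_wavelength_nm, fwhm_nm = fwhm_nm,
         mean_irradiance = mean_irradiance,
         extent_deg = extent_deg, pixel_deg = pixel_deg,
         refresh_hz = refresh_hz, duration_ms = duration_ms,
         spectrum = spectrum, wavelength_nm = wavelength_nm),
    class = "grating_spec"
  )
}

#' Number of frames and frame duration of a grating spec
#'
#' Frame count is `round(duration * refresh / 1000)` (round to nearest, which
#' preserves the 4 drift cycles at the defaults); frame duration is
#' `1000 / refresh` ms.
#'
#' @param spec A [grating_spec()].
#' @return A list with `n_frames`, `frame_duration_ms`, `n_cycles`.
#' @export
grating_timing <- function(spec) {
  list(
    n_frames = round(spec$duration_ms * spec$refresh_hz / 1000),
    frame_duration_ms = 1000 / spec$refresh_hz,
    n_cycles = round(spec$duration_ms / 1000 * spec$temporal_frequency_hz)
  )
}

# spectral radiance profile of the spec, unit integral over the grid
spec_spectral_profile <- function(spec) {
  wl <- spec$wavelength_nm
  if (spec$spectrum == "flat") {
    p <- rep(1, length(wl))
  } else {
    sigma <- spec$fwhm_nm / (2 * sqrt(2 * log(2)))
    p <- exp(-(wl - spec$peak_wavelength_nm)^2 / (2 * sigma^2))
  }
  p / sum(p)
}

#' Generate a drifting-grating scene sequence
#'
#' Each frame is `mean_irradiance * (1 + contrast * sin(2*pi*(omega*y - f*t)))`
#' where `t` is the frame-center timestamp, distributed spectrally over the
#' beam profile. Scenes are stored in separable form: a list of spatial
#' frames plus one spectral profile (exact for space-independent spectra).
#'
#' @param spec A [grating_spec()].
#' @return A `scene_sequence`: list with `frames` (list of matrices, rows =
#'   y from bottom up, columns = x), `pixel_deg`, `frame_duration_ms`,
#'   `times_ms` (frame centers), `wavelength_nm`, `spectral_profile`
#'   (unit sum), `mean_level`, and the generating `spec`.
#' @export
make_grating_sequence <- function(spec) {
  stopifnot(inherits(spec, "grating_spec"))
  nyq <- 1 / (2 * spec$pixel_deg)
  if (spec$spatial_frequency_cpd > nyq) {
    stop(sprintf("spatial frequency %.1f c/deg exceeds the %.1f c/deg raster Nyquist",
                 spec$spatial_frequency_cpd, nyq), call. = FALSE)
  }
  tm <- grating_timing(spec)
  n_px <- round(spec$extent_deg / spec$pixel_deg)
  yv <- (seq_len(n_px) - (n_px + 1) / 2) * spec$pixel_deg
  times <- (seq_len(tm$n_frames) - 0.5) * tm$frame_duration_ms
  f <- spec$temporal_frequency_hz
  om <- spec$spatial_frequency_cpd
  frames <- purrr::map(times, function(t_ms) {
    phase <- 2 * pi * (om * yv - f * t_ms / 1000)
    col <- spec$mean_irradiance * (1 + spec$contrast * sin(phase))
    matrix(col, nrow = n_px, ncol = n_px)
  })
  structure(
    list(frames = frames, pixel_deg = spec$pixel_deg,
         frame_duration_ms = tm$frame_duration_ms, times_ms = times,
         wavelength_nm = spec$wavelength_nm,
         spectral_profile = spec_spectral_profile(spec),
         mean_level = spec$mean_irradiance, spec = spec),
    class = "scene_sequence"
  )
}

#' Generate the uniform background scene
#'
#' A spatially uniform field at the mean irradiance with the same spectral
#' profile; equal to [make_grating_sequence()] at contrast 0 (one frame).
#'
#' @param spec A [grating_spec()].
#' @return A one-frame `scene_sequence`.
#' @export
make_background <- function(spec) {
  stopifnot(inherits(spec, "grating_spec"))
  tm <- grating_timing(spec)
  n_px <- round(spec$extent_deg / spec$pixel_deg)
  structure(
    list(frames = list(matrix(spec$mean_irradiance, n_px, n_px)),
         pixel_deg = spec$pixel_deg,
         frame_duration_ms = tm$frame_duration_ms,
         times_ms = tm$frame_duration_ms / 2,
         wavelength_nm = spec$wavelength_nm,
         spectral_profile = spec_spectral_profile(spec),
         mean_level = spec$mean_irradiance, spec = spec),
    class = "scene_sequence"
  )
}

#' LED primary set for chromatic flicker stimulation
#'
#' Gaussian spectral radiance shapes; defaults are the three stimulation LEDs
#' (420/7, 530/17, 660/10 nm center/FWHM).
#'
#' @param centers_nm,fwhms_nm Center wavelengths and FWHMs, nm.
#' @param max_power Per-primary maximum power (arbitrary units).
#' @param wavelength_nm Wavelength grid.
#' @return Object of class `primary_set`: list with `spectra` (matrix
#'   wavelength x primary, each column peak-scaled to `max_power`),
#'   `wavelength_nm`, `centers_nm`.
#' @export
primary_set <- function(centers_nm = c(420, 530, 660),
                        fwhms_nm = c(7, 17, 10),
                        max_power = rep(1, length(centers_nm)),
                        wavelength_nm = seq(400, 700, by = 5)) {
  stopifnot(length(centers_nm) == length(fwhms_nm))
  spectra <- vapply(seq_along(centers_nm), function(i) {
    sigma <- fwhms_nm[i] / (2 * sqrt(2 * log(2)))
    s <- exp(-(wavelength_nm - centers_nm[i])^2 / (2 * sigma^2))
    s / sum(s) * max_power[i]
  }, numeric(length(wavelength_nm)))
  structure(list(spectra = spectra, wavelength_nm = wavelength_nm,
                 centers_nm = centers_nm),
            class = "primary_set")
}

# cone-class x primary excitation matrix around a background of half-maximum
# primary power; entries are cone contrasts per unit primary modulation.
cone_contrast_matrix <- function(primaries, fundamentals, background = NULL) {
  stopifnot(inherits(primaries, "primary_set"))
  F <- vapply(fundamentals, function(f) {
    if (!isTRUE(all.equal(f$wavelength_nm, primaries$wavelength_nm))) {
      stop("fundamentals and primaries must share a wavelength grid.",
           call. = FALSE)
    }
    f$sensitivity
  }, numeric(length(primaries$wavelength_nm)))
  M <- t(F) %*% primaries$spectra        # class x primary excitations per unit power
  if (is.null(background)) background <- rep(0.5, ncol(M))
  e0 <- as.numeric(M %*% background)
  if (any(e0 <= 0)) stop("background produces zero excitation for a cone class",
                         call. = FALSE)
  sweep(M * rep(background, each = nrow(M)), 1, e0, "/")
}

#' Solve a silent-substitution stimulus
#'
#' Finds sinusoidal primary modulation depths (relative to a mean background
#' at half-maximum primary power) that null cone contrast on the silenced
#' classes and maximize contrast on the target classes within the unit
#' modulation gamut (`|m| <= 1` per primary). The direction is the projection
#' of the summed target-contrast gradient onto the null space of the silenced
#' constraints, scaled to the gamut boundary.
#'
#' @param primaries A [primary_set()].
#' @param fundamentals Named list of [cone_fundamental()] tibbles; names are
#'   the cone classes.
#' @param target Character vector of class names to maximize.
#' @param silence Character vector of class names to null.
#' @param frequency_hz Flicker frequency (metadata).
#' @param background Background primary powers (fractions of maximum);
#'   default half-maximum on every primary.
#' @param contrast_matrix Optional precomputed class-by-primary cone-contrast
#'   matrix (row names are class names); when supplied, `primaries` and
#'   `fundamentals` may be `NULL`.
#' @return Object of class `flicker_stimulus`: list with `modulation`
#'   (per-primary depths in `[-1, 1]`), `achieved_contrasts` (named, per
#'   class), `target`, `silence`, `frequency_hz`.
#' @export
silent_substitution <- function(primaries, fundamentals, target, silence,
                                frequency_hz = 0.15, background = NULL,
                                contrast_matrix = NULL) {
  if (is.null(contrast_matrix)) {
    classes <- names(fundamentals)
    B <- cone_contrast_matrix(primaries, fundamentals, background)
    rownames(B) <- classes
  } else {
    B <- contrast_matrix
    classes <- rownames(B)
  }
  stopifnot(all(target %in% classes), all(silence %in% classes))
  n_p <- ncol(B)
  if (length(silence) + 1 > n_p && length(silence) >= n_p) {
    stop("more silenced classes than primaries allow", call. = FALSE)
  }
  S <- B[silence, , drop = FALSE]
  if (length(silence) > 0 && qr(S)$rank < nrow(S)) {
    stop(sprintf("silencing constraints are rank deficient (rank %d < %d)",
                 qr(S)$rank, nrow(S)), call. = FALSE)
  }
  # orthonormal basis of the null space of S
  if (length(silence) > 0) {
    qrS <- qr(t(S))
    Qfull <- qr.Q(qrS, complete = TRUE)
    N <- Qfull[, seq(nrow(S) + 1, n_p), drop = FALSE]
  } else {
    N <- diag(n_p)
  }
  if (ncol(N) == 0) stop("no modulation direction nulls all silenced classes",
                         call. = FALSE)
  g <- colSums(B[target, , drop = FALSE])     # target contrast gradient
  dir <- as.numeric(N %*% (t(N) %*% g))
  if (max(abs(dir)) < 1e-12) {
    stop("target contrast is unreachable within the silenced null space",
         call. = FALSE)
  }
  m <- dir / max(abs(dir))                    # scale to gamut |m| <= 1
  achieved <- as.numeric(B %*% m)
  names(achieved) <- classes
  structure(
    list(modulation = m, achieved_contrasts = achieved,
         target = target, silence = silence, frequency_hz = frequency_hz,
         contrast_matrix = B),
    class = "flicker_stimulus"
  )
}

#' Luminous efficiency from L and M fundamentals
#'
#' Equal weighting of the L and M cone fundamentals (macaque L:M ratio is
#' close to unity), peak-normalized.
#'
#' @param L_fund,M_fund [cone_fundamental()] tibbles on a shared grid.
#' @return A tibble `wavelength_nm`, `sensitivity` with peak 1.
#' @export
luminous_efficiency <- function(L_fund, M_fund) {
  if (!isTRUE(all.equal(L_fund$wavelength_nm, M_fund$wavelength_nm))) {
    stop("fundamentals must share a wavelength grid.", call. = FALSE)
  }
  v <- 0.5 * L_fund$sensitivity + 0.5 * M_fund$sensitivity
  tibble::tibble(wavelength_nm = L_fund$wavelength_nm,
                 sensitivity = v / max(v))
}

#' @export
print.scene_sequence <- function(x, ...) {
  cat("<scene_sequence>", length(x$frames), "frames of",
      nrow(x$frames[[1]]), "x", ncol(x$frames[[1]]), "px at",
      x$pixel_deg, "deg/px,", round(x$frame_duration_ms, 2), "ms/frame\n")
  invisible(x)
}
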