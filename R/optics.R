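#' Eye geometry: axial length and retinal magnification
#'
#' The conversion between degrees of visual angle and retinal extent scales
#' linearly with axial length relative to a model human eye (24.2 mm axial
#' length, 291.2 um/deg).
#'
#' @param axial_length_mm Axial length of the eye in mm (> 0).
#' @return For [retinal_magnification()], the retinal magnification in
#'   micrometers per degree of visual angle. For [eye_geometry()], an object
#'   of class `eye_geometry` with fields `axial_length_mm` and `um_per_deg`.
#' @examples
#' retinal_magnification(16.56) # ~199 um/deg (macaque foveal imaging eye)
#' retinal_magnification(24.2)  # 291.2, the model human value
#' @export
retinal_magnification <- function(axial_length_mm) {
  if (!is.numeric(axial_length_mm) || any(axial_length_mm <= 0)) {
    stop("`axial_length_mm` must be positive.", call. = FALSE)
  }
  291.2 * axial_length_mm / 24.2
}

#' @rdname retinal_magnification
#' @export
eye_geometry <- function(axial_length_mm = 16.56) {
  structure(
    list(
      axial_length_mm = axial_length_mm,
      um_per_deg = retinal_magnification(axial_length_mm)
    ),
    class = "eye_geometry"
  )
}

#' Pupil and wavefront specification
#'
#' Describes the exit pupil and residual wave aberrations used to compute the
#' point spread function. Zernike terms use the OSA/ANSI double-index
#' convention `(n, m)` with coefficients in micrometers RMS; the defocus term
#' is `(2, 0)`. An empty term list is diffraction limited.
#'
#' @param diameter_mm Pupil diameter in mm (> 0). Default 6.7, the dilated
#'   pupil used during adaptive-optics stimulation.
#' @param wavelength_nm Imaging/stimulation wavelength in nm. Default 561.
#' @param defocus_D Residual defocus in diopters, converted internally to a
#'   Zernike (2, 0) coefficient and added to `zernike`.
#' @param zernike A data frame with columns `n`, `m`, `coeff_um` giving
#'   additional Zernike terms, or `NULL`.
#' @return An object of class `pupil_spec`.
#' @export
pupil_spec <- function(diameter_mm = 6.7, wavelength_nm = 561,
                       defocus_D = 0, zernike = NULL) {
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive.", call. = FALSE)
  if (wavelength_nm <= 0) stop("`wavelength_nm` must be positive.", call. = FALSE)
  terms <- if (is.null(zernike)) {
    tibble::tibble(n = integer(), m = integer(), coeff_um = numeric())
  } else {
    stopifnot(all(c("n", "m", "coeff_um") %in% names(zernike)))
    tibble::as_tibble(zernike[, c("n", "m", "coeff_um")])
  }
  if (defocus_D != 0) {
    terms <- dplyr::bind_rows(
      terms,
      tibble::tibble(n = 2L, m = 0L,
                     coeff_um = defocus_to_zernike(defocus_D, diameter_mm))
    )
  }
  structure(
    list(diameter_mm = diameter_mm, wavelength_nm = wavelength_nm,
         defocus_D = defocus_D, zernike = terms),
    class = "pupil_spec"
  )
}

#' Convert defocus in diopters to a Zernike defocus coefficient
#'
#' Uses the standard relation `c = D * a^2 / (4 * sqrt(3))` with `a` the pupil
#' radius in mm, giving the OSA/ANSI-normalized (2, 0) coefficient in
#' micrometers RMS. Positive diopters map to positive coefficients; the same
#' convention is used when building the pupil function, so only consistency
#' (not the absolute sign) affects the rotationally symmetric PSFs modeled
#' here.
#'
#' @param defocus_D Defocus in diopters.
#' @param pupil_diameter_mm Pupil diameter in mm (> 0).
#' @return Zernike (2, 0) coefficient in micrometers RMS.
#' @examples
#' defocus_to_zernike(0.067, 6.7)
#' @export
defocus_to_zernike <- function(defocus_D, pupil_diameter_mm) {
  if (any(pupil_diameter_mm <= 0)) {
    stop("`pupil_diameter_mm` must be positive.", call. = FALSE)
  }
  defocus_D * (pupil_diameter_mm / 2)^2 / (4 * sqrt(3))
}

# Zernike radial polynomial R_n^|m|(rho), OSA/ANSI normalization applied in
# zernike_eval(). rho may be a vector/matrix.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  if ((n - m) %% 2 != 0) return(rho * 0)
  k <- 0:((n - m) / 2)
  out <- rho * 0
  for (kk in k) {
    coef <- (-1)^kk * factorial(n - kk) /
      (factorial(kk) * factorial((n + m) / 2 - kk) * factorial((n - m) / 2 - kk))
    out <- out + coef * rho^(n - 2 * kk)
  }
  out
}

# Normalized Zernike polynomial Z_n^m at polar (rho, theta), unit RMS over the
# unit disk (OSA/ANSI).
zernike_eval <- function(n, m, rho, theta) {
  norm <- sqrt(2 * (n + 1) / (1 + as.numeric(m == 0)))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * zernike_radial(n, m, rho) * ang
}

#' Compute the point spread function and modulation transfer function
#'
#' Models the eye as a circular-aperture optical system with the supplied
#' wavefront aberrations. The PSF is `|FT(pupil function)|^2` normalized to
#' unit sum on a grid of visual angle; the MTF is the magnitude of the PSF's
#' Fourier transform, normalized to 1 at zero frequency.
#'
#' The PSF grid must resolve the incoherent cutoff frequency
#' `d/lambda * pi/180` c/deg; the default 0.0012 deg pixel resolves the
#' 208.4 c/deg cutoff of a 6.7 mm pupil at 561 nm with margin.
#'
#' @param pupil A [pupil_spec()].
#' @param geometry An [eye_geometry()] (carried for unit conversions
#'   downstream; the PSF itself is expressed in degrees of visual angle).
#' @param psf_pixel_deg PSF pixel size in degrees of visual angle.
#' @param pupil_samples Number of samples across the pupil diameter.
#' @return An object of class `optical_transfer`: list with `psf` (matrix,
#'   unit sum), `pixel_deg`, `mtf` (tibble `freq_cpd`, `mtf` -- the radial
#'   average), `otf` (full 2-D complex OTF, fftshifted so DC is centered),
#'   `freq_axis_cpd`, and provenance fields.
#' @export
compute_psf_mtf <- function(pupil, geometry = eye_geometry(),
                            psf_pixel_deg = 0.0012, pupil_samples = 128) {
  stopifnot(inherits(pupil, "pupil_spec"))
  lambda_mm <- pupil$wavelength_nm * 1e-6
  d_mm <- pupil$diameter_mm
  cutoff_cpd <- d_mm / lambda_mm * pi / 180
  nyquist_cpd <- 1 / (2 * psf_pixel_deg)
  if (nyquist_cpd <= cutoff_cpd) {
    stop(sprintf(
      paste0("PSF grid undersampled: pixel %.5f deg gives Nyquist %.1f c/deg ",
             "but the incoherent cutoff is %.1f c/deg; use a pixel smaller ",
             "than %.5f deg."),
      psf_pixel_deg, nyquist_cpd, cutoff_cpd, 1 / (2 * cutoff_cpd)
    ), call. = FALSE)
  }
  # Pupil-plane sampling delta such that the PSF angular pixel is
  # lambda / (N * delta): choose N from the required padding.
  theta_rad <- psf_pixel_deg * pi / 180
  array_mm <- lambda_mm / theta_rad      # physical size of the pupil array
  n_fft <- 2^ceiling(log2(max(array_mm / d_mm * pupil_samples,
                              2 * pupil_samples))) * 2L
  delta_mm <- array_mm / n_fft
  half <- n_fft / 2
  ax <- (seq_len(n_fft) - half - 1) * delta_mm
  rho2 <- outer(ax^2, ax^2, "+")
  rho <- sqrt(rho2) / (d_mm / 2)
  inside <- rho <= 1
  opd_um <- matrix(0, n_fft, n_fft)   # wavefront error in um
  if (nrow(pupil$zernike) > 0) {
    X <- matrix(ax, n_fft, n_fft)
    Y <- matrix(ax, n_fft, n_fft, byrow = TRUE)
    theta <- atan2(Y, X)
    for (i in seq_len(nrow(pupil$zernike))) {
      zr <- pupil$zernike[i, ]
      opd_um <- opd_um + zr$coeff_um *
        zernike_eval(zr$n, zr$m, pmin(rho, 1), theta)
    }
  }
  lambda_um <- pupil$wavelength_nm * 1e-3
  pupil_fun <- matrix(0 + 0i, n_fft, n_fft)
  pupil_fun[inside] <- exp(2i * pi * opd_um[inside] / lambda_um)
  field <- stats::fft(pupil_fun)
  psf <- Matrix_shift(Mod(field)^2)
  psf <- psf / sum(psf)
  # MTF: FFT of PSF. DC at [1,1] after inverse shift.
  otf <- stats::fft(Matrix_ishift(psf))
  otf <- otf / Re(otf[1, 1])
  otf_sh <- Matrix_shift(otf)
  freq_axis <- (seq_len(n_fft) - half - 1) / (n_fft * psf_pixel_deg)
  mtf2 <- Mod(otf_sh)
  fr <- sqrt(outer(freq_axis^2, freq_axis^2, "+"))
  keep <- fr <= min(1.2 * cutoff_cpd, max(freq_axis))
  br <- seq(0, max(fr[keep]) + 1, by = 1)
  bin <- findInterval(fr[keep], br)
  mtf_rad <- tapply(mtf2[keep], bin, mean)
  freq_rad <- tapply(fr[keep], bin, mean)
  structure(
    list(
      psf = psf, pixel_deg = psf_pixel_deg,
      otf = otf_sh, freq_axis_cpd = freq_axis,
      mtf = tibble::tibble(freq_cpd = c(0, as.numeric(freq_rad)),
                           mtf = c(1, as.numeric(mtf_rad))),
      cutoff_cpd = cutoff_cpd,
      kind = "pupil", pupil = pupil, geometry = geometry
    ),
    class = "optical_transfer"
  )
}

# fftshift / ifftshift for square matrices
Matrix_shift <- function(m) {
  n <- nrow(m); h <- floor(n / 2)
  m[c((h + 1):n, 1:h), c((h + 1):n, 1:h)]
}
Matrix_ishift <- function(m) {
  n <- nrow(m); h <- ceiling(n / 2)
  m[c((h + 1):n, 1:h), c((h + 1):n, 1:h)]
}

#' Analytic diffraction-limited MTF of a circular aperture
#'
#' Reference formula `(2/pi) * (acos(v) - v * sqrt(1 - v^2))` with
#' `v = f / f_cutoff`, used as an independent oracle for [compute_psf_mtf()].
#'
#' @param freq_cpd Spatial frequency in c/deg.
#' @param diameter_mm Pupil diameter in mm.
#' @param wavelength_nm Wavelength in nm.
#' @return MTF values in `[0, 1]`.
#' @export
diffraction_mtf <- function(freq_cpd, diameter_mm = 6.7, wavelength_nm = 561) {
  cutoff <- diameter_mm / (wavelength_nm * 1e-6) * pi / 180
  v <- pmin(pmax(freq_cpd / cutoff, 0), 1)
  (2 / pi) * (acos(v) - v * sqrt(1 - v^2))
}

#' Gaussian-blur reference optics
#'
#' A hypothetical optical system whose PSF is an isotropic Gaussian
#' `exp(-(r/rho)^2)` with characteristic radius `rho` in degrees; its MTF is
#' `exp(-(pi * rho * f)^2)`. `rho = 0` is a delta PSF (MTF identically 1).
#'
#' @param characteristic_radius_deg Gaussian PSF characteristic radius in
#'   degrees of visual angle (>= 0).
#' @param psf_pixel_deg PSF grid pixel in degrees.
#' @param support_deg Full width of the PSF grid in degrees.
#' @return An `optical_transfer` object (see [compute_psf_mtf()]).
#' @export
gaussian_optics <- function(characteristic_radius_deg,
                            psf_pixel_deg = 0.0012, support_deg = 0.12) {
  rho <- characteristic_radius_deg
  if (rho < 0) stop("`characteristic_radius_deg` must be >= 0.", call. = FALSE)
  n <- 2 * floor(support_deg / psf_pixel_deg / 2) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * psf_pixel_deg
  if (rho == 0) {
    psf <- matrix(0, n, n)
    psf[(n + 1) / 2, (n + 1) / 2] <- 1
  } else {
    r2 <- outer(ax^2, ax^2, "+")
    psf <- exp(-r2 / rho^2)
    psf <- psf / sum(psf)
  }
  fgrid <- seq(0, 300, by = 1)
  structure(
    list(
      psf = psf, pixel_deg = psf_pixel_deg,
      otf = NULL, freq_axis_cpd = NULL,
      mtf = tibble::tibble(freq_cpd = fgrid, mtf = exp(-(pi * rho * fgrid)^2)),
      cutoff_cpd = Inf,
      kind = if (rho == 0) "delta" else "gaussian",
      characteristic_radius_deg = rho
    ),
    class = "optical_transfer"
  )
}

#' Evaluate the (radial) MTF of an optical transfer object
#'
#' @param optics An `optical_transfer`.
#' @param freq_cpd Frequencies in c/deg.
#' @return MTF values, linearly interpolated from the radial MTF table
#'   (analytic for Gaussian/delta optics).
#' @export
mtf_at <- function(optics, freq_cpd) {
  stopifnot(inherits(optics, "optical_transfer"))
  if (optics$kind == "delta") return(rep(1, length(freq_cpd)))
  if (optics$kind == "gaussian") {
    return(exp(-(pi * optics$characteristic_radius_deg * freq_cpd)^2))
  }
  stats::approx(optics$mtf$freq_cpd, optics$mtf$mtf, xout = freq_cpd,
                rule = 2)$y
}

# Bin (integrate) a PSF onto a coarser raster with pixel `pixel_deg`, centered,
# returning an odd-sized kernel that sums to 1. Used to apply optics on the
# stimulus raster without undersampling the pupil transform.
psf_on_raster <- function(optics, pixel_deg, support_deg = NULL) {
  psf <- optics$psf
  p <- optics$pixel_deg
  n <- nrow(psf)
  ax <- (seq_len(n) - (n + 1 + (n %% 2 == 0)) / 2) * p
  if (optics$kind == "delta") {
    return(matrix(1, 1, 1))
  }
  half_extent <- max(abs(ax))
  if (is.null(support_deg)) support_deg <- 2 * half_extent
  m <- 2 * floor(min(support_deg, 2 * half_extent) / (2 * pixel_deg)) + 1
  # index of coarse pixel for each fine pixel
  ix <- round(ax / pixel_deg)
  keep <- abs(ix) <= (m - 1) / 2
  idx <- ix[keep] + (m + 1) / 2
  sub <- psf[keep, keep, drop = FALSE]
  agg <- matrix(0, m, m)
  grp <- outer(idx, idx, function(a, b) (a - 1) * m + b)
  sums <- tapply(as.numeric(sub), as.numeric(grp), sum)
  agg[as.integer(names(sums))] <- sums
  agg / sum(agg)
}

#' @export
print.optical_transfer <- function(x, ...) {
  cat("<optical_transfer>", x$kind, "\n")
  if (!is.null(x$psf)) {
    cat("  PSF:", nrow(x$psf), "x", ncol(x$psf), "px at",
        x$pixel_deg, "deg/px\n")
  }
  if (is.finite(x$cutoff_cpd)) cat("  cutoff:", round(x$cutoff_cpd, 1), "c/deg\n")
  invisible(x)
}
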