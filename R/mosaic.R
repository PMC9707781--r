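#' Gaussian entrance-aperture characteristic radius of a cone
#'
#' Cones act as Gaussian apertures with characteristic radius
#' `0.204 * sqrt(2) * D`, where `D` is the inner-segment diameter.
#'
#' @param diameter_um Inner-segment diameter in micrometers (>= 0).
#' @return Characteristic radius in micrometers.
#' @examples
#' aperture_radius(2.07)
#' @export
aperture_radius <- function(diameter_um) {
  if (any(diameter_um < 0)) stop("`diameter_um` must be >= 0.", call. = FALSE)
  0.204 * sqrt(2) * diameter_um
}

# Hexagonal spacing (um) for a density in cones/mm^2: area per cone is
# sqrt(3)/2 * s^2 for a hex lattice.
hex_spacing_um <- function(density_mm2) sqrt(2 / (sqrt(3) * density_mm2)) * 1e3

#' Default eccentricity-dependent cone density profile
#'
#' Radially symmetric density falling from the foveal peak to roughly
#' 150,000 cones/mm^2 at 0.65 deg, linearly interpolated and held constant
#' beyond; only the peak value is well constrained by imaging, the falloff
#' approximates published foveal density curves.
#'
#' @param peak_density_mm2 Density at the foveal center in cones/mm^2.
#' @return A function mapping eccentricity in degrees to density in
#'   cones/mm^2.
#' @export
default_density_falloff <- function(peak_density_mm2 = 270200) {
  function(ecc_deg) {
    frac <- stats::approx(c(0, 0.2, 0.4, 0.65), c(1, 0.86, 0.68, 0.555),
                          xout = pmin(abs(ecc_deg), 0.65), rule = 2)$y
    peak_density_mm2 * frac
  }
}

#' Synthesize a foveal cone mosaic
#'
#' Builds a quasi-hexagonal cone mosaic: a hexagonal lattice is warped
#' radially so that local density follows the target eccentricity profile,
#' positional jitter is added (with minimum-distance rejection at half the
#' local spacing), S cones are placed on a jittered regular sublattice
#' (quasi-regular packing, no S-free zone), and the remaining cones are
#' assigned L or M by independent draws.
#'
#' @param peak_density_mm2 Peak cone density, cones/mm^2.
#' @param extent_deg Width of the square mosaic in degrees of visual angle.
#' @param class_fractions Named or ordered numeric vector of length 3,
#'   fractions of L, M, S cones; must sum to 1.
#' @param density_falloff Function of eccentricity (deg) returning density
#'   (cones/mm^2); default [default_density_falloff()].
#' @param geometry An [eye_geometry()] used for the um <-> deg conversion.
#' @param jitter_frac Positional jitter SD as a fraction of local spacing.
#' @param seed Integer seed; the mosaic is deterministic given the seed.
#' @return A `cone_mosaic`: tibble with columns `x_deg`, `y_deg`, `class`
#'   (factor L/M/S), `diameter_um`, `aperture_um` (Gaussian characteristic
#'   radius, um) plus attributes `um_per_deg`, `extent_deg`,
#'   `peak_density_mm2`.
#' @examples
#' mos <- synthesize_cone_mosaic(extent_deg = 0.2, seed = 1)
#' dplyr::count(mos, class)
#' @export
synthesize_cone_mosaic <- function(peak_density_mm2 = 270200,
                                   extent_deg = 0.5,
                                   class_fractions = c(L = 0.48, M = 0.48, S = 0.04),
                                   density_falloff = NULL,
                                   geometry = eye_geometry(),
                                   jitter_frac = 0.12,
                                   seed = 1) {
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("`class_fractions` must sum to 1.", call. = FALSE)
  }
  if (extent_deg < 0) stop("`extent_deg` must be >= 0.", call. = FALSE)
  empty <- tibble::tibble(x_deg = numeric(), y_deg = numeric(),
                          class = factor(character(), levels = c("L", "M", "S")),
                          diameter_um = numeric(), aperture_um = numeric())
  if (extent_deg == 0) {
    return(new_cone_mosaic(empty, geometry, extent_deg, peak_density_mm2))
  }
  if (is.null(density_falloff)) {
    density_falloff <- default_density_falloff(peak_density_mm2)
  }
  upd <- geometry$um_per_deg
  half_um <- extent_deg / 2 * upd

  withr_seed(seed, {
    s0 <- hex_spacing_um(peak_density_mm2)
    # Base hex lattice at peak spacing, generous margin for the radial warp.
    r_need <- half_um * sqrt(2) * 1.35
    ny <- ceiling(r_need / (s0 * sqrt(3) / 2)) + 2
    nx <- ceiling(r_need / s0) + 2
    rows <- seq(-ny, ny)
    pts <- purrr::map_dfr(rows, function(iy) {
      y <- iy * s0 * sqrt(3) / 2
      off <- (iy %% 2) * s0 / 2
      tibble::tibble(x = seq(-nx, nx) * s0 + off, y = y)
    })
    # Radial warp: map uniform-lattice radius r to R so that the enclosed
    # count matches the integrated target density.
    rmax <- max(sqrt(pts$x^2 + pts$y^2))
    Rgrid <- seq(0, rmax * 1.2, length.out = 600)
    dens <- density_falloff(Rgrid / upd)                  # cones/mm^2
    cum <- cumsum(c(0, diff(Rgrid)) * 2 * pi * Rgrid * dens * 1e-6)  # counts
    d0 <- peak_density_mm2
    # uniform lattice count within r: pi r^2 d0 * 1e-6
    r_of_R <- sqrt(cum / (pi * d0 * 1e-6))
    warp <- stats::approxfun(r_of_R, Rgrid, rule = 2)
    r <- sqrt(pts$x^2 + pts$y^2)
    scale <- ifelse(r > 0, warp(r) / r, 1)
    pts$x <- pts$x * scale
    pts$y <- pts$y * scale
    keep <- abs(pts$x) <= half_um & abs(pts$y) <= half_um
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
    if (n == 0) {
      return(new_cone_mosaic(empty, geometry, extent_deg, peak_density_mm2))
    }
    ecc <- sqrt(pts$x^2 + pts$y^2) / upd
    local_s <- hex_spacing_um(density_falloff(ecc))
    # jitter with minimum-distance rejection (half the local spacing)
    x0 <- pts$x; y0 <- pts$y
    x <- x0 + stats::rnorm(n, 0, jitter_frac * local_s)
    y <- y0 + stats::rnorm(n, 0, jitter_frac * local_s)
    for (iter in 1:4) {
      nn <- nearest_neighbor_dist(x, y)
      bad <- which(nn < 0.5 * local_s)
      if (length(bad) == 0) break
      x[bad] <- x0[bad] + stats::rnorm(length(bad), 0, 0.5 * jitter_frac * local_s[bad])
      y[bad] <- y0[bad] + stats::rnorm(length(bad), 0, 0.5 * jitter_frac * local_s[bad])
    }
    nn <- nearest_neighbor_dist(x, y)
    bad <- which(nn < 0.5 * local_s)
    x[bad] <- x0[bad]; y[bad] <- y0[bad]

    # class assignment: S on a jittered coarse sublattice, L/M independent
    cls <- rep(NA_character_, n)
    fS <- class_fractions[[3]]
    if (fS > 0) {
      sS <- mean(local_s) / sqrt(fS)     # spacing of the S sublattice
      nyS <- ceiling(half_um / (sS * sqrt(3) / 2)) + 1
      nxS <- ceiling(half_um / sS) + 1
      sub <- purrr::map_dfr(seq(-nyS, nyS), function(iy) {
        yv <- iy * sS * sqrt(3) / 2
        off <- (iy %% 2) * sS / 2
        tibble::tibble(x = seq(-nxS, nxS) * sS + off, y = yv)
      })
      sub$x <- sub$x + stats::rnorm(nrow(sub), 0, 0.15 * sS)
      sub$y <- sub$y + stats::rnorm(nrow(sub), 0, 0.15 * sS)
      sub <- sub[abs(sub$x) <= half_um & abs(sub$y) <= half_um, , drop = FALSE]
      if (nrow(sub) > 0) {
        for (i in seq_len(nrow(sub))) {
          j <- which.min((x - sub$x[i])^2 + (y - sub$y[i])^2)
          cls[j] <- "S"
        }
      }
    }
    lm_idx <- which(is.na(cls))
    pL <- class_fractions[[1]] / (class_fractions[[1]] + class_fractions[[2]])
    cls[lm_idx] <- ifelse(stats::runif(length(lm_idx)) < pL, "L", "M")

    diameter <- local_s
    out <- tibble::tibble(
      x_deg = x / upd, y_deg = y / upd,
      class = factor(cls, levels = c("L", "M", "S")),
      diameter_um = diameter,
      aperture_um = aperture_radius(diameter)
    )
    new_cone_mosaic(out, geometry, extent_deg, peak_density_mm2)
  })
}

new_cone_mosaic <- function(tbl, geometry, extent_deg, peak_density_mm2) {
  structure(tbl,
            class = c("cone_mosaic", class(tibble::tibble()))) -> out
  attr(out, "um_per_deg") <- geometry$um_per_deg
  attr(out, "extent_deg") <- extent_deg
  attr(out, "peak_density_mm2") <- peak_density_mm2
  out
}

# Nearest-neighbor distances via grid buckets (avoids O(n^2) memory).
nearest_neighbor_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(Inf, n))
  area <- max((max(x) - min(x)) * (max(y) - min(y)), 1e-9)
  cell <- max(2 * sqrt(area / n), 1e-6)
  cx <- floor((x - min(x)) / cell)
  cy <- floor((y - min(y)) / cell)
  ncx <- max(cx) + 1
  key <- cx + cy * ncx
  buckets <- split(seq_len(n), key)
  nn <- rep(Inf, n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- as.character((cx[i] + dx) + (cy[i] + dy) * ncx)
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (length(cand)) {
      nn[i] <- sqrt(min((x[cand] - x[i])^2 + (y[cand] - y[i])^2))
    }
  }
  nn
}

# run code with a temporary RNG seed, restoring the global state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Local cone density of a mosaic in radial annuli
#'
#' @param mosaic A `cone_mosaic`.
#' @param annulus_um Annulus width in micrometers.
#' @return Tibble with `ecc_um`, `density_mm2` per annulus (annuli clipped to
#'   the square mosaic support are corrected for the clipped area).
#' @export
mosaic_density_profile <- function(mosaic, annulus_um = 10) {
  upd <- attr(mosaic, "um_per_deg")
  half <- attr(mosaic, "extent_deg") / 2 * upd
  r <- sqrt(mosaic$x_deg^2 + mosaic$y_deg^2) * upd
  br <- seq(0, max(half, max(r) + annulus_um), by = annulus_um)
  idx <- findInterval(r, br, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(br) - 1)
  area <- purrr::map_dbl(seq_len(length(br) - 1), function(i) {
    annulus_area_in_square(br[i], br[i + 1], half)
  })
  keep <- area > 0
  tibble::tibble(
    ecc_um = (br[-length(br)] + br[-1])[keep] / 2,
    density_mm2 = counts[keep] / (area[keep] * 1e-6)
  )
}

# area of the annulus [r1, r2] intersected with the centered square of
# half-width h (numeric, exact enough via circle-square intersection)
annulus_area_in_square <- function(r1, r2, h) {
  circ_in_square <- function(r) {
    if (r <= h) return(pi * r^2)
    if (r >= h * sqrt(2)) return(4 * h^2)
    # circle radius r > h: area = pi r^2 - 4 * circular segment beyond x = h
    seg <- r^2 * acos(h / r) - h * sqrt(r^2 - h^2)
    pi * r^2 - 4 * seg
  }
  max(circ_in_square(r2) - circ_in_square(r1), 0)
}

#' Hexagonal packing spacing of a mosaic region
#'
#' The hex spacing is estimated as the mean distance to the 6 nearest
#' neighbors of each cone within `radius_deg` of the mosaic center. For a
#' perfect hexagonal lattice this equals the lattice constant; unlike the
#' single nearest-neighbor distance it is nearly unbiased under positional
#' jitter.
#'
#' @param mosaic A `cone_mosaic`.
#' @param radius_deg Radius of the central region used for the estimate.
#' @return Spacing in micrometers.
#' @export
mosaic_hex_spacing <- function(mosaic, radius_deg = 0.05) {
  upd <- attr(mosaic, "um_per_deg")
  x <- mosaic$x_deg * upd
  y <- mosaic$y_deg * upd
  r <- sqrt(x^2 + y^2)
  ctr <- which(r <= radius_deg * upd)
  if (length(ctr) == 0) return(NA_real_)
  d6 <- purrr::map_dbl(ctr, function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    mean(sort(d[-i])[1:6])
  })
  mean(d6)
}

#' Govardovskii A1 visual-pigment template
#'
#' Standard alpha + beta band template for A1 pigments, evaluated on a
#' wavelength grid and peak-normalized.
#'
#' @param lambda_max_nm Wavelength of peak absorbance, nm (330-600).
#' @param wavelength_nm Wavelength grid in nm.
#' @return A tibble with `wavelength_nm`, `sensitivity` (peak 1), and
#'   attribute `lambda_max_nm`.
#' @export
cone_fundamental <- function(lambda_max_nm,
                             wavelength_nm = seq(400, 700, by = 5)) {
  if (lambda_max_nm < 330 || lambda_max_nm > 600) {
    stop("`lambda_max_nm` must be in [330, 600].", call. = FALSE)
  }
  if (any(wavelength_nm < 300) || any(wavelength_nm > 800)) {
    warning("wavelengths outside 300-800 nm clamped to template support")
    wavelength_nm <- pmin(pmax(wavelength_nm, 300), 800)
  }
  s <- govardovskii_a1(lambda_max_nm, wavelength_nm)
  out <- tibble::tibble(wavelength_nm = wavelength_nm,
                        sensitivity = s / max(s))
  attr(out, "lambda_max_nm") <- lambda_max_nm
  out
}

# raw (un-normalized) Govardovskii et al. (2000) A1 alpha+beta template
govardovskii_a1 <- function(lmax, wl) {
  x <- lmax / wl
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  b <- 0.922; cc <- 1.104
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  lmb <- 189 + 0.315 * lmax
  bb <- -40.5 + 0.195 * lmax
  beta <- 0.26 * exp(-((wl - lmb) / bb)^2)
  alpha + beta
}

#' Ocular media: lens and macular pigment transmittance
#'
#' Smooth synthetic transmittance templates with the qualitative shape of
#' published young-eye lens and foveal macular pigment spectra: the lens
#' absorbs steeply below ~450 nm, the macular pigment peaks near 460 nm with
#' a density that decays with eccentricity. These stand in for unpublished
#' per-animal measurements; both can be replaced by user tables.
#'
#' @param wavelength_nm Wavelength grid in nm.
#' @param macular_peak_density Macular pigment optical density at 460 nm at
#'   the foveal center.
#' @param macular_ecc_scale_deg Eccentricity (deg) at which macular density
#'   has fallen by 1/e.
#' @return An object of class `ocular_media`: list with `wavelength_nm`,
#'   `lens_transmittance`, and `macular_density(ecc_deg)` /
#'   `macular_transmittance(ecc_deg)` functions.
#' @export
ocular_media <- function(wavelength_nm = seq(400, 700, by = 5),
                         macular_peak_density = 0.35,
                         macular_ecc_scale_deg = 1.0) {
  wl <- wavelength_nm
  # synthetic lens optical density: steep short-wavelength absorption
  lens_od <- 1.8 * exp(-(wl - 365)^2 / (2 * 45^2)) + 0.1 * exp(-(wl - 400) / 60)
  lens_od[wl > 550] <- 0
  lens_t <- pmin(10^(-lens_od), 1)
  # synthetic macular pigment density spectrum, peak-normalized near 460 nm
  mac_shape <- exp(-((wl - 460) / 38)^2) + 0.35 * exp(-((wl - 420) / 18)^2)
  mac_shape <- mac_shape / max(mac_shape)
  media <- list(
    wavelength_nm = wl,
    lens_transmittance = lens_t,
    macular_density = function(ecc_deg) {
      macular_peak_density * exp(-abs(ecc_deg) / macular_ecc_scale_deg)
    },
    macular_transmittance = function(ecc_deg) {
      10^(-outer(mac_shape, macular_peak_density *
                   exp(-abs(ecc_deg) / macular_ecc_scale_deg)))
    }
  )
  structure(media, class = "ocular_media")
}

#' Effective quantal efficiency of a cone through the ocular media
#'
#' Pointwise product of the cone-class fundamental and the macular pigment
#' transmittance at the cone's eccentricity. Lens transmittance is applied at
#' the stimulus-radiance stage (it is a property of the light path shared by
#' all cones), not here.
#'
#' @param fundamental A [cone_fundamental()] tibble.
#' @param media An [ocular_media()].
#' @param ecc_deg Eccentricity of the cone in degrees.
#' @return A tibble `wavelength_nm`, `sensitivity` (not re-normalized).
#' @export
effective_quantal_efficiency <- function(fundamental, media, ecc_deg = 0) {
  if (!isTRUE(all.equal(fundamental$wavelength_nm, media$wavelength_nm))) {
    stop("fundamental and media must share a wavelength grid.", call. = FALSE)
  }
  mt <- media$macular_transmittance(ecc_deg)[, 1]
  tibble::tibble(wavelength_nm = fundamental$wavelength_nm,
                 sensitivity = fundamental$sensitivity * mt)
}

#' Default macaque cone fundamentals
#'
#' Govardovskii templates at the default macaque peak wavelengths
#' (S 430, M 530, L 561 nm).
#'
#' @param wavelength_nm Wavelength grid.
#' @param lambda_max Named vector of peak wavelengths for L, M, S.
#' @return Named list of [cone_fundamental()] tibbles (`L`, `M`, `S`).
#' @export
macaque_fundamentals <- function(wavelength_nm = seq(400, 700, by = 5),
                                 lambda_max = c(L = 561, M = 530, S = 430)) {
  purrr::map(as.list(lambda_max), cone_fundamental,
             wavelength_nm = wavelength_nm)
}

#' Read / write a cone mosaic as a delimited table
#'
#' Columns: `x_deg`, `y_deg`, `class`, `diameter_um`, `aperture_um`.
#'
#' @param mosaic A `cone_mosaic`.
#' @param path File path (tab-separated).
#' @param geometry An [eye_geometry()] restored on read.
#' @return `write_mosaic()` returns `path` invisibly; `read_mosaic()` a
#'   `cone_mosaic`.
#' @export
write_mosaic <- function(mosaic, path) {
  readr::write_tsv(as.data.frame(mosaic), path)
  invisible(path)
}

#' @rdname write_mosaic
#' @export
read_mosaic <- function(path, geometry = eye_geometry()) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           x_deg = "d", y_deg = "d", class = "c",
                           diameter_um = "d", aperture_um = "d"))
  tbl$class <- factor(tbl$class, levels = c("L", "M", "S"))
  ext <- if (nrow(tbl)) 2 * max(abs(c(tbl$x_deg, tbl$y_deg))) else 0
  new_cone_mosaic(tibble::as_tibble(tbl), geometry, ext, NA_real_)
}
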