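#' Synthesize a flicker fluorescence trace
#'
#' Baseline plus a sinusoidal response at the stimulus frequency, a linear
#' drift, and seeded white Gaussian noise: the minimal generative model of a
#' 90-s chromatic-flicker recording epoch.
#'
#' @param response_amplitude Amplitude of the stimulus-locked component.
#' @param stim_freq_hz Stimulus frequency, Hz (0.15-0.2 in the experiments).
#' @param phase_rad Response phase relative to the stimulus (pi for OFF).
#' @param noise_sigma SD of the additive white noise.
#' @param drift Linear drift in fluorescence units per second.
#' @param duration_s Trace duration, s.
#' @param rate_hz Sampling rate, Hz (> 2x the stimulus frequency).
#' @param baseline Constant baseline level.
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @return Tibble `time_s`, `value` with attributes `stim_freq_hz`, `seed`.
#' @export
synth_flicker_trace <- function(response_amplitude, stim_freq_hz = 0.15,
                                phase_rad = 0, noise_sigma = 1, drift = 0,
                                duration_s = 90, rate_hz = 16,
                                baseline = 100, seed = 1) {
  if (rate_hz <= 2 * stim_freq_hz) {
    stop("`rate_hz` must exceed twice the stimulus frequency.", call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  withr_seed(seed, {
    v <- baseline + response_amplitude * sin(2 * pi * stim_freq_hz * t + phase_rad) +
      drift * t + stats::rnorm(n, 0, noise_sigma)
    out <- tibble::tibble(time_s = t, value = v)
  })
  attr(out, "stim_freq_hz") <- stim_freq_hz
  attr(out, "seed") <- seed
  out
}

#' Synthesize a multi-session measured-STF dataset from a ground-truth RF
#'
#' Runs the forward model for the supplied ground-truth pooling weights and
#' adds independent per-frequency Gaussian session noise with SD expressed
#' as a fraction of the peak response (default 0.10, emulating the observed
#' week-to-week variability). Per-frequency SEM is computed across sessions.
#' An optional negative offset corrupts all sessions downward to exercise
#' the offset-correction rule (overestimated background fluorescence).
#'
#' @param truth An `rf_weights` object (the ground-truth receptive field).
#' @param context An [stf_model_context()] (defines mosaic, optics and the
#'   frequency grid).
#' @param sessions Number of sessions (>= 1).
#' @param noise_frac Session noise SD as a fraction of the peak amplitude.
#' @param offset Constant subtracted from every dff (set negative-going
#'   data with, e.g., `offset = 0.2` which subtracts 0.2).
#' @param seed Integer seed.
#' @return A list of class `synth_stf`: `sessions` (tibble `session`,
#'   `freq_cpd`, `dff`, `sem`), `averaged` (tibble `freq_cpd`, `dff`,
#'   `sem` across sessions), `truth_stf` (noise-free model STF), `truth`.
#' @export
synth_stf_dataset <- function(truth, context, sessions = 3,
                              noise_frac = 0.10, offset = 0, seed = 1) {
  stopifnot(sessions >= 1)
  stf <- compute_model_stf(truth, context)
  peak <- max(stf$amplitude)
  withr_seed(seed, {
    per_session <- purrr::map_dfr(seq_len(sessions), function(s) {
      noise <- stats::rnorm(nrow(stf), 0, noise_frac * peak)
      tibble::tibble(session = s, freq_cpd = stf$freq_cpd,
                     dff = stf$amplitude + noise - offset,
                     sem = noise_frac * peak)
    })
  })
  averaged <- per_session |>
    dplyr::group_by(.data$freq_cpd) |>
    dplyr::summarise(
      sem = if (dplyr::n() > 1) {
        stats::sd(.data$dff) / sqrt(dplyr::n())
      } else {
        noise_frac * peak
      },
      dff = mean(.data$dff),
      .groups = "drop"
    ) |>
    dplyr::select("freq_cpd", "dff", "sem")
  # guard the degenerate zero-noise case: SEM identically zero is floored in
  # the objective, keep it as computed here
  structure(
    list(sessions = per_session, averaged = averaged, truth_stf = stf,
         truth = truth),
    class = "synth_stf"
  )
}

#' Monte-Carlo simulation of achromatic midget RGCs in a random mosaic
#'
#' A hexagonally packed mosaic of `n_cones` cones (a disk of about 25 cone
#' radii) is assigned L/M/S classes independently with the given fractions.
#' Each interior cone (all 6 neighbors present) is taken as a midget RGC
#' center wired to its 6 adjacent cones as surround. Cells whose 6 surround
#' cones all match the center class are "true achromatic"; cells with at
#' least 5 matches are "thresholded achromatic". Fractions are averaged
#' over seeded mosaic repeats.
#'
#' @param n_cones Number of cones in the mosaic.
#' @param fractions L/M/S probabilities, summing to 1.
#' @param n_repeats Number of independent mosaic realizations.
#' @param seed Integer seed.
#' @return A list of class `achromatic_sim`: `true_fraction`,
#'   `thresholded_fraction` (means over repeats), `per_repeat` (tibble),
#'   `se_true`, `se_thresholded` (Monte-Carlo standard errors of the means),
#'   `n_centers`, `n_repeats`.
#' @export
achromatic_midget_sim <- function(n_cones = 2400,
                                  fractions = c(L = 0.48, M = 0.48, S = 0.04),
                                  n_repeats = 10000, seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must sum to 1.", call. = FALSE)
  }
  lat <- hex_disk_lattice(n_cones)
  nbr <- lat$neighbors          # matrix n_interior x 6
  centers <- lat$interior
  n <- nrow(lat$coords)
  withr_seed(seed, {
    res <- matrix(0, n_repeats, 2)
    for (r in seq_len(n_repeats)) {
      cls <- sample.int(3, n, replace = TRUE, prob = fractions)
      match_count <- rowSums(matrix(cls[nbr] == cls[centers], ncol = 6))
      res[r, 1] <- mean(match_count == 6)
      res[r, 2] <- mean(match_count >= 5)
    }
  })
  per_repeat <- tibble::tibble(repeat_id = seq_len(n_repeats),
                               true_fraction = res[, 1],
                               thresholded_fraction = res[, 2])
  structure(
    list(true_fraction = mean(res[, 1]),
         thresholded_fraction = mean(res[, 2]),
         se_true = stats::sd(res[, 1]) / sqrt(n_repeats),
         se_thresholded = stats::sd(res[, 2]) / sqrt(n_repeats),
         per_repeat = per_repeat,
         n_centers = length(centers), n_repeats = n_repeats),
    class = "achromatic_sim"
  )
}

# Hexagonal disk lattice of ~n_cones cones: axial coordinates, neighbor
# index matrix for interior cones (all 6 neighbors present).
hex_disk_lattice <- function(n_cones) {
  # rings until the count reaches n_cones, then keep the nearest n_cones
  radius <- 0
  while (3 * radius * (radius + 1) + 1 < n_cones) radius <- radius + 1
  qr <- expand.grid(q = -radius:radius, r = -radius:radius)
  qr <- qr[abs(qr$q + qr$r) <= radius, ]
  x <- qr$q + qr$r / 2
  y <- qr$r * sqrt(3) / 2
  d <- x^2 + y^2
  keep <- order(d)[seq_len(min(n_cones, nrow(qr)))]
  qr <- qr[keep, ]; x <- x[keep]; y <- y[keep]
  key <- paste(qr$q, qr$r)
  index <- stats::setNames(seq_along(key), key)
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  nbr_idx <- sapply(seq_len(6), function(k) {
    unname(index[paste(qr$q + dirs[k, 1], qr$r + dirs[k, 2])])
  })
  interior <- which(rowSums(!is.na(nbr_idx)) == 6)
  list(coords = cbind(x = x, y = y),
       neighbors = matrix(nbr_idx[interior, ], ncol = 6),
       interior = interior)
}

#' Closed-form expectation for the achromatic midget simulation
#'
#' With independent class assignment, a center of class `t` (probability
#' `p_t`) has all 6 surround cones matching with probability `p_t^6` and at
#' least 5 matching with probability `p_t^6 + 6 p_t^5 (1 - p_t)`; summing
#' over classes weighted by `p_t` gives the expected fractions.
#'
#' @param fractions L/M/S probabilities, summing to 1.
#' @return Tibble `true_fraction`, `thresholded_fraction`.
#' @export
achromatic_analytic <- function(fractions = c(0.48, 0.48, 0.04)) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must sum to 1.", call. = FALSE)
  }
  p <- fractions
  tibble::tibble(
    true_fraction = sum(p * p^6),
    thresholded_fraction = sum(p * (p^6 + 6 * p^5 * (1 - p)))
  )
}

#' Write a deterministic fixture bundle
#'
#' Generates the plain-text fixtures used by examples and tests: a small
#' cone mosaic, the default cone fundamentals and ocular-media spectra
#' (synthetic templates), a wavefront description, and one flicker trace.
#' Byte-identical for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the named vector of file paths.
#' @export
fixture_bundle <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mosaic = file.path(dir, "mosaic.tsv"),
    spectra = file.path(dir, "fundamentals.tsv"),
    media = file.path(dir, "ocular_media_synthetic.tsv"),
    wavefront = file.path(dir, "wavefront.yaml"),
    trace = file.path(dir, "trace.tsv")
  )
  mos <- synthesize_cone_mosaic(extent_deg = 0.2, seed = seed)
  write_mosaic(mos, paths[["mosaic"]])
  fund <- macaque_fundamentals()
  tbl <- tibble::tibble(
    wavelength_nm = fund$L$wavelength_nm,
    L = fund$L$sensitivity, M = fund$M$sensitivity, S = fund$S$sensitivity
  )
  readr::write_tsv(tbl, paths[["spectra"]])
  med <- ocular_media()
  readr::write_tsv(tibble::tibble(
    wavelength_nm = med$wavelength_nm,
    lens_transmittance = med$lens_transmittance,
    macular_transmittance_fovea = med$macular_transmittance(0)[, 1]
  ), paths[["media"]])
  writeLines(yaml::as.yaml(list(
    pupil_diameter_mm = 6.7, wavelength_nm = 561,
    terms = list(list(n = 2L, m = 0L,
                      coeff_um = round(defocus_to_zernike(0.067, 6.7), 6)))
  )), paths[["wavefront"]])
  tr <- synth_flicker_trace(5, seed = seed)
  readr::write_tsv(tr, paths[["trace"]])
  invisible(paths)
}

#' Read a wavefront description file
#'
#' YAML with fields `pupil_diameter_mm`, `wavelength_nm` and `terms`
#' (list of `{n, m, coeff_um}`).
#'
#' @param path File path.
#' @param defocus_D Extra defocus added on top of the file's terms.
#' @return A [pupil_spec()].
#' @export
read_wavefront <- function(path, defocus_D = 0) {
  y <- yaml::read_yaml(path)
  terms <- purrr::map_dfr(y$terms %||% list(), tibble::as_tibble)
  pupil_spec(diameter_mm = y$pupil_diameter_mm,
             wavelength_nm = y$wavelength_nm,
             defocus_D = defocus_D,
             zernike = if (nrow(terms)) terms else NULL)
}

#' Read / write measured STF tables
#'
#' Delimited table with columns `cell_id`, `session`, `freq_cpd`, `dff`,
#' `sem`.
#'
#' @param stf Tibble in that layout.
#' @param path File path (tab-separated).
#' @return `write_stf()` the path invisibly; `read_stf()` a tibble.
#' @export
write_stf <- function(stf, path) {
  readr::write_tsv(stf, path)
  invisible(path)
}

#' @rdname write_stf
#' @export
read_stf <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
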