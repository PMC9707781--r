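#' d-prime response metric from a fluorescence time course
#'
#' The trace is Hann-windowed and Fourier transformed; the amplitude at the
#' bin nearest the stimulus frequency is the signal. The SNR is the signal
#' minus the mean amplitude in the noise band, divided by the sample
#' standard deviation of the noise-band amplitudes (a d-prime equivalent).
#' The sign is flipped to negative when the response is more than 90 degrees
#' out of phase with the stimulus (an OFF response); the phase reference is
#' a windowed sinusoid `sin(2*pi*f*t + stim_phase)` analyzed identically.
#'
#' @param trace Tibble with columns `time_s`, `value`, uniformly sampled.
#' @param stim_freq_hz Stimulus frequency in Hz (below the noise band).
#' @param noise_band_hz Noise band `c(lo, hi)` in Hz; default 0.32-1.08.
#' @param stim_phase_rad Stimulus sine phase at `t = 0`.
#' @return A list of class `response_metric`: `snr` (signed), `amplitude`,
#'   `phase_rad`, `response_sign` (`"ON"`/`"OFF"`), `noise_mean`, `noise_sd`.
#' @export
fourier_response <- function(trace, stim_freq_hz,
                             noise_band_hz = c(0.32, 1.08),
                             stim_phase_rad = 0) {
  t <- trace$time_s
  x <- trace$value
  n <- length(x)
  dt <- stats::median(diff(t))
  if (n * dt < 2 / stim_freq_hz) {
    stop("trace must cover at least 2 stimulus cycles.", call. = FALSE)
  }
  if (stim_freq_hz >= noise_band_hz[1]) {
    stop("stimulus frequency must lie below the noise band.", call. = FALSE)
  }
  w <- hann_window(n)
  X <- stats::fft((x - mean(x)) * w)
  freqs <- (seq_len(n) - 1) / (n * dt)
  half <- freqs <= 1 / (2 * dt)
  k_sig <- which.min(abs(freqs - stim_freq_hz))
  amps <- Mod(X)
  in_band <- which(freqs >= noise_band_hz[1] & freqs <= noise_band_hz[2] & half)
  if (length(in_band) < 3) {
    stop("noise band contains fewer than 3 frequency bins.", call. = FALSE)
  }
  noise_mean <- mean(amps[in_band])
  noise_sd <- stats::sd(amps[in_band])
  if (noise_sd == 0) stop("noise band has zero variance.", call. = FALSE)
  snr <- (amps[k_sig] - noise_mean) / noise_sd
  # phase relative to the stimulus, via an identically windowed reference
  ref <- stats::fft(sin(2 * pi * stim_freq_hz * t + stim_phase_rad) * w)
  dphi <- Arg(X[k_sig] / ref[k_sig])
  off <- abs(dphi) > pi / 2
  structure(
    list(snr = if (off) -abs(snr) else abs(snr),
         amplitude = amps[k_sig], phase_rad = Arg(X[k_sig]),
         response_sign = if (off) "OFF" else "ON",
         noise_mean = noise_mean, noise_sd = noise_sd),
    class = "response_metric"
  )
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))

#' Delta-F/F with propagated standard error
#'
#' `dff = (S - B) / S17`, the stimulus-driven signal minus the background,
#' normalized by the response to the 17 c/deg reference grating. The
#' standard error follows from first-order error propagation:
#' `sem = sqrt((var_S + var_B) / S17^2 + (S - B)^2 * var_S17 / S17^4)`.
#'
#' @param background_mean,signal_mean Mean fluorescence in the background
#'   (first 10 s of adaptation) and signal (last 10 s of stimulation)
#'   windows.
#' @param reference_mean Mean signal at the 17 c/deg reference frequency
#'   (> 0).
#' @param var_background,var_signal,var_reference Variances of the three
#'   quantities (of the means).
#' @return Tibble with `dff`, `dff_sem`.
#' @export
delta_f_over_f <- function(background_mean, signal_mean, reference_mean,
                           var_background = 0, var_signal = 0,
                           var_reference = 0) {
  if (any(reference_mean <= 0)) {
    stop("`reference_mean` must be positive.", call. = FALSE)
  }
  num <- signal_mean - background_mean
  dff <- num / reference_mean
  sem <- sqrt((var_signal + var_background) / reference_mean^2 +
                num^2 * var_reference / reference_mean^4)
  tibble::tibble(dff = dff, dff_sem = sem)
}

#' Epoch means and variances of a fluorescence trace
#'
#' Helper for grating responses: background is the mean of the first
#' `background_s` seconds of the adaptation epoch, signal the mean of the
#' last `signal_s` seconds of stimulation. Variances are of the epoch means
#' (sample variance / n).
#'
#' @param trace Tibble `time_s`, `value`.
#' @param stim_onset_s,stim_end_s Stimulus epoch boundaries, s.
#' @param background_s,signal_s Window lengths, s.
#' @return Tibble `background_mean`, `signal_mean`, `var_background`,
#'   `var_signal`.
#' @export
epoch_means <- function(trace, stim_onset_s, stim_end_s,
                        background_s = 10, signal_s = 10) {
  bg <- trace$value[trace$time_s < min(background_s, stim_onset_s)]
  sg <- trace$value[trace$time_s >= stim_end_s - signal_s &
                      trace$time_s < stim_end_s]
  tibble::tibble(
    background_mean = mean(bg), signal_mean = mean(sg),
    var_background = stats::var(bg) / length(bg),
    var_signal = stats::var(sg) / length(sg)
  )
}

#' Cone weights from responses to cone-isolating stimuli
#'
#' Each class's response metric is divided by the cone modulation (contrast)
#' of its isolating stimulus and the resulting weights are normalized so the
#' absolute weights sum to one, preserving signs.
#'
#' @param snr Named or ordered numeric vector of response metrics for the
#'   L, M, S isolating stimuli.
#' @param modulation Cone modulations (contrasts) of the three stimuli,
#'   same order; must be positive where measured.
#' @return Tibble `wL`, `wM`, `wS` with `sum(abs(w)) == 1`.
#' @export
cone_weight_vector <- function(snr, modulation) {
  stopifnot(length(snr) == length(modulation))
  if (any(modulation <= 0)) {
    stop("`modulation` must be positive for measured classes.", call. = FALSE)
  }
  raw <- snr / modulation
  tot <- sum(abs(raw))
  if (tot == 0) stop("all responses are zero; weights undefined.", call. = FALSE)
  w <- raw / tot
  tibble::tibble(wL = w[1], wM = w[2], wS = w[3])
}

#' Functionally classify a cell from its chromatic response metrics
#'
#' Applies the significance cutoff `|snr| >= threshold` (default 2) and the
#' rule set: significant L and M with opposite signs (or a significant L-M
#' isoluminant response) and no significant S gives an L-M or M-L opponent
#' cell (sign of the L response, or of the isoluminant response, decides
#' which); S only gives S-ON/S-OFF; luminance only gives luminance-ON/OFF;
#' opponency plus significant S gives mixed; nothing significant is
#' unresponsive.
#'
#' @param snr Named list/vector of response metrics; recognized names are
#'   `L`, `M`, `S`, `LM` (isoluminant L-M) and `lum` (achromatic); supply
#'   the stimuli run in the session.
#' @param threshold Significance cutoff on `|snr|`.
#' @return A list of class `cell_classification`: `group`, `responsive`
#'   (named logical), `snr`.
#' @export
classify_cell <- function(snr, threshold = 2) {
  snr <- unlist(snr)
  known <- c("L", "M", "S", "LM", "lum")
  if (!any(names(snr) %in% known)) {
    stop("no recognized stimuli; expected names among L, M, S, LM, lum.",
         call. = FALSE)
  }
  sig <- abs(snr) >= threshold
  has <- function(nm) nm %in% names(snr)
  sig_of <- function(nm) has(nm) && sig[[nm]]
  opponent <- if (has("L") && has("M")) {
    sig_of("L") && sig_of("M") && sign(snr[["L"]]) != sign(snr[["M"]])
  } else {
    sig_of("LM")
  }
  if (!has("L") && !has("M") && !has("LM") && !has("S") && !has("lum")) {
    stop("classification undefined: no usable stimuli supplied.", call. = FALSE)
  }
  s_sig <- sig_of("S")
  lum_sig <- sig_of("lum")
  single_lm <- !opponent &&
    ((sig_of("L") && !sig_of("M")) || (sig_of("M") && !sig_of("L")))
  group <- if (opponent && s_sig) {
    "mixed L-M S"
  } else if (opponent) {
    dir_sign <- if (has("L") && sig_of("L")) sign(snr[["L"]]) else sign(snr[["LM"]])
    if (dir_sign > 0) "L-M opponent" else "M-L opponent"
  } else if (s_sig && !any(c(sig_of("L"), sig_of("M"), lum_sig, sig_of("LM")))) {
    if (snr[["S"]] > 0) "S-ON" else "S-OFF"
  } else if (s_sig) {
    "mixed L-M S"
  } else if (single_lm) {
    # responses to a single cone class only: treated with luminance cells
    if ((if (sig_of("L")) snr[["L"]] else snr[["M"]]) > 0) {
      "luminance-ON"
    } else {
      "luminance-OFF"
    }
  } else if (lum_sig) {
    if (snr[["lum"]] > 0) "luminance-ON" else "luminance-OFF"
  } else {
    "unresponsive"
  }
  structure(list(group = group, responsive = sig, snr = snr),
            class = "cell_classification")
}

#' Classify many cells from a metrics table
#'
#' @param metrics Tibble with columns `cell_id`, `stimulus` (names as in
#'   [classify_cell()]) and `snr`.
#' @param threshold Significance cutoff.
#' @return Tibble `cell_id`, `group`.
#' @export
classify_cells <- function(metrics, threshold = 2) {
  metrics |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(group = {
      v <- stats::setNames(.data$snr, .data$stimulus)
      classify_cell(v, threshold)$group
    }, .groups = "drop")
}
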