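# Shared heavy fixtures, built once per test run and cached. The mosaic is a
# 0.3-deg patch of the full foveal model (same peak density and class
# fractions); contexts run the full image-based forward model.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

test_mosaic <- function() {
  cached("mosaic", synthesize_cone_mosaic(extent_deg = 0.3, seed = 11))
}

test_optics <- function(defocus_D = 0.067) {
  cached(paste0("optics", defocus_D),
         compute_psf_mtf(pupil_spec(6.7, 561, defocus_D)))
}

test_context <- function(defocus_D = 0.067) {
  cached(paste0("context", defocus_D),
         stf_model_context(test_mosaic(), test_optics(defocus_D)))
}

# ground-truth single-cone cell used by several tests
test_truth_single <- function(kc = 1.5, ks = 0.25, rs_deg = 0.05) {
  build_rf_weights(test_mosaic(), kc = kc, ks = ks, rs_deg = rs_deg,
                   center_position = c(0, 0), scenario = "single-cone")
}

noise_free_measured <- function(weights, context) {
  stf <- compute_model_stf(weights, context)
  tibble::tibble(freq_cpd = stf$freq_cpd, dff = stf$amplitude, sem = 0)
}
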