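## High-level experiment helpers tying the modules together the way the
## original symmetry determination was run: long filaments windowed by the
## image box, many noisy segments averaged into a class average, and the
## rise read off the averaged meridional profile.

#' Default synthetic filament
#'
#' Synthetic monomer propagated with the given symmetry; a convenience
#' wrapper used throughout the tests and the CLI.
#'
#' @param seed generator seed.
#' @param n subunit count (default 30, ~150 A).
#' @param params a [helical_params()] object.
#' @return A `filament_model`.
#' @export
default_filament <- function(seed = 1L, n = 30L, params = rip2_params()) {
  mono <- make_synthetic_monomer(synthetic_monomer_spec(params = params,
                                                        seed = seed))
  build_filament(mono, params, n)
}

#' Noise level for a target signal-to-noise ratio
#'
#' Converts a power SNR (variance of the noise-free image over noise
#' variance) into the `noise_sigma` fraction-of-peak convention used by
#' [micrograph_spec()].
#'
#' @param signal noise-free `projection_image`.
#' @param snr target power signal-to-noise ratio, > 0.
#' @return `noise_sigma` value.
#' @export
noise_sigma_for_snr <- function(signal, snr) {
  stopifnot(inherits(signal, "projection_image"), snr > 0)
  stats::sd(signal$pixels) / sqrt(snr) / max(signal$pixels)
}

#' Class average of many noisy segments
#'
#' Averages `n_segments` aligned noisy renders of the same filament, the
#' real-space analogue of a 2D class average. Because the noise is
#' additive white Gaussian, the average of `K` independent renders is
#' distributionally identical to a single render with the noise scaled by
#' `1/sqrt(K)`; that shortcut is used so the simulation stays cheap, and
#' it is exact, not an approximation.
#'
#' @param filament a `filament_model`.
#' @param spec a [micrograph_spec()]; its `noise_sigma` is the
#'   per-segment noise.
#' @param n_segments number of segments entering the average, >= 1.
#' @return A `projection_image`.
#' @export
class_average_micrograph <- function(filament, spec = micrograph_spec(),
                                     n_segments = 2000L) {
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 1L)
  eff <- spec
  eff$noise_sigma <- spec$noise_sigma / sqrt(n_segments)
  render_micrograph(filament, eff)
}

#' Simulate the layer-line rise measurement end to end
#'
#' Renders a synthetic filament long enough to overfill the field of view
#' (the image box acts as the segment window, as when segments are
#' extracted from micrographs of long filaments - windowing in z is what
#' puts the layer-line comb exactly at multiples of 1/rise), builds a
#' class average at the requested per-segment SNR, and estimates the rise
#' from the furthest meridional layer line.
#'
#' @param params a [helical_params()] object.
#' @param seed seed for the monomer and for the noise field.
#' @param snr per-segment power SNR; `Inf` for a noiseless render.
#' @param n_segments segments in the class average.
#' @param spec a [micrograph_spec()] for calibration/box/blur (its
#'   noise_sigma and seed are overridden here).
#' @param lane_halfwidth,detection_threshold passed to
#'   [meridional_profile()].
#' @return list with `rise` (Angstrom), `profile`, `image`, `filament`.
#' @export
layerline_rise_experiment <- function(params = rip2_params(), seed = 1L,
                                      snr = Inf, n_segments = 2000L,
                                      spec = micrograph_spec(),
                                      lane_halfwidth = 0L,
                                      detection_threshold = 5) {
  n <- as.integer(ceiling(spec$box * spec$pixel_size / params$rise)) + 12L
  fil <- default_filament(seed = seed, n = n, params = params)
  clean_spec <- spec
  clean_spec$noise_sigma <- 0
  clean <- suppressWarnings(render_micrograph(fil, clean_spec))
  img <- if (is.finite(snr)) {
    noisy_spec <- spec
    noisy_spec$noise_sigma <- noise_sigma_for_snr(clean, snr)
    noisy_spec$seed <- as.integer(seed)
    suppressWarnings(class_average_micrograph(fil, noisy_spec, n_segments))
  } else clean
  prof <- meridional_profile(power_spectrum(img),
                             lane_halfwidth = lane_halfwidth,
                             detection_threshold = detection_threshold)
  list(rise = estimate_rise(prof), profile = prof, image = img,
       filament = fil)
}
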