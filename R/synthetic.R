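#' Configuration of the synthetic EEG generator
#'
#' The generator emulates the qualitative spectral contrast between the two
#' classes in the public Bonn recordings: normal segments carry a
#' theta-dominant (4-8 Hz) oscillation of moderate amplitude, while ictal
#' segments carry a much larger delta-dominant (0.5-4 Hz) oscillation with
#' additional elevated alpha- and beta-band power.  Both ride on 1/f-shaped
#' background noise.  It is an emulation target for testing the pipeline, not
#' a biophysical model of EEG.
#'
#' @param n_per_class Segments to generate per class.
#' @param length Samples per segment (default 4097).
#' @param sampling_rate_hz Sampling rate (default 173.61 Hz).
#' @param normal_band_hz Frequency interval of the normal class's dominant
#'   oscillation (default theta, 4-8 Hz).
#' @param ictal_band_hz Frequency interval of the ictal class's dominant
#'   oscillation (default delta, 0.5-4 Hz).
#' @param ictal_amplitude_gain Multiplier on the ictal dominant-oscillation
#'   amplitude relative to normal (default 4; must be > 0, with 1 meaning no
#'   amplitude contrast).
#' @param broadband_gain_ictal Amplitude of the extra ictal alpha (8-13 Hz)
#'   and beta (13-30 Hz) components, relative to the normal base amplitude
#'   (default 1.5; 0 disables them).
#' @param noise_sd Standard deviation of the 1/f background noise relative to
#'   the normal base amplitude (default 0.25, i.e. a fairly clean recording;
#'   chosen so the class-mean spectra keep their theta/delta peak contrast).
#' @param noise_highpass_hz Corner of the second-order high-pass applied to
#'   the background noise (default 0.53 Hz, the acquisition high-pass of the
#'   public Bonn recordings); keeps sub-delta drift from dominating the
#'   spectrum.
#' @param seed Master seed; each segment is fully determined by
#'   `(seed, class, index)`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 100L, length = 4097L,
                         sampling_rate_hz = 173.61,
                         normal_band_hz = c(4, 8),
                         ictal_band_hz = c(0.5, 4),
                         ictal_amplitude_gain = 4.0,
                         broadband_gain_ictal = 1.5,
                         noise_sd = 0.25, noise_highpass_hz = 0.53,
                         seed = 1L) {
  nyq <- sampling_rate_hz / 2
  for (band in list(normal_band_hz, ictal_band_hz)) {
    if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
        band[2] >= nyq) {
      stopf("bands must be increasing intervals within (0, %.2f)", nyq)
    }
  }
  if (ictal_amplitude_gain <= 0) stopf("ictal_amplitude_gain must be > 0")
  if (broadband_gain_ictal < 0) stopf("broadband_gain_ictal must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (noise_highpass_hz < 0 || noise_highpass_hz >= nyq) {
    stopf("noise_highpass_hz must lie in [0, Nyquist)")
  }
  structure(
    list(n_per_class = as.integer(n_per_class), length = as.integer(length),
         sampling_rate_hz = sampling_rate_hz,
         normal_band_hz = as.numeric(normal_band_hz),
         ictal_band_hz = as.numeric(ictal_band_hz),
         ictal_amplitude_gain = ictal_amplitude_gain,
         broadband_gain_ictal = broadband_gain_ictal,
         noise_sd = noise_sd, noise_highpass_hz = noise_highpass_hz,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# 1/f background noise: white Gaussian noise spectrally shaped so power
# falls as 1/f (amplitude as f^{-1/2}) above the acquisition high-pass
# corner, with a second-order high-pass rolloff below it; rescaled to unit
# SD.
pink_noise <- function(n, fs, f_hp) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  k <- c(1L, seq_len(n - 1L))         # guard DC; mirror conjugate bins
  f <- pmin(k, n - k) * fs / n
  shape <- if (f_hp > 0) {
    ifelse(f >= f_hp, 1 / sqrt(f), (f / f_hp)^2 / sqrt(f_hp))
  } else {
    1 / sqrt(pmax(f, fs / n))
  }
  shape[1] <- 0                       # remove DC offset
  shaped <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Generate one synthetic EEG segment
#'
#' The segment is the sum of a dominant class-band oscillation (randomized
#' frequency and phase, amplitude jittered around the class mean), for the
#' ictal class two additional alpha- and beta-band oscillations scaled by
#' `broadband_gain_ictal`, and 1/f background noise of SD `noise_sd`.  The
#' ictal dominant amplitude is multiplied by `ictal_amplitude_gain`.  The
#' output is fully determined by `(config$seed, class_label, index)`.
#'
#' @param class_label `"normal"` or `"epileptic"`.
#' @param config A [synth_config()].
#' @param index Segment index within its class (used for seeding and
#'   `source_id`).
#' @return An [eeg_segment].
#' @export
generate_segment <- function(class_label, config = synth_config(),
                             index = 1L) {
  if (!class_label %in% c("normal", "epileptic")) {
    stopf("class_label must be 'normal' or 'epileptic'")
  }
  is_ictal <- class_label == "epileptic"
  seed <- derive_seed(config$seed, if (is_ictal) 2L else 1L, index)
  n <- config$length
  t <- (seq_len(n) - 1L) / config$sampling_rate_hz
  samples <- with_seed(seed, {
    band <- if (is_ictal) config$ictal_band_hz else config$normal_band_hz
    f0 <- stats::runif(1L, band[1], band[2])
    phase <- stats::runif(1L, 0, 2 * pi)
    base_amp <- stats::runif(1L, 0.8, 1.2)
    amp <- base_amp * if (is_ictal) config$ictal_amplitude_gain else 1
    x <- amp * sin(2 * pi * f0 * t + phase)
    if (is_ictal && config$broadband_gain_ictal > 0) {
      fa <- stats::runif(1L, 8, 13)
      fb <- stats::runif(1L, 13, 30)
      bamp <- config$broadband_gain_ictal * base_amp
      x <- x + bamp * sin(2 * pi * fa * t + stats::runif(1L, 0, 2 * pi)) +
        bamp * sin(2 * pi * fb * t + stats::runif(1L, 0, 2 * pi))
    }
    if (config$noise_sd > 0) {
      x <- x + config$noise_sd *
        pink_noise(n, config$sampling_rate_hz, config$noise_highpass_hz)
    }
    x
  })
  eeg_segment(samples, sampling_rate_hz = config$sampling_rate_hz,
              label = class_label,
              source_id = sprintf("synth/%s/%04d", class_label, index))
}

#' Generate a labeled synthetic dataset
#'
#' @param config A [synth_config()].
#' @return List of `2 * n_per_class` [eeg_segment] objects (all normal
#'   segments first, then all ictal segments), with `config` attached as an
#'   attribute.
#' @examples
#' ds <- generate_dataset(synth_config(n_per_class = 3, length = 512))
#' table(vapply(ds, `[[`, "", "label"))
#' @export
generate_dataset <- function(config = synth_config()) {
  out <- c(
    lapply(seq_len(config$n_per_class), function(i)
      generate_segment("normal", config, i)),
    lapply(seq_len(config$n_per_class), function(i)
      generate_segment("epileptic", config, i))
  )
  attr(out, "config") <- config
  out
}
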