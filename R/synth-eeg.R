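#' Simulate a multichannel EEG recording with planted microstates
#'
#' Builds a recording in which, at every sample, the scalp topography is
#' the planted template map of the current label scaled by an oscillatory
#' intensity carrier, plus spatially smoothed white noise:
#' `x(t) = a(t) * map[label(t), ] + noise(t)`. The carrier is a sinusoid at
#' `cfg$carrier_freq_hz` with a random phase per recording, and the noise
#' is scaled so that the root-mean-square amplitude ratio of signal to
#' noise equals `cfg$snr` (`Inf` for a noise-free recording). Because the
#' template maps are zero-mean across channels, the noise-free recording
#' is average-reference-free by construction.
#'
#' @param maps a [microstate_model] of planted templates.
#' @param labels a [label_sequence] (defines the record length).
#' @param cfg a [synth_config]; `n_channels` must match the maps.
#' @param montage montage used for the spatial noise smoothing; defaults
#'   to [montage_1010()] restricted to the maps' channels.
#' @param amplitude_uv RMS amplitude of the carrier, microvolts (sets the
#'   absolute scale; 15 by default).
#' @param annotations optional annotations tibble passed through.
#' @param noise_smoothing_mm kernel width of the spatial smoothing, as a
#'   chord fraction of the unit sphere (0 disables smoothing).
#' @return An [eeg_recording].
#' @export
simulate_eeg <- function(maps, labels, cfg, montage = NULL,
                         amplitude_uv = 15, annotations = NULL,
                         noise_smoothing_mm = 0.3) {
  stopifnot(inherits(maps, "microstate_model"),
            inherits(labels, "label_sequence"),
            inherits(cfg, "synth_config"))
  n_ch <- ncol(maps$maps)
  if (n_ch != cfg$n_channels) {
    stop_microdyn("maps have %d channels but cfg expects %d", n_ch,
                  cfg$n_channels)
  }
  if (seq_classes(labels) > maps$k) {
    stop_microdyn("label sequence has more classes than the model has maps")
  }
  if (is.null(montage)) {
    full <- montage_1010()
    if (n_ch != nrow(full)) {
      stop_microdyn("provide a montage for %d channels", n_ch)
    }
    montage <- full
  }
  n <- length(labels)
  fs <- cfg$fs
  amp <- amplitude_uv * sqrt(2)          # sinusoid peak for target RMS
  x <- with_seed(child_seed(cfg$seed, 97L), {
    phase <- stats::runif(1L, 0, 2 * pi)
    a <- amp * sin(2 * pi * cfg$carrier_freq_hz * (seq_len(n) - 1L) / fs +
                     phase)
    s <- maps$maps[as.integer(labels), , drop = FALSE] * a   # n x ch
    if (is.finite(cfg$snr)) {
      e <- matrix(stats::rnorm(n * n_ch), n, n_ch)
      if (noise_smoothing_mm > 0) {
        p <- montage_positions(montage)
        d <- as.matrix(stats::dist(p))
        ker <- exp(-(d / noise_smoothing_mm)^2)
        ker <- ker / rowSums(ker)
        e <- e %*% t(ker)
      }
      e <- e * sqrt(mean(s^2)) / sqrt(mean(e^2)) / cfg$snr
      s <- s + e
    }
    t(s)                                               # channels x samples
  })
  eeg_recording(x, fs = fs, montage = montage, reference = "original",
                annotations = annotations)
}
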