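#' Configuration for the synthetic-EEG generator
#'
#' Collects the knobs of the synthetic study conditions: channel count,
#' sampling rate, number of planted microstate classes, mean dwell time,
#' between-class transition matrix, oscillatory carrier frequency,
#' signal-to-noise ratio and a seed. Defaults emulate a 64-channel cap
#' sampled at 500 Hz with alpha-band carriers and 50 ms mean dwell, the
#' package's standing convention for quasi-stable topographic states.
#'
#' @param n_channels number of channels (must match the montage used).
#' @param fs sampling rate, Hz.
#' @param k_true number of planted microstate classes.
#' @param mean_duration_ms mean dwell time of a class, milliseconds.
#' @param transition_matrix `k_true` x `k_true` row-stochastic matrix of
#'   between-class jump probabilities; the diagonal may be zero (dwell is
#'   governed by `mean_duration_ms`, not by self-transitions). `NULL` means
#'   uniform over the other classes.
#' @param carrier_freq_hz frequency of the oscillatory intensity carrier.
#' @param snr linear amplitude ratio RMS(signal)/RMS(noise); `Inf` means
#'   noise-free.
#' @param dwell "geometric" (memoryless, the default) or "fixed" (every run
#'   exactly `mean_duration_ms`, for sharp run-length oracles).
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_channels = 64, fs = 500, k_true = 7,
                         mean_duration_ms = 50, transition_matrix = NULL,
                         carrier_freq_hz = 10, snr = 1,
                         dwell = c("geometric", "fixed"), seed = 1) {
  dwell <- match.arg(dwell)
  if (!is_count(n_channels) || n_channels < 8) {
    stop_microdyn("n_channels must be a count >= 8")
  }
  if (mean_duration_ms <= 0) stop_microdyn("mean_duration_ms must be > 0")
  if (fs <= 2 * carrier_freq_hz) {
    stop_microdyn("fs must exceed twice the carrier frequency")
  }
  if (!is.numeric(snr) || snr <= 0) {
    stop_microdyn("snr must be > 0 (use Inf for noise-free)")
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k_true - 1), k_true, k_true)
    diag(transition_matrix) <- 0
    if (k_true == 1L) transition_matrix <- matrix(1, 1, 1)
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != k_true ||
      ncol(transition_matrix) != k_true) {
    stop_microdyn("transition_matrix must be %d x %d", k_true, k_true)
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    stop_microdyn("transition_matrix rows must be non-negative and sum to 1")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         k_true = as.integer(k_true), mean_duration_ms = mean_duration_ms,
         transition_matrix = transition_matrix,
         carrier_freq_hz = carrier_freq_hz, snr = snr, dwell = dwell,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}
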