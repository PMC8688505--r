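#' Zero-phase band-pass FIR filter
#'
#' Hamming windowed-sinc band-pass with delay compensation (the kernel is
#' symmetric, so compensating the group delay yields a zero-phase,
#' one-pass filter). The kernel length follows a 1 Hz transition band at
#' the low edge, giving at least 50 dB of stop-band attenuation for drift
#' below the pass band.
#'
#' @param rec an [eeg_recording].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param transition_hz transition bandwidth at the low edge.
#' @return The filtered recording.
#' @export
bandpass_fir <- function(rec, lo = 1, hi = 40, transition_hz = 1) {
  fs <- rec$fs
  if (!(lo > 0 && lo < hi && hi < fs / 2)) {
    stop_microdyn("need 0 < lo < hi < fs/2")
  }
  ntaps <- ceiling(3.3 * fs / transition_hz)
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  if (n_samples(rec) < ntaps) {
    stop_microdyn("record (%d samples) shorter than the filter (%d taps)",
                  n_samples(rec), ntaps)
  }
  h_lo <- windowed_sinc(hi / fs, ntaps)
  h_hi <- windowed_sinc(lo / fs, ntaps)
  kernel <- h_lo - h_hi                   # band-pass = LP(hi) - LP(lo)
  rec$data <- t(apply(rec$data, 1L, fir_filtfft, kernel = kernel))
  rec
}

#' Quality-control reports
#'
#' Collects, for one preprocessing pass, the globally bad channels (with
#' the criterion that flagged each), the rejected epochs, and the locally
#' interpolated (epoch, channel) pairs, plus the fraction of epochs
#' rejected.
#'
#' @param bad_global_channels tibble `channel`, `criterion`.
#' @param bad_segments tibble `epoch`, `criterion`.
#' @param interpolated_local tibble `epoch`, `channel`, `criterion`.
#' @param n_epochs total number of epochs considered.
#' @return A `qc_report`.
#' @export
qc_report <- function(bad_global_channels = NULL, bad_segments = NULL,
                      interpolated_local = NULL, n_epochs = NA_integer_) {
  empty_ch <- tibble::tibble(channel = character(), criterion = character())
  empty_seg <- tibble::tibble(epoch = integer(), criterion = character())
  empty_loc <- tibble::tibble(epoch = integer(), channel = character(),
                              criterion = character())
  norm <- function(x, template) {
    if (is.null(x) || !nrow(x)) template else x
  }
  bad_segments <- norm(bad_segments, empty_seg)
  frac <- if (is.na(n_epochs) || n_epochs == 0) 0 else
    length(unique(bad_segments$epoch)) / n_epochs
  structure(
    list(bad_global_channels = norm(bad_global_channels, empty_ch),
         bad_segments = bad_segments,
         interpolated_local = norm(interpolated_local, empty_loc),
         n_epochs = n_epochs,
         fraction_rejected = frac),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> %d bad channels, %d rejected epochs (%.1f%%), %d local interpolations\n",
    nrow(x$bad_global_channels), length(unique(x$bad_segments$epoch)),
    100 * x$fraction_rejected, nrow(x$interpolated_local)))
  invisible(x)
}

#' Detect globally bad channels
#'
#' Flags a channel when any of three rule-based criteria fires:
#' * `flat` — some rolling window of `flat_s` seconds has peak-to-peak
#'   amplitude below `flat_ptp_uv` microvolts;
#' * `correlation` — the channel's best correlation with its `n_neighbors`
#'   nearest electrodes falls below `corr_threshold`;
#' * `amplitude` — the robust z-score of the channel's RMS amplitude
#'   across channels exceeds `amp_sd` standard deviations.
#'
#' @param rec an [eeg_recording].
#' @param flat_s flat-window length, seconds.
#' @param flat_ptp_uv peak-to-peak threshold defining "flat".
#' @param corr_threshold neighbour-correlation threshold.
#' @param amp_sd amplitude z-score threshold.
#' @param n_neighbors neighbours entering the correlation rule.
#' @return A [qc_report] with `bad_global_channels` filled in.
#' @export
detect_bad_channels <- function(rec, flat_s = 5, flat_ptp_uv = 0.5,
                                corr_threshold = 0.8, amp_sd = 3,
                                n_neighbors = 4) {
  x <- rec$data
  n_ch <- nrow(x)
  if (n_ch < 8L) stop_microdyn("need at least 8 channels")
  rows <- list()
  # flat rule: rolling windows stepping by 1 s
  win <- as.integer(round(flat_s * rec$fs))
  if (ncol(x) >= win) {
    step <- as.integer(round(rec$fs))
    starts <- seq(1L, ncol(x) - win + 1L, by = step)
    for (ch in seq_len(n_ch)) {
      ptp <- vapply(starts, function(s0) {
        seg <- x[ch, s0:(s0 + win - 1L)]
        max(seg) - min(seg)
      }, numeric(1L))
      if (any(ptp < flat_ptp_uv)) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(channel = rownames(x)[ch], criterion = "flat")
      }
    }
  }
  # neighbour-correlation rule
  nb <- channel_neighbors(rec$montage, k = n_neighbors)
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  for (ch in seq_len(n_ch)) {
    best <- max(abs(cc[ch, nb[[rownames(x)[ch]]]]))
    if (best < corr_threshold) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(channel = rownames(x)[ch], criterion = "correlation")
    }
  }
  # robust amplitude rule on per-channel RMS
  rms <- sqrt(rowMeans(x^2))
  med <- stats::median(rms)
  s <- stats::mad(rms)
  if (s > 0) {
    z <- (rms - med) / s
    for (ch in which(abs(z) > amp_sd)) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(channel = rownames(x)[ch], criterion = "amplitude")
    }
  }
  qc_report(bad_global_channels = dplyr::bind_rows(rows))
}

#' Segment a recording into fixed-length epochs
#'
#' Consecutive non-overlapping epochs; a trailing remainder shorter than
#' one epoch is dropped. Annotation tags are carried to the epochs whose
#' onset falls inside them.
#'
#' @param rec an [eeg_recording].
#' @param length_s epoch length in seconds; `length_s * fs` must be an
#'   integer.
#' @return An `eeg_epochs` object: channels x samples x epochs array plus
#'   metadata.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  len <- length_s * rec$fs
  if (abs(len - round(len)) > 1e-9) {
    stop_microdyn("length_s * fs must be an integer")
  }
  len <- as.integer(round(len))
  n_ep <- n_samples(rec) %/% len
  if (n_ep < 1L) stop_microdyn("record shorter than one epoch")
  idx <- seq_len(n_ep * len)
  arr <- array(rec$data[, idx], dim = c(nrow(rec$data), len, n_ep),
               dimnames = list(rownames(rec$data), NULL, NULL))
  onset <- (seq_len(n_ep) - 1L) * length_s
  cond <- rep(NA_character_, n_ep)
  run <- rep(NA_integer_, n_ep)
  if (nrow(rec$annotations) > 0) {
    for (i in seq_len(nrow(rec$annotations))) {
      a <- rec$annotations[i, ]
      hit <- onset >= a$onset - 1e-9 & onset < a$onset + a$duration - 1e-9
      cond[hit] <- a$condition
      run[hit] <- a$run
    }
  }
  structure(
    list(data = arr, fs = rec$fs, montage = rec$montage,
         reference = rec$reference, length_s = length_s,
         epochs = tibble::tibble(epoch = seq_len(n_ep), onset = onset,
                                 condition = cond, run = run)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs of %g s, %d channels @ %g Hz\n",
              dim(x$data)[3L], x$length_s, dim(x$data)[1L], x$fs))
  invisible(x)
}

# the four per-(epoch, channel) statistics of the local-channel QC
faster_statistics <- function(epochs) {
  arr <- epochs$data
  list(
    variance = apply(arr, c(1L, 3L), stats::var),
    median_gradient = apply(arr, c(1L, 3L),
                            function(v) stats::median(abs(diff(v)))),
    amplitude_range = apply(arr, c(1L, 3L), function(v) max(v) - min(v)),
    mean_deviation = {
      mu <- apply(arr, c(1L, 3L), mean)
      abs(sweep(mu, 2L, colMeans(mu)))
    }
  )
}

#' Local-channel quality control within epochs
#'
#' For every (epoch, channel) pair, computes four statistics — variance,
#' median absolute gradient, amplitude range and deviation from the mean
#' amplitude — z-scores each across channels within the epoch, and flags
#' the pair when any |z| exceeds `z_threshold`. Flagged channels are meant
#' to be interpolated within their epoch, not dropped. A criterion whose
#' statistic has zero spread in an epoch is skipped with a warning.
#'
#' @param epochs an `eeg_epochs` object (>= 3 epochs).
#' @param z_threshold z-score cut-off.
#' @return A [qc_report] with `interpolated_local` listing the flags.
#' @export
faster_local_qc <- function(epochs, z_threshold = 3) {
  n_ep <- dim(epochs$data)[3L]
  if (n_ep < 3L) stop_microdyn("need at least 3 epochs")
  stats_list <- faster_statistics(epochs)
  labels <- dimnames(epochs$data)[[1L]] %||% epochs$montage$channel
  rows <- list()
  for (crit in names(stats_list)) {
    s <- stats_list[[crit]]                  # channels x epochs
    mu <- colMeans(s)
    sdv <- apply(s, 2L, stats::sd)
    degenerate <- sdv == 0
    if (any(degenerate)) {
      warn_microdyn("criterion '%s' skipped in %d epoch(s): zero spread",
                    crit, sum(degenerate))
      sdv[degenerate] <- Inf
    }
    z <- abs(sweep(sweep(s, 2L, mu), 2L, sdv, "/"))
    hit <- which(z > z_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        epoch = as.integer(hit[, 2L]),
        channel = labels[hit[, 1L]],
        criterion = crit
      )
    }
  }
  qc_report(interpolated_local = dplyr::bind_rows(rows), n_epochs = n_ep)
}

#' Interpolate locally flagged channels within their epochs
#'
#' @param epochs an `eeg_epochs` object.
#' @param qc a [qc_report] from [faster_local_qc()].
#' @return The epochs with flagged channels rebuilt by spherical splines.
#' @export
repair_epochs <- function(epochs, qc) {
  flags <- unique(qc$interpolated_local[, c("epoch", "channel")])
  if (!nrow(flags)) return(epochs)
  p <- montage_positions(epochs$montage)
  for (ep in unique(flags$epoch)) {
    bad <- flags$channel[flags$epoch == ep]
    good <- setdiff(epochs$montage$channel, bad)
    if (length(bad) >= length(good)) {
      warn_microdyn("epoch %d: too many flagged channels, left untouched", ep)
      next
    }
    op <- spline_operator(p[good, , drop = FALSE], p[bad, , drop = FALSE])
    epochs$data[bad, , ep] <- op %*% epochs$data[good, , ep]
  }
  epochs
}

#' Reject bad epochs
#'
#' An epoch is rejected when any channel exceeds `amp_uv` microvolts in
#' absolute amplitude, or when either probability criterion fires: the
#' z-score (across epochs) of a channel's Gaussian negative log-likelihood
#' in the epoch ("single-electrode probability"), or the z-score of the
#' epoch's pooled negative log-likelihood over all channels
#' ("electrode-group probability"), exceeds `z_threshold`.
#'
#' @param epochs an `eeg_epochs` object.
#' @param amp_uv absolute amplitude threshold, microvolts.
#' @param z_threshold z-score cut-off for the probability criteria.
#' @return A [qc_report] with `bad_segments` filled in.
#' @export
reject_segments <- function(epochs, amp_uv = 100, z_threshold = 3) {
  arr <- epochs$data
  n_ep <- dim(arr)[3L]
  rows <- list()
  absmax <- apply(arr, 3L, function(m) max(abs(m)))
  for (ep in which(absmax > amp_uv)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(epoch = ep,
                                                criterion = "amplitude")
  }
  # Gaussian negative log-likelihood per (channel, epoch), parameters
  # estimated per channel across all epochs
  n_ch <- dim(arr)[1L]
  nll <- matrix(0, n_ch, n_ep)
  for (ch in seq_len(n_ch)) {
    v <- arr[ch, , ]
    mu <- mean(v)
    sg <- stats::sd(as.vector(v))
    if (sg == 0) next
    nll[ch, ] <- colMeans((v - mu)^2) / (2 * sg^2)
  }
  zch <- t(scale(t(nll)))                     # z across epochs per channel
  zch[!is.finite(zch)] <- 0
  single_hit <- apply(abs(zch) > z_threshold, 2L, any)
  pooled <- colMeans(nll)
  zp <- as.vector(scale(pooled))
  zp[!is.finite(zp)] <- 0
  group_hit <- abs(zp) > z_threshold
  for (ep in which(single_hit)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(epoch = ep,
                                                criterion = "single_probability")
  }
  for (ep in which(group_hit)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(epoch = ep,
                                                criterion = "group_probability")
  }
  rep <- qc_report(bad_segments = dplyr::bind_rows(rows), n_epochs = n_ep)
  if (length(unique(rep$bad_segments$epoch)) == n_ep && n_ep > 0L) {
    stop_microdyn("segment rejection dropped every epoch")
  }
  rep
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample;
#' idempotent.
#'
#' @param rec an [eeg_recording].
#' @return The re-referenced recording, with `reference = "average"`.
#' @export
average_reference <- function(rec) {
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Downsample with anti-aliasing
#'
#' Low-pass filters at 80% of the new Nyquist frequency (zero-phase
#' windowed-sinc) and keeps every `fs/fs_new`-th sample; the rate ratio
#' must be an integer.
#'
#' @param rec an [eeg_recording].
#' @param fs_new target rate in Hz, `< fs`.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, fs_new) {
  fs <- rec$fs
  if (fs_new >= fs) stop_microdyn("fs_new must be below fs")
  ratio <- fs / fs_new
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop_microdyn("fs (%g) must be an integer multiple of fs_new (%g)",
                  fs, fs_new)
  }
  ratio <- as.integer(round(ratio))
  cutoff <- 0.4 * fs_new                    # 80% of the new Nyquist
  ntaps <- ceiling(3.3 * fs / (0.2 * fs_new))
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  kernel <- windowed_sinc(cutoff / fs, ntaps)
  filtered <- t(apply(rec$data, 1L, fir_filtfft, kernel = kernel))
  keep <- seq(1L, ncol(filtered), by = ratio)
  rec$data <- filtered[, keep, drop = FALSE]
  rec$fs <- fs_new
  rec
}

#' MARA-style artefact-removal hook
#'
#' Placeholder stage for ICA-based artefact removal: the default hook
#' returns its input unchanged. Supply `fun` to plug in an external
#' decomposition.
#'
#' @param rec an [eeg_recording].
#' @param fun optional function `rec -> rec`.
#' @return The (possibly transformed) recording.
#' @export
artifact_removal_hook <- function(rec, fun = NULL) {
  if (is.null(fun)) rec else fun(rec)
}

#' Reassemble retained epochs into a continuous recording
#'
#' @param epochs an `eeg_epochs` object.
#' @param drop integer epochs to exclude (e.g. from [reject_segments()]).
#' @return An [eeg_recording] concatenating the retained epochs.
#' @export
assemble_recording <- function(epochs, drop = integer()) {
  keep <- setdiff(seq_len(dim(epochs$data)[3L]), drop)
  if (!length(keep)) stop_microdyn("no epochs left to assemble")
  x <- matrix(epochs$data[, , keep], nrow = dim(epochs$data)[1L])
  rownames(x) <- dimnames(epochs$data)[[1L]]
  meta <- epochs$epochs[keep, ]
  len_s <- epochs$length_s
  ann <- NULL
  if (any(!is.na(meta$condition))) {
    ann <- tibble::tibble(
      onset = (seq_along(keep) - 1L) * len_s,
      duration = len_s,
      condition = meta$condition,
      run = meta$run
    )
  }
  eeg_recording(x, fs = epochs$fs, montage = epochs$montage,
                reference = epochs$reference, annotations = ann)
}

#' Full rule-based preprocessing chain
#'
#' Runs the package's cleaning chain in order: band-pass filter, global
#' bad-channel detection, artefact-removal hook, epoching, local-channel
#' QC with spherical-spline repair, segment rejection, spherical-spline
#' interpolation of the global bad channels, average reference, and
#' downsampling.
#'
#' @param rec an [eeg_recording].
#' @param lo,hi filter band, Hz.
#' @param epoch_s epoch length, seconds.
#' @param fs_new target sampling rate, Hz (`NULL` to skip).
#' @param qc list of threshold overrides passed to the QC stages
#'   (`flat_s`, `flat_ptp_uv`, `corr_threshold`, `amp_sd`, `amp_uv`,
#'   `z_threshold`).
#' @param artifact_fun optional hook passed to [artifact_removal_hook()].
#' @return list with `recording` (cleaned, average-referenced, resampled)
#'   and `qc` (merged [qc_report]).
#' @export
preprocess <- function(rec, lo = 1, hi = 40, epoch_s = 2, fs_new = 250,
                       qc = list(), artifact_fun = NULL) {
  q <- function(name, default) qc[[name]] %||% default
  rec <- bandpass_fir(rec, lo, hi)
  global <- detect_bad_channels(rec,
                                flat_s = q("flat_s", 5),
                                flat_ptp_uv = q("flat_ptp_uv", 0.5),
                                corr_threshold = q("corr_threshold", 0.8),
                                amp_sd = q("amp_sd", 3))
  rec <- artifact_removal_hook(rec, artifact_fun)
  epochs <- epoch_recording(rec, epoch_s)
  local <- faster_local_qc(epochs, z_threshold = q("z_threshold", 3))
  epochs <- repair_epochs(epochs, local)
  segs <- reject_segments(epochs, amp_uv = q("amp_uv", 100),
                          z_threshold = q("z_threshold", 3))
  cleaned <- assemble_recording(epochs, drop = unique(segs$bad_segments$epoch))
  bad_ch <- unique(global$bad_global_channels$channel)
  if (length(bad_ch)) {
    cleaned <- spherical_spline_interpolate(cleaned, bad_ch)
  }
  cleaned <- average_reference(cleaned)
  if (!is.null(fs_new) && fs_new < cleaned$fs) {
    cleaned <- downsample(cleaned, fs_new)
  }
  report <- qc_report(
    bad_global_channels = global$bad_global_channels,
    bad_segments = segs$bad_segments,
    interpolated_local = local$interpolated_local,
    n_epochs = dim(epochs$data)[3L]
  )
  list(recording = cleaned, qc = report)
}
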