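#' Canonical frequency bands
#'
#' The default band set of the task-related power analysis: delta
#' (1-3.5 Hz), theta (4-7.5 Hz), alpha (8-13.5 Hz), beta (14-29 Hz).
#'
#' @return tibble with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    lo = c(1, 4, 8, 14),
    hi = c(3.5, 7.5, 13.5, 29)
  )
}

#' Welch power spectral density
#'
#' One-sided PSD per channel in microvolts^2/Hz by Welch's method: the
#' record is split into windows of `nperseg` samples with `noverlap`
#' samples of overlap, each segment is mean-subtracted, tapered by a Hann
#' window, and the periodograms are averaged. Defaults match a 2-s window
#' with 50% overlap at a 250 Hz analysis rate.
#'
#' @param rec an [eeg_recording] (or channels x samples matrix with `fs`).
#' @param nperseg window length, samples.
#' @param noverlap overlap, samples.
#' @param fs sampling rate when `rec` is a bare matrix.
#' @return tibble with columns `channel`, `freq` (Hz), `psd`
#'   (microvolts^2/Hz); attribute `fs`.
#' @export
welch_psd <- function(rec, nperseg = 500, noverlap = 250, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$data
    fs <- rec$fs
  } else {
    x <- as.matrix(rec)
    if (is.null(fs)) stop_microdyn("fs required for a bare matrix")
  }
  n <- ncol(x)
  if (n < nperseg) {
    stop_microdyn("record (%d samples) shorter than one window (%d)",
                  n, nperseg)
  }
  step <- nperseg - noverlap
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))
  u <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  freq <- (seq_len(nfreq) - 1L) * fs / nperseg
  psd <- matrix(0, nrow(x), nfreq)
  for (s0 in starts) {
    seg <- x[, s0:(s0 + nperseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2L, w, "*")
    ft <- t(stats::mvfft(t(seg)))
    p <- (Mod(ft[, seq_len(nfreq), drop = FALSE])^2) / (fs * u)
    p[, 2:(nfreq - 1L)] <- 2 * p[, 2:(nfreq - 1L)]
    psd <- psd + p
  }
  psd <- psd / length(starts)
  labels <- rownames(x) %||% paste0("ch", seq_len(nrow(x)))
  out <- tibble::tibble(
    channel = rep(labels, times = nfreq),
    freq = rep(freq, each = nrow(x)),
    psd = as.vector(psd)
  )
  attr(out, "fs") <- fs
  out
}

#' Band power by trapezoidal integration
#'
#' Integrates the PSD between the band edges with the composite
#' trapezoidal rule; the edges are included by linear interpolation of the
#' spectrum when they fall between frequency bins.
#'
#' @param psd tibble from [welch_psd()].
#' @param lo,hi band edges in Hz (or a one-row band tibble via `band`).
#' @param band optional row of [eeg_bands()].
#' @return tibble with columns `channel`, `power` (microvolts^2).
#' @export
band_power <- function(psd, lo = NULL, hi = NULL, band = NULL) {
  if (!is.null(band)) {
    lo <- band$lo
    hi <- band$hi
  }
  if (is.null(lo) || is.null(hi) || !(lo < hi)) {
    stop_microdyn("need band edges lo < hi")
  }
  freqs <- sort(unique(psd$freq))
  if (lo < min(freqs) - 1e-9 || hi > max(freqs) + 1e-9) {
    stop_microdyn("band [%g, %g] outside spectral support [%g, %g]",
                  lo, hi, min(freqs), max(freqs))
  }
  chans <- unique(psd$channel)
  power <- vapply(chans, function(ch) {
    sub <- psd[psd$channel == ch, ]
    sub <- sub[order(sub$freq), ]
    f <- sub$freq
    p <- sub$psd
    inner <- f > lo & f < hi
    grid_f <- c(lo, f[inner], hi)
    grid_p <- c(stats::approx(f, p, xout = lo)$y, p[inner],
                stats::approx(f, p, xout = hi)$y)
    trapz(grid_f, grid_p)
  }, numeric(1L))
  tibble::tibble(channel = chans, power = unname(power))
}

#' Task-related power (log-power change from a reference)
#'
#' The log band power during an activation condition minus the log band
#' power during the reference (the first resting block): positive values
#' are power increases from rest, negative values task-related power
#' decreases. Base-10 logarithms by default; inference in the package is
#' sign- and order-based, hence invariant to the base.
#'
#' @param activation_power,reference_power positive band powers
#'   (scalars or equal-length vectors).
#' @param log_base base of the logarithm.
#' @return TRP value(s).
#' @export
compute_trp <- function(activation_power, reference_power, log_base = 10) {
  if (any(activation_power <= 0) || any(reference_power <= 0)) {
    stop_microdyn("band powers must be positive to take logarithms")
  }
  log(activation_power, base = log_base) -
    log(reference_power, base = log_base)
}

#' Band-power and TRP table for a set of recordings
#'
#' Computes per-channel band powers for every recording and the TRP of
#' each task recording against the participant's reference (first rest)
#' recording, in every canonical band.
#'
#' @param recs named list of [eeg_recording]s (cleaned, at the analysis
#'   rate), one per (condition, run).
#' @param meta tibble with one row per recording: `name`, `participant`,
#'   `condition`, `run`.
#' @param reference_condition condition tag of the resting reference.
#' @param bands band definition tibble, defaults to [eeg_bands()].
#' @param nperseg,noverlap Welch parameters.
#' @return tibble with columns `participant`, `condition`, `run`,
#'   `channel`, `band`, `power`, `log_power`, `trp`.
#' @export
band_power_table <- function(recs, meta, reference_condition = "REST",
                             bands = eeg_bands(), nperseg = 500,
                             noverlap = 250) {
  stopifnot(all(meta$name %in% names(recs)))
  per_rec <- lapply(seq_len(nrow(meta)), function(i) {
    rec <- recs[[meta$name[i]]]
    psd <- welch_psd(rec, nperseg = nperseg, noverlap = noverlap)
    rows <- lapply(seq_len(nrow(bands)), function(b) {
      bp <- band_power(psd, lo = bands$lo[b], hi = bands$hi[b])
      tibble::tibble(participant = meta$participant[i],
                     condition = meta$condition[i],
                     run = meta$run[i],
                     channel = bp$channel,
                     band = bands$band[b],
                     power = bp$power)
    })
    dplyr::bind_rows(rows)
  })
  tab <- dplyr::bind_rows(per_rec)
  tab$log_power <- log10(tab$power)
  ref <- tab[tab$condition == reference_condition, ]
  if (!nrow(ref)) {
    stop_microdyn("no recording tagged with the reference condition '%s'",
                  reference_condition)
  }
  ref <- dplyr::summarise(
    dplyr::group_by(ref, .data$participant, .data$channel, .data$band),
    ref_log_power = mean(.data$log_power), .groups = "drop")
  no_ref <- setdiff(unique(tab$participant), unique(ref$participant))
  if (length(no_ref)) {
    message(sprintf(
      "excluding participant(s) without a %s reference from TRP: %s",
      reference_condition, paste(no_ref, collapse = ", ")))
    tab <- tab[!tab$participant %in% no_ref, ]
  }
  tab <- dplyr::left_join(tab, ref,
                          by = c("participant", "channel", "band"))
  tab$trp <- tab$log_power - tab$ref_log_power
  tab$ref_log_power <- NULL
  tab
}

#' Aggregate TRP over cortical regions and hemispheres
#'
#' Averages TRP within each (region, hemisphere) electrode group, after
#' first averaging across runs of the same condition. Channels outside
#' the grouping are ignored; a listed channel missing from the data
#' triggers a warning and the mean is taken over the available ones.
#'
#' @param table tibble from [band_power_table()].
#' @param regions grouping tibble, defaults to [region_table()].
#' @param drop_reference drop the reference condition (its TRP is 0)?
#' @param reference_condition tag of the reference condition.
#' @return tibble `participant`, `condition`, `band`, `region`,
#'   `hemisphere`, `trp`.
#' @export
aggregate_regions <- function(table, regions = region_table(),
                              drop_reference = TRUE,
                              reference_condition = "REST") {
  if (drop_reference) {
    table <- table[table$condition != reference_condition, ]
  }
  missing <- setdiff(regions$channel, unique(table$channel))
  if (length(missing)) {
    warn_microdyn("channels missing from the data: %s",
                  paste(missing, collapse = ", "))
  }
  # condition-wise TRP: average across runs of the same condition first
  cond <- dplyr::summarise(
    dplyr::group_by(table, .data$participant, .data$condition,
                    .data$channel, .data$band),
    trp = mean(.data$trp), .groups = "drop")
  joined <- dplyr::inner_join(cond, regions, by = "channel")
  dplyr::summarise(
    dplyr::group_by(joined, .data$participant, .data$condition, .data$band,
                    .data$region, .data$hemisphere),
    trp = mean(.data$trp), .groups = "drop")
}
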