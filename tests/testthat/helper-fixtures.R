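# shared fixture builders; everything is generated in code at test time

the_montage <- montage_1010()

# small montage for cheap tests
small_montage <- function(n = 8) {
  montage(the_montage$channel[seq_len(n)],
          as.matrix(the_montage[seq_len(n), c("x", "y", "z")]))
}

# planted maps + labels + recording in one call
synth_recording <- function(seed = 1, k = 7, fs = 250, seconds = 60,
                            snr = 2, mean_duration_ms = 50,
                            carrier = 10, montage = the_montage,
                            annotations = NULL) {
  maps <- make_template_maps(montage, k, seed = seed)
  cfg <- synth_config(n_channels = nrow(montage), fs = fs, k_true = k,
                      mean_duration_ms = mean_duration_ms,
                      carrier_freq_hz = carrier, snr = snr, seed = seed + 1)
  labels <- simulate_label_sequence(cfg, as.integer(fs * seconds))
  rec <- simulate_eeg(maps, labels, cfg, montage = montage,
                      annotations = annotations)
  list(maps = maps, labels = labels, rec = rec, cfg = cfg)
}

# greedy-free optimal matching of recovered to planted maps, returning the
# per-class |spatial correlation| under the best permutation
recovery_correlations <- function(recovered, planted) {
  cc <- abs(microdyn:::map_correlation(recovered$maps, planted$maps))
  perm <- microdyn:::best_permutation(cc)
  list(corr = cc[cbind(seq_len(nrow(cc)), perm)], perm = perm)
}

# minimal EDF writer (16-bit, one data-record per second) used to exercise
# the reader against a known signal
write_edf_fixture <- function(path, x, fs, labels,
                              phys_range = c(-200, 200)) {
  n_ch <- nrow(x)
  record_s <- 1
  spr <- as.integer(fs * record_s)
  n_rec <- ncol(x) %/% spr
  dig_min <- -32768; dig_max <- 32767
  gain <- (phys_range[2] - phys_range[1]) / (dig_max - dig_min)
  dig <- round((x - phys_range[1]) / gain + dig_min)
  dig <- pmin(pmax(dig, dig_min), dig_max)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- as.character(s)
    vapply(s, function(z) formatC(z, width = w, flag = "-"), character(1))
  }
  wr <- function(s, w) writeChar(paste(pad(s, w), collapse = ""), con,
                                 eos = NULL)
  wr("0", 8); wr("patient", 80); wr("recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + 256 * n_ch, 8); wr("", 44); wr(n_rec, 8); wr(record_s, 8)
  wr(n_ch, 4)
  wr(labels, 16); wr(rep("", n_ch), 80); wr(rep("uV", n_ch), 8)
  wr(rep(phys_range[1], n_ch), 8); wr(rep(phys_range[2], n_ch), 8)
  wr(rep(dig_min, n_ch), 8); wr(rep(dig_max, n_ch), 8)
  wr(rep("", n_ch), 80); wr(rep(spr, n_ch), 8); wr(rep("", n_ch), 32)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      writeBin(as.integer(dig[ch, ((r - 1) * spr + 1):(r * spr)]), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
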