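test_that("Welch spectra conserve power and localise sinusoids", {
  set.seed(1)
  fs <- 250
  x <- matrix(rnorm(2 * fs * 60), 2, fs * 60)
  rownames(x) <- c("a", "b")
  psd <- welch_psd(x, fs = fs)
  total <- band_power(psd, lo = 0, hi = fs / 2)
  expect_true(all(abs(total$power - 1) < 0.05))      # Parseval

  t <- (0:(fs * 60 - 1)) / fs
  amp <- 3
  xs <- matrix(amp * sin(2 * pi * 10 * t), 1)
  rownames(xs) <- "s"
  ps <- welch_psd(xs, fs = fs)
  alpha <- band_power(ps, lo = 8, hi = 13.5)$power
  theta <- band_power(ps, lo = 4, hi = 7.5)$power
  expect_lt(abs(alpha / (amp^2 / 2) - 1), 0.05)
  expect_gt(alpha / theta, 100)                      # leakage bound

  z <- welch_psd(matrix(0, 1, 1000), fs = fs)
  expect_true(all(z$psd == 0))
  expect_error(welch_psd(matrix(0, 1, 100), fs = fs), "shorter than")
})

test_that("band powers integrate the spectrum exactly on flat pieces", {
  # flat PSD of height c over the band: integral = c * width
  freq <- seq(0, 125, by = 0.5)
  flat <- tibble::tibble(channel = "a", freq = freq, psd = 2)
  expect_equal(band_power(flat, lo = 8, hi = 13.5)$power, 2 * 5.5)
  # boundary interpolation: edges between bins still give c * width
  expect_equal(band_power(flat, lo = 8.25, hi = 13.3)$power, 2 * 5.05)
  expect_error(band_power(flat, lo = 10, hi = 10), "lo < hi")
  expect_error(band_power(flat, lo = 100, hi = 200), "outside")

  # additivity over adjacent bands on a smooth spectrum
  smooth <- tibble::tibble(channel = "a", freq = freq,
                           psd = 1 / (1 + (freq / 10)^2))
  whole <- band_power(smooth, lo = 1, hi = 29)$power
  parts <- sum(vapply(seq_len(4), function(i) {
    b <- eeg_bands()[i, ]
    band_power(smooth, lo = b$lo, hi = b$hi)$power
  }, numeric(1)))
  # the default bands leave small gaps (3.5-4, 7.5-8, 13.5-14); compare on
  # the covered support
  covered <- sum(vapply(seq_len(4), function(i) {
    b <- eeg_bands()[i, ]
    microdyn:::trapz(c(b$lo, freq[freq > b$lo & freq < b$hi], b$hi),
                     stats::approx(freq, smooth$psd,
                                   xout = c(b$lo, freq[freq > b$lo &
                                                         freq < b$hi],
                                            b$hi))$y)
  }, numeric(1)))
  expect_lt(abs(parts - covered) / covered, 0.01)
  expect_lt(parts, whole)
})

test_that("TRP is an antisymmetric log ratio", {
  expect_equal(compute_trp(5, 5), 0)
  expect_equal(compute_trp(10, 1), 1)
  expect_equal(compute_trp(1, 10), -1)
  expect_equal(compute_trp(3.7, 1.2), -compute_trp(1.2, 3.7))
  expect_error(compute_trp(0, 1), "positive")
  expect_equal(compute_trp(8, 2, log_base = 2), 2)
})

test_that("a planted 10x alpha power change is recovered as TRP = 1", {
  mont <- the_montage
  maps <- make_template_maps(mont, 4, seed = 51)
  base <- synth_config(n_channels = 64, fs = 250, k_true = 4,
                       carrier_freq_hz = 10, snr = 5, seed = 52)
  labels <- simulate_label_sequence(base, 250 * 60)
  rest <- simulate_eeg(maps, labels, base, montage = mont)
  task_cfg <- base
  task_cfg$snr <- 5 * sqrt(10)      # same absolute noise, 10x alpha power
  task <- simulate_eeg(maps, labels, task_cfg, montage = mont,
                       amplitude_uv = 15 * sqrt(10))
  recs <- list(rest = rest, task = task)
  meta <- tibble::tibble(name = c("rest", "task"),
                         participant = "p1",
                         condition = c("REST", "IG"),
                         run = 1L)
  tab <- band_power_table(recs, meta)
  agg <- aggregate_regions(tab)
  frontal_alpha <- agg$trp[agg$band == "alpha" & agg$region == "frontal"]
  expect_true(all(abs(frontal_alpha - 1) < 0.02))
})

test_that("regional aggregation follows the printed electrode groups", {
  rt <- region_table()
  base <- tidyr::expand_grid(participant = "p1", condition = c("IG", "IE"),
                             run = 1L, channel = rt$channel,
                             band = "alpha")
  base$power <- 1
  base$log_power <- 0
  base$trp <- 0
  # constant TRP -> every region mean equals that constant
  base$trp <- 0.3
  agg <- aggregate_regions(base)
  expect_true(all(abs(agg$trp - 0.3) < 1e-12))
  expect_equal(nrow(agg), 2 * 5 * 2)      # condition x region x hemisphere

  # left-frontal at 1, everything else 0
  lf <- rt$channel[rt$region == "frontal" & rt$hemisphere == "left"]
  base$trp <- ifelse(base$channel %in% lf, 1, 0)
  agg2 <- aggregate_regions(base)
  expect_true(all(agg2$trp[agg2$region == "frontal" &
                             agg2$hemisphere == "left"] == 1))
  expect_true(all(agg2$trp[!(agg2$region == "frontal" &
                               agg2$hemisphere == "left")] == 0))

  expect_warning(aggregate_regions(base[base$channel != "Fp1", ]),
                 "missing")
})
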