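test_that("template maps are centred, unit-norm, distinct and reproducible", {
  for (k in c(4, 7)) {
    mm <- make_template_maps(the_montage, k, seed = k)
    expect_equal(dim(mm$maps), c(k, 64))
    expect_true(all(abs(rowMeans(mm$maps)) < 1e-12))
    expect_equal(unname(sqrt(rowSums(mm$maps^2))), rep(1, k),
                 tolerance = 1e-12)
    cc <- abs(tcrossprod(mm$maps))
    expect_lte(max(cc[upper.tri(cc)]), 0.7)
  }
  expect_identical(make_template_maps(the_montage, 7, seed = 2)$maps,
                   make_template_maps(the_montage, 7, seed = 2)$maps)
  expect_error(make_template_maps(small_montage(8), 7), "2 <= k")
})

test_that("label sequences honour the configured dwell law", {
  cfg1 <- synth_config(n_channels = 8, fs = 250, k_true = 1,
                       transition_matrix = matrix(1, 1, 1), seed = 1)
  expect_true(all(as.integer(simulate_label_sequence(cfg1, 500)) == 1L))

  cfg2 <- synth_config(n_channels = 8, fs = 250, k_true = 2,
                       mean_duration_ms = 40, seed = 2)
  s <- simulate_label_sequence(cfg2, 2e5)
  mean_run <- mean(rle(as.integer(s))$lengths)
  expect_lt(abs(mean_run / 10 - 1), 0.15)   # geometric mean fs*ms/1000 = 10

  # dwell-mean convergence at n = 1e6 (relative error < 5%)
  cfg3 <- synth_config(n_channels = 8, fs = 250, k_true = 4,
                       mean_duration_ms = 50, seed = 3)
  s3 <- simulate_label_sequence(cfg3, 1e6)
  expect_lt(abs(mean(rle(as.integer(s3))$lengths) / 12.5 - 1), 0.05)

  # fixed-dwell mode gives exact run lengths away from the boundary
  cfg4 <- synth_config(n_channels = 8, fs = 250, k_true = 3,
                       mean_duration_ms = 40, dwell = "fixed", seed = 4)
  runs <- rle(as.integer(simulate_label_sequence(cfg4, 5000)))$lengths
  expect_true(all(head(runs, -1) == 10))

  expect_identical(as.integer(simulate_label_sequence(cfg2, 1000)),
                   as.integer(simulate_label_sequence(cfg2, 1000)))
  expect_error(synth_config(n_channels = 8, k_true = 2,
                            transition_matrix = matrix(c(0.5, 0.2, 0.5, 0.2),
                                                       2)),
               "sum to 1")
})

test_that("markov chain generator matches its transition structure", {
  expect_true(all(as.integer(
    simulate_markov_sequence(diag(3), 100, seed = 1)) ==
      as.integer(simulate_markov_sequence(diag(3), 100, seed = 1))[1]))

  p_alt <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE)
  s <- as.integer(simulate_markov_sequence(p_alt, 1000, seed = 2))
  expect_true(all(diff(s) != 0))

  p_unif <- matrix(1 / 7, 7, 7)
  s7 <- as.integer(simulate_markov_sequence(p_unif, 5e4, seed = 3))
  freq <- tabulate(s7, 7) / length(s7)
  expect_true(all(abs(freq - 1 / 7) < 0.01))
  # lag-1 independence: empirical transition probabilities near uniform
  trans <- table(head(s7, -1), tail(s7, -1))
  expect_lt(max(abs(trans / rowSums(trans) - 1 / 7)), 0.02)
})

test_that("fractional Gaussian noise has the exact target covariance", {
  h <- 0.7
  x <- fgn(2^15, h, seed = 5)
  r1_theory <- 0.5 * (2^(2 * h) - 2)
  expect_lt(abs(stats::var(x) - 1), 0.05)
  expect_lt(abs(stats::cor(x[-1], x[-length(x)]) - r1_theory), 0.03)
  expect_identical(fgn(1000, 0.6, seed = 9), fgn(1000, 0.6, seed = 9))
  expect_error(fgn(1000, 1.2), "H must be")
})

test_that("sign-thresholded fGn keeps the planted Hurst scaling", {
  s5 <- simulate_hurst_sequence(0.5, 1e5, seed = 11)
  h5 <- dfa_hurst(map_pm1(s5, list(left = 1L, right = 2L)))$hurst
  expect_gt(h5, 0.45)
  expect_lt(h5, 0.55)
  s7 <- simulate_hurst_sequence(0.7, 1e5, seed = 12)
  h7 <- dfa_hurst(map_pm1(s7, list(left = 1L, right = 2L)))$hurst
  expect_gt(h7, 0.63)
  expect_lt(h7, 0.77)
  expect_identical(as.integer(simulate_hurst_sequence(0.6, 1000, seed = 3)),
                   as.integer(simulate_hurst_sequence(0.6, 1000, seed = 3)))
})

test_that("synthetic EEG realises the planted topography model", {
  mont <- the_montage
  maps <- make_template_maps(mont, 4, seed = 21)
  cfg <- synth_config(n_channels = 64, fs = 250, k_true = 4, snr = Inf,
                      seed = 22)
  labels <- simulate_label_sequence(cfg, 2500)
  rec <- simulate_eeg(maps, labels, cfg, montage = mont)
  # noise-free: per-sample topography is exactly proportional to its map
  g <- gfp(rec)$gfp
  strong <- which(g > 0.5 * max(g))
  cors <- vapply(strong, function(t) {
    abs(stats::cor(rec$data[, t], maps$maps[as.integer(labels)[t], ]))
  }, numeric(1))
  expect_true(all(cors > 1 - 1e-9))
  # zero-mean maps propagate to zero channel means in the noise-free limit
  expect_lt(max(abs(colMeans(rec$data))), 1e-9)
  expect_error(synth_config(n_channels = 64, snr = 0), "snr")
  rec2 <- simulate_eeg(maps, labels, cfg, montage = mont)
  expect_identical(rec$data, rec2$data)

  # configured RMS signal-to-noise ratio is realised
  cfg_n <- synth_config(n_channels = 64, fs = 250, k_true = 4, snr = 2,
                        seed = 22)   # same seed: identical carrier phase
  rec_n <- simulate_eeg(maps, labels, cfg_n, montage = mont)
  noise <- rec_n$data - rec$data
  expect_lt(abs(sqrt(mean(rec$data^2)) / sqrt(mean(noise^2)) - 2), 1e-9)
})
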