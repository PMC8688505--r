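test_that("GFP is the population SD across electrodes", {
  x <- matrix(c(2, -2, 5, 5, 1, 7), nrow = 2)
  g <- gfp(x)
  expect_equal(g$gfp, c(2, 0, 3))
  # adding a constant to all channels leaves GFP unchanged
  expect_equal(gfp(x + 5)$gfp, g$gfp)
  expect_error(gfp(x[1, , drop = FALSE]), "2 channels")
})

test_that("GFP peaks are strict maxima with a first-sample plateau rule", {
  expect_length(gfp_peaks(1:10 / 10), 0)
  v <- c(0, 1, 0, 2, 2, 2, 0, 3, 0)
  expect_equal(gfp_peaks(v), c(2, 4, 8))   # plateau counted once, at start
  # rectified alpha: two GFP peaks per carrier cycle
  fx <- synth_recording(seed = 61, seconds = 20, snr = Inf, carrier = 10)
  pk <- gfp_peaks(gfp(fx$rec))
  expect_lt(abs(length(pk) / 20 - 20), 2)  # ~20 peaks/s at 10 Hz
  # minimum separation keeps the larger of two close peaks
  pk2 <- gfp_peaks(c(0, 5, 4.9, 6, 0, 1, 0), min_separation_ms = 3 * 1000,
                   fs = 1)
  expect_equal(pk2, 4)
})

test_that("modified k-means recovers planted maps from clean peaks", {
  fx <- synth_recording(seed = 62, seconds = 60, snr = Inf, k = 5)
  rec <- average_reference(fx$rec)
  pk <- gfp_peaks(gfp(rec))
  pm <- t(rec$data[, pk])
  mod <- modified_kmeans(pm, 5, n_restarts = 10, seed = 1)
  rc <- recovery_correlations(mod, fx$maps)
  expect_true(all(rc$corr >= 0.999))
  expect_lt(mod$cost, 1e-12)               # perfect fit: F = 0
  expect_gt(mod$gev, 1 - 1e-12)
  # cost trace never increases
  expect_true(all(diff(attr(mod, "f_trace")) <= 1e-12))
  # polarity invariance: flipping every sample leaves F and labels equal
  mod_f <- modified_kmeans(-pm, 5, n_restarts = 10, seed = 1)
  expect_equal(mod_f$cost, mod$cost, tolerance = 1e-12)
  expect_identical(attr(mod_f, "assignments"), attr(mod, "assignments"))
})

test_that("cross-validation selects the planted class count", {
  fx <- synth_recording(seed = 63, seconds = 90, snr = 10, k = 5)
  rec <- average_reference(fx$rec)
  pm <- t(rec$data[, gfp_peaks(gfp(rec))])
  sel <- select_optimal_k(pm, k_range = 3:8, n_restarts = 8, seed = 2)
  expect_equal(sel$k_opt, 5)
  expect_equal(nrow(sel$cv), 6)
  # k too large for the channel count is skipped with a warning
  small <- pm[, 1:8] - rowMeans(pm[, 1:8])
  expect_warning(select_optimal_k(small, k_range = c(3, 8), n_restarts = 2,
                                  seed = 3),
                 "skipped")
})

test_that("group alignment recovers permutations and ignores polarity", {
  maps <- make_template_maps(the_montage, 7, seed = 64)
  perms <- list(c(3, 1, 2, 7, 6, 5, 4), c(2, 3, 4, 5, 6, 7, 1), 1:7)
  flips <- list(c(1, -1, 1, 1, -1, 1, 1), rep(1, 7), c(-1, rep(1, 6)))
  subj <- lapply(1:3, function(i) {
    microstate_model(maps$maps[perms[[i]], ] * flips[[i]],
                     channel_labels = the_montage$channel)
  })
  al <- align_maps_group(subj)
  expect_gt(al$mean_abs_corr, 1 - 1e-9)
  # aligned subject maps all match the group maps up to sign
  for (i in 1:3) {
    cc <- abs(microdyn:::map_correlation(
      al$group_model$maps,
      subj[[i]]$maps[al$permutations[[i]], , drop = FALSE]))
    expect_true(all(diag(cc) > 1 - 1e-9))
  }
  # 7! candidate permutations are searched exhaustively
  expect_equal(nrow(microdyn:::permutations_all(7)), 5040)
  expect_equal(anyDuplicated(apply(microdyn:::permutations_all(5), 1,
                                   paste, collapse = "")), 0)
})

test_that("back-fitting is polarity-invariant and exact on pure maps", {
  maps <- make_template_maps(the_montage, 4, seed = 65)
  x <- t(maps$maps[c(2, 2, 3, 1, 4, 2), ])
  rec <- eeg_recording(x, 250, the_montage, reference = "average")
  bf <- backfit(rec, maps)
  expect_equal(as.integer(bf), c(2, 2, 3, 1, 4, 2))
  rec_neg <- rec
  rec_neg$data <- -rec_neg$data
  expect_equal(as.integer(backfit(rec_neg, maps)), as.integer(bf))
  # zero-GFP sample inherits the previous label
  x2 <- x
  x2[, 3] <- 0
  bf2 <- backfit(eeg_recording(x2, 250, the_montage), maps)
  expect_equal(as.integer(bf2)[3], as.integer(bf2)[2])
  # full recovery on noise-free synthetic data at carrier non-zero samples
  fx <- synth_recording(seed = 66, seconds = 30, snr = Inf)
  bff <- backfit(average_reference(fx$rec), fx$maps)
  g <- gfp(fx$rec)$gfp
  nz <- g > 1e-6 * max(g)
  expect_true(all(as.integer(bff)[nz] == as.integer(fx$labels)[nz]))
})

test_that("global explained variance behaves as a weighted fit share", {
  set.seed(67)
  maps <- make_template_maps(the_montage, 4, seed = 67)
  pure <- maps$maps[rep(1:4, 25), ] * runif(100, 0.5, 2)
  expect_equal(gev(pure, maps), 1, tolerance = 1e-12)
  # random labels against orthogonal maps: expectation 1/k
  q <- qr.Q(qr(t(maps$maps)))           # orthonormal basis of the maps
  m0 <- t(q)
  m0 <- m0 - rowMeans(m0)
  m0 <- m0 / sqrt(rowSums(m0^2))
  omaps <- microstate_model(m0)
  draws <- m0[sample.int(4, 2000, replace = TRUE), ]
  rand_labels <- sample.int(4, 2000, replace = TRUE)
  g <- gev(draws, omaps, labels = rand_labels)
  expect_lt(abs(g - 0.25), 0.05)
  # sign flips leave gev unchanged
  flip <- microstate_model(maps$maps * c(1, -1, 1, -1))
  expect_equal(gev(pure, flip), gev(pure, maps), tolerance = 1e-12)
})

test_that("microstate parameters are exact run-length statistics", {
  s <- label_sequence(c(1L, 1L, 2L, 2L, 2L), fs = 5, n_classes = 2)
  p <- microstate_parameters(s)
  expect_equal(p$coverage, c(0.4, 0.6))
  expect_equal(p$duration_ms, c(400, 600))
  expect_equal(p$occurrence_hz, c(1, 1))

  cst <- label_sequence(rep(2L, 100), fs = 10, n_classes = 3)
  pc <- microstate_parameters(cst)
  expect_equal(pc$coverage, c(0, 1, 0))
  expect_equal(pc$occurrence_hz[2], 1 / 10)
  expect_true(is.na(pc$duration_ms[1]) && pc$occurrence_hz[1] == 0)

  # planted geometric dwell mean is recovered from the labels themselves
  cfg <- synth_config(n_channels = 16, fs = 250, k_true = 4,
                      mean_duration_ms = 50, seed = 68)
  s2 <- simulate_label_sequence(cfg, 1e5)
  p2 <- microstate_parameters(s2)
  expect_lt(abs(sum(p2$coverage * p2$duration_ms) / 50 - 1), 0.1)
  expect_equal(sum(p2$coverage), 1)
  total_runs <- sum(p2$n_runs)
  expect_equal(sum(p2$occurrence_hz), total_runs / (1e5 / 250))
})
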