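make_rec <- function(x, fs = 250, mont = NULL) {
  mont <- mont %||% small_montage(nrow(x))
  eeg_recording(x, fs = fs, montage = mont)
}

test_that("band-pass filter attenuates drift and passes the alpha band", {
  fs <- 500
  t <- (0:(fs * 30 - 1)) / fs
  drift <- matrix(rep(10 * sin(2 * pi * 0.1 * t), 8), nrow = 8, byrow = TRUE)
  out <- bandpass_fir(make_rec(drift, fs), 1, 40)
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(drift^2)), 0.05)

  sine <- matrix(rep(sin(2 * pi * 10 * t), 8), nrow = 8, byrow = TRUE)
  rec <- make_rec(sine, fs)
  f1 <- bandpass_fir(rec, 1, 40)
  mid <- 3000:12000                      # away from edge effects
  amp_ratio <- sqrt(mean(f1$data[1, mid]^2) / mean(sine[1, mid]^2))
  expect_lt(abs(amp_ratio - 1), 0.02)

  # filtering twice equals filtering once within passband ripple
  f2 <- bandpass_fir(f1, 1, 40)
  expect_lt(max(abs(f2$data[, mid] - f1$data[, mid])), 0.02)

  expect_error(bandpass_fir(make_rec(sine[, 1:100, drop = FALSE], fs), 1, 40),
               "shorter than the filter")
  expect_error(bandpass_fir(rec, 40, 1), "lo < hi")
})

test_that("bad-channel rules fire on planted pathologies", {
  fx <- synth_recording(seed = 31, seconds = 12, snr = 10,
                        montage = small_montage(16))
  rec <- fx$rec
  # channel flat for > 5 s
  rec_flat <- rec
  rec_flat$data[3, 1:(6 * 250)] <- 0
  qc <- detect_bad_channels(rec_flat)
  flagged <- qc$bad_global_channels
  expect_true("flat" %in% flagged$criterion[flagged$channel ==
                                              rec$montage$channel[3]])

  # smooth field everywhere, one channel independent noise
  pos <- microdyn:::montage_positions(rec$montage)
  field <- outer(as.vector(pos %*% c(0.2, -0.4, 0.9)),
                 sin(2 * pi * 5 * (1:2500) / 250)) * 20
  noisy <- field
  noisy[5, ] <- rnorm(2500) * 20
  qc2 <- detect_bad_channels(make_rec(noisy, mont = rec$montage))
  f2 <- qc2$bad_global_channels
  expect_true("correlation" %in% f2$criterion[f2$channel ==
                                                rec$montage$channel[5]])

  # i.i.d. channels: the robust amplitude rule fires at (at most) its
  # nominal two-sided 3-sigma rate per channel
  set.seed(42)
  hits <- vapply(1:20, function(i) {
    x <- matrix(rnorm(64 * 1000), 64, 1000)
    q <- detect_bad_channels(make_rec(x, mont = the_montage))
    sum(q$bad_global_channels$criterion == "amplitude")
  }, numeric(1))
  expect_lt(mean(hits) / 64, 0.02)
})

test_that("epoching splits records exactly and keeps annotations", {
  x <- matrix(rnorm(8 * 2500), 8, 2500)            # 10 s at 250 Hz
  ann <- tibble::tibble(onset = c(0, 6), duration = c(6, 4),
                        condition = c("A", "B"), run = c(1L, 1L))
  rec <- eeg_recording(x, 250, small_montage(8), annotations = ann)
  ep <- epoch_recording(rec, 2)
  expect_equal(dim(ep$data), c(8, 500, 5))
  expect_identical(ep$epochs$condition, c("A", "A", "A", "B", "B"))

  x2 <- matrix(rnorm(8 * 2475), 8, 2475)           # 9.9 s -> 4 epochs
  expect_equal(dim(epoch_recording(make_rec(x2), 2)$data)[3], 4)
  expect_error(epoch_recording(make_rec(x[, 1:100, drop = FALSE]), 2),
               "shorter than one epoch")
})

test_that("local-channel QC flags gross single-epoch artifacts only", {
  fx <- synth_recording(seed = 33, seconds = 20, snr = 5,
                        montage = small_montage(16))
  ep <- epoch_recording(average_reference(fx$rec), 2)
  ep$data[4, , 3] <- ep$data[4, , 3] * 20
  qc <- faster_local_qc(ep)
  hit <- qc$interpolated_local
  lab <- ep$montage$channel[4]
  expect_true(any(hit$epoch == 3 & hit$channel == lab &
                    hit$criterion == "variance"))
  expect_true(any(hit$epoch == 3 & hit$channel == lab &
                    hit$criterion == "amplitude_range"))
  # repaired, not dropped
  rep <- repair_epochs(ep, qc)
  expect_equal(dim(rep$data), dim(ep$data))
  expect_gt(max(abs(ep$data[4, , 3] - rep$data[4, , 3])), 0)

  # homogeneous Gaussian epochs: per-channel flag rate near the nominal
  # two-sided 3-sigma level
  set.seed(7)
  xs <- array(rnorm(16 * 250 * 40), c(16, 250, 40))
  eph <- ep
  eph$data <- xs
  eph$epochs <- tibble::tibble(epoch = 1:40, onset = (0:39),
                               condition = NA_character_,
                               run = NA_integer_)
  qch <- faster_local_qc(eph)
  rate <- nrow(unique(qch$interpolated_local[, c("epoch", "channel")])) /
    (16 * 40)
  expect_lt(rate, 0.05)
})

test_that("segment rejection drops amplitude and probability outliers", {
  set.seed(8)
  xs <- array(rnorm(8 * 250 * 12) * 10, c(8, 250, 12))
  base <- epoch_recording(make_rec(matrix(xs, 8), fs = 250), 1)
  base$data[2, 100, 5] <- 150
  qc <- reject_segments(base)
  expect_true(any(qc$bad_segments$epoch == 5 &
                    qc$bad_segments$criterion == "amplitude"))

  clean <- epoch_recording(make_rec(matrix(xs * 0.8, 8), fs = 250), 1)
  qc2 <- reject_segments(clean, z_threshold = 10)
  expect_equal(nrow(qc2$bad_segments), 0)

  # probability rule behaves like amplitude-outlier detection on Gaussian
  # epochs: epochs with inflated variance are the ones it rejects
  set.seed(9)
  arr <- array(rnorm(8 * 250 * 40) * 10, c(8, 250, 40))
  arr[, , 31:40] <- arr[, , 31:40] * 2.2
  ep <- epoch_recording(make_rec(matrix(arr, 8), fs = 250), 1)
  qc3 <- reject_segments(ep, amp_uv = 1e9)
  rej <- unique(qc3$bad_segments$epoch)
  # z-score oracle on per-epoch RMS
  rms <- apply(arr, 3, function(m) sqrt(mean(m^2)))
  zrej <- which(abs(scale(rms)) > 3)
  rate_diff <- abs(length(rej) - length(zrej)) / 40
  expect_lt(rate_diff, 0.1)
  expect_true(all(rej > 30))
})

test_that("spherical splines reproduce smooth fields", {
  mont <- the_montage
  # constant field is reproduced exactly
  recc <- eeg_recording(matrix(5, 64, 10), 100, mont)
  out <- spherical_spline_interpolate(recc, "Fz")
  expect_equal(unname(out$data["Fz", 1]), 5, tolerance = 1e-6)

  # smooth dipolar field: interpolation matches the true channel closely
  pos <- microdyn:::montage_positions(mont)
  tt <- seq(0, 1, length.out = 200)
  moments <- rbind(c(0.3, -0.5, 0.8), c(-0.6, 0.2, 0.4))
  field <- (pos %*% t(moments)) %*% rbind(sin(2 * pi * tt), cos(2 * pi * tt))
  rec <- eeg_recording(field * 10, 200, mont)
  for (ch in c("C3", "POz", "F4")) {
    est <- spherical_spline_interpolate(rec, ch)$data[ch, ]
    expect_gt(stats::cor(est, rec$data[ch, ]), 0.95)
  }

  # interpolation and average reference commute (both are linear)
  a <- average_reference(spherical_spline_interpolate(rec, "C3"))
  b <- spherical_spline_interpolate(average_reference(rec), "C3")
  b$data["C3", ] <- b$data["C3", ] - colMeans(b$data[setdiff(mont$channel,
                                                             "C3"), ]) * 0
  expect_lt(max(abs(average_reference(a)$data - average_reference(b)$data)),
            1e-6)
  expect_error(spherical_spline_interpolate(rec, mont$channel[1:40]),
               "more bad")
})

test_that("average reference and downsampling behave as specified", {
  fx <- synth_recording(seed = 35, seconds = 10, snr = 3, k = 4,
                        montage = small_montage(12), fs = 500)
  ar <- average_reference(fx$rec)
  expect_lt(max(abs(colMeans(ar$data))), 1e-9)
  expect_lt(max(abs(average_reference(ar)$data - ar$data)), 1e-12)

  fs <- 500
  t <- (0:(fs * 20 - 1)) / fs
  sine <- matrix(rep(sin(2 * pi * 10 * t), 8), nrow = 8, byrow = TRUE)
  rec <- make_rec(sine, fs)
  ds <- downsample(rec, 250)
  expect_lte(abs(ncol(ds$data) - ncol(rec$data) / 2), 1)
  mid <- 1000:4000
  amp <- sqrt(2 * mean(ds$data[1, mid]^2))
  expect_lt(abs(amp - 1), 0.02)
  expect_error(downsample(rec, 600), "below fs")
  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("the full chain returns a consistent recording and QC ledger", {
  ann <- tibble::tibble(onset = 0, duration = 20, condition = "REST",
                        run = 1L)
  fx <- synth_recording(seed = 36, seconds = 20, fs = 500, snr = 2,
                        annotations = ann)
  res <- suppressWarnings(preprocess(fx$rec))
  rec <- res$recording
  expect_equal(rec$fs, 250)
  expect_identical(rec$reference, "average")
  expect_lt(max(abs(colMeans(rec$data))), 1e-9)
  # provenance: retained + rejected epochs account for the full record
  n_total <- res$qc$n_epochs
  n_rej <- length(unique(res$qc$bad_segments$epoch))
  expect_equal(ncol(rec$data) / 250 / 2 + n_rej, n_total)
  expect_true(res$qc$fraction_rejected >= 0 &&
                res$qc$fraction_rejected <= 1)
  # determinism
  res2 <- suppressWarnings(preprocess(fx$rec))
  expect_identical(res$recording$data, res2$recording$data)
})
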