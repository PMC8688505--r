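lseq <- function(x, fs = 250, m = max(x)) {
  label_sequence(as.integer(x), fs = fs, n_classes = m)
}

test_that("plug-in joint entropy matches closed forms", {
  cst <- lseq(rep(1, 1000), m = 3)
  for (k in c(1, 2, 4)) expect_equal(joint_entropy(cst, k), 0)

  alt <- lseq(rep(c(1, 2), 500))
  expect_equal(joint_entropy(alt, 2), 1, tolerance = 1e-6)

  set.seed(71)
  iid <- lseq(sample(1:2, 1e6, replace = TRUE))
  expect_lt(abs(joint_entropy(iid, 1) - 1), 0.001)

  expect_error(joint_entropy(lseq(1:4), 10), "smaller than the sequence")
  expect_warning(joint_entropy(lseq(sample(1:5, 50, replace = TRUE),
                                    m = 5), 3, warn_bias = TRUE),
                 "biased")
})

test_that("entropy rate is exact on deterministic and Markov sequences", {
  expect_equal(entropy_rate(lseq(rep(1, 1000), m = 2), k = 3), 0)
  expect_equal(entropy_rate(lseq(rep(c(1, 2), 500)), k = 1), 0)

  # analytic oracle: sticky 7-state chain
  p_stay <- 0.8
  P <- matrix((1 - p_stay) / 6, 7, 7)
  diag(P) <- p_stay
  s <- simulate_markov_sequence(P, 1e6, seed = 72)
  expect_lt(abs(entropy_rate(s, k = 1) - markov_entropy_rate(P)), 0.01)

  # conditioning on longer histories cannot increase the plug-in rate on
  # a Markov sequence of this length
  s2 <- simulate_markov_sequence(P, 2e5, seed = 73)
  rates <- vapply(1:3, function(k) entropy_rate(s2, k = k), numeric(1))
  expect_true(all(diff(rates) <= 1e-10))
})

test_that("autoinformation satisfies its identities", {
  per <- lseq(rep(c(1, 2, 3, 1, 2, 3), 400))     # period 3
  curve <- aif(per, max_lag_ms = 40)
  h <- joint_entropy(per, 1)
  expect_equal(curve$aif[curve$lag == 0], h, tolerance = 1e-12)
  expect_equal(curve$aif[curve$lag == 3], h, tolerance = 1e-6)

  set.seed(74)
  iid <- lseq(sample(1:7, 2e4, replace = TRUE))
  ci <- aif(iid, max_lag_ms = 200)
  tail_vals <- ci$aif[ci$lag >= 1]
  m <- 7
  n <- 2e4
  # plug-in MI of independent pairs ~ chi-sq[(m-1)^2] / (2 n ln 2);
  # bound every lag by a far-tail quantile of that law
  bound <- stats::qchisq(1 - 0.001 / length(tail_vals), (m - 1)^2) /
    (2 * n * log(2))
  expect_true(all(tail_vals < bound))
  expect_lt(mean(tail_vals), 2 * (m - 1)^2 / (2 * n * log(2)))

  expect_error(aif(lseq(1:10), max_lag_ms = 200), "sequence length")
})

test_that("first AIF peak latency is read off the curve in ms", {
  curve <- tibble::tibble(lag = 0:20, lag_ms = (0:20) * 4,
                          aif = c(2, exp(-(1:20 - 10)^2 / 4)))
  attr(curve, "fs") <- 250
  expect_equal(first_peak_latency(curve), 40)     # bump at lag 10 -> 40 ms

  mono <- tibble::tibble(lag = 0:20, lag_ms = (0:20) * 4,
                         aif = 2 * exp(-(0:20) / 3))
  attr(mono, "fs") <- 250
  expect_true(is.na(first_peak_latency(mono)))

  # alpha-locked labels: a state persists across 10 Hz cycles while the
  # opposite-polarity half cycle is taken up by transient other classes, so
  # the label process repeats with the full carrier period and the AIF
  # peaks near 100 ms at fs = 250
  set.seed(78)
  n_cycles <- 800
  state <- integer(n_cycles)
  state[1] <- 1L
  for (c in 2:n_cycles) {
    state[c] <- if (runif(1) < 0.8) state[c - 1] else sample(1:4, 1)
  }
  labs <- unlist(lapply(seq_len(n_cycles), function(c) {
    c(rep(state[c], 12), rep(sample(1:4, 1), 13))
  }))
  curve2 <- aif(lseq(labs, m = 4), max_lag_ms = 200)
  pk <- first_peak_latency(curve2)
  expect_gte(pk, 90)
  expect_lte(pk, 110)
})

test_that("bipartition enumeration yields the 35 canonical splits", {
  parts <- enumerate_bipartitions(1:7)
  expect_length(parts, 35)
  expect_true(all(vapply(parts, function(p) length(p$left) == 3 &&
                           length(p$right) == 4, logical(1))))
  # each class sits in the 3-set in C(6,2) = 15 partitions
  counts <- table(unlist(lapply(parts, `[[`, "left")))
  expect_true(all(counts == 15))
  # no duplicates under set equality
  keys <- vapply(parts, function(p) paste(sort(p$left), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_error(enumerate_bipartitions(c(1, 1, 2)), "distinct")
})

test_that("plus-minus mapping and DFA respect their symmetries", {
  s <- lseq(c(1, 1, 2, 3, 2, 1), m = 3)
  part <- list(left = c(1), right = c(2, 3))
  expect_equal(map_pm1(s, part), c(-1, -1, 1, 1, 1, -1))
  swapped <- list(left = c(2, 3), right = c(1))
  expect_equal(map_pm1(s, swapped), -map_pm1(s, part))
  expect_true(all(map_pm1(lseq(c(1, 1), m = 3), part) == -1))
  expect_error(map_pm1(lseq(c(1, 4), m = 4), part), "outside")

  set.seed(75)
  x <- sample(c(-1, 1), 1e5, replace = TRUE)
  d <- dfa_hurst(x)
  expect_gt(d$hurst, 0.45)
  expect_lt(d$hurst, 0.55)
  expect_gt(d$r_squared, 0.95)
  dneg <- dfa_hurst(-x)
  expect_equal(dneg$hurst, d$hurst, tolerance = 1e-12)
  expect_true(is.na(dfa_hurst(rep(1, 1000))$hurst))
  expect_error(dfa_hurst(x[1:100]), "at least 500")
})

test_that("partition-averaged Hurst is invariant to class relabelling", {
  cfg <- synth_config(n_channels = 16, fs = 250, k_true = 7,
                      mean_duration_ms = 20, seed = 76)
  s <- simulate_label_sequence(cfg, 2e4)
  h <- suppressWarnings(hurst_mean(s))
  expect_equal(h$n_used, 35)
  # a permutation of class labels maps the partition set onto itself
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  s_perm <- label_sequence(perm[as.integer(s)], fs = 250, n_classes = 7)
  h_perm <- suppressWarnings(hurst_mean(s_perm))
  expect_equal(h_perm$hurst_mean, h$hurst_mean, tolerance = 1e-12)
  expect_equal(sort(h_perm$per_partition$hurst),
               sort(h$per_partition$hurst), tolerance = 1e-12)
  # entropy rate and AIF are exactly invariant too
  expect_equal(entropy_rate(s_perm, k = 2), entropy_rate(s, k = 2),
               tolerance = 1e-12)
  expect_equal(aif(s_perm, max_lag_ms = 40)$aif,
               aif(s, max_lag_ms = 40)$aif, tolerance = 1e-12)
})

test_that("seq_dynamics bundles the statistics consistently", {
  s <- simulate_hurst_sequence(0.6, 5e3, seed = 77)
  s7 <- label_sequence(((as.integer(s) - 1) * 3 +
                          rep(1:3, length.out = 5e3)),
                       fs = 250, n_classes = 6)
  d <- suppressWarnings(seq_dynamics(s7, k = 2))
  expect_s3_class(d, "seq_dynamics")
  expect_equal(d$aif$aif[1], joint_entropy(s7, 1), tolerance = 1e-12)
  td <- tidy(d)
  expect_equal(td$entropy_rate, d$entropy_rate)
  expect_equal(td$hurst_mean, d$hurst_mean)
})
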