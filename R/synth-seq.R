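#' Simulate a semi-Markov microstate label sequence
#'
#' Generates the planted ground-truth label sequence of a synthetic
#' recording: dwell times are geometric (memoryless) with the configured
#' mean, or exactly fixed in `dwell = "fixed"` mode, and the class entered
#' after each dwell is drawn from the configured between-class transition
#' matrix (diagonal ignored after renormalisation; dwell is governed by the
#' dwell-time law, not by self-transitions).
#'
#' @param cfg a [synth_config].
#' @param n_samples sequence length in samples.
#' @return A [label_sequence] at `cfg$fs`.
#' @export
simulate_label_sequence <- function(cfg, n_samples) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is_count(n_samples)) stop_microdyn("n_samples must be a count")
  k <- cfg$k_true
  mean_dwell <- cfg$fs * cfg$mean_duration_ms / 1000
  p <- cfg$transition_matrix
  jump <- p
  diag(jump) <- 0
  rs <- rowSums(jump)
  if (k > 1L && any(rs <= 0)) {
    stop_microdyn("transition matrix has a state with no exit transition")
  }
  if (k > 1L) jump <- jump / rs
  labels <- with_seed(cfg$seed, {
    out <- integer(n_samples)
    cur <- sample.int(k, 1L)
    t0 <- 1L
    while (t0 <= n_samples) {
      d <- if (cfg$dwell == "fixed") {
        max(1L, as.integer(round(mean_dwell)))
      } else {
        stats::rgeom(1L, 1 / mean_dwell) + 1L
      }
      t1 <- min(n_samples, t0 + d - 1L)
      out[t0:t1] <- cur
      t0 <- t1 + 1L
      if (k > 1L) cur <- sample.int(k, 1L, prob = jump[cur, ])
    }
    out
  })
  label_sequence(labels, fs = cfg$fs, n_classes = k)
}

#' Simulate a first-order Markov chain
#'
#' Oracle generator for entropy-rate tests: a stationary first-order Markov
#' chain over `nrow(P)` symbols, started from the stationary distribution.
#'
#' @param P row-stochastic transition matrix.
#' @param n sequence length.
#' @param seed integer seed.
#' @param fs nominal sampling rate attached to the sequence (Hz).
#' @return A [label_sequence].
#' @export
simulate_markov_sequence <- function(P, n, seed = 1, fs = 250) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (ncol(P) != k || any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9)) {
    stop_microdyn("P must be square and row-stochastic")
  }
  pi0 <- markov_stationary(P)
  labels <- with_seed(seed, {
    out <- integer(n)
    out[1L] <- sample.int(k, 1L, prob = pi0)
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      cum <- t(apply(P, 1L, cumsum))
      for (t in 2L:n) {
        out[t] <- findInterval(u[t - 1L], cum[out[t - 1L], ]) + 1L
      }
    }
    out
  })
  label_sequence(labels, fs = fs, n_classes = k)
}

# stationary distribution of an irreducible chain (left eigenvector)
markov_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8) {
    stop_microdyn("transition matrix has no unit eigenvalue; chain reducible?")
  }
  v <- Re(e$vectors[, i])
  if (any(v < -1e-10) && any(v > 1e-10)) v <- -v
  v <- abs(v)
  if (sum(v) == 0) stop_microdyn("no stationary distribution found")
  v / sum(v)
}

#' Analytic entropy rate of a first-order Markov chain (bits/sample)
#'
#' @param P row-stochastic transition matrix.
#' @return entropy rate in bits per sample.
#' @export
markov_entropy_rate <- function(P) {
  pi0 <- markov_stationary(P)
  rows <- apply(P, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(pi0 * rows)
}

#' Exact fractional Gaussian noise by circulant embedding
#'
#' Generates fGn with Hurst exponent `H` using the Davies-Harte circulant
#' embedding of the exact autocovariance, so the sample has the target
#' covariance to machine precision (no generator bias confounding the DFA
#' estimates tested against it).
#'
#' @param n length.
#' @param H Hurst exponent in (0, 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
fgn <- function(n, H, seed = 1) {
  if (!(H > 0 && H < 1)) stop_microdyn("H must be in (0,1)")
  if (!is_count(n) || n < 2) stop_microdyn("n must be a count >= 2")
  k <- 0:(n - 1)
  r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  g <- c(r, 0, rev(r[-1L]))          # circulant first row, length 2n
  lam <- Re(stats::fft(g))
  if (min(lam) < -1e-8 * max(lam)) {
    stop_microdyn("circulant embedding not non-negative definite for n=%d", n)
  }
  lam <- pmax(lam, 0)
  m <- length(g)
  x <- with_seed(seed, {
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    Re(stats::fft(sqrt(lam / (2 * m)) * z))[seq_len(n)] * sqrt(2)
  })
  x
}

#' Simulate a binary sequence with planted Hurst exponent
#'
#' Sign-thresholds exact fractional Gaussian noise: the resulting two-class
#' sequence keeps the long-range scaling of the underlying fGn (the sign
#' transform maps autocorrelations through the arcsine law, which preserves
#' the power-law tail exponent), giving a ground-truth oracle for the DFA
#' estimator.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n length.
#' @param seed integer seed.
#' @param fs nominal sampling rate (Hz).
#' @return A [label_sequence] with classes 1 (negative) and 2 (positive).
#' @export
simulate_hurst_sequence <- function(H, n, seed = 1, fs = 250) {
  x <- fgn(n, H, seed = seed)
  label_sequence(ifelse(x >= 0, 2L, 1L), fs = fs, n_classes = 2L)
}

# Long-range-correlated label sequence: class identities are quantile bins
# of fGn sampled at dwell events, so the +/-1 partition series inherits the
# fGn's Hurst scaling while dwell times keep the configured mean.
simulate_lrc_label_sequence <- function(cfg, n_samples, H = 0.75) {
  stopifnot(inherits(cfg, "synth_config"))
  k <- cfg$k_true
  mean_dwell <- cfg$fs * cfg$mean_duration_ms / 1000
  n_events <- ceiling(n_samples / mean_dwell * 2) + 10L
  latent <- fgn(n_events, H, seed = cfg$seed)
  qs <- stats::quantile(latent, probs = seq_len(k - 1L) / k)
  states <- findInterval(latent, qs) + 1L
  labels <- with_seed(child_seed(cfg$seed, 1L), {
    out <- integer(n_samples)
    t0 <- 1L
    ev <- 1L
    prev <- 0L
    while (t0 <= n_samples) {
      cur <- states[ev]
      if (cur == prev) cur <- if (cur < k) cur + 1L else cur - 1L
      d <- if (cfg$dwell == "fixed") {
        max(1L, as.integer(round(mean_dwell)))
      } else {
        stats::rgeom(1L, 1 / mean_dwell) + 1L
      }
      t1 <- min(n_samples, t0 + d - 1L)
      out[t0:t1] <- cur
      t0 <- t1 + 1L
      ev <- ev + 1L
      prev <- cur
    }
    out
  })
  label_sequence(labels, fs = cfg$fs, n_classes = k)
}
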