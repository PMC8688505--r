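#' Plug-in joint entropy of k-grams
#'
#' Maximum-likelihood (plug-in) entropy, in bits, of the empirical
#' distribution of length-`k` windows of the sequence. No bias correction
#' is applied; a warning flags sequences shorter than `10 * m^k` symbols
#' (alphabet size `m`), where the plug-in estimate is noticeably biased
#' downward.
#'
#' @param seq a [label_sequence] (or integer vector in `1..m`).
#' @param k history length (window size), `>= 1`.
#' @param m alphabet size (defaults to the sequence's class count).
#' @param warn_bias emit the undersampling warning?
#' @return joint entropy in bits.
#' @export
joint_entropy <- function(seq, k, m = NULL, warn_bias = FALSE) {
  x <- as.integer(seq)
  m <- m %||% (if (inherits(seq, "label_sequence")) seq_classes(seq) else
    max(x))
  n <- length(x)
  if (k >= n) stop_microdyn("k (%d) must be smaller than the sequence (%d)",
                            k, n)
  if (m^k > 2^31 - 1) stop_microdyn("alphabet^k too large to tabulate")
  if (warn_bias && n < 10 * m^k) {
    warn_microdyn("sequence length %d < 10 * %d^%d; plug-in entropy biased",
                  n, m, k)
  }
  counts <- gram_counts(x, k, m)
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# counts of length-k windows encoded in base m
gram_counts <- function(x, k, m) {
  nwin <- length(x) - k + 1L
  code <- numeric(nwin)
  for (j in seq_len(k)) {
    code <- code + (x[j:(nwin + j - 1L)] - 1) * m^(j - 1)
  }
  tabulate(as.integer(code) + 1L, nbins = as.integer(m^k))
}

#' Finite entropy rate of a label sequence
#'
#' The conditional entropy of the next symbol given the previous `k`
#' symbols, estimated as the difference of plug-in joint entropies of
#' `(k+1)`-grams and `k`-grams, in bits per sample. The default history of
#' six samples probes short-range temporal dependence at a 250 Hz label
#' rate.
#'
#' @inheritParams joint_entropy
#' @param k history length.
#' @return entropy rate in bits/sample.
#' @export
entropy_rate <- function(seq, k = 6, m = NULL, warn_bias = FALSE) {
  x <- as.integer(seq)
  m <- m %||% (if (inherits(seq, "label_sequence")) seq_classes(seq) else
    max(x))
  n <- length(x)
  if (k + 1L >= n) stop_microdyn("sequence too short for history k = %d", k)
  if (warn_bias && n < 10 * m^(k + 1L)) {
    warn_microdyn("sequence length %d < 10 * %d^%d; plug-in entropy biased",
                  n, m, k + 1L)
  }
  ent <- function(counts) {
    p <- counts[counts > 0]
    p <- p / sum(p)
    -sum(p * log2(p))
  }
  # (k+1)-grams and their k-gram prefixes over identical window starts, so
  # the difference is the plug-in conditional entropy (exactly 0 for
  # deterministic sequences)
  ent(gram_counts(x, k + 1L, m)) - ent(gram_counts(x[-n], k, m))
}

#' Autoinformation function of a label sequence
#'
#' Mutual information, in bits, between the sequence and its lag-`tau`
#' shifted copy, for every lag from 0 to `max_lag_ms`. Marginals are
#' estimated on the overlapping segment at each lag. At lag zero the
#' autoinformation equals the marginal entropy.
#'
#' @param seq a [label_sequence].
#' @param max_lag_ms largest lag, in milliseconds.
#' @return tibble with columns `lag` (samples), `lag_ms`, and `aif` (bits),
#'   carrying `fs` as an attribute.
#' @export
aif <- function(seq, max_lag_ms = 200) {
  stopifnot(inherits(seq, "label_sequence"))
  fs <- seq_fs(seq)
  m <- seq_classes(seq)
  n <- length(seq)
  max_lag <- as.integer(round(max_lag_ms * fs / 1000))
  if (max_lag >= n) stop_microdyn("max lag (%d samples) >= sequence length",
                                  max_lag)
  x <- as.integer(seq)
  vals <- vapply(0:max_lag, function(tau) {
    a <- x[seq_len(n - tau)]
    b <- x[(1L + tau):n]
    joint <- tabulate((a - 1L) * m + b, nbins = m * m)
    pj <- joint / sum(joint)
    pa <- tabulate(a, nbins = m) / length(a)
    pb <- tabulate(b, nbins = m) / length(b)
    ent <- function(p) {
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    ent(pa) + ent(pb) - ent(pj)
  }, numeric(1L))
  out <- tibble::tibble(lag = 0:max_lag, lag_ms = (0:max_lag) * 1000 / fs,
                        aif = pmax(vals, 0))
  attr(out, "fs") <- fs
  out
}

#' Latency of the first autoinformation peak
#'
#' The lag, in milliseconds, of the first strict local maximum of the
#' autoinformation curve for lags >= 1 sample (no smoothing). Periodic
#' microstate dynamics — e.g. polarity-equivalent states riding an alpha
#' cycle — produce such a peak near the carrier period. Returns `NA` when
#' the curve decays monotonically.
#'
#' @param aif_curve tibble from [aif()].
#' @param fs sampling rate (defaults to the curve's attribute).
#' @return latency in ms, or `NA_real_` if no peak exists.
#' @export
first_peak_latency <- function(aif_curve, fs = NULL) {
  fs <- fs %||% attr(aif_curve, "fs")
  v <- aif_curve$aif[aif_curve$lag >= 1L]
  lags <- aif_curve$lag[aif_curve$lag >= 1L]
  if (length(v) < 3L) return(NA_real_)
  i <- which(v[2:(length(v) - 1L)] > v[1:(length(v) - 2L)] &
               v[2:(length(v) - 1L)] > v[3:length(v)]) + 1L
  if (!length(i)) return(NA_real_)
  lags[i[1L]] * 1000 / fs
}

#' Enumerate 3-vs-4 bipartitions of a 7-class label set
#'
#' All unordered splits of the class set into one subset of size
#' `floor(m/2)` and its complement; for the canonical seven classes this
#' gives the 35 three-versus-four bipartitions used by the Hurst analysis.
#'
#' @param labels vector of distinct class labels (default `1:7`).
#' @return list of bipartitions, each a list with elements `left` (the
#'   smaller set, mapped to -1) and `right` (mapped to +1).
#' @export
enumerate_bipartitions <- function(labels = 1:7) {
  if (anyDuplicated(labels)) stop_microdyn("class labels must be distinct")
  m <- length(labels)
  if (m < 2L) stop_microdyn("need at least 2 classes")
  h <- m %/% 2L
  sets <- utils::combn(labels, h, simplify = FALSE)
  if (m %% 2L == 0L) {
    # even m: keep each unordered pair once (drop complements)
    keep <- vapply(sets, function(s) labels[1L] %in% s, logical(1L))
    sets <- sets[keep]
  }
  lapply(sets, function(s) list(left = s, right = setdiff(labels, s)))
}

#' Map a label sequence onto a +/-1 series under a bipartition
#'
#' Classes in the partition's `left` component map to -1, classes in
#' `right` to +1.
#'
#' @param seq a [label_sequence].
#' @param partition one element of [enumerate_bipartitions()].
#' @return numeric vector of -1/+1 values.
#' @export
map_pm1 <- function(seq, partition) {
  x <- as.integer(seq)
  covered <- c(partition$left, partition$right)
  if (!all(unique(x) %in% covered)) {
    stop_microdyn("sequence contains labels outside the bipartition")
  }
  ifelse(x %in% partition$left, -1, 1)
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' Standard first-order DFA of a +/-1 (or any numeric) series: the
#' mean-removed cumulative sum is split into non-overlapping windows of
#' logarithmically spaced sizes between 4 samples and the series length;
#' each window is detrended by a least-squares line and the root mean
#' squared residual is averaged over the identically sized windows. The
#' Hurst exponent is the slope of `log(fluctuation)` against
#' `log(window size)`. Because fluctuations at the largest window sizes
#' average over too few windows to be stable, the reported exponent is
#' fitted on windows up to a quarter of the series length; the full-range
#' slope is also returned in the diagnostics.
#'
#' @param series numeric vector, length >= 500.
#' @param n_sizes number of window sizes (>= 10).
#' @param fit_fraction largest window used in the slope fit, as a fraction
#'   of the series length.
#' @return list with `hurst`, `hurst_full_range`, `r_squared`, and a
#'   `fluctuations` tibble (window size, fluctuation, in the fit range or
#'   not).
#' @export
dfa_hurst <- function(series, n_sizes = 20, fit_fraction = 0.25) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 500L) stop_microdyn("DFA needs at least 500 samples, got %d", n)
  if (stats::sd(x) == 0) {
    return(list(hurst = NA_real_, hurst_full_range = NA_real_,
                r_squared = NA_real_,
                fluctuations = tibble::tibble(size = integer(),
                                              fluctuation = numeric(),
                                              in_fit = logical())))
  }
  y <- cumsum(x - mean(x))
  sizes <- unique(round(exp(seq(log(4), log(n), length.out = max(10, n_sizes)))))
  sizes <- sizes[sizes >= 4 & sizes <= n]
  fl <- vapply(sizes, function(s) {
    nw <- n %/% s
    m <- matrix(y[seq_len(nw * s)], nrow = s)
    t1 <- seq_len(s)
    xm <- cbind(1, t1)
    beta <- solve(crossprod(xm), crossprod(xm, m))
    resid <- m - xm %*% beta
    mean(sqrt(colMeans(resid^2)))
  }, numeric(1L))
  ok <- fl > 0
  sizes <- sizes[ok]
  fl <- fl[ok]
  in_fit <- sizes <= max(4, n * fit_fraction)
  fit <- stats::lm(log(fl[in_fit]) ~ log(sizes[in_fit]))
  fit_full <- stats::lm(log(fl) ~ log(sizes))
  list(
    hurst = unname(coef(fit)[2L]),
    hurst_full_range = unname(coef(fit_full)[2L]),
    r_squared = summary(fit)$r.squared,
    fluctuations = tibble::tibble(size = sizes, fluctuation = fl,
                                  in_fit = in_fit)
  )
}

#' Mean DFA Hurst exponent over all bipartitions
#'
#' Maps the sequence to a +/-1 series under every 3-vs-4 bipartition of
#' its class set, estimates the DFA Hurst exponent of each, and returns
#' the arithmetic mean together with the per-partition values. Partitions
#' whose series is constant (one component never visited) are excluded
#' from the mean with a warning.
#'
#' @param seq a [label_sequence] (7 classes for the canonical 35
#'   partitions; other class counts use all half-vs-rest splits).
#' @return list with `hurst_mean`, `per_partition` tibble, and `n_used`.
#' @export
hurst_mean <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  parts <- enumerate_bipartitions(seq_len(seq_classes(seq)))
  hs <- vapply(seq_along(parts), function(i) {
    s <- map_pm1(seq, parts[[i]])
    if (length(unique(s)) < 2L) return(NA_real_)
    dfa_hurst(s)$hurst
  }, numeric(1L))
  if (anyNA(hs)) {
    warn_microdyn("%d of %d partitions degenerate; excluded from the mean",
                  sum(is.na(hs)), length(hs))
  }
  list(
    hurst_mean = mean(hs, na.rm = TRUE),
    per_partition = tibble::tibble(
      partition = seq_along(parts),
      left = vapply(parts, function(p) paste(p$left, collapse = ","),
                    character(1L)),
      hurst = hs
    ),
    n_used = sum(!is.na(hs))
  )
}

#' All temporal-dynamics statistics of a label sequence
#'
#' Convenience wrapper computing the finite entropy rate, the
#' autoinformation curve with its first-peak latency, and the
#' partition-averaged DFA Hurst exponent of one sequence.
#'
#' @param seq a [label_sequence].
#' @param k entropy-rate history length.
#' @param max_lag_ms autoinformation lag range.
#' @return A `seq_dynamics` object (list with `entropy_rate`, `aif`,
#'   `first_peak_latency_ms`, `hurst_mean`, `hurst_per_partition`).
#' @export
seq_dynamics <- function(seq, k = 6, max_lag_ms = 200) {
  curve <- aif(seq, max_lag_ms = max_lag_ms)
  h <- hurst_mean(seq)
  structure(
    list(entropy_rate = entropy_rate(seq, k = k),
         k = k,
         aif = curve,
         first_peak_latency_ms = first_peak_latency(curve),
         hurst_mean = h$hurst_mean,
         hurst_per_partition = h$per_partition,
         n_classes = seq_classes(seq),
         fs = seq_fs(seq),
         n_samples = length(seq)),
    class = "seq_dynamics"
  )
}

#' @export
print.seq_dynamics <- function(x, ...) {
  cat(sprintf("<seq_dynamics> %d samples, %d classes @ %g Hz\n",
              x$n_samples, x$n_classes, x$fs))
  cat(sprintf("  entropy rate (k=%d): %.3f bits/sample\n", x$k,
              x$entropy_rate))
  cat(sprintf("  AIF first peak: %s ms\n",
              ifelse(is.na(x$first_peak_latency_ms), "none",
                     format(x$first_peak_latency_ms))))
  cat(sprintf("  mean Hurst over %d partitions: %.3f\n",
              nrow(x$hurst_per_partition), x$hurst_mean))
  invisible(x)
}
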