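# internal helpers shared across modules

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic generators in the package go
# through this so they are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a stream index, staying inside
# the 32-bit integer range R requires for set.seed().
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483629)
}

stop_microdyn <- function(msg, ..., class = "microdyn_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

warn_microdyn <- function(msg, ...) {
  rlang::warn(sprintf(msg, ...))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

# unit-normalise columns of a matrix
unit_cols <- function(m) {
  sweep(m, 2L, sqrt(colSums(m^2)), "/")
}

# run-length encoding of an integer label vector as a tibble
run_lengths <- function(labels) {
  r <- rle(as.integer(labels))
  tibble::tibble(class = r$values, length = r$lengths)
}

# linear FIR convolution with delay compensation (zero-phase for a symmetric
# kernel of odd length); FFT-based, edge-padded by reflection
fir_filtfft <- function(x, kernel) {
  n <- length(x)
  l <- length(kernel)
  half <- (l - 1L) %/% 2L
  pad <- pmin(half, n - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  m <- length(xp) + l - 1L
  nfft <- stats::nextn(m, 2L)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - length(xp)))) *
                       stats::fft(c(kernel, numeric(nfft - l))),
                     inverse = TRUE)) / nfft
  y[pad + half + seq_len(n)]
}

# Hamming windowed-sinc low-pass kernel; fc in cycles/sample, ntaps odd
windowed_sinc <- function(fc, ntaps) {
  stopifnot(ntaps %% 2L == 1L)
  m <- ntaps - 1L
  k <- seq_len(ntaps) - 1L
  h <- 2 * fc * sinc(2 * fc * (k - m / 2))
  w <- 0.54 - 0.46 * cos(2 * pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# simple trapezoidal integral on an (x, y) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
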