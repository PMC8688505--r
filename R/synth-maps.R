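# Template topographies for the synthetic generator: random mixtures of
# low-order real spherical harmonics evaluated at the electrode positions.
# Low-order harmonics give the smooth, dipolar-to-quadrupolar fields that
# scalp potentials of deep synchronous generators produce.

# associated Legendre P_l^m(x) (unnormalised), recurrence over degree
legendre_plm <- function(l, m, x) {
  pmm <- if (m == 0) rep(1, length(x)) else {
    (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * (1 - x^2)^(m / 2)
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (ll in (m + 2):l) {
    p <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- p
  }
  pmmp1
}

# real spherical-harmonic design matrix (degrees 1..l_max) at unit positions
sh_design <- function(positions, l_max = 3) {
  z <- pmin(pmax(positions[, 3L], -1), 1)
  th <- acos(z)
  ph <- atan2(positions[, 2L], positions[, 1L])
  cols <- list()
  for (l in seq_len(l_max)) {
    for (m in -l:l) {
      v <- legendre_plm(l, abs(m), cos(th))
      v <- if (m > 0) v * cos(m * ph) else if (m < 0) v * sin(-m * ph) else v
      cols[[length(cols) + 1L]] <- v / sqrt(sum(v^2))
    }
  }
  do.call(cbind, cols)
}

#' Generate planted microstate template maps
#'
#' Draws `k` smooth template topographies as random mixtures of spherical
#' harmonics of degree 1-3 on the montage, centred (zero mean across
#' channels) and unit-norm. Candidate sets whose maximum pairwise absolute
#' spatial correlation exceeds `max_corr` are rejected and redrawn, so the
#' planted classes are guaranteed to be distinguishable.
#'
#' @param montage a [montage].
#' @param k number of maps, `2 <= k <= n_channels / 2`.
#' @param seed integer seed; the same seed yields bit-identical maps.
#' @param max_corr rejection threshold on pairwise |spatial correlation|.
#' @param max_tries rejection-sampling budget.
#' @return A [microstate_model] holding the `k` x channels map matrix.
#' @export
make_template_maps <- function(montage, k, seed = 1, max_corr = 0.7,
                               max_tries = 1000) {
  n_ch <- nrow(montage)
  if (!is_count(k) || k < 2 || k > n_ch / 2) {
    stop_microdyn("k must satisfy 2 <= k <= n_channels/2 (= %g)", n_ch / 2)
  }
  basis <- sh_design(montage_positions(montage), l_max = 3)
  maps <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      w <- matrix(stats::rnorm(ncol(basis) * k), ncol(basis), k)
      m <- basis %*% w
      m <- sweep(m, 2L, colMeans(m))
      m <- unit_cols(m)
      cc <- abs(crossprod(m))
      if (max(cc[upper.tri(cc)]) <= max_corr) break
      m <- NULL
    }
    m
  })
  if (is.null(maps)) {
    stop_microdyn(
      "could not draw %d maps with pairwise |corr| <= %.2f in %d attempts; montage too small for k",
      k, max_corr, max_tries)
  }
  microstate_model(t(maps), channel_labels = montage$channel, seed = seed)
}
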