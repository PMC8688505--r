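# Spherical-spline scalp interpolation (order-4 Legendre series).
# The interpolating field is v(r) = c0 + sum_i c_i g(cos(r, r_i)) with
# g(x) = sum_l (2l+1) / (l (l+1))^m P_l(x) / (4 pi), the classical
# order-m spherical spline on the unit sphere.

legendre_series_g <- function(x, m = 4, n_terms = 50) {
  # evaluate sum over degrees via the three-term Legendre recurrence
  p_prev <- rep(1, length(x))      # P_0
  p_cur <- x                       # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (l in 2:n_terms) {
    p_next <- ((2 * l - 1) * x * p_cur - (l - 1) * p_prev) / l
    out <- out + (2 * l + 1) / (l * (l + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  out / (4 * pi)
}

# interpolation operator mapping good-channel data to bad-channel estimates
spline_operator <- function(pos_good, pos_bad, m = 4, n_terms = 50,
                            lambda = 1e-8) {
  ng <- nrow(pos_good)
  g_gg <- legendre_series_g(tcrossprod(pos_good), m, n_terms)
  g_bg <- legendre_series_g(pos_bad %*% t(pos_good), m, n_terms)
  a <- rbind(cbind(g_gg + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  # weights solve [G 1; 1' 0] [c; c0] = [y; 0]; interpolate via [g_bg 1]
  inv <- solve(a)
  op <- cbind(g_bg, rep(1, nrow(pos_bad))) %*% inv[, seq_len(ng), drop = FALSE]
  op
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels by order-4 spherical-spline estimates from
#' the remaining channels, using the classical Legendre-series spline on
#' the unit sphere. Good channels are untouched.
#'
#' @param rec an [eeg_recording].
#' @param bad character vector of channel labels to rebuild.
#' @param m spline order.
#' @param n_terms Legendre series truncation.
#' @return The recording with bad channels replaced.
#' @export
spherical_spline_interpolate <- function(rec, bad, m = 4, n_terms = 50) {
  if (!length(bad)) return(rec)
  labels <- rec$montage$channel
  if (!all(bad %in% labels)) {
    stop_microdyn("unknown channels: %s",
                  paste(setdiff(bad, labels), collapse = ", "))
  }
  good <- setdiff(labels, bad)
  if (length(good) < 4L) stop_microdyn("need at least 4 good channels")
  if (length(bad) >= length(good)) {
    stop_microdyn("more bad channels (%d) than good (%d)", length(bad),
                  length(good))
  }
  p <- montage_positions(rec$montage)
  op <- spline_operator(p[good, , drop = FALSE], p[bad, , drop = FALSE],
                        m = m, n_terms = n_terms)
  rec$data[bad, ] <- op %*% rec$data[good, , drop = FALSE]
  rec
}
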