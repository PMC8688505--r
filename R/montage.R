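#' Electrode montages on the unit sphere
#'
#' A montage pairs channel labels from the international 10-10 system with
#' 3-D sensor positions on a unit sphere (head-centred: +x right, +y nasion,
#' +z vertex). Positions drive neighbourhood definitions for channel quality
#' control, spherical-spline interpolation, and the smooth template
#' topographies used by the synthetic-EEG generator.
#'
#' @param channel_labels character vector of unique channel names.
#' @param positions numeric matrix (channels x 3) of unit-norm coordinates.
#' @return An object of class `montage`: a tibble with columns `channel`,
#'   `x`, `y`, `z`.
#' @examples
#' m <- montage_1010()
#' nrow(m)
#' @export
montage <- function(channel_labels, positions) {
  channel_labels <- as.character(channel_labels)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_labels)) {
    stop_microdyn("montage channel labels must be unique")
  }
  if (length(channel_labels) < 8L) {
    stop_microdyn("a montage needs at least 8 channels, got %d",
                  length(channel_labels))
  }
  if (nrow(positions) != length(channel_labels) || ncol(positions) != 3L) {
    stop_microdyn("positions must be a %d x 3 matrix", length(channel_labels))
  }
  norms <- sqrt(rowSums(positions^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop_microdyn("montage positions must lie on the unit sphere (1e-9)")
  }
  out <- tibble::tibble(channel = channel_labels,
                        x = positions[, 1L], y = positions[, 2L],
                        z = positions[, 3L])
  class(out) <- c("montage", class(out))
  out
}

montage_positions <- function(m) {
  p <- as.matrix(m[, c("x", "y", "z")])
  rownames(p) <- m$channel
  p
}

# spherical linear interpolation between unit vectors
slerp <- function(v0, v1, t) {
  omega <- acos(max(-1, min(1, sum(v0 * v1))))
  if (omega < 1e-12) return(v0)
  (sin((1 - t) * omega) * v0 + sin(t * omega) * v1) / sin(omega)
}

#' Built-in 10-10 montage
#'
#' Constructs a 64-channel montage of the international 10-10 system from
#' the geometry of the system itself: midline electrodes are spaced at 10%
#' steps along the nasion-inion arc, the outer ring sits at 72 degrees
#' inclination with 18-degree azimuthal spacing, and intermediate
#' electrodes are placed by spherical interpolation between the midline and
#' ring electrode of their row. Three sub-ring electrodes (FT9, FT10, Iz)
#' complete the 64-channel cap; the analysis set of the package's default
#' study uses the remaining 63 channels with Cz-style caps in mind.
#'
#' @param n_channels 64 (full cap) or 61 (without the sub-ring electrodes).
#' @return A [montage].
#' @export
montage_1010 <- function(n_channels = 64) {
  if (!n_channels %in% c(61, 64)) {
    stop_microdyn("montage_1010 supports 61 or 64 channels")
  }
  deg <- pi / 180
  ring_incl <- 72 * deg
  # unit vector at inclination (from vertex) and azimuth alpha measured from
  # +y (nasion) positive toward the left ear (-x)
  vec <- function(incl, alpha) {
    c(-sin(incl) * sin(alpha), sin(incl) * cos(alpha), cos(incl))
  }
  midline <- list(
    Fpz = vec(ring_incl, 0), AFz = vec(54 * deg, 0), Fz = vec(36 * deg, 0),
    FCz = vec(18 * deg, 0), Cz = c(0, 0, 1), CPz = vec(18 * deg, pi),
    Pz = vec(36 * deg, pi), POz = vec(54 * deg, pi), Oz = vec(ring_incl, pi)
  )
  ring_left <- list(
    Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
    TP7 = 108, P7 = 126, PO7 = 144, O1 = 162
  )
  pos <- list()
  for (nm in names(midline)) pos[[nm]] <- midline[[nm]]
  for (nm in names(ring_left)) {
    a <- ring_left[[nm]] * deg
    pos[[nm]] <- vec(ring_incl, a)
    nm_r <- mirror_label(nm)
    pos[[nm_r]] <- vec(ring_incl, -a)
  }
  # intermediate rows: (midline anchor, ring anchor, labels inward->outward)
  rows <- list(
    list("AFz", "AF7", c("AF3")),
    list("Fz",  "F7",  c("F1", "F3", "F5")),
    list("FCz", "FT7", c("FC1", "FC3", "FC5")),
    list("Cz",  "T7",  c("C1", "C3", "C5")),
    list("CPz", "TP7", c("CP1", "CP3", "CP5")),
    list("Pz",  "P7",  c("P1", "P3", "P5")),
    list("POz", "PO7", c("PO3"))
  )
  for (row in rows) {
    v0 <- pos[[row[[1L]]]]
    v1l <- pos[[row[[2L]]]]
    v1r <- pos[[mirror_label(row[[2L]])]]
    labs <- row[[3L]]
    fr <- if (length(labs) == 1L) 0.5 else seq_along(labs) / (length(labs) + 1L)
    for (i in seq_along(labs)) {
      pos[[labs[i]]] <- slerp(v0, v1l, fr[i])
      pos[[mirror_label(labs[i])]] <- slerp(v0, v1r, fr[i])
    }
  }
  if (n_channels == 64) {
    pos[["FT9"]] <- vec(90 * deg, 72 * deg)
    pos[["FT10"]] <- vec(90 * deg, -72 * deg)
    pos[["Iz"]] <- vec(90 * deg, pi)
  }
  labels <- names(pos)
  p <- do.call(rbind, pos)
  p <- p / sqrt(rowSums(p^2))
  montage(labels, p)
}

mirror_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1L]]
  if (length(m) == 0L) return(label)
  num <- as.integer(m[3L])
  paste0(m[2L], if (num %% 2L == 1L) num + 1L else num - 1L)
}

#' Nearest-neighbour channels by great-circle distance
#'
#' @param m a [montage].
#' @param k number of neighbours per channel.
#' @return named list of character vectors of neighbour labels.
#' @export
channel_neighbors <- function(m, k = 4) {
  p <- montage_positions(m)
  g <- tcrossprod(p)                # cosine of central angle
  diag(g) <- -Inf
  out <- lapply(seq_len(nrow(p)), function(i) {
    m$channel[order(g[i, ], decreasing = TRUE)[seq_len(k)]]
  })
  names(out) <- m$channel
  out
}

#' Cortical region and hemisphere lookup for 10-10 channels
#'
#' Returns the region ("frontal", "central", "temporal", "parietal",
#' "occipital") and hemisphere ("left", "right") grouping used by the
#' task-related power analysis. The left-hemisphere memberships follow the
#' odd-numbered electrode groups conventional in task-related power studies
#' of design cognition; right-hemisphere groups use the corresponding
#' even-numbered electrodes. Channels outside the grouping (midline and
#' sub-ring electrodes) are absent from the table.
#'
#' @return tibble with columns `channel`, `region`, `hemisphere`.
#' @export
region_table <- function() {
  left <- list(
    frontal  = c("Fp1", "AF3", "AF7", "F1", "F3", "F5", "F7", "FC1", "FC3"),
    central  = c("FC5", "C1", "C3", "C5"),
    temporal = c("FT7", "T7", "TP7", "CP5", "P5"),
    parietal = c("CP1", "CP3", "P1", "P3"),
    occipital = c("PO3", "PO7", "P7", "O1")
  )
  rows <- lapply(names(left), function(reg) {
    lch <- left[[reg]]
    rch <- vapply(lch, mirror_label, character(1L))
    tibble::tibble(
      channel = c(lch, rch),
      region = reg,
      hemisphere = rep(c("left", "right"), each = length(lch))
    )
  })
  dplyr::bind_rows(rows)
}
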