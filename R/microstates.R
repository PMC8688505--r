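#' Microstate models
#'
#' A `microstate_model` holds `k` unit-norm, zero-mean template
#' topographies (rows of `maps`), together with the fit diagnostics of the
#' modified k-means: the residual cost `F` (mean squared residual per
#' channel after projecting each sample onto its assigned map, normalised
#' by `n_samples * (n_channels - 1)`), the cross-validation criterion `cv`,
#' and the global explained variance `gev` at GFP peaks. A model is
#' equivalent under sign flip of any map (polarity invariance).
#'
#' @param maps k x channels numeric matrix.
#' @param channel_labels channel names matching the columns.
#' @param cost residual cost F of the fit (optional).
#' @param cv cross-validation criterion (optional).
#' @param gev global explained variance in `[0, 1]` (optional).
#' @param seed seed that produced the fit (optional, for reproducibility).
#' @param label_names optional per-class names (e.g. canonical letters).
#' @return A `microstate_model`.
#' @export
microstate_model <- function(maps, channel_labels = NULL, cost = NA_real_,
                             cv = NA_real_, gev = NA_real_, seed = NA_integer_,
                             label_names = NULL) {
  maps <- as.matrix(maps)
  norms <- sqrt(rowSums(maps^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop_microdyn("each microstate map must be unit-norm (1e-9)")
  }
  if (!is.null(channel_labels)) colnames(maps) <- channel_labels
  structure(
    list(maps = maps, k = nrow(maps), cost = cost, cv = cv, gev = gev,
         seed = seed, label_names = label_names),
    class = "microstate_model"
  )
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d, %d channels", x$k, ncol(x$maps)))
  if (is.finite(x$cost)) cat(sprintf(", F = %.4g", x$cost))
  if (is.finite(x$cv)) cat(sprintf(", CV = %.4g", x$cv))
  if (is.finite(x$gev)) cat(sprintf(", GEV = %.3f", x$gev))
  cat("\n")
  invisible(x)
}

#' Global field power
#'
#' The per-sample population standard deviation of the potentials across
#' electrodes (divisor `n_channels`, not `n_channels - 1`). GFP is
#' invariant to adding a constant to all channels at a sample; its peaks
#' mark the moments of maximal topographic signal strength that are
#' submitted to the clustering.
#'
#' @param rec an [eeg_recording] (or a channels x samples matrix).
#' @return A tibble with columns `time` (s) and `gfp` (microvolts),
#'   carrying the sampling rate as attribute `fs`.
#' @export
gfp <- function(rec) {
  x <- if (inherits(rec, "eeg_recording")) rec$data else as.matrix(rec)
  fs <- if (inherits(rec, "eeg_recording")) rec$fs else NA_real_
  if (nrow(x) < 2L) stop_microdyn("GFP needs at least 2 channels")
  mu <- colMeans(x)
  v <- sqrt(colMeans(x^2) - mu^2)
  v[v < 0] <- 0
  out <- tibble::tibble(
    time = if (is.finite(fs)) (seq_len(ncol(x)) - 1L) / fs else
      seq_len(ncol(x)) - 1,
    gfp = v
  )
  attr(out, "fs") <- fs
  out
}

#' Local maxima of a GFP series
#'
#' Strict local maxima of the GFP curve; on a plateau of tied values only
#' the first plateau sample counts. An optional minimum separation keeps,
#' among peaks closer than `min_separation_ms`, the higher one.
#'
#' @param series tibble from [gfp()], or a numeric vector.
#' @param min_separation_ms minimum separation between retained peaks
#'   (0 keeps all strict maxima).
#' @param fs sampling rate, required when `series` is a bare vector and
#'   `min_separation_ms > 0`.
#' @return integer vector of peak sample indices (1-based).
#' @export
gfp_peaks <- function(series, min_separation_ms = 0, fs = NULL) {
  if (is.data.frame(series)) {
    v <- series$gfp
    fs <- fs %||% attr(series, "fs")
  } else {
    v <- as.numeric(series)
  }
  n <- length(v)
  if (n < 3L) stop_microdyn("need at least 3 samples to find peaks")
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3L) return(integer())
  mid <- 2L:(nr - 1L)
  is_peak <- r$values[mid] > r$values[mid - 1L] &
    r$values[mid] > r$values[mid + 1L]
  peaks <- starts[mid][is_peak]
  if (min_separation_ms > 0) {
    if (is.null(fs) || !is.finite(fs)) {
      stop_microdyn("fs required for a minimum peak separation")
    }
    min_gap <- min_separation_ms * fs / 1000
    keep <- logical(length(peaks))
    taken <- numeric(0)
    for (i in order(v[peaks], decreasing = TRUE)) {
      if (!length(taken) || all(abs(peaks[i] - taken) >= min_gap)) {
        keep[i] <- TRUE
        taken <- c(taken, peaks[i])
      }
    }
    peaks <- sort(peaks[keep])
  }
  peaks
}

# centre columns (channels are rows? here samples x channels: centre rows)
center_rows <- function(v) v - rowMeans(v)

#' Modified k-means clustering of peak topographies
#'
#' The polarity-invariant k-means of microstate analysis: each sample
#' topography is assigned to the template map maximising the squared
#' spatial projection (polarity ignored), and each map is re-estimated as
#' the dominant eigenvector of its assigned samples' outer-product sum.
#' Iterations stop when the relative change of the residual cost `F` drops
#' below `tol`; the best of `n_restarts` random restarts (seeded from `k`
#' distinct peak topographies) is retained, and the cross-validation
#' criterion is evaluated on the winner.
#'
#' @param peak_maps samples x channels matrix of (average-referenced)
#'   topographies, typically the EEG at GFP peaks.
#' @param k number of classes.
#' @param n_restarts random restarts.
#' @param seed integer seed.
#' @param tol relative tolerance on `F`.
#' @param max_iter iteration cap per restart.
#' @return A [microstate_model] with `cost`, `cv` and `gev` filled in,
#'   plus attribute `assignments` (the winning hard assignment).
#' @export
modified_kmeans <- function(peak_maps, k, n_restarts = 100, seed = 1,
                            tol = 1e-6, max_iter = 1000) {
  v <- as.matrix(peak_maps)
  n <- nrow(v)
  n_ch <- ncol(v)
  if (n < k) stop_microdyn("need at least k samples, got %d < %d", n, k)
  v <- center_rows(v)
  ss_tot <- sum(v^2)
  denom <- n * (n_ch - 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    rs <- child_seed(seed, r)
    init <- with_seed(rs, sample.int(n, k))
    maps <- unit_cols(t(v[init, , drop = FALSE]))    # channels x k
    f_old <- Inf
    assign <- NULL
    f_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      proj <- v %*% maps                             # n x k
      p2 <- proj^2
      assign <- max.col(p2, ties.method = "first")
      fit2 <- p2[cbind(seq_len(n), assign)]
      f_new <- (ss_tot - sum(fit2)) / denom
      f_trace <- c(f_trace, f_new)
      # update: dominant eigenvector per cluster
      for (j in seq_len(k)) {
        idx <- which(assign == j)
        if (length(idx) == 0L) {
          # documented fallback: reseed an empty cluster from the worst-fit
          # sample under the current model
          worst <- which.min(fit2 / pmax(rowSums(v^2), .Machine$double.eps))
          maps[, j] <- v[worst, ] / sqrt(sum(v[worst, ]^2))
          next
        }
        s <- crossprod(v[idx, , drop = FALSE])       # n_ch x n_ch
        maps[, j] <- eigen(s, symmetric = TRUE)$vectors[, 1L]
      }
      if (is.finite(f_old) && (f_old - f_new) <= tol * max(f_old, .Machine$double.eps)) {
        f_old <- f_new
        break
      }
      f_old <- f_new
    }
    if (is.null(best) || f_old < best$cost) {
      best <- list(maps = maps, cost = f_old, assign = assign, seed = rs,
                   f_trace = f_trace)
    }
  }
  maps <- t(unit_cols(best$maps))                    # k x channels
  proj <- v %*% t(maps)
  p2 <- proj^2
  assign <- max.col(p2, ties.method = "first")
  fit2 <- p2[cbind(seq_len(n), assign)]
  f_final <- (ss_tot - sum(fit2)) / denom
  cv <- if (n_ch - 1 - k > 0) {
    f_final * ((n_ch - 1) / (n_ch - 1 - k))^2
  } else {
    NA_real_
  }
  model <- microstate_model(maps, channel_labels = colnames(peak_maps),
                            cost = f_final, cv = cv, seed = seed)
  model$gev <- gev_from_projection(v, fit2)
  attr(model, "assignments") <- assign
  attr(model, "f_trace") <- best$f_trace
  model
}

# GEV given centred samples and their squared fitted projections
gev_from_projection <- function(v_centred, fit2) {
  ss <- rowSums(v_centred^2)
  ok <- ss > 0
  sum(fit2[ok]) / sum(ss[ok])
}

#' Select the number of microstate classes by cross-validation
#'
#' Fits the modified k-means for each `k` in `k_range` and returns the `k`
#' minimising the cross-validation criterion
#' `CV = sigma_hat^2 * ((n_ch - 1) / (n_ch - 1 - k))^2`. Values of `k` for
#' which the penalty denominator is non-positive are skipped with a
#' warning. All per-`k` models are retained for reporting.
#'
#' @inheritParams modified_kmeans
#' @param k_range integer vector of candidate class counts.
#' @return list with elements `k_opt`, `models` (named list per k) and
#'   `cv` (tibble of k and CV values).
#' @export
select_optimal_k <- function(peak_maps, k_range = 2:10, n_restarts = 100,
                             seed = 1) {
  n_ch <- ncol(peak_maps)
  models <- list()
  rows <- list()
  for (k in k_range) {
    if (n_ch - 1 - k <= 0) {
      warn_microdyn("k = %d skipped: CV undefined for %d channels", k, n_ch)
      next
    }
    m <- modified_kmeans(peak_maps, k, n_restarts = n_restarts,
                         seed = child_seed(seed, k))
    models[[as.character(k)]] <- m
    rows[[length(rows) + 1L]] <- tibble::tibble(k = k, cost = m$cost,
                                                cv = m$cv, gev = m$gev)
  }
  if (!length(rows)) stop_microdyn("no admissible k in k_range")
  cv_tab <- dplyr::bind_rows(rows)
  k_opt <- cv_tab$k[which.min(cv_tab$cv)]
  list(k_opt = k_opt, models = models, cv = cv_tab)
}

#' Align subject-level microstate maps into a group model
#'
#' Finds, for every subject model, the label permutation (with sign flips
#' absorbed by the polarity-invariant correlation) that maximises the mean
#' absolute spatial correlation with the evolving group-mean maps, then
#' re-estimates each group map as the dominant eigenvector of the aligned
#' subject maps. Sweeps repeat until the permutations stabilise.
#' Permutations are searched exhaustively for `k <= 8` (5040 candidates at
#' `k = 7`) and by a greedy best-match with pairwise exchange refinement
#' beyond that.
#'
#' @param subject_models list of [microstate_model]s sharing `k` and the
#'   channel set.
#' @param max_sweeps sweep cap.
#' @return list with `group_model` (a [microstate_model]), `permutations`
#'   (list of integer vectors: group class -> subject class), and
#'   `mean_abs_corr`.
#' @export
align_maps_group <- function(subject_models, max_sweeps = 100) {
  k <- unique(vapply(subject_models, function(m) m$k, integer(1L)))
  if (length(k) != 1L) stop_microdyn("all models must share k")
  n_ch <- unique(vapply(subject_models, function(m) ncol(m$maps), integer(1L)))
  if (length(n_ch) != 1L) stop_microdyn("all models must share the channel set")
  ns <- length(subject_models)
  group <- subject_models[[1L]]$maps                    # k x n_ch
  perms <- replicate(ns, seq_len(k), simplify = FALSE)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    new_perms <- lapply(subject_models, function(m) {
      best_permutation(abs(map_correlation(group, m$maps)))
    })
    # re-estimate group maps as dominant eigenvectors (sign-agnostic mean)
    for (j in seq_len(k)) {
      s <- matrix(0, n_ch, n_ch)
      for (i in seq_len(ns)) {
        mj <- subject_models[[i]]$maps[new_perms[[i]][j], ]
        s <- s + tcrossprod(mj)
      }
      group[j, ] <- eigen(s, symmetric = TRUE)$vectors[, 1L]
    }
    group <- group - rowMeans(group)
    group <- group / sqrt(rowSums(group^2))
    if (identical(new_perms, perms)) {
      perms <- new_perms
      converged <- TRUE
      break
    }
    perms <- new_perms
  }
  if (!converged) {
    warn_microdyn("group alignment did not stabilise in %d sweeps", max_sweeps)
  }
  mac <- mean(vapply(seq_len(ns), function(i) {
    cc <- abs(map_correlation(group, subject_models[[i]]$maps))
    mean(cc[cbind(seq_len(k), perms[[i]])])
  }, numeric(1L)))
  gm <- microstate_model(group,
                         channel_labels = colnames(subject_models[[1L]]$maps))
  list(group_model = gm, permutations = perms, mean_abs_corr = mac)
}

# Pearson correlation between rows of two map matrices (k1 x n, k2 x n)
map_correlation <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  ac <- ac / sqrt(rowSums(ac^2))
  bc <- bc / sqrt(rowSums(bc^2))
  tcrossprod(ac, bc)
}

# permutation maximising sum of score[i, perm[i]]
best_permutation <- function(score) {
  k <- nrow(score)
  if (k <= 8L) {
    perms <- permutations_all(k)
    idx <- cbind(rep(seq_len(k), nrow(perms)), as.vector(t(perms)))
    sums <- rowSums(matrix(score[idx], nrow(perms), k, byrow = TRUE))
    perms[which.max(sums), ]
  } else {
    # greedy assignment + pairwise-exchange polish
    perm <- integer(k)
    taken <- logical(k)
    for (i in order(apply(score, 1L, max), decreasing = TRUE)) {
      j <- order(score[i, ], decreasing = TRUE)
      j <- j[!taken[j]][1L]
      perm[i] <- j
      taken[j] <- TRUE
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
        cur <- score[a, perm[a]] + score[b, perm[b]]
        swp <- score[a, perm[b]] + score[b, perm[a]]
        if (swp > cur + 1e-12) {
          tmp <- perm[a]; perm[a] <- perm[b]; perm[b] <- tmp
          improved <- TRUE
        }
      }
    }
    perm
  }
}

permutations_all <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  idx <- 1L
  for (pos in seq_len(k)) {
    for (r in seq_len(nrow(sub))) {
      out[idx, ] <- append(sub[r, ], k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Back-fit microstate maps to a recording
#'
#' Assigns every sample of the recording to the template map with the
#' highest absolute spatial correlation (polarity ignored). No temporal
#' smoothing or minimum-duration constraint is applied, so the temporal
#' statistics of the resulting sequence are unmodified. Samples with zero
#' GFP carry the previous sample's label (tie rule); exact ties in the
#' argmax go to the lowest class index.
#'
#' @param rec an [eeg_recording] (average-referenced).
#' @param model a [microstate_model] on the same channel set.
#' @return A [label_sequence] at the recording's sampling rate.
#' @export
backfit <- function(rec, model) {
  x <- t(rec$data)                                   # samples x channels
  if (ncol(x) != ncol(model$maps)) {
    stop_microdyn("recording and model channel sets differ")
  }
  xc <- center_rows(x)
  maps <- model$maps - rowMeans(model$maps)
  maps <- maps / sqrt(rowSums(maps^2))
  p2 <- (xc %*% t(maps))^2
  labels <- max.col(p2, ties.method = "first")
  zero <- rowSums(xc^2) < .Machine$double.eps * ncol(x)
  if (any(zero)) {
    idx <- which(!zero)
    if (!length(idx)) stop_microdyn("recording has zero GFP everywhere")
    # carry the previous non-degenerate label forward (and backward at the
    # start of the record)
    filled <- labels
    pos <- findInterval(seq_along(labels), idx)
    pos[pos == 0L] <- 1L
    filled[zero] <- labels[idx][pos[zero]]
    labels <- filled
  }
  label_sequence(labels, fs = rec$fs, n_classes = model$k,
                 condition = if (nrow(rec$annotations) > 0)
                   rec$annotations$condition[1L] else NA_character_)
}

#' Global explained variance at GFP peaks
#'
#' The GFP^2-weighted mean of the squared spatial correlation between each
#' peak topography and its assigned template map — the share of the
#' topographic variance at GFP peaks captured by the model.
#'
#' @param peak_maps samples x channels matrix of peak topographies.
#' @param model a [microstate_model].
#' @param labels integer assignment of each peak row to a class (defaults
#'   to the model's own argmax assignment).
#' @return scalar in `[0, 1]`.
#' @export
gev <- function(peak_maps, model, labels = NULL) {
  v <- center_rows(as.matrix(peak_maps))
  if (nrow(v) == 0L) stop_microdyn("gev needs at least one peak")
  maps <- model$maps - rowMeans(model$maps)
  maps <- maps / sqrt(rowSums(maps^2))
  proj <- v %*% t(maps)
  if (is.null(labels)) {
    labels <- max.col(proj^2, ties.method = "first")
  }
  fit2 <- proj[cbind(seq_len(nrow(v)), labels)]^2
  gev_from_projection(v, fit2)
}

#' Duration, occurrence and coverage of a label sequence
#'
#' Run-length statistics per microstate class: mean duration (ms) of the
#' uninterrupted runs of the class, occurrence (runs per second) and
#' coverage (fraction of samples). A class absent from the sequence has
#' missing duration, zero occurrence and zero coverage. Coverages sum to
#' one exactly.
#'
#' @param seq a [label_sequence].
#' @return tibble with columns `class`, `n_runs`, `duration_ms`,
#'   `occurrence_hz`, `coverage`.
#' @export
microstate_parameters <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"))
  fs <- seq_fs(seq)
  k <- seq_classes(seq)
  total_s <- length(seq) / fs
  runs <- run_lengths(seq)
  per <- dplyr::summarise(
    dplyr::group_by(runs, .data$class),
    n_runs = dplyr::n(),
    mean_len = mean(.data$length),
    n_samples = sum(.data$length),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(class = seq_len(k)), per,
                          by = "class")
  tibble::tibble(
    class = out$class,
    n_runs = ifelse(is.na(out$n_runs), 0L, out$n_runs),
    duration_ms = out$mean_len * 1000 / fs,
    occurrence_hz = ifelse(is.na(out$n_runs), 0, out$n_runs / total_s),
    coverage = ifelse(is.na(out$n_samples), 0, out$n_samples / length(seq))
  )
}
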