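#' Tidy a microstate model
#'
#' One row per (class, channel) with the template map value.
#'
#' @param x a [microstate_model].
#' @param ... unused.
#' @return tibble `class`, `channel`, `value`.
#' @export
tidy.microstate_model <- function(x, ...) {
  ch <- colnames(x$maps) %||% paste0("ch", seq_len(ncol(x$maps)))
  tibble::tibble(
    class = rep(seq_len(x$k), times = ncol(x$maps)),
    channel = rep(ch, each = x$k),
    value = as.vector(x$maps)
  )
}

#' @export
glance.microstate_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_channels = ncol(x$maps), cost = x$cost,
                 cv = x$cv, gev = x$gev)
}

#' Tidy sequence-dynamics results
#'
#' @param x a [seq_dynamics] object.
#' @param ... unused.
#' @return one-row tibble of the scalar statistics.
#' @export
tidy.seq_dynamics <- function(x, ...) {
  tibble::tibble(
    entropy_rate = x$entropy_rate,
    entropy_history = x$k,
    aif_first_peak_ms = x$first_peak_latency_ms,
    hurst_mean = x$hurst_mean,
    n_partitions = nrow(x$hurst_per_partition),
    n_samples = x$n_samples
  )
}

#' @export
glance.seq_dynamics <- tidy.seq_dynamics

#' Tidy a QC report
#'
#' @param x a [qc_report].
#' @param ... unused.
#' @return tibble with one row per flagged item (`stage`, `epoch`,
#'   `channel`, `criterion`).
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$bad_global_channels, stage = "global_channel",
                  epoch = NA_integer_),
    dplyr::mutate(x$bad_segments, stage = "segment",
                  channel = NA_character_),
    dplyr::mutate(x$interpolated_local, stage = "local_channel")
  )
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_bad_channels = nrow(x$bad_global_channels),
    n_rejected_epochs = length(unique(x$bad_segments$epoch)),
    n_local_interpolations = nrow(x$interpolated_local),
    fraction_rejected = x$fraction_rejected
  )
}

#' Tidy a cohort report
#'
#' The per-(participant, condition) sequence-dynamics table — the
#' cohort's primary outcome.
#'
#' @param x a `cohort_report` from [run_study()].
#' @param table which table to return: "dynamics", "parameters", "trp" or
#'   "qc".
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cohort_report <- function(x, table = c("dynamics", "parameters",
                                            "trp", "qc"), ...) {
  switch(match.arg(table),
         dynamics = x$dynamics_condition,
         parameters = x$parameters_condition,
         trp = x$trp_regions,
         qc = x$qc)
}

#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    n_participants = length(unique(x$meta$participant)),
    n_recordings = nrow(x$meta),
    k = x$group_model$k,
    alignment_mean_abs_corr = x$alignment$mean_abs_corr
  )
}
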