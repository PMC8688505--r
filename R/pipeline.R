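#' Configuration of a synthetic study
#'
#' Describes the synthetic cohort emulating the package's reference study
#' layout: an eyes-closed resting block plus five self-paced task
#' conditions (problem understanding PU, idea generation IG, rating idea
#' generation RIG, idea evaluation IE, rating idea evaluation RIE), each
#' task recorded in several runs. Per-condition dynamics plant the
#' contrast the sequence statistics should recover: the idea-generation
#' condition switches between microstates with the least temporal
#' structure (memoryless, fastest switching), while the reading/rating
#' conditions carry long-range-correlated switching; task alpha power is
#' scaled down relative to rest to emulate task-related
#' desynchronisation.
#'
#' @param n_participants cohort size.
#' @param runs_per_condition task runs per condition.
#' @param run_length_s length of every recording, seconds.
#' @param fs acquisition sampling rate, Hz.
#' @param fs_analysis analysis rate after downsampling, Hz.
#' @param k number of planted microstate classes.
#' @param snr signal-to-noise amplitude ratio of the rest recordings;
#'   task recordings share the rest noise level, so their effective ratio
#'   scales with the alpha amplitude.
#' @param carrier_freq_hz oscillatory carrier frequency.
#' @param conditions named list of per-condition settings, each a list
#'   with `dynamics` ("markov" or "lrc"), `mean_duration_ms`, `hurst`
#'   (for "lrc") and `amplitude` (alpha amplitude relative to rest).
#' @param seed master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 8, runs_per_condition = 2,
                         run_length_s = 60, fs = 500, fs_analysis = 250,
                         k = 7, snr = 2, carrier_freq_hz = 10,
                         conditions = NULL, seed = 1) {
  default_conditions <- list(
    REST = list(dynamics = "lrc", mean_duration_ms = 60, hurst = 0.70,
                amplitude = 1.0),
    PU   = list(dynamics = "lrc", mean_duration_ms = 60, hurst = 0.72,
                amplitude = 0.85),
    IG   = list(dynamics = "markov", mean_duration_ms = 45, hurst = NA,
                amplitude = 0.60),
    RIG  = list(dynamics = "lrc", mean_duration_ms = 65, hurst = 0.78,
                amplitude = 0.90),
    IE   = list(dynamics = "markov", mean_duration_ms = 50, hurst = NA,
                amplitude = 0.70),
    RIE  = list(dynamics = "lrc", mean_duration_ms = 65, hurst = 0.78,
                amplitude = 0.90)
  )
  conditions <- conditions %||% default_conditions
  if (!"REST" %in% names(conditions)) {
    stop_microdyn("a REST condition is required as the TRP reference")
  }
  structure(
    list(n_participants = n_participants,
         runs_per_condition = runs_per_condition,
         run_length_s = run_length_s, fs = fs, fs_analysis = fs_analysis,
         k = k, snr = snr, carrier_freq_hz = carrier_freq_hz,
         conditions = conditions, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Simulate a full synthetic study
#'
#' Generates every recording of the configured cohort: shared planted
#' template maps on the built-in 10-10 montage, per-run planted label
#' sequences with the per-condition dynamics, and noisy recordings with a
#' common noise level across conditions (so planted amplitude scalings
#' survive as absolute power differences).
#'
#' @param config a [study_config].
#' @return list with `recordings` (named list of [eeg_recording]s),
#'   `meta` (tibble `name`, `participant`, `condition`, `run`),
#'   `maps` (the planted [microstate_model]), and `truth` (named list of
#'   planted [label_sequence]s).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  mont <- montage_1010()
  maps <- make_template_maps(mont, config$k,
                             seed = child_seed(config$seed, 1L))
  n <- as.integer(config$run_length_s * config$fs)
  recordings <- list()
  truth <- list()
  meta <- list()
  idx <- 0L
  for (p in seq_len(config$n_participants)) {
    for (cond in names(config$conditions)) {
      cs <- config$conditions[[cond]]
      n_runs <- if (cond == "REST") 1L else config$runs_per_condition
      for (r in seq_len(n_runs)) {
        idx <- idx + 1L
        seed_r <- child_seed(config$seed, 1000L * p + 37L * idx)
        cfg <- synth_config(
          n_channels = nrow(mont), fs = config$fs, k_true = config$k,
          mean_duration_ms = cs$mean_duration_ms,
          carrier_freq_hz = config$carrier_freq_hz,
          snr = config$snr * cs$amplitude, seed = seed_r
        )
        labs <- if (cs$dynamics == "lrc") {
          simulate_lrc_label_sequence(cfg, n, H = cs$hurst)
        } else {
          simulate_label_sequence(cfg, n)
        }
        ann <- tibble::tibble(onset = 0, duration = config$run_length_s,
                              condition = cond, run = r)
        rec <- simulate_eeg(maps, labs, cfg, montage = mont,
                            amplitude_uv = 15 * cs$amplitude,
                            annotations = ann)
        name <- sprintf("p%02d_%s_r%d", p, cond, r)
        recordings[[name]] <- rec
        truth[[name]] <- labs
        meta[[length(meta) + 1L]] <- tibble::tibble(
          name = name, participant = sprintf("p%02d", p),
          condition = cond, run = r)
      }
    }
  }
  list(recordings = recordings, meta = dplyr::bind_rows(meta),
       maps = maps, truth = truth)
}

#' Run the full analysis pipeline on a study
#'
#' Executes, in order: preprocessing of every recording, task-related
#' power analysis against the first resting block (per-band
#' condition-area-hemisphere ANOVA and Bonferroni post-hocs), microstate
#' model fitting per run (class count forced to `fit_k` for
#' comparability), group map alignment, back-fitting, microstate
#' parameters with their condition-by-class ANOVAs, and sequence
#' dynamics (entropy rate, autoinformation latency, partition-averaged
#' Hurst exponent) with one-way condition ANOVAs. Every stage failure
#' aborts with an error naming the stage.
#'
#' @param study output of [simulate_study()], or a list with the same
#'   shape holding real recordings.
#' @param fit_k class count of the per-run models.
#' @param n_restarts k-means restarts per fit.
#' @param scan_k optional integer range; when given, the cross-validation
#'   optimal class count is additionally computed per run and logged.
#' @param entropy_k entropy-rate history length.
#' @param fs_analysis analysis sampling rate.
#' @param seed seed for the model fits.
#' @param verbose print stage progress?
#' @return A `cohort_report` (list of tables and test results).
#' @export
run_study <- function(study, fit_k = 7, n_restarts = 10, scan_k = NULL,
                      entropy_k = 6, fs_analysis = 250, seed = 1,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_microdyn("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))
    })
  }
  meta <- study$meta
  ## --- preprocessing -----------------------------------------------------
  say("preprocessing %d recordings", nrow(meta))
  qc_list <- list()
  cleaned <- stage("preprocess", {
    out <- list()
    for (nm in meta$name) {
      res <- suppressWarnings(
        preprocess(study$recordings[[nm]], fs_new = fs_analysis))
      out[[nm]] <- res$recording
      qc_list[[nm]] <- res$qc
    }
    out
  })
  ## --- task-related power ------------------------------------------------
  say("task-related power")
  trp_tab <- stage("trp", band_power_table(cleaned, meta))
  trp_regions <- stage("trp", suppressWarnings(aggregate_regions(trp_tab)))
  trp_anova <- list()
  trp_posthoc <- list()
  for (b in unique(trp_regions$band)) {
    sub <- trp_regions[trp_regions$band == b, ]
    # statistics degrade gracefully on cohorts too small to test (< 3
    # subjects); the error object is kept in place of the table
    trp_anova[[b]] <- tryCatch(suppressWarnings(
      rm_anova(sub, dv = "trp",
               within = c("condition", "region", "hemisphere"))),
      error = function(e) e)
    trp_posthoc[[b]] <- tryCatch(bonferroni_posthoc(
      sub, dv = "trp", condition = "condition", within = "region"),
      error = function(e) e)
  }
  ## --- microstates -------------------------------------------------------
  say("fitting microstate models")
  models <- list()
  scan_tab <- list()
  fit <- stage("microstates", {
    for (nm in meta$name) {
      rec <- cleaned[[nm]]
      g <- gfp(rec)
      pk <- gfp_peaks(g)
      pm <- t(rec$data[, pk, drop = FALSE])
      models[[nm]] <- modified_kmeans(pm, fit_k, n_restarts = n_restarts,
                                      seed = child_seed(seed, length(models)))
      if (!is.null(scan_k)) {
        sel <- select_optimal_k(pm, k_range = scan_k,
                                n_restarts = n_restarts,
                                seed = child_seed(seed, length(models)))
        scan_tab[[nm]] <- tibble::tibble(name = nm, k_opt = sel$k_opt)
      }
    }
    models
  })
  say("aligning group maps")
  alignment <- stage("alignment", align_maps_group(fit))
  group_model <- alignment$group_model
  say("back-fitting")
  sequences <- stage("backfit", {
    out <- list()
    for (nm in meta$name) out[[nm]] <- backfit(cleaned[[nm]], group_model)
    out
  })
  ## --- microstate parameters --------------------------------------------
  params <- stage("parameters", {
    rows <- lapply(seq_len(nrow(meta)), function(i) {
      pp <- microstate_parameters(sequences[[meta$name[i]]])
      pp$participant <- meta$participant[i]
      pp$condition <- meta$condition[i]
      pp$run <- meta$run[i]
      pp
    })
    dplyr::bind_rows(rows)
  })
  param_cond <- dplyr::summarise(
    dplyr::group_by(params, .data$participant, .data$condition, .data$class),
    duration_ms = mean(.data$duration_ms),
    occurrence_hz = mean(.data$occurrence_hz),
    coverage = mean(.data$coverage), .groups = "drop")
  param_anova <- list()
  for (pv in c("coverage", "duration_ms", "occurrence_hz")) {
    param_anova[[pv]] <- tryCatch(
      suppressWarnings(rm_anova(param_cond, dv = pv,
                                within = c("condition", "class"))),
      error = function(e) e)
  }
  ## --- sequence dynamics -------------------------------------------------
  say("sequence dynamics")
  dyn <- stage("seqstats", {
    rows <- lapply(seq_len(nrow(meta)), function(i) {
      d <- suppressWarnings(
        seq_dynamics(sequences[[meta$name[i]]], k = entropy_k))
      tibble::tibble(participant = meta$participant[i],
                     condition = meta$condition[i], run = meta$run[i],
                     entropy_rate = d$entropy_rate,
                     aif_first_peak_ms = d$first_peak_latency_ms,
                     hurst_mean = d$hurst_mean)
    })
    dplyr::bind_rows(rows)
  })
  dyn_cond <- dplyr::summarise(
    dplyr::group_by(dyn, .data$participant, .data$condition),
    entropy_rate = mean(.data$entropy_rate),
    aif_first_peak_ms = mean(.data$aif_first_peak_ms, na.rm = TRUE),
    hurst_mean = mean(.data$hurst_mean), .groups = "drop")
  dyn_tests <- list(
    entropy_rate = tryCatch(
      suppressMessages(suppressWarnings(condition_anova_seqstats(
        dyn_cond, dv = "entropy_rate"))), error = function(e) e),
    hurst_mean = tryCatch(
      suppressMessages(suppressWarnings(condition_anova_seqstats(
        dyn_cond, dv = "hurst_mean"))), error = function(e) e)
  )
  ## --- QC summary ---------------------------------------------------------
  qc_summary <- dplyr::bind_rows(lapply(names(qc_list), function(nm) {
    q <- qc_list[[nm]]
    tibble::tibble(name = nm,
                   n_bad_channels = nrow(q$bad_global_channels),
                   n_rejected_epochs = length(unique(q$bad_segments$epoch)),
                   fraction_rejected = q$fraction_rejected,
                   n_local_interpolations = nrow(q$interpolated_local))
  }))
  structure(
    list(meta = meta,
         trp = trp_tab, trp_regions = trp_regions,
         trp_anova = trp_anova, trp_posthoc = trp_posthoc,
         models = fit, group_model = group_model, alignment = alignment,
         k_scan = if (length(scan_tab)) dplyr::bind_rows(scan_tab) else NULL,
         sequences = sequences,
         parameters = params, parameters_condition = param_cond,
         parameter_anova = param_anova,
         dynamics = dyn, dynamics_condition = dyn_cond,
         dynamics_tests = dyn_tests,
         qc = qc_summary),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d participants, %d recordings\n",
              length(unique(x$meta$participant)), nrow(x$meta)))
  cat(sprintf("  group model: k = %d, mean |corr| to subjects = %.3f\n",
              x$group_model$k, x$alignment$mean_abs_corr))
  agg <- dplyr::summarise(
    dplyr::group_by(x$dynamics_condition, .data$condition),
    entropy_rate = mean(.data$entropy_rate),
    hurst = mean(.data$hurst_mean), .groups = "drop")
  cat("  sequence dynamics by condition:\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("    %-5s entropy %.3f bits/sample, Hurst %.3f\n",
                agg$condition[i], agg$entropy_rate[i], agg$hurst[i]))
  }
  invisible(x)
}
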