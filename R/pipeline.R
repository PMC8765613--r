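# End-to-end pipeline orchestration: synth -> preprocess -> respiration ->
# spectral -> band dynamics -> behavior -> pac, with TSV/JSON outputs and a
# run report.

#' Default pipeline configuration
#'
#' All stage parameters in one list; sizes default to a small smoke-scale run
#' (full-scale values from the source analyses are noted per field). Override
#' any entry via `pipeline_config(n_perm = 10000, ...)`.
#'
#' @param out_dir output directory.
#' @param recording,events optional paths to an existing recording container
#'   and event TSV; when NULL the synth stage generates them.
#' @param ... overrides for any config entry (see Details in the source).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("odorosc_run_"),
                            recording = NULL, events = NULL, ...) {
  cfg <- list(
    out_dir = out_dir, recording = recording, events = events,
    stages = c("synth", "preprocess", "respiration", "spectral",
               "dynamics", "behavior", "pac"),
    synth = synth_config(n_trials = 40, seed = 1),
    target_rate = 500, lowpass = 235, notch_base = 60, notch_bandwidth = 4,
    epoch_window = c(-2, 4), baseline_window = c(-0.55, -0.05),
    n_perm = 200,            # 10000 at full scale
    q = 0.05,
    bank_step = 4,           # keep every 4th filter-bank band for spectrograms
    cluster_p = 0.01, cluster_n_perm = 200,
    bootstrap_reps = 200,    # 2000 at full scale
    peak_phase_reps = 200,   # repetition count for the peak-phase bootstrap
    balanced_n_each = NULL,  # default: number of incorrect trials (71 at full scale)
    balanced_reps = 200,
    corr_inner = 200, corr_outer = 20,   # 1000 / 50 at full scale
    svm_reps = 100, svm_n_per_class = 30, svm_folds = 5, svm_C = 1,
    pac_window = c(0, 1), pac_bins = 18, pac_n_perm = 200,  # 1000 at full scale
    seed = 7
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

zmap_to_tsv <- function(zm, path) {
  long <- expand.grid(time_s = zm$time_axis, band_hz = zm$band_centers)
  long <- long[, c("band_hz", "time_s")]
  long$z <- as.vector(t(zm$z))
  long$sig <- as.vector(t(zm$significance_mask))
  write_tsv(long, path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on either a generated
#' synthetic session or supplied recording + event files, writing TSV/JSON
#' results and a resolved-config echo to `out_dir`. Any stage failure aborts
#' with the completed stages reported in the error.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: list of per-stage output paths, parameter echo,
#'   wall-clock seconds per stage, and collected warnings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(outputs = list(), timings = list(), warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, conditionMessage(w))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- withCallingHandlers(expr, warning = function(w) {
      note(w); invokeRestart("muffleWarning")
    })
    report$timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    value
  }
  enabled <- function(s) s %in% config$stages

  # --- synth / inputs --------------------------------------------------------
  if (enabled("synth") && is.null(config$recording)) {
    sim <- stage("synth", generate_recording(config$synth))
    rec_raw <- sim$recording
    events <- sim$events
    resp_trace <- sim$respiration
    rec_path <- file.path(config$out_dir, "recording.tsv")
    write_recording(rec_raw, rec_path)
    ev_path <- file.path(config$out_dir, "events.tsv")
    write_events(events, ev_path)
    jsonlite::write_json(sim$truth, file.path(config$out_dir, "truth.json"),
                         dataframe = "rows", digits = NA)
    report$outputs$synth <- c(rec_path, ev_path,
                              file.path(config$out_dir, "truth.json"))
  } else {
    if (is.null(config$recording) || is.null(config$events)) {
      stop("no input: provide recording + events paths or enable the synth stage")
    }
    rec_raw <- read_recording(config$recording)
    events <- read_events(config$events)
    resp_trace <- NULL
  }

  # --- preprocess ------------------------------------------------------------
  rec <- if (enabled("preprocess")) {
    stage("preprocess", preprocess_recording(
      rec_raw, cutoff = config$lowpass, base = config$notch_base,
      bandwidth = config$notch_bandwidth, target_rate = config$target_rate))
  } else rec_raw

  # --- respiration -----------------------------------------------------------
  if (enabled("respiration") && !is.null(resp_trace)) {
    breaths <- stage("respiration", detect_breaths(resp_trace$trace,
                                                   resp_trace$sampling_rate))
    n <- min(lengths(breaths[c("inhale_onsets", "exhale_onsets",
                               "peak_times", "trough_times")]))
    breath_tab <- data.frame(
      inhale_onset_s = breaths$inhale_onsets[seq_len(n)],
      exhale_onset_s = breaths$exhale_onsets[seq_len(n)],
      peak_time_s = breaths$peak_times[seq_len(n)],
      trough_time_s = breaths$trough_times[seq_len(n)])
    report$outputs$respiration <-
      write_tsv(breath_tab, file.path(config$out_dir, "breaths.tsv"))
  }

  # --- spectral --------------------------------------------------------------
  bank <- build_filter_bank()
  bank_sub <- bank[seq(1, nrow(bank), by = config$bank_step), ]
  odor_ev <- events[events$condition == "odor", ]
  if (enabled("spectral")) {
    stack <- stage("spectral", amplitude_stack(rec, bank_sub))
    zm <- stage("spectral_zmap", circular_shift_zmap(
      stack, odor_ev, config$epoch_window, config$baseline_window,
      n_perm = config$n_perm, q = config$q, seed = config$seed))
    report$outputs$spectral <-
      zmap_to_tsv(zm, file.path(config$out_dir, "zmap_odor.tsv"))
    no_odor_ev <- events[events$condition == "no_odor", ]
    if (nrow(no_odor_ev) >= 5) {
      ta <- baseline_correct(epoch_stack(stack, odor_ev, config$epoch_window),
                             stack, config$baseline_window)
      tb <- baseline_correct(epoch_stack(stack, no_odor_ev, config$epoch_window),
                             stack, config$baseline_window)
      zd <- stage("spectral_diff", condition_difference_zmap(
        ta, tb, n_perm = config$n_perm, q = config$q, seed = config$seed))
      report$outputs$spectral_diff <-
        zmap_to_tsv(zd, file.path(config$out_dir, "zmap_odor_vs_no_odor.tsv"))
    }
  }

  # --- band dynamics ---------------------------------------------------------
  if (enabled("dynamics")) {
    if (!enabled("spectral")) stop("dynamics stage requires the spectral stage")
    tz <- baseline_correct(epoch_stack(stack, odor_ev, config$epoch_window),
                           stack, config$baseline_window, z_normalize = TRUE)
    cluster_rows <- list(); phase_rows <- list()
    resp_epochs <- NULL
    if (!is.null(resp_trace)) {
      resp_rec <- continuous_recording(resp_trace$trace,
                                       resp_trace$sampling_rate)
      if (resp_rec$sampling_rate != rec$sampling_rate) {
        resp_rec <- downsample(resp_rec, rec$sampling_rate)
      }
      resp_stack <- structure(list(amplitudes = resp_rec$samples,
                                   band_centers = 0,
                                   sampling_rate = resp_rec$sampling_rate,
                                   start_time = 0), class = "amplitude_stack")
      re <- epoch_stack(resp_stack, tz$meta, config$epoch_window)
      resp_epochs <- re$amplitudes[, 1, ]
    }
    for (bn in names(band_definitions())) {
      series <- stage(paste0("dynamics_", bn),
                      band_average(tz, bn))
      cl <- cluster_mass_test(series, config$cluster_p,
                              n_perm = config$cluster_n_perm,
                              seed = config$seed)
      if (nrow(cl$clusters)) {
        cluster_rows[[bn]] <- data.frame(band = bn, cl$clusters)
      }
      if (!is.null(resp_epochs)) {
        ps <- peak_phase_bootstrap(series, resp_epochs, tz$time_axis,
                                   rec$sampling_rate,
                                   reps = config$peak_phase_reps,
                                   seed = config$seed)
        phase_rows[[bn]] <- data.frame(
          band = bn, mean_angle_rad = ps$mean_angle, plv = ps$plv,
          rayleigh_z = ps$rayleigh_z, rayleigh_p = ps$rayleigh_p)
      }
    }
    # pointwise odor vs no-odor percent-change comparison (trial counts
    # matched by subsampling no-odor without replacement)
    no_odor_ev <- events[events$condition == "no_odor", ]
    if (nrow(no_odor_ev) >= 3) {
      set.seed(config$seed)
      traw_o <- attach_baseline(epoch_stack(stack, odor_ev, config$epoch_window),
                                stack, config$baseline_window)
      traw_n <- attach_baseline(epoch_stack(stack, no_odor_ev, config$epoch_window),
                                stack, config$baseline_window)
      n_match <- min(nrow(traw_o$meta), nrow(traw_n$meta))
      keep_o <- sort(sample(nrow(traw_o$meta), n_match))
      keep_n <- sort(sample(nrow(traw_n$meta), n_match))
      lat_rows <- list()
      for (bn in names(band_definitions())) {
        so <- band_average(traw_o, bn); sn <- band_average(traw_n, bn)
        pco <- percent_change(so[keep_o, , drop = FALSE],
                              attr(so, "baseline")[keep_o])
        pcn <- percent_change(sn[keep_n, , drop = FALSE],
                              attr(sn, "baseline")[keep_n])
        attr(pco, "time_axis") <- traw_o$time_axis
        pt <- pointwise_condition_test(pco, pcn, q = config$q)
        lat_rows[[bn]] <- data.frame(band = bn, onset_s = pt$onset,
                                     offset_s = pt$offset,
                                     n_sig = sum(pt$mask))
      }
      report$outputs$latencies <- write_tsv(
        do.call(rbind, lat_rows), file.path(config$out_dir, "latencies.tsv"))
    }
    if (length(cluster_rows)) {
      report$outputs$clusters <- write_tsv(
        do.call(rbind, cluster_rows), file.path(config$out_dir, "clusters.tsv"))
    }
    if (length(phase_rows)) {
      report$outputs$peak_phase <- write_tsv(
        do.call(rbind, phase_rows), file.path(config$out_dir, "peak_phase.tsv"))
    }
  }

  # --- behavior --------------------------------------------------------------
  if (enabled("behavior")) {
    if (!enabled("dynamics")) stop("behavior stage requires the dynamics stage")
    if (!"correct" %in% names(odor_ev) || all(is.na(odor_ev$correct))) {
      stop("behavior stage needs a 'correct' column in the event table")
    }
    n_each <- config$balanced_n_each
    if (is.null(n_each)) n_each <- max(sum(!tz$meta$correct), 2)
    bod <- stage("behavior_balanced", balanced_outcome_difference(
      tz, n_each = n_each, reps = config$balanced_reps, seed = config$seed))
    diff_tab <- data.frame(
      band = names(bod$t_vs_zero),
      mean_difference = vapply(bod$t_vs_zero, `[[`, numeric(1), "mean"),
      t = vapply(bod$t_vs_zero, `[[`, numeric(1), "t"),
      p = vapply(bod$t_vs_zero, `[[`, numeric(1), "p"),
      boot_z = vapply(bod$bootstrap_z, `[[`, numeric(1), "z"),
      boot_p = vapply(bod$bootstrap_z, `[[`, numeric(1), "p"))
    report$outputs$balanced <- write_tsv(
      diff_tab, file.path(config$out_dir, "outcome_differences.tsv"))

    traw <- attach_baseline(epoch_stack(stack, odor_ev, config$epoch_window),
                            stack, config$baseline_window)
    svm_tab <- list()
    for (bn in names(band_definitions())) {
      series <- band_average(traw, bn)
      ev <- stage(paste0("behavior_svm_", bn), svm_separability(
        series, traw$meta$correct, traw$time_axis,
        n_per_class = config$svm_n_per_class, reps = config$svm_reps,
        folds = config$svm_folds, C = config$svm_C, seed = config$seed))
      svm_tab[[bn]] <- list(band = bn, auc = ev$auc,
                            optimized_accuracy = ev$optimized_accuracy,
                            cv_accuracy = ev$cv_accuracy, folds = ev$folds)
    }
    jsonlite::write_json(svm_tab, file.path(config$out_dir, "classifier_eval.json"),
                         auto_unbox = TRUE, digits = NA)
    report$outputs$svm <- file.path(config$out_dir, "classifier_eval.json")

    if (!is.null(resp_epochs)) {
      series_list <- lapply(band_definitions(), function(b) band_average(tz, b))
      bac <- stage("behavior_correlation", bootstrap_accuracy_correlation(
        series_list, tz$meta$correct, tz$time_axis, resp_epochs,
        inner = config$corr_inner, outer = config$corr_outer,
        seed = config$seed))
      corr_tab <- data.frame(
        band_window = colnames(bac$r),
        mean_r = colMeans(bac$r),
        t = bac$t_vs_zero["t", ],
        p = bac$t_vs_zero["p", ],
        transition_s = bac$transition_s)
      report$outputs$correlation <- write_tsv(
        corr_tab, file.path(config$out_dir, "accuracy_correlation.tsv"))
    }
  }

  # --- pac -------------------------------------------------------------------
  if (enabled("pac")) {
    pac_bank <- pac_band_subset()
    pr <- stage("pac", mi_null_circular_shift(
      rec, odor_ev, window = config$pac_window, bank = pac_bank,
      n_bins = config$pac_bins, n_perm = config$pac_n_perm, q = config$q,
      seed = config$seed))
    pac_tab <- data.frame(band_hz = pr$amp_band_centers, mi_raw = pr$mi_raw,
                          mi_z = pr$mi_z, p_adj = pr$p_adj, sig = pr$fdr_mask)
    report$outputs$pac <- write_tsv(pac_tab, file.path(config$out_dir, "pac.tsv"))
  }

  # --- metadata --------------------------------------------------------------
  echo <- config
  echo$synth <- unclass(echo$synth)
  echo$synth$band_specs <- lapply(echo$synth$band_specs, unclass)
  jsonlite::write_json(echo[setdiff(names(echo), c("stages"))],
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  report$outputs$config <- file.path(config$out_dir, "run_config.json")
  report$parameters <- config
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  outputs:\n")
  for (nm in names(x$outputs)) {
    cat(sprintf("    %-12s %s\n", nm, paste(x$outputs[[nm]], collapse = ", ")))
  }
  cat(sprintf("  %d warning(s); total wall clock %.1f s\n",
              length(x$warnings), sum(unlist(x$timings))))
  invisible(x)
}
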