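# End-to-end orchestration: simulate -> preprocess -> detect -> clean ->
# features -> compare, with per-subject failure isolation (a blink-free
# subject is excluded and logged, never aborts the run) and deterministic
# outputs under fixed seeds.

#' Pipeline configuration
#'
#' Gathers every analysis parameter with the canonical defaults: 50 Hz
#' notch; 0.5-20 Hz band-pass; 0.5-16 Hz vEOG band; 3 s blink separation;
#' 3 s epochs (-1.5..1.5 s); 128 ms Hamming window with 100 ms overlap;
#' 0.5-4 Hz keep-band with the (-0.5, 0.1) s blink interval zeroed;
#' (-1500, -500) ms trial baseline; C1 window 0-190 ms, C2 window
#' 210-450 ms, 20 ms peak-amplitude window, (-1300, -1100) ms component
#' baseline; delta sub-bands 0.5-1.5 / 1.5-3.5 / 3.5-4.5 Hz with the
#' 0-1000 ms ICC window; 1000 permutations at alpha 0.05.
#'
#' @param n_subjects number of simulated paired subjects.
#' @param synth a [synth_config()] used as the per-subject template (each
#'   subject gets `seed = synth$seed + subject_index`).
#' @param subject_overrides optional named list (by subject index as
#'   character) of synth_config argument overrides, e.g.
#'   `list("3" = list(blink_rate_per_min = 0.34))`.
#' @param notch_hz,band_hz preprocessing filter settings.
#' @param veog_channel,veog_band,amp_threshold_frac,min_separation_s blink
#'   detection settings.
#' @param epoch_span epoch extent, s.
#' @param stft_window_ms,stft_overlap_ms STFT analysis settings (window length
#'   and inter-window overlap, ms).
#' @param mask_f_keep,mask_t_zero binary mask specification.
#' @param trial_baseline trial baseline-correction interval, s.
#' @param c1_window_ms,c2_window_ms,peak_halfwidth_ms,component_baseline_ms
#'   component measurement windows.
#' @param cwt_freqs CWT frequency grid, Hz.
#' @param bands delta sub-band edges, Hz.
#' @param band_window_s post-blink ICC window, s.
#' @param n_perm permutation count for all permutation tests.
#' @param alpha significance threshold.
#' @param seed master seed; all per-subject and per-test seeds derive
#'   from it.
#' @param do_tf_stats run the (comparatively expensive) CWT and
#'   time-frequency permutation stage.
#' @param tf_time_decim decimation factor of the epoch time axis for the
#'   time-frequency statistics maps (power itself is computed at full
#'   resolution).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 9,
                            synth = synth_config(),
                            subject_overrides = list(),
                            notch_hz = 50,
                            band_hz = c(0.5, 20),
                            veog_channel = "Fp1",
                            veog_band = c(0.5, 16),
                            amp_threshold_frac = 0.6,
                            min_separation_s = 3,
                            epoch_span = c(-1.5, 1.5),
                            stft_window_ms = 128,
                            stft_overlap_ms = 100,
                            mask_f_keep = c(0.5, 4.0),
                            mask_t_zero = c(-0.5, 0.1),
                            trial_baseline = c(-1.5, -0.5),
                            c1_window_ms = c(0, 190),
                            c2_window_ms = c(210, 450),
                            peak_halfwidth_ms = 10,
                            component_baseline_ms = c(-1300, -1100),
                            cwt_freqs = seq(0.5, 20, by = 0.5),
                            bands = list(
                              low_delta = c(0.5, 1.5),
                              mid_delta = c(1.5, 3.5),
                              high_delta = c(3.5, 4.5)
                            ),
                            band_window_s = c(0, 1.0),
                            n_perm = 1000,
                            alpha = 0.05,
                            seed = 1L,
                            do_tf_stats = TRUE,
                            tf_time_decim = 4L) {
  cfg <- as.list(environment())
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  win_ms <- c(c1_window_ms, c2_window_ms, component_baseline_ms,
              trial_baseline * 1000, band_window_s * 1000, mask_t_zero * 1000)
  if (any(win_ms < epoch_span[1] * 1000) || any(win_ms > epoch_span[2] * 1000)) {
    stop("all analysis windows must lie within the epoch span")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

merge_synth_overrides <- function(synth, overrides, seed) {
  args <- unclass(synth)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  args$seed <- seed
  do.call(synth_config, args)
}

#' Analyze one recording of one subject/system
#'
#' Preprocess (notch + band-pass), detect blinks, epoch, time-frequency
#' denoise, and measure OCI (raw and cleaned) plus the C1/C2 components per
#' channel. Returns NULL (a logged exclusion, mirroring a blink-free
#' participant) when no usable blink events survive detection.
#'
#' @param rec a raw `eeg_recording`.
#' @param cfg a [pipeline_config()].
#' @return List with `events`, `raw_average`, `cleaned` (denoise output),
#'   `oci` (per-channel data.frame), `components` (per-channel data.frame),
#'   `n_trials`, or NULL when the recording has no identifiable blinks.
#' @export
analyze_recording <- function(rec, cfg) {
  rec <- notch_filter(rec, cfg$notch_hz)
  rec <- bandpass_filter(rec, cfg$band_hz[1], cfg$band_hz[2], order = 4)
  events <- tryCatch(
    suppressWarnings(detect_blinks(
      rec,
      veog_channel = cfg$veog_channel,
      amp_threshold_frac = cfg$amp_threshold_frac,
      min_separation_s = cfg$min_separation_s
    )),
    error = function(e) NULL
  )
  if (is.null(events) || length(events$peak_samples) == 0L) return(NULL)
  epochs <- tryCatch(epoch_around_blinks(rec, events, cfg$epoch_span),
    error = function(e) NULL
  )
  if (is.null(epochs)) return(NULL)
  p <- stft_params(rec$fs, cfg$stft_window_ms, cfg$stft_overlap_ms)
  den <- denoise_epochs(epochs, p,
    f_keep = cfg$mask_f_keep, t_zero = cfg$mask_t_zero,
    baseline = cfg$trial_baseline
  )
  raw_avg <- apply(epochs$trials, c(2, 3), mean)
  tax <- epochs$time_axis
  channels <- rec$channel_labels
  oci <- do.call(rbind, lapply(seq_along(channels), function(j) {
    raw <- compute_oci(raw_avg[j, ], tax, stage = "raw")
    cln <- compute_oci(den$average$waveform[j, ], tax, stage = "cleaned")
    data.frame(
      channel = channels[j], oci_raw = raw$oci, oci_cleaned = cln$oci,
      pct_reduction = 100 * (1 - cln$oci / raw$oci),
      stringsAsFactors = FALSE
    )
  }))
  comps <- do.call(rbind, lapply(seq_along(channels), function(j) {
    cm <- measure_components(
      den$average$waveform[j, ], tax,
      c1_window = cfg$c1_window_ms, c2_window = cfg$c2_window_ms,
      peak_halfwidth_ms = cfg$peak_halfwidth_ms,
      baseline_window = cfg$component_baseline_ms
    )
    data.frame(
      channel = channels[j], c1_amp = cm$c1_amp, c1_lat = cm$c1_lat,
      c2_amp = cm$c2_amp, c2_lat = cm$c2_lat, baseline_amp = cm$baseline_amp,
      stringsAsFactors = FALSE
    )
  }))
  list(
    events = events, epochs = epochs, raw_average = raw_avg,
    cleaned = den, time_axis = tax, oci = oci, components = comps,
    n_trials = dim(epochs$trials)[1]
  )
}

# Trial-averaged, baseline-corrected CWT log power per channel.
subject_tf_power <- function(cleaned_trials, time_axis, fs, cfg) {
  K <- dim(cleaned_trials)[1]
  C <- dim(cleaned_trials)[2]
  out <- vector("list", C)
  for (ch in seq_len(C)) {
    acc <- NULL
    for (k in seq_len(K)) {
      P <- cwt_log_power(cleaned_trials[k, ch, ], fs,
        freqs = cfg$cwt_freqs, time_axis = time_axis
      )
      P <- tf_baseline_correct(P, cfg$trial_baseline)
      acc <- if (is.null(acc)) P$log_power else acc + P$log_power
    }
    out[[ch]] <- structure(
      list(log_power = acc / K, freqs = cfg$cwt_freqs, times = time_axis,
           baseline_interval = cfg$trial_baseline),
      class = "tf_power"
    )
  }
  out
}

#' Run the full dual-system pipeline on synthetic subjects
#'
#' Simulates `n_subjects` paired sessions, runs the complete per-recording
#' analysis for both systems, and computes every cross-system statistic:
#' OCI reduction with Wilcoxon raw-vs-cleaned tests, C1/C2 amplitude and
#' latency paired t and Pearson comparisons, component-vs-baseline tests,
#' time-domain and delta sub-band ICC with permutation nulls, and the
#' point-wise time-frequency permutation test. Subjects in which either
#' system yields no identifiable blinks are excluded and logged.
#'
#' @param cfg a [pipeline_config()].
#' @return A `report_bundle` list: `oci_table`, `component_table`,
#'   `oci_tests`, `component_tests`, `icc_table`, `tf_tests`, `run_log`,
#'   plus the per-subject averages used to build them.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # derived seeds stay well inside 32-bit integer range for any base seed
  seed0 <- as.integer(cfg$seed %% 1000000000)
  systems <- names(cfg$synth$system_noise_scale)
  subjects <- list()
  excluded <- integer(0)
  log_lines <- list()
  for (s in seq_len(cfg$n_subjects)) {
    ov <- cfg$subject_overrides[[as.character(s)]]
    scfg <- tryCatch(
      merge_synth_overrides(cfg$synth, ov %||% list(), seed0 + s),
      error = function(e) NULL
    )
    session <- if (is.null(scfg)) NULL else tryCatch(
      generate_paired_session(scfg), error = function(e) NULL
    )
    res <- NULL
    if (!is.null(session)) {
      res <- lapply(systems, function(sys) analyze_recording(session[[sys]], cfg))
      names(res) <- systems
    }
    if (is.null(session) || any(vapply(res, is.null, logical(1)))) {
      excluded <- c(excluded, s)
      log_lines[[length(log_lines) + 1L]] <- list(
        stage = "subject", subject = s, status = "excluded",
        reason = "no identifiable blink events (or unsatisfiable configuration)"
      )
      next
    }
    log_lines[[length(log_lines) + 1L]] <- list(
      stage = "subject", subject = s, status = "included",
      n_trials = vapply(res, function(r) r$n_trials, numeric(1))
    )
    subjects[[as.character(s)]] <- res
  }
  if (length(subjects) == 0L) stop("all subjects failed; nothing to analyze")
  included <- as.integer(names(subjects))
  channels <- cfg$synth$channels
  tax <- subjects[[1]][[1]]$time_axis

  long <- function(extract) {
    do.call(rbind, lapply(names(subjects), function(s) {
      do.call(rbind, lapply(systems, function(sys) {
        df <- extract(subjects[[s]][[sys]])
        cbind(subject = as.integer(s), system = sys, df,
              stringsAsFactors = FALSE)
      }))
    }))
  }
  oci_table <- long(function(r) r$oci)
  component_table <- long(function(r) r$components)

  # OCI raw vs cleaned per system/channel (Wilcoxon), plus reduction summary
  oci_tests <- do.call(rbind, lapply(systems, function(sys) {
    do.call(rbind, lapply(channels, function(ch) {
      sub <- oci_table[oci_table$system == sys & oci_table$channel == ch, ]
      wt <- tryCatch(wilcoxon_signed_rank(sub$oci_raw, sub$oci_cleaned),
        error = function(e) NULL
      )
      data.frame(
        system = sys, channel = ch, n = nrow(sub),
        mean_pct_reduction = mean(sub$pct_reduction),
        wilcoxon_V = if (is.null(wt)) NA_real_ else wt$statistic,
        p_value = if (is.null(wt)) NA_real_ else wt$p_value,
        stringsAsFactors = FALSE
      )
    }))
  }))

  # component comparisons between systems and against baseline
  measures <- c("c1_amp", "c1_lat", "c2_amp", "c2_lat")
  component_tests <- do.call(rbind, lapply(channels, function(ch) {
    do.call(rbind, lapply(measures, function(m) {
      va <- component_table[component_table$system == systems[1] &
        component_table$channel == ch, m]
      vb <- component_table[component_table$system == systems[2] &
        component_table$channel == ch, m]
      tt <- tryCatch(paired_ttest(va, vb), error = function(e) NULL)
      pc <- tryCatch(pearson_correlation(va, vb), error = function(e) NULL)
      data.frame(
        channel = ch, measure = m,
        t = if (is.null(tt)) NA_real_ else tt$statistic,
        t_p = if (is.null(tt)) NA_real_ else tt$p_value,
        r = if (is.null(pc)) NA_real_ else pc$r,
        r_p = if (is.null(pc)) NA_real_ else pc$p_value,
        stringsAsFactors = FALSE
      )
    }))
  }))
  baseline_tests <- do.call(rbind, lapply(systems, function(sys) {
    do.call(rbind, lapply(channels, function(ch) {
      sub <- component_table[component_table$system == sys &
        component_table$channel == ch, ]
      t1 <- tryCatch(paired_ttest(sub$c1_amp, sub$baseline_amp), error = function(e) NULL)
      t2 <- tryCatch(paired_ttest(sub$c2_amp, sub$baseline_amp), error = function(e) NULL)
      data.frame(
        system = sys, channel = ch,
        c1_vs_baseline_t = if (is.null(t1)) NA_real_ else t1$statistic,
        c1_vs_baseline_p = if (is.null(t1)) NA_real_ else t1$p_value,
        c2_vs_baseline_t = if (is.null(t2)) NA_real_ else t2$statistic,
        c2_vs_baseline_p = if (is.null(t2)) NA_real_ else t2$p_value,
        stringsAsFactors = FALSE
      )
    }))
  }))

  # time-domain ICC per channel with permutation null
  icc_rows <- list()
  for (j in seq_along(channels)) {
    pairs <- lapply(subjects, function(r) {
      list(
        a = r[[systems[1]]]$cleaned$average$waveform[j, ],
        b = r[[systems[2]]]$cleaned$average$waveform[j, ]
      )
    })
    icc <- icc_permutation_test(pairs,
      n_perm = cfg$n_perm,
      seed = seed0 + 100000L + j
    )
    icc_rows[[length(icc_rows) + 1L]] <- data.frame(
      domain = "time", channel = channels[j], mean_icc = icc$mean_icc,
      se_icc = stats::sd(icc$per_subject_iccs) / sqrt(length(icc$per_subject_iccs)),
      p_value = icc$p_value, stringsAsFactors = FALSE
    )
  }

  tf_tests <- NULL
  if (cfg$do_tf_stats) {
    tf_power <- lapply(subjects, function(r) {
      lapply(systems, function(sys) {
        subject_tf_power(
          r[[sys]]$cleaned$cleaned_trials, tax, cfg$synth$fs, cfg
        )
      }) |> stats::setNames(systems)
    })
    # delta sub-band ICC per channel
    for (j in seq_along(channels)) {
      series <- lapply(tf_power, function(tp) {
        lapply(systems, function(sys) {
          band_series(tp[[sys]][[j]], bands = cfg$bands, window = cfg$band_window_s)
        }) |> stats::setNames(systems)
      })
      for (b in names(cfg$bands)) {
        pairs <- lapply(series, function(ss) {
          list(a = ss[[systems[1]]][[b]], b = ss[[systems[2]]][[b]])
        })
        icc <- icc_permutation_test(pairs,
          n_perm = cfg$n_perm,
          seed = seed0 + 200000L + 10L * j + match(b, names(cfg$bands))
        )
        icc_rows[[length(icc_rows) + 1L]] <- data.frame(
          domain = b, channel = channels[j], mean_icc = icc$mean_icc,
          se_icc = stats::sd(icc$per_subject_iccs) / sqrt(length(icc$per_subject_iccs)),
          p_value = icc$p_value, stringsAsFactors = FALSE
        )
      }
    }
    # point-wise time-frequency permutation test per channel
    tidx <- seq(1, length(tax), by = cfg$tf_time_decim)
    tf_tests <- lapply(seq_along(channels), function(j) {
      arr <- function(sys) {
        m <- t(vapply(
          tf_power,
          function(tp) as.numeric(tp[[sys]][[j]]$log_power[, tidx]),
          numeric(length(cfg$cwt_freqs) * length(tidx))
        ))
        array(m, dim = c(length(subjects), length(cfg$cwt_freqs), length(tidx)))
      }
      res <- tf_permutation_test(arr(systems[1]), arr(systems[2]),
        n_perm = cfg$n_perm, seed = seed0 + 300000L + j,
        alpha = cfg$alpha
      )
      res$freqs <- cfg$cwt_freqs
      res$times <- tax[tidx]
      res$channel <- channels[j]
      res
    })
    names(tf_tests) <- channels
  }
  icc_table <- do.call(rbind, icc_rows)

  run_log <- list(
    package_version = as.character(utils::packageVersion("broeeg")),
    seed = cfg$seed, n_subjects_configured = cfg$n_subjects,
    included_subjects = included, excluded_subjects = excluded,
    n_permutations = cfg$n_perm, events = log_lines
  )
  structure(
    list(
      oci_table = oci_table, component_table = component_table,
      oci_tests = oci_tests, component_tests = component_tests,
      baseline_tests = baseline_tests, icc_table = icc_table,
      tf_tests = tf_tests, run_log = run_log,
      subjects = subjects, time_axis = tax, config = cfg
    ),
    class = "report_bundle"
  )
}

#' Render a report bundle to files
#'
#' Writes the per-subject and test tables as TSV, the ICC summary
#' additionally as a Markdown table (mean +/- SE, starred at
#' `p < alpha`), and the run log as JSON. Output is deterministic for a
#' fixed configuration and seed (no timestamps).
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
render_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wt(bundle$oci_table, "oci_per_subject.tsv")
  wt(bundle$component_table, "components_per_subject.tsv")
  wt(bundle$oci_tests, "oci_tests.tsv")
  wt(bundle$component_tests, "component_tests.tsv")
  wt(bundle$baseline_tests, "component_vs_baseline.tsv")
  wt(bundle$icc_table, "icc_table.tsv")

  alpha <- bundle$config$alpha
  channels <- bundle$config$synth$channels
  md <- file.path(dir, "icc_table.md")
  rows <- unique(bundle$icc_table$domain)
  lines <- c(
    paste0("| Domain | ", paste(channels, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(channels) + 1L), collapse = "|"), "|")
  )
  for (d in rows) {
    cells <- vapply(channels, function(ch) {
      r <- bundle$icc_table[bundle$icc_table$domain == d &
        bundle$icc_table$channel == ch, ]
      if (nrow(r) == 0L || !is.finite(r$mean_icc)) return("NA")
      sprintf(
        "%.2f ± %.2f%s", r$mean_icc, r$se_icc,
        if (is.finite(r$p_value) && r$p_value < alpha) " *" else ""
      )
    }, character(1))
    lines <- c(lines, paste0("| ", d, " | ", paste(cells, collapse = " | "), " |"))
  }
  writeLines(lines, md)
  paths <- c(paths, md)

  if (!is.null(bundle$tf_tests)) {
    sig <- do.call(rbind, lapply(bundle$tf_tests, function(r) {
      data.frame(
        channel = r$channel,
        frac_significant = mean(r$p_map < r$alpha),
        stringsAsFactors = FALSE
      )
    }))
    wt(sig, "tf_significance_summary.tsv")
  }
  lg <- file.path(dir, "run_log.json")
  jsonlite::write_json(bundle$run_log, lg, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, lg)
  invisible(paths)
}

#' Save / load a pipeline configuration
#'
#' JSON round trip: `load_pipeline_config(save_pipeline_config(cfg, p))`
#' reconstructs an equal object.
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON path.
#' @return `path` (save) or a `pipeline_config` (load).
#' @export
save_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$synth <- unclass(x$synth)
  # keep the names of named vectors (JSON arrays would drop them)
  x$synth$blink_amp_uv <- as.list(x$synth$blink_amp_uv)
  x$synth$system_noise_scale <- as.list(x$synth$system_noise_scale)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sy <- as.list(x$synth)
  sy$channels <- as.character(sy$channels)
  sy$blink_amp_uv <- unlist(sy$blink_amp_uv)
  sy$system_noise_scale <- unlist(sy$system_noise_scale)
  x$synth <- do.call(synth_config, sy)
  x$bands <- lapply(x$bands, as.numeric)
  x$subject_overrides <- lapply(x$subject_overrides, as.list)
  x$seed <- as.integer(x$seed)
  x$tf_time_decim <- as.integer(x$tf_time_decim)
  do.call(pipeline_config, x)
}
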