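# Pipeline configuration, orchestration and TSV outputs.

cohort_template <- function() {
  list(name = "group", n = 200L,
       d0_median = 11e-6, d0_sdlog = 0.06,
       t_cont_median = 0.20, t_cont_sdlog = 0.20,
       tau_median = 0.20, tau_sdlog = 0.35,
       u_flow_mean = 8e-3, u_flow_sd = 5e-4,
       event_rate = 0.5, deficit = 0.3)
}

#' Default pipeline configuration
#'
#' A nested list holding every tunable parameter of the pipeline, in SI units:
#' channel geometry, acquisition settings, preprocessing (moving-average
#' window, downsampling factor, baseline window), detection thresholds,
#' recovery-fit controls, statistics options, simulated cohorts (defaulting to
#' the stiff/viscous versus soft/fast preset contrast), and the master seed.
#' Configurations round-trip losslessly through YAML via [write_config()] /
#' [read_config()]; unknown keys are rejected on validation.
#'
#' @return A list of class `mnps_config`.
#' @export
default_config <- function() {
  presets <- apl_cohort_presets()
  as_cohort <- function(p, n) {
    co <- cohort_template()
    for (f in setdiff(names(co), c("n"))) co[[f]] <- p[[f]]
    co$n <- n
    co
  }
  structure(list(
    geometry = list(h_channel = 12.9e-6,
                    sizing_width = 13e-6, sizing_length = 800e-6,
                    contraction_width = 7e-6, contraction_length = 2000e-6,
                    node_width = 85e-6, node_length = 50e-6,
                    recovery_width = 13e-6, recovery_length = 290e-6,
                    n_recovery = 10L),
    acquisition = list(sample_rate = 50000, baseline_current = 10e-6,
                       noise_sigma = 6e-9, drift_slope = 0),
    preprocess = list(filter_window = 20L, downsample_factor = 20L,
                      baseline_window_s = 2.0),
    detection = list(k_threshold = 5, merge_gap_s = 0.025,
                     min_duration_s = 0.05, abs_threshold = 0),
    fit = list(min_points = 4L, tau_min_s = 0.005, tau_max_s = 2.0),
    stats = list(alpha = 0.05, adjustment = "auto"),
    simulate = list(contraction_amp = 3, overlap_fraction = 0,
                    t_first_s = 1.5, end_margin_s = 1.0),
    cohorts = list(as_cohort(presets$resistant, 200L),
                   as_cohort(presets$sensitive, 200L)),
    seed = 1L), class = "mnps_config")
}

check_keys <- function(x, template, path) {
  unknown <- setdiff(names(x), names(template))
  if (length(unknown))
    stop("unknown configuration key(s) under ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Validate a configuration against the schema and fill defaults
#'
#' @param config A (possibly partial) configuration list.
#' @return A complete validated `mnps_config`.
#' @export
validate_config <- function(config) {
  tmpl <- default_config()
  check_keys(config, tmpl, "top level")
  out <- unclass(tmpl)
  for (sec in names(config)) {
    if (sec == "cohorts") next
    if (is.list(tmpl[[sec]])) {
      check_keys(config[[sec]], tmpl[[sec]], sec)
      for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  if (!is.null(config$cohorts)) {
    ct <- cohort_template()
    out$cohorts <- lapply(seq_along(config$cohorts), function(i) {
      co <- config$cohorts[[i]]
      check_keys(co, ct, sprintf("cohorts[[%d]]", i))
      filled <- ct
      for (k in names(co)) filled[[k]] <- co[[k]]
      filled
    })
  }
  g <- out$geometry
  if (g$contraction_width >= g$sizing_width ||
      any(c(g$h_channel, g$sizing_width, g$sizing_length) <= 0))
    stop("invalid geometry configuration", call. = FALSE)
  if (out$stats$alpha <= 0 || out$stats$alpha >= 1)
    stop("stats$alpha must be in (0, 1)", call. = FALSE)
  structure(out, class = "mnps_config")
}

#' Build a [channel_geometry()] from a configuration
#' @param config An `mnps_config`.
#' @return A `channel_geometry`.
#' @export
config_geometry <- function(config) {
  g <- config$geometry
  channel_geometry(
    h_channel = g$h_channel,
    sizing = channel_segment(g$sizing_width, g$sizing_length),
    contraction = channel_segment(g$contraction_width, g$contraction_length),
    node = channel_segment(g$node_width, g$node_length),
    recovery = rep(list(channel_segment(g$recovery_width, g$recovery_length)),
                   as.integer(g$n_recovery)))
}

#' Build an [acquisition_config()] from a configuration
#' @param config An `mnps_config`.
#' @return An `mnps_acquisition` (carries the config's master seed).
#' @export
config_acquisition <- function(config) {
  a <- config$acquisition
  acquisition_config(a$sample_rate, a$baseline_current, a$noise_sigma,
                     a$drift_slope, seed = config$seed)
}

#' Cohort specifications from a configuration
#' @param config An `mnps_config`.
#' @return List of `list(params = group_params, n = count)` usable by
#'   [simulate_trace()].
#' @export
config_cohorts <- function(config) {
  lapply(config$cohorts, function(co) {
    list(params = group_params(co$name, co$d0_median, co$d0_sdlog,
                               co$t_cont_median, co$t_cont_sdlog,
                               co$tau_median, co$tau_sdlog,
                               co$u_flow_mean, co$u_flow_sd,
                               co$event_rate, co$deficit),
         n = as.integer(co$n))
  })
}

#' Write a configuration to YAML
#' @param config An `mnps_config` (validated first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Read and validate a YAML configuration
#' @param path A file written by [write_config()] (or hand-authored).
#' @return A validated `mnps_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Hash of the effective configuration
#'
#' MD5 of the canonical YAML serialization of the validated configuration;
#' every output table carries it so results can be traced to the exact
#' parameter set, and any parameter change changes the hash.
#'
#' @param config An `mnps_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  config <- validate_config(config)
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf, precision = 15L)
  unname(tools::md5sum(tf))
}

#' Run the analysis chain on one conditioned-or-raw trace
#'
#' Conditions the trace (moving average, downsample), estimates the baseline,
#' detects pulses, segments each into subpulses, applies QC, and phenotypes
#' every accepted event.
#'
#' @param trace A raw `mnps_trace`.
#' @param config An `mnps_config`.
#' @return List: `processed` (conditioned trace), `baseline`, `events`
#'   (detection table with `qc_code`/`qc_detail`), `subpulses` (all segmented
#'   plateaus), `features` (per-cell phenotypes of accepted events, SI units).
#' @export
analyze_trace <- function(trace, config = default_config()) {
  config <- validate_config(config)
  geom <- config_geometry(config)
  pp <- config$preprocess
  ds <- preprocess_trace(trace, pp$filter_window, pp$downsample_factor)
  bl_win <- round(pp$baseline_window_s * ds$sample_rate)
  bl <- estimate_baseline(ds, window = bl_win)
  det <- config$detection
  abs_thr <- if (det$abs_threshold > 0) det$abs_threshold else NULL
  ev <- detect_pulses(ds, bl, k = det$k_threshold,
                      merge_gap = det$merge_gap_s,
                      min_duration = det$min_duration_s,
                      abs_threshold = abs_thr)
  if (nrow(ev) > 0) {
    # second pass: re-estimate the baseline with detected events bridged,
    # removing their downward pull, then re-detect against it
    bl <- estimate_baseline(ds, window = bl_win, exclude = ev)
    ev <- detect_pulses(ds, bl, k = det$k_threshold,
                        merge_gap = det$merge_gap_s,
                        min_duration = det$min_duration_s,
                        abs_threshold = abs_thr)
  }
  subs <- list()
  feats <- list()
  qc_code <- character(nrow(ev))
  qc_detail <- character(nrow(ev))
  tau_band <- c(config$fit$tau_min_s, config$fit$tau_max_s)
  for (i in seq_len(nrow(ev))) {
    sp <- segment_subpulses(ev[i, ], ds, bl, geom, k = det$k_threshold,
                            abs_threshold = abs_thr)
    qc <- qc_event(ev[i, ], sp, geom, noise_scale = bl$noise_scale,
                   n_samples = length(ds$samples))
    qc_code[i] <- qc$code
    qc_detail[i] <- qc$detail
    subs[[i]] <- sp
    if (qc$code == "ok") {
      ph <- tryCatch(phenotype_event(sp, geom,
                                     min_points = config$fit$min_points,
                                     tau_band = tau_band),
                     error = function(e) e)
      if (inherits(ph, "error")) {
        qc_code[i] <- "low_snr"
        qc_detail[i] <- conditionMessage(ph)
      } else {
        feats[[length(feats) + 1L]] <- ph
      }
    }
  }
  ev$qc_code <- qc_code
  ev$qc_detail <- qc_detail
  features <- if (length(feats)) do.call(rbind, feats) else
    phenotype_event_skeleton()
  subpulses <- if (length(subs)) do.call(rbind, subs) else empty_subpulses()
  rownames(features) <- rownames(subpulses) <- NULL
  list(processed = ds, baseline = bl, events = ev, subpulses = subpulses,
       features = features)
}

phenotype_event_skeleton <- function() {
  data.frame(event_id = integer(), d0 = numeric(), u_flow = numeric(),
             t_cont = numeric(), strain = numeric(), wcdi = numeric(),
             tau = numeric(), tau_ci_low = numeric(), tau_ci_high = numeric(),
             i0_amp = numeric(), r_squared = numeric(),
             n_recovery_points = integer(), fit_valid = logical(),
             tau_in_band = logical())
}

features_human_units <- function(features) {
  data.frame(event_id = features$event_id,
             group = if ("group" %in% names(features)) features$group else NA,
             d0_um = features$d0 * 1e6,
             u_flow_mm_s = features$u_flow * 1e3,
             t_cont_ms = features$t_cont * 1e3,
             strain = features$strain,
             wcdi = features$wcdi,
             tau_ms = features$tau * 1e3,
             tau_ci_low_ms = features$tau_ci_low * 1e3,
             tau_ci_high_ms = features$tau_ci_high * 1e3,
             r2 = features$r_squared,
             n_recovery_points = features$n_recovery_points,
             valid = features$fit_valid,
             stringsAsFactors = FALSE)
}

cohort_comparisons <- function(features, config) {
  alpha <- config$stats$alpha
  adjustment <- config$stats$adjustment
  metrics <- list(wcdi = function(f) f$wcdi,
                  tau = function(f) f$tau[f$fit_valid])
  groups <- unique(features$group)
  if (length(groups) < 2L) return(NULL)
  rows <- list()
  for (m in names(metrics)) {
    vals <- lapply(groups, function(g) {
      f <- features[features$group == g, , drop = FALSE]
      v <- metrics[[m]](f)
      v[is.finite(v)]
    })
    names(vals) <- groups
    vals <- vals[vapply(vals, length, integer(1)) >= 2L]
    if (length(vals) < 2L) next
    if (length(vals) == 2L) {
      m_tests <- if (adjustment %in% c("bonferroni")) length(metrics) else 1L
      rows[[m]] <- compare_two(vals[[1]], vals[[2]], alpha = alpha,
                               m_tests = m_tests, metric = m,
                               group_a = names(vals)[1],
                               group_b = names(vals)[2])
    } else {
      rows[[m]] <- tukey_all_pairs(vals, metric = m, alpha = alpha)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline and write its output tables
#'
#' Accepts traces (named list of `mnps_trace` objects or named file paths,
#' names taken as group labels); with `traces = NULL` the cohorts in the
#' configuration are simulated first and events inherit their simulated
#' group via schedule matching. Writes `events.tsv`, `subpulses.tsv`,
#' `features.tsv`, `comparisons.tsv`, `power_report.tsv` and `run_log.txt`
#' into `out_dir`; every table opens with the configuration hash. Output is
#' deterministic (byte-identical) for a fixed configuration and seed.
#'
#' @param config An `mnps_config`.
#' @param traces `NULL`, or a named list of `mnps_trace` / named character
#'   vector of trace paths.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the assembled tables (`events`,
#'   `subpulses`, `features`, `comparisons`) and `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), traces = NULL,
                         out_dir = ".") {
  config <- validate_config(config)
  hash <- config_hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (is.null(traces)) {
    sim <- simulate_trace(config_cohorts(config),
                          acq = config_acquisition(config),
                          geometry = config_geometry(config),
                          contraction_amp = config$simulate$contraction_amp,
                          overlap_fraction = config$simulate$overlap_fraction,
                          t_first = config$simulate$t_first_s,
                          end_margin = config$simulate$end_margin_s)
    traces <- list(simulated = sim$trace)
    truth <- sim$truth
  }
  if (is.character(traces)) {
    paths <- traces
    traces <- lapply(paths, read_trace)
    names(traces) <- names(paths) %||% basename(paths)
  }

  all_ev <- list(); all_sub <- list(); all_feat <- list()
  counts <- list()
  for (nm in names(traces)) {
    res <- analyze_trace(traces[[nm]], config)
    ev <- res$events; sub <- res$subpulses; feat <- res$features
    if (nrow(ev)) ev$trace <- nm
    if (nrow(sub)) sub$trace <- nm
    if (nrow(feat)) {
      feat$trace <- nm
      feat$group <- nm
      if (!is.null(truth) && nrow(truth)) {
        # simulated input: recover each event's group from the ground truth
        # by entry-time containment (events are non-overlapping by design)
        for (j in seq_len(nrow(feat))) {
          eid <- feat$event_id[j]
          t1 <- ev$t_start[ev$event_id == eid]
          hit <- which.min(abs(truth$entry_time - t1))
          feat$group[j] <- truth$group[hit]
        }
      }
    }
    all_ev[[nm]] <- ev; all_sub[[nm]] <- sub; all_feat[[nm]] <- feat
    counts[[nm]] <- table(factor(ev$qc_code,
                                 levels = c("ok", "missing_subpulses",
                                            "coincidence", "truncated",
                                            "low_snr")))
  }
  events <- do.call(rbind, all_ev)
  subpulses <- do.call(rbind, all_sub)
  features <- do.call(rbind, all_feat)
  rownames(events) <- rownames(subpulses) <- rownames(features) <- NULL

  comparisons <- cohort_comparisons(features, config)

  ev_out <- data.frame(trace = events$trace, event_id = events$event_id,
                       start_s = events$t_start, end_s = events$t_end,
                       qc_code = events$qc_code, stringsAsFactors = FALSE)
  sub_out <- data.frame(trace = subpulses$trace,
                        event_id = subpulses$event_id, kind = subpulses$kind,
                        order = subpulses$order,
                        t_start_s = subpulses$t_start,
                        t_end_s = subpulses$t_end,
                        depth_a = subpulses$depth, level_a = subpulses$level,
                        stringsAsFactors = FALSE)
  write_tsv_with_hash(ev_out, file.path(out_dir, "events.tsv"), hash)
  write_tsv_with_hash(sub_out, file.path(out_dir, "subpulses.tsv"), hash)
  write_tsv_with_hash(features_human_units(features),
                      file.path(out_dir, "features.tsv"), hash)
  if (!is.null(comparisons)) {
    write_tsv_with_hash(comparisons, file.path(out_dir, "comparisons.tsv"),
                        hash)
    power_report <- data.frame(test_id = seq_len(nrow(comparisons)),
                               group_a = comparisons$group_a,
                               group_b = comparisons$group_b,
                               metric = comparisons$metric,
                               n_a = comparisons$n_a, n_b = comparisons$n_b,
                               effect_size = comparisons$effect_size,
                               power = comparisons$power,
                               min_effect_for_power80 =
                                 comparisons$min_effect_for_power80,
                               stringsAsFactors = FALSE)
    write_tsv_with_hash(power_report,
                        file.path(out_dir, "power_report.tsv"), hash)
  }
  log_lines <- c(sprintf("config_hash: %s", hash),
                 sprintf("seed: %s", format(config$seed)),
                 "event counts by QC code:",
                 unlist(lapply(names(counts), function(nm)
                   sprintf("  %s: %s", nm,
                           paste(sprintf("%s=%d", names(counts[[nm]]),
                                         as.integer(counts[[nm]])),
                                 collapse = " ")))),
                 "parameters:",
                 paste0("  ", strsplit(yaml::as.yaml(unclass(config),
                                                     precision = 15L),
                                       "\n")[[1]]))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(events = events, subpulses = subpulses, features = features,
                 comparisons = comparisons, truth = truth,
                 config_hash = hash))
}
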