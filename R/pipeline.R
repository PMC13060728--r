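# End-to-end orchestration: simulate a session to trial logs on disk,
# analyse a log directory into outcome/event/metric tables, and summarize.

#' Pipeline configuration
#'
#' Collects every tunable of the simulate/analyse chain with its default:
#' scene overrides, session design (experiment, reps, seed), locomotion
#' policy, gaze schedule and event parameters, per-phase pupil load, and
#' analysis parameters (velocity filter, I-VT threshold, HMM iterations,
#' grid and GTE window, snap radius). The resolved configuration is written
#' beside every run's outputs.
#'
#' @param ... Overrides of the defaults (unknown keys error).
#' @return List of class `sw_config`.
#' @export
sw_config <- function(...) {
  cfg <- list(
    experiment = 1, reps = 7, seed = 1, fs = 80,
    scene_overrides = list(),
    policy = default_policy(),
    schedule = default_gaze_schedule(),
    event_params = default_event_params(),
    pupil_load = default_pupil_load(),
    sg_window = 11, sg_order = 3,
    ivt_threshold = 100, min_fix_dur = 0.06,
    hmm_max_iter = 50, hmm_tol = 1e-5,
    grid_bins = c(6, 12, 3), gte_window = 80,
    snap_radius = 0.1, max_duration_s = 16)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "sw_config")
}

write_config <- function(cfg, path) {
  ser <- rapply(unclass(cfg), function(x) x, how = "replace")
  yaml::write_yaml(ser, path)
}

#' Simulate a full session to trial logs
#'
#' Builds the session design for the configured experiment, simulates each
#' trial with a per-trial seed derived from the session seed, and writes one
#' trial-log directory per trial plus a `manifest.json` and the resolved
#' configuration. Deterministic given the configuration.
#'
#' @param config An `sw_config`.
#' @param out_dir Output directory (created).
#' @return Invisibly, the manifest data.frame (trial, seed, log path).
#' @export
run_simulate <- function(config = sw_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  layout <- build_default_scene(config$scene_overrides)
  conds <- enumerate_conditions(config$experiment)
  des <- generate_session_design(conds, config$reps, config$seed)
  trials <- des$ordered_trials
  seeds <- derive_seeds(config$seed, nrow(trials))
  manifest <- data.frame(trial = trials$trial, seed = seeds,
                         path = sprintf("trial_%03d", trials$trial))
  for (i in seq_len(nrow(trials))) {
    tr <- simulate_trial(trials[i, ], layout = layout,
                         policy = config$policy,
                         schedule = config$schedule,
                         event_params = config$event_params,
                         pupil_load = config$pupil_load,
                         seed = seeds[i], fs = config$fs)
    write_trial_log(tr, file.path(out_dir, manifest$path[i]))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Analyse a single trial
#'
#' The full per-trial chain: vergence reconstruction and attribution,
#' angular kinematics, HMM event classification, phase segmentation,
#' outcome scoring, and the metric suite.
#'
#' @param trial An `sw_trial`.
#' @param config An `sw_config`.
#' @return List: `outcome` (one-row data.frame), `phases`, `events`,
#'   `metrics` (tidy trial x phase x metric), `attribution`.
#' @export
analyze_trial <- function(trial, config = sw_config()) {
  fr <- trial$frames
  fs <- trial$meta$fs %||% config$fs
  layout <- trial$layout
  head <- data.frame(t = fr$t, x = fr$head_x, z = fr$head_z)

  phases <- segment_phases(fr, layout)
  arrival <- detect_gate_arrival(head, layout, trial$condition)
  hooked <- if (max(head$z) >= layout$row2_z)
    detect_hooked(head, layout, trial$condition) else FALSE
  outcome <- data.frame(
    condition_gate = trial$condition$gate_side,
    condition_rows = trial$condition$row_directions,
    sitter_position = trial$condition$sitter_position,
    deadline_s = trial$condition$deadline_s,
    duration_s = if (is.na(arrival$t_arrival)) tail(fr$t, 1)
                 else arrival$t_arrival,
    reached = arrival$reached,
    success = assess_success(arrival$t_arrival, trial$condition$deadline_s,
                             reached = arrival$reached),
    path_class = if (hooked) "hooked" else "direct",
    stringsAsFactors = FALSE)

  att <- attribute_frames(trial, snap_radius = config$snap_radius)
  kin <- angular_kinematics(fr)
  vel <- sg_velocity(cbind(kin$az_deg, kin$el_deg), fs,
                     config$sg_window, config$sg_order)
  feats <- hmm_features(kin)
  hmm <- hmm_fit_decode(feats, max_iter = config$hmm_max_iter,
                        tol = config$hmm_tol, seed = trial$meta$seed %||% 1)
  segs <- segment_events(hmm$labels, fr, vel)
  pairs <- fixation_saccade_pairs(segs)
  kres <- k_coefficient(pairs, phases)

  grid <- grid_spec(config$grid_bins, layout = layout)
  states <- discretize_gaze(att[att$valid, ], grid)
  states_full <- rep(NA_integer_, nrow(att))
  states_full[att$valid] <- states
  gres <- gte(states_full, window = config$gte_window)
  gph <- gte_by_phase(gres, fr$t, phases, config$gte_window)

  kind <- target_kind_of(att$target_id, layout)
  phase_fr <- phase_of_frames(fr$t, fr$head_z, layout)
  attn <- label_attention(kind, phase_fr)
  seg4 <- data.frame(label = phases$label, t_start = phases$t_start,
                     t_end = phases$t_end)
  alloc <- gaze_allocation(fr$t, attn, seg4)

  gaps <- gap_crossing(head, trial$walker_tracks, layout)
  midline <- distance_from_midline(head, layout = layout)
  lph <- lhipa_by_phase(fr$pupil_mm, fr$t, phases, fs)
  estats <- event_stats_by_phase(segs, phases)

  m <- list()
  add <- function(phase, metric, value)
    data.frame(phase = phase, metric = metric, value = value,
               stringsAsFactors = FALSE)
  m[[length(m) + 1]] <- add(NA, "duration_s", outcome$duration_s)
  m[[length(m) + 1]] <- add(NA, "success", as.numeric(outcome$success))
  m[[length(m) + 1]] <- add(NA, "midline_distance_m", midline)
  for (r in 1:2)
    m[[length(m) + 1]] <- add(NA, sprintf("gap_fraction_row%d", r),
                              gaps$gap_fraction[gaps$row == r])
  m[[length(m) + 1]] <- add(gph$phase, "gte", gph$gte)
  if (!is.null(kres$mean_by_phase))
    m[[length(m) + 1]] <- add(kres$mean_by_phase$phase, "k",
                              kres$mean_by_phase$k)
  m[[length(m) + 1]] <- add(lph$phase, "lhipa", lph$lhipa)
  if (!is.null(alloc))
    for (lab in ATTENTION_LABELS)
      m[[length(m) + 1]] <- add(alloc$segment, paste0("alloc_", lab),
                                alloc[[lab]])
  metrics <- do.call(rbind, m)

  list(outcome = outcome, phases = phases, events = segs, metrics = metrics,
       attribution = att, event_stats = estats)
}

#' Analyse a directory of trial logs
#'
#' Reads every trial log under `log_dir`, runs [analyze_trial()] on each,
#' applies the two-stage exclusion filter, and writes `outcomes.csv`,
#' `events.csv`, `metrics.csv`, `exclusions.json` and an error ledger to
#' `out_dir`. A failing trial is recorded and skipped; the run continues.
#'
#' @param log_dir Directory produced by [run_simulate()] (or hand-built
#'   logs).
#' @param config An `sw_config`.
#' @param out_dir Output directory (defaults to `log_dir/analysis`).
#' @return Invisibly, a list with `outcomes`, `events`, `metrics`,
#'   `filter` (exclusion ledger), `errors`.
#' @export
run_analyze <- function(log_dir, config = sw_config(),
                        out_dir = file.path(log_dir, "analysis")) {
  dirs <- sort(list.dirs(log_dir, recursive = FALSE))
  dirs <- dirs[file.exists(file.path(dirs, "header.json"))]
  if (!length(dirs)) stopf("no readable trial logs under %s", log_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outcomes <- list(); events <- list(); metrics <- list(); errors <- list()
  for (d in dirs) {
    id <- basename(d)
    res <- tryCatch({
      tr <- read_trial_log(d)
      analyze_trial(tr, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      next
    }
    res$outcome$trial_id <- id
    res$events$trial_id <- id
    res$metrics$trial_id <- id
    outcomes[[id]] <- res$outcome
    events[[id]] <- res$events
    metrics[[id]] <- res$metrics
  }
  if (!length(outcomes)) stopf("no trial under %s could be analysed", log_dir)
  outcomes <- do.call(rbind, outcomes)
  events <- do.call(rbind, events)
  metrics <- do.call(rbind, metrics)
  filt <- filter_trials(outcomes, config$max_duration_s)
  # atomic-ish writes: write to temp names, then rename
  wr <- function(x, name) {
    tmp <- file.path(out_dir, paste0(".", name, ".tmp"))
    data.table::fwrite(x, tmp)
    file.rename(tmp, file.path(out_dir, name))
  }
  wr(outcomes, "outcomes.csv")
  wr(events, "events.csv")
  wr(metrics, "metrics.csv")
  jsonlite::write_json(list(ledger = filt$ledger, errors = errors),
                       file.path(out_dir, "exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(list(outcomes = outcomes, events = events, metrics = metrics,
                 filter = filt, errors = errors))
}

#' Summarize an analysed session
#'
#' Aggregates the analysis tables into per-condition success and duration,
#' per-phase attention allocation, GTE, K and LHIPA means, and gap-crossing
#' statistics, and writes `report.json`. Identical inputs give identical
#' summaries.
#'
#' @param analysis Result of [run_analyze()] (or its output directory).
#' @param out_dir Where to write `report.json` (optional).
#' @return List of summary data.frames.
#' @export
run_report <- function(analysis, out_dir = NULL) {
  if (is.character(analysis)) {
    rd <- function(f) as.data.frame(data.table::fread(file.path(analysis, f)))
    analysis <- list(outcomes = rd("outcomes.csv"),
                     metrics = rd("metrics.csv"))
    analysis$metrics$phase[analysis$metrics$phase == ""] <- NA
    analysis$filter <- filter_trials(analysis$outcomes)
  }
  oc <- analysis$filter$performance
  if (!nrow(oc)) {
    rep <- list(success_by_condition = "no data", phase_means = "no data")
  } else {
    key <- interaction(oc$condition_gate, oc$sitter_position, oc$deadline_s,
                       drop = TRUE)
    succ <- aggregate(cbind(success = oc$success,
                            duration_s = oc$duration_s),
                      by = list(condition = key), FUN = mean)
    mt <- analysis$metrics
    keep_ids <- analysis$filter$gaze$trial_id
    mt <- mt[is.na(mt$phase) | mt$trial_id %in% keep_ids, ]
    phm <- aggregate(value ~ phase + metric,
                     data = mt[!is.na(mt$phase) & !is.na(mt$value), ],
                     FUN = mean)
    glob <- aggregate(value ~ metric,
                      data = mt[is.na(mt$phase) & !is.na(mt$value), ],
                      FUN = mean)
    rep <- list(success_by_condition = succ, phase_means = phm,
                trial_means = glob,
                exclusions = analysis$filter$ledger)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}
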