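#' Simulate one trial observed by both systems
#'
#' Generates the ground-truth kinematics for a trial configuration and
#' passes it through both observation models.
#'
#' @param config A [trial_config()].
#' @param mocap_profile,sdk_profile [sensor_profile()]s for the two systems.
#' @return A list with `truth`, `mocap` and `sdk` trajectory sets.
#' @export
simulate_trial <- function(config,
                           mocap_profile = sensor_profile("mocap_like"),
                           sdk_profile = sensor_profile("sdk_like")) {
  truth <- simulate_truth(config)
  list(
    truth = truth,
    mocap = observe_mocap(truth, mocap_profile, config),
    sdk = observe_sdk(truth, sdk_profile, config)
  )
}

exercise_arm <- function(exercise) if (exercise == "SAL") "L" else "R"

#' Angle-level analysis of one observed trial pair
#'
#' The per-trial analysis chain: gap-fill the SDK trajectory (LOCF), compute
#' both systems' angle series for the exercising arm, resample both onto
#' the common comparison rate, and synchronize them by cross-correlation of
#' alpha.
#'
#' @param mocap_traj,sdk_traj Observed `trajectory_set`s of the same trial.
#' @param arm `"L"`/`"R"`; defaults to the trial's exercising arm.
#' @param common_fps Common comparison rate (default 30, the slower
#'   stream's rate).
#' @param max_lag Synchronization search window in seconds.
#' @return An `aligned_trial` (see [synchronize()]).
#' @export
analyze_trial <- function(mocap_traj, sdk_traj, arm = NULL,
                          common_fps = 30, max_lag = 2) {
  if (is.null(arm)) arm <- exercise_arm(sdk_traj$meta$exercise)
  jn <- arm_joint_names(arm)
  required <- c("chest", "left_shoulder", "right_shoulder", jn$elbow, jn$wrist)
  sdk_filled <- locf_fill(sdk_traj, required)
  mocap_series <- compute_angle_series(mocap_traj, arm)
  sdk_series <- compute_angle_series(sdk_filled, arm)
  ref <- resample_series(mocap_series, common_fps)
  test <- resample_series(sdk_series, common_fps)
  synchronize(ref, test, max_lag = max_lag)
}

#' Agreement metrics for all three angles of an aligned trial
#'
#' @param aligned An `aligned_trial`.
#' @param r2 R-squared variant (see [agreement_metrics()]).
#' @return A three-row tibble (alpha, beta, gamma).
#' @export
trial_metrics <- function(aligned, r2 = "correlation") {
  dplyr::bind_rows(lapply(c("alpha", "beta", "gamma"), function(a) {
    agreement_metrics(aligned_pair(aligned, a), r2 = r2)
  }))
}

#' Run the full synthetic validation study
#'
#' Simulates and analyzes the whole cohort grid (subject x exercise x
#' distance): ground truth, both observers, LOCF gap filling, angle
#' computation, resampling, synchronization and agreement metrics. Every
#' trial's RNG stream is derived deterministically from `seed` and the
#' trial's identity, so rerunning with the same arguments reproduces every
#' number.
#'
#' @param subjects Named list of [subject_model()]s (default: the packaged
#'   14-participant roster).
#' @param distances Camera distances in meters (default `c(2, 2.5, 3.5)`).
#' @param exercises `"SAL"`, `"SAR"` or both.
#' @param n_reps Repetitions per trial (default 5).
#' @param seed Global integer seed.
#' @param mocap_profile,sdk_profile Sensor profiles.
#' @param common_fps,max_lag Analysis options (see [analyze_trial()]).
#' @param r2 R-squared variant.
#' @param keep_pairs Keep the aligned per-frame alpha pairs (needed for
#'   calibration); default `TRUE`.
#' @return A `validation_study`: list with `metrics` (per-trial x angle
#'   tibble), `alpha_pairs` (named list of aligned alpha pair tibbles) and
#'   `lags` (per-trial recovered lags).
#' @export
run_validation_study <- function(subjects = cohort_subjects(),
                                 distances = c(2.0, 2.5, 3.5),
                                 exercises = c("SAL", "SAR"),
                                 n_reps = 5, seed = 1L,
                                 mocap_profile = sensor_profile("mocap_like"),
                                 sdk_profile = sensor_profile("sdk_like"),
                                 common_fps = 30, max_lag = 2,
                                 r2 = "correlation", keep_pairs = TRUE) {
  metrics <- list()
  pairs <- list()
  lags <- list()
  for (subject in subjects) {
    for (exercise in exercises) {
      script <- exercise_script(exercise, n_reps = n_reps)
      for (d in distances) {
        cfg <- trial_config(subject, script, d,
                            seed = derive_seed(seed, subject$subject_id,
                                               exercise, d))
        trial <- simulate_trial(cfg, mocap_profile, sdk_profile)
        aligned <- analyze_trial(trial$mocap, trial$sdk,
                                 common_fps = common_fps, max_lag = max_lag)
        key <- sprintf("%s_%s_%sm", subject$subject_id, exercise, format(d))
        metrics[[key]] <- trial_metrics(aligned, r2 = r2)
        lags[[key]] <- aligned$lag
        if (keep_pairs) pairs[[key]] <- aligned_pair(aligned, "alpha")
      }
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics), alpha_pairs = pairs,
         lags = unlist(lags), seed = seed),
    class = "validation_study"
  )
}

#' Calibration strata from a validation study
#'
#' Converts the aligned per-frame alpha pairs of a study into per-stratum
#' [calibration_dataset()]s (SDK alpha as predictor, mocap alpha as
#' response), one per subject x exercise x distance.
#'
#' @param study A `validation_study` run with `keep_pairs = TRUE`.
#' @param min_n Drop strata with fewer aligned samples than this (default
#'   10, the calibration minimum).
#' @return A named list of `calibration_dataset`s.
#' @export
calibration_strata <- function(study, min_n = 10) {
  stopifnot(inherits(study, "validation_study"), length(study$alpha_pairs) > 0)
  out <- list()
  for (key in names(study$alpha_pairs)) {
    p <- study$alpha_pairs[[key]]
    if (nrow(p) < min_n) next
    meta <- attr(p, "meta")
    meta$arm <- attr(p, "arm")
    out[[key]] <- calibration_dataset(p$test, p$reference, meta = meta)
  }
  out
}

# --- run configuration ------------------------------------------------------

RUN_CONFIG_KEYS <- list(
  top = c("seed", "subjects", "distances", "exercises", "n_reps",
          "sensors", "analysis", "calibration"),
  sensors = c("mocap_noise_sd", "sdk_noise_sd_at_2m", "noise_distance_exponent",
              "dropout_speed_threshold", "dropout_probability",
              "elbow_marker_offset_m"),
  analysis = c("common_fps", "max_lag_s", "r2"),
  calibration = c("families", "train_frac")
)

#' Default run configuration
#'
#' The packaged study conditions: the 14-participant roster, both
#' exercises, the 2 / 2.5 / 3.5 m distance grid, 5 repetitions, default
#' sensor profiles, 30 fps comparison rate and all ten calibration
#' families.
#'
#' @param seed Integer seed.
#' @return A named list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    subjects = demographics_roster()$subject,
    distances = c(2.0, 2.5, 3.5),
    exercises = c("SAL", "SAR"),
    n_reps = 5L,
    sensors = list(
      mocap_noise_sd = 0.001, sdk_noise_sd_at_2m = 0.008,
      noise_distance_exponent = 1.5,
      dropout_speed_threshold = 60, dropout_probability = 0.2,
      elbow_marker_offset_m = 0.03
    ),
    analysis = list(common_fps = 30, max_lag_s = 2, r2 = "correlation"),
    calibration = list(families = REGRESSOR_FAMILIES, train_frac = 0.8)
  )
}

#' Read and validate a run configuration
#'
#' Loads a YAML (or JSON) run configuration, rejects unknown keys, and
#' fills unset fields from [default_run_config()].
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (possibly partial).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0) {
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(cfg, RUN_CONFIG_KEYS$top, "top level")
  for (section in c("sensors", "analysis", "calibration")) {
    if (!is.null(cfg[[section]])) {
      check_keys(cfg[[section]], RUN_CONFIG_KEYS[[section]], section)
    }
  }
  base <- default_run_config(seed = cfg$seed %||% 1L)
  out <- utils::modifyList(base, cfg)
  stopifnot(all(out$exercises %in% c("SAL", "SAR")),
            all(out$distances > 0), out$n_reps >= 1)
  bad_subj <- setdiff(out$subjects, demographics_roster()$subject)
  if (length(bad_subj) > 0) {
    stop("config names unknown subjects: ", paste(bad_subj, collapse = ", "),
         call. = FALSE)
  }
  out
}

config_profiles <- function(cfg) {
  s <- cfg$sensors
  list(
    mocap = sensor_profile(
      "mocap_like", position_noise_sd_at_2m = s$mocap_noise_sd,
      marker_offsets = list(left_elbow = c(0, 0, s$elbow_marker_offset_m),
                            right_elbow = c(0, 0, s$elbow_marker_offset_m))
    ),
    sdk = sensor_profile(
      "sdk_like", position_noise_sd_at_2m = s$sdk_noise_sd_at_2m,
      noise_distance_exponent = s$noise_distance_exponent,
      dropout_speed_threshold = s$dropout_speed_threshold,
      dropout_probability = s$dropout_probability
    )
  )
}

# Polynomial rolling hash (31-bit) of the serialized config, for
# provenance logging.
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg)
  h <- 5381
  for (code in utf8ToInt(txt)) h <- (h * 33 + code) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline and write its result files
#'
#' Executes the staged pipeline on a run configuration: `simulate` writes
#' per-trial trajectory CSVs for both systems, `angles` re-reads them and
#' writes per-trial angle-series CSVs, `evaluate` writes per-trial metric
#' rows, the aggregated agreement table, difference-plot and histogram
#' data, and the statistical-test reports, `calibrate` writes the stratum x
#' family calibration grid, and `report` assembles a single summary JSON.
#' Every run writes the fully-resolved configuration, its hash and the seed
#' alongside the results, so every emitted table is re-derivable from the
#' stored files.
#'
#' @param config A configuration list (see [default_run_config()] /
#'   [read_run_config()]) or a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param stages Which stages to run (in order).
#' @return Invisibly, a list with the in-memory stage outputs.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = c("simulate", "angles", "evaluate",
                                    "calibrate", "report")) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("shoulderkin")),
         r_version = R.version.string),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE
  )
  profiles <- config_profiles(cfg)
  roster <- demographics_roster()
  subjects <- cohort_subjects(roster[roster$subject %in% cfg$subjects, ])
  state <- list(config = cfg)

  trial_grid <- expand.grid(
    subject = names(subjects), exercise = cfg$exercises,
    distance = cfg$distances, stringsAsFactors = FALSE
  )
  traj_dir <- file.path(out_dir, "trajectories")
  angle_dir <- file.path(out_dir, "angles")
  trial_key <- function(g) sprintf("%s_%s_%sm", g$subject, g$exercise,
                                   format(g$distance))

  if ("simulate" %in% stages) {
    dir.create(traj_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(trial_grid))) {
      g <- trial_grid[i, ]
      script <- exercise_script(g$exercise, n_reps = cfg$n_reps)
      tc <- trial_config(subjects[[g$subject]], script, g$distance,
                         seed = derive_seed(cfg$seed, g$subject, g$exercise,
                                            g$distance))
      trial <- simulate_trial(tc, profiles$mocap, profiles$sdk)
      for (sys in c("mocap", "sdk")) {
        write_trajectory(trial[[sys]],
                         file.path(traj_dir, paste0(trial_key(g), "_", sys, ".csv")))
      }
    }
  }

  if ("angles" %in% stages) {
    dir.create(angle_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(trial_grid))) {
      g <- trial_grid[i, ]
      arm <- exercise_arm(g$exercise)
      jn <- arm_joint_names(arm)
      required <- c("chest", "left_shoulder", "right_shoulder", jn$elbow, jn$wrist)
      for (sys in c("mocap", "sdk")) {
        traj <- read_trajectory(file.path(traj_dir,
                                          paste0(trial_key(g), "_", sys, ".csv")))
        if (sys == "sdk") traj <- locf_fill(traj, required)
        series <- compute_angle_series(traj, arm)
        write_angle_series(series,
                           file.path(angle_dir, paste0(trial_key(g), "_", sys, ".csv")))
      }
    }
  }

  if (any(c("evaluate", "calibrate") %in% stages)) {
    aligned_trials <- list()
    for (i in seq_len(nrow(trial_grid))) {
      g <- trial_grid[i, ]
      ref <- resample_series(
        read_angle_series(file.path(angle_dir, paste0(trial_key(g), "_mocap.csv"))),
        cfg$analysis$common_fps)
      test <- resample_series(
        read_angle_series(file.path(angle_dir, paste0(trial_key(g), "_sdk.csv"))),
        cfg$analysis$common_fps)
      aligned_trials[[trial_key(g)]] <- synchronize(ref, test,
                                                    max_lag = cfg$analysis$max_lag_s)
    }
    state$aligned <- aligned_trials
  }

  if ("evaluate" %in% stages) {
    metrics <- dplyr::bind_rows(lapply(state$aligned, trial_metrics,
                                       r2 = cfg$analysis$r2))
    readr::write_csv(metrics, file.path(out_dir, "trial_metrics.csv"))
    agg <- aggregate_report(metrics)
    readr::write_csv(agg, file.path(out_dir, "agreement_table.csv"))

    alpha_mae <- metrics[metrics$angle == "alpha", ]
    wide <- tidyr::pivot_wider(
      alpha_mae[, c("subject", "exercise", "distance", "mae")],
      names_from = "distance", values_from = "mae")
    tests <- list()
    mat <- as.matrix(wide[, as.character(sort(cfg$distances))])
    if (length(cfg$distances) >= 2 && nrow(mat) >= 3 && !anyNA(mat)) {
      tests$distance_effect <- distance_effect_test(mat)
    }
    if (all(c("SAL", "SAR") %in% cfg$exercises)) {
      al <- alpha_mae[alpha_mae$exercise == "SAL", ]
      ar <- alpha_mae[alpha_mae$exercise == "SAR", ]
      key <- function(d) paste(d$subject, d$distance)
      common <- intersect(key(al), key(ar))
      if (length(common) >= 3) {
        tests$arm_difference <- arm_difference_test(
          al$mae[match(common, key(al))], ar$mae[match(common, key(ar))])
      }
    }
    errs <- unlist(lapply(state$aligned, function(tr) {
      p <- aligned_pair(tr, "alpha")
      p$test - p$reference
    }), use.names = FALSE)
    tests$normality <- normality_tests(errs)
    jsonlite::write_json(
      rapply(tests, function(x) x, how = "list"),
      file.path(out_dir, "stat_tests.json"), auto_unbox = TRUE, force = TRUE,
      digits = NA
    )
    diff_data <- dplyr::bind_rows(lapply(names(state$aligned), function(k) {
      dp <- difference_plot_data(aligned_pair(state$aligned[[k]], "alpha"))
      dplyr::mutate(dp$points, trial = k, mean_line = dp$mean_line,
                    upper_line = dp$upper_line, lower_line = dp$lower_line)
    }))
    readr::write_csv(diff_data, file.path(out_dir, "difference_plot_alpha.csv"))
    hist_data <- dplyr::bind_rows(lapply(names(state$aligned), function(k) {
      p <- aligned_pair(state$aligned[[k]], "alpha")
      dplyr::mutate(histogram_data(p$test, bin_width = 5), trial = k)
    }))
    readr::write_csv(hist_data, file.path(out_dir, "histograms_alpha.csv"))
    state$metrics <- metrics
    state$aggregate <- agg
    state$tests <- tests
  }

  if ("calibrate" %in% stages) {
    strata <- list()
    for (k in names(state$aligned)) {
      p <- aligned_pair(state$aligned[[k]], "alpha")
      meta <- attr(p, "meta")
      meta$arm <- attr(p, "arm")
      if (nrow(p) >= 10) {
        strata[[k]] <- calibration_dataset(p$test, p$reference, meta)
      }
    }
    cmp <- run_model_comparison(strata, families = cfg$calibration$families,
                                train_frac = cfg$calibration$train_frac,
                                seed = cfg$seed)
    readr::write_csv(cmp$results, file.path(out_dir, "calibration_grid.csv"))
    readr::write_csv(cmp$by_family, file.path(out_dir, "calibration_by_family.csv"))
    readr::write_csv(cmp$by_subject, file.path(out_dir, "calibration_by_subject.csv"))
    state$calibration <- cmp
  }

  if ("report" %in% stages) {
    summary <- list(seed = cfg$seed, config_hash = config_hash(cfg))
    if (!is.null(state$aggregate)) summary$agreement <- state$aggregate
    if (!is.null(state$calibration)) summary$calibration <- state$calibration$by_family
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(state)
}
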