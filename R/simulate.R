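#' Joint names tracked by the simulator
#'
#' The upper-extremity landmark set shared by the reference (mocap-like) and
#' depth-camera (SDK-like) observation models.
#' @export
JOINT_NAMES <- c(
  "chest", "c7", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist"
)

#' Define an exercise script
#'
#' Describes one shoulder-abduction trial: which arm exercises, how many
#' repetitions, the peak abduction angle, and the timing. Each repetition
#' follows a raised-cosine velocity profile (smooth start and stop), rising
#' from 0 to `peak_abduction` degrees and back, separated by rests.
#'
#' @param exercise `"SAL"` (left arm) or `"SAR"` (right arm).
#' @param n_reps Number of repetitions (default 5).
#' @param peak_abduction Peak abduction angle in degrees (default 90; must be
#'   in (0, 180\]).
#' @param rep_duration Seconds per repetition; `NA` (default) means "use the
#'   subject's own speed" ([subject_model()]'s `rep_duration`).
#' @param rest_duration Seconds of rest before the first and after each
#'   repetition (default 1).
#' @param velocity_profile Only `"raised_cosine"` is implemented.
#' @return An `exercise_script` object.
#' @examples
#' exercise_script("SAL")
#' @export
exercise_script <- function(exercise = c("SAL", "SAR"), n_reps = 5,
                            peak_abduction = 90, rep_duration = NA_real_,
                            rest_duration = 1,
                            velocity_profile = "raised_cosine") {
  exercise <- match.arg(exercise)
  velocity_profile <- match.arg(velocity_profile)
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    stop("`n_reps` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(peak_abduction) || peak_abduction <= 0 || peak_abduction > 180) {
    stop("`peak_abduction` must be in (0, 180] degrees", call. = FALSE)
  }
  if (!is.na(rep_duration) && rep_duration <= 0) {
    stop("`rep_duration` must be positive", call. = FALSE)
  }
  if (rest_duration < 0) stop("`rest_duration` must be non-negative", call. = FALSE)
  structure(
    list(
      exercise = exercise, n_reps = as.integer(n_reps),
      peak_abduction = peak_abduction, rep_duration = rep_duration,
      rest_duration = rest_duration, velocity_profile = velocity_profile
    ),
    class = "exercise_script"
  )
}

script_rep_duration <- function(script, subject) {
  if (is.na(script$rep_duration)) subject$rep_duration else script$rep_duration
}

script_total_duration <- function(script, subject) {
  T <- script_rep_duration(script, subject)
  script$rest_duration + script$n_reps * (T + script$rest_duration)
}

#' Scripted abduction angle and angular speed
#'
#' Evaluates the ground-truth abduction profile of the exercising arm at
#' arbitrary times: rest segments at 0 degrees, each repetition a raised
#' cosine 0 -> peak -> 0 over `rep_duration` seconds.
#'
#' @param times Numeric vector of times in seconds (>= 0).
#' @param script An [exercise_script()].
#' @param subject A [subject_model()] (supplies the repetition duration when
#'   the script leaves it `NA`).
#' @return A tibble with columns `time`, `alpha` (degrees) and `speed`
#'   (degrees/second, signed).
#' @export
abduction_profile <- function(times, script, subject) {
  T <- script_rep_duration(script, subject)
  rest <- script$rest_duration
  cycle <- T + rest
  alpha <- numeric(length(times))
  speed <- numeric(length(times))
  tt <- times - rest # time since first rep began
  in_block <- tt >= 0 & tt < script$n_reps * cycle
  phase <- tt[in_block] %% cycle
  in_rep <- phase < T
  u <- phase[in_rep] / T
  a <- script$peak_abduction * (1 - cos(2 * pi * u)) / 2
  v <- script$peak_abduction * pi / T * sin(2 * pi * u)
  idx <- which(in_block)[in_rep]
  alpha[idx] <- a
  speed[idx] <- v
  tibble(time = times, alpha = alpha, speed = speed)
}

#' Define a sensor observation profile
#'
#' Describes how one measurement system observes the true skeleton: its
#' frame rate, positional noise model, rigid anatomical marker offsets
#' (mocap-like only) and velocity-dependent keypoint dropouts (SDK-like
#' only).
#'
#' The SDK-like per-joint noise sd grows with camera distance as
#' `position_noise_sd_at_2m * (distance / 2)^noise_distance_exponent`; the
#' mocap-like system surrounds the subject, so its noise sd is the constant
#' `position_noise_sd_at_2m`.
#'
#' @param system `"mocap_like"` or `"sdk_like"`.
#' @param fps Frame rate (default 256 for mocap-like, 30 for SDK-like).
#' @param position_noise_sd_at_2m Per-axis Gaussian noise sd in meters at the
#'   2 m reference distance (defaults 0.001 mocap-like, 0.008 SDK-like).
#' @param noise_distance_exponent Exponent of the distance scaling (default
#'   1.5; ignored for mocap-like).
#' @param marker_offsets Named list of length-3 numeric offsets in meters,
#'   one per joint. Elbow/wrist offsets are expressed in the local segment
#'   frame (lateral, along-segment distal, anterior->posterior) and rotate
#'   with the limb; other joints' offsets are world-frame. Must be empty for
#'   sdk_like. Default mocap-like offset: 0.03 m posterior on both elbows
#'   (the physical marker sits on the back of the elbow).
#' @param dropout_speed_threshold Arm angular speed in degrees/second above
#'   which the SDK may lose the elbow and wrist (default 60).
#' @param dropout_probability Per-frame probability of losing elbow+wrist of
#'   the exercising arm when above the speed threshold (default 0.2;
#'   mocap-like systems never drop markers, so 0).
#' @return A `sensor_profile` object.
#' @examples
#' sensor_profile("sdk_like")
#' sensor_profile("mocap_like", position_noise_sd_at_2m = 0)
#' @export
sensor_profile <- function(system = c("mocap_like", "sdk_like"),
                           fps = NULL,
                           position_noise_sd_at_2m = NULL,
                           noise_distance_exponent = 1.5,
                           marker_offsets = NULL,
                           dropout_speed_threshold = 60,
                           dropout_probability = NULL) {
  system <- match.arg(system)
  if (is.null(fps)) fps <- if (system == "mocap_like") 256 else 30
  if (is.null(position_noise_sd_at_2m)) {
    position_noise_sd_at_2m <- if (system == "mocap_like") 0.001 else 0.008
  }
  if (is.null(dropout_probability)) {
    dropout_probability <- if (system == "mocap_like") 0 else 0.2
  }
  if (is.null(marker_offsets)) {
    marker_offsets <- if (system == "mocap_like") {
      list(left_elbow = c(0, 0, 0.03), right_elbow = c(0, 0, 0.03))
    } else {
      list()
    }
  }
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (position_noise_sd_at_2m < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (dropout_probability < 0 || dropout_probability > 1) {
    stop("`dropout_probability` must be in [0, 1]", call. = FALSE)
  }
  if (system == "sdk_like" && length(marker_offsets) > 0) {
    stop("`marker_offsets` must be empty for sdk_like systems", call. = FALSE)
  }
  stopifnot(all(vapply(marker_offsets, length, 1L) == 3L))
  structure(
    list(
      system = system, fps = fps,
      position_noise_sd_at_2m = position_noise_sd_at_2m,
      noise_distance_exponent = noise_distance_exponent,
      marker_offsets = marker_offsets,
      dropout_speed_threshold = dropout_speed_threshold,
      dropout_probability = dropout_probability
    ),
    class = "sensor_profile"
  )
}

#' Define a trial configuration
#'
#' One trial = one subject performing one exercise script at one camera
#' distance, with a seed that fully determines every downstream random
#' stream.
#'
#' @param subject A [subject_model()].
#' @param script An [exercise_script()].
#' @param distance Camera-to-subject distance in meters (the study grid is
#'   2, 2.5 and 3.5 m, but any positive distance is accepted).
#' @param seed Integer seed.
#' @return A `trial_config` object.
#' @export
trial_config <- function(subject, script, distance, seed = 1L) {
  stopifnot(inherits(subject, "subject_model"), inherits(script, "exercise_script"))
  if (!is.numeric(distance) || distance <= 0) {
    stop("`distance` must be positive (meters)", call. = FALSE)
  }
  structure(
    list(subject = subject, script = script, distance = distance,
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

# --- trajectory container ---------------------------------------------------

#' Construct a trajectory set
#'
#' Container for one trial's observations from one system: per-joint
#' position matrices on a uniform time grid, with per-frame validity flags.
#' Most users obtain these from [simulate_truth()], the observers or
#' [read_trajectory()]; this constructor supports importing external data.
#'
#' @param time Numeric vector of frame times (seconds), uniformly spaced.
#' @param joints Named list of n x 3 position matrices (meters), one per
#'   joint.
#' @param valid Named list of logical vectors (default: all observations
#'   valid).
#' @param fps Frame rate; default inferred from `time`.
#' @param meta List of trial metadata (`subject_id`, `exercise`,
#'   `distance`, `system`).
#' @return A `trajectory_set` object.
#' @export
trajectory_set <- function(time, joints, valid = NULL, fps = NULL,
                           meta = list()) {
  stopifnot(is.list(joints), !is.null(names(joints)), length(time) >= 1)
  n <- length(time)
  for (j in names(joints)) {
    m <- joints[[j]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3) {
      stop("joint `", j, "` must be an n x 3 matrix matching `time`",
           call. = FALSE)
    }
  }
  if (n >= 2) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6) {
      stop("`time` must be strictly increasing and uniformly spaced",
           call. = FALSE)
    }
    if (is.null(fps)) fps <- 1 / dt[1]
  } else if (is.null(fps)) {
    stop("`fps` required for single-frame trajectories", call. = FALSE)
  }
  if (is.null(valid)) {
    valid <- lapply(joints, function(m) rep(TRUE, n))
  }
  stopifnot(identical(names(valid), names(joints)),
            all(vapply(valid, length, 1L) == n))
  new_trajectory_set(time, joints, valid, fps, meta)
}

new_trajectory_set <- function(time, joints, valid, fps, meta,
                               filled = NULL) {
  if (is.null(filled)) {
    filled <- lapply(valid, function(v) rep(FALSE, length(v)))
  }
  structure(
    list(time = time, joints = joints, valid = valid, filled = filled,
         fps = fps, meta = meta),
    class = "trajectory_set"
  )
}

#' @exportS3Method base::print
print.trajectory_set <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<trajectory_set> %s | %s | %.1f m | %s | %d frames @ %g fps (%.1f s)\n",
    m$subject_id %||% "?", m$exercise %||% "?", m$distance %||% NA,
    m$system %||% "?", length(x$time), x$fps, diff(range(x$time))
  ))
  inv <- sum(!unlist(x$valid))
  if (inv > 0) cat(sprintf("  %d invalid joint observations\n", inv))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames in a trajectory set
#' @param traj A `trajectory_set`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$time)

#' Extract one pose from a trajectory set
#'
#' @param traj A `trajectory_set`.
#' @param i Frame index.
#' @return A `pose`: list with `time`, `positions` (joints x 3 matrix),
#'   `valid` and `filled` (named logical vectors).
#' @export
get_pose <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  pos <- t(vapply(traj$joints, function(m) m[i, ], numeric(3)))
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(
      time = traj$time[i],
      positions = pos,
      valid = vapply(traj$valid, `[`, logical(1), i),
      filled = vapply(traj$filled, `[`, logical(1), i)
    ),
    class = "pose"
  )
}

#' Construct a single pose from named joint positions
#'
#' Convenience constructor for tests and geometric edge cases.
#'
#' @param positions Named list of length-3 numeric vectors (meters) or a
#'   named matrix with 3 columns.
#' @param valid Optional named logical; defaults to all `TRUE`.
#' @param time Time stamp in seconds.
#' @return A `pose` object.
#' @examples
#' p <- pose(list(chest = c(0, 1.2, 2), left_shoulder = c(0.2, 1.2, 2)))
#' @export
pose <- function(positions, valid = NULL, time = 0) {
  if (is.list(positions)) {
    positions <- do.call(rbind, positions)
  }
  stopifnot(is.matrix(positions), ncol(positions) == 3, !is.null(rownames(positions)))
  colnames(positions) <- c("x", "y", "z")
  if (is.null(valid)) {
    valid <- setNames(rep(TRUE, nrow(positions)), rownames(positions))
  }
  structure(
    list(time = time, positions = positions, valid = valid,
         filled = setNames(rep(FALSE, nrow(positions)), rownames(positions))),
    class = "pose"
  )
}

# --- ground truth -----------------------------------------------------------

#' Simulate noiseless ground-truth kinematics
#'
#' Forward-kinematic simulation of one shoulder-abduction trial. The subject
#' stands facing the camera at `(0, 0, distance)` in a camera-centered frame
#' (x lateral with the subject's left positive, y vertical up, z depth away
#' from the camera; the camera sits 1 m above the ground). The exercising
#' arm sweeps in the subject's frontal plane following the script's
#' raised-cosine profile with the elbow fully extended
#' (shoulder-elbow-wrist exactly collinear); the other arm hangs at 0
#' degrees. Output is exact (no noise, no offsets, all joints valid) at the
#' internal rate, 256 fps by default.
#'
#' @param config A [trial_config()].
#' @param internal_fps Internal sampling rate; must be >= 256.
#' @return A `trajectory_set` with `meta$system = "truth"`.
#' @examples
#' s <- subject_model("S1", 1.70)
#' tr <- simulate_truth(trial_config(s, exercise_script("SAL"), 2.0))
#' @export
simulate_truth <- function(config, internal_fps = 256) {
  stopifnot(inherits(config, "trial_config"))
  if (internal_fps < 256) stop("`internal_fps` must be >= 256", call. = FALSE)
  subject <- config$subject
  script <- config$script
  d <- config$distance
  total <- script_total_duration(script, subject)
  n <- floor(total * internal_fps) + 1L
  time <- (seq_len(n) - 1L) / internal_fps
  prof <- abduction_profile(time, script, subject)
  a_rad <- prof$alpha * pi / 180

  h <- subject$height
  r <- anthropometric_ratios
  y_sh <- subject$chest_height - 1 # chest marker and shoulders share height
  shw <- subject$shoulder_half_width
  ua <- subject$upper_arm_length
  fa <- subject$forearm_length

  const_joint <- function(p) matrix(rep(p, each = n), nrow = n)
  joints <- list(
    chest = const_joint(c(0, y_sh, d)),
    c7 = const_joint(c(0, y_sh, d + 0.10)),
    left_ear = const_joint(c(r[["ear_half_width"]] * h, r[["ear_height"]] * h - 1, d)),
    right_ear = const_joint(c(-r[["ear_half_width"]] * h, r[["ear_height"]] * h - 1, d)),
    left_shoulder = const_joint(c(shw, y_sh, d)),
    right_shoulder = const_joint(c(-shw, y_sh, d))
  )

  arm_joints <- function(side_sign, shoulder, alpha_rad) {
    # direction of the (extended) arm in the frontal plane
    dir <- cbind(side_sign * sin(alpha_rad), -cos(alpha_rad), 0)
    elbow <- shoulder + ua * dir
    wrist <- elbow + fa * dir
    list(elbow = elbow, wrist = wrist)
  }
  left_alpha <- if (script$exercise == "SAL") a_rad else rep(0, n)
  right_alpha <- if (script$exercise == "SAR") a_rad else rep(0, n)
  la <- arm_joints(+1, joints$left_shoulder, left_alpha)
  ra <- arm_joints(-1, joints$right_shoulder, right_alpha)
  joints$left_elbow <- la$elbow
  joints$left_wrist <- la$wrist
  joints$right_elbow <- ra$elbow
  joints$right_wrist <- ra$wrist
  joints <- joints[JOINT_NAMES]

  valid <- lapply(joints, function(m) rep(TRUE, n))
  new_trajectory_set(
    time = time, joints = joints, valid = valid, fps = internal_fps,
    meta = list(
      subject_id = subject$subject_id, exercise = script$exercise,
      distance = d, system = "truth", seed = config$seed
    )
  )
}

# Linear-interpolation resampling of raw trajectories onto a uniform grid at
# `fps` spanning the source time range (no extrapolation).
resample_trajectory <- function(traj, fps) {
  t0 <- traj$time[1]
  t1 <- traj$time[length(traj$time)]
  time <- seq(ceiling(t0 * fps), floor(t1 * fps)) / fps
  if (length(time) == length(traj$time) && max(abs(time - traj$time)) < 1e-9) {
    out <- traj # source already lies on the target grid
    out$valid <- lapply(out$valid, function(v) rep(TRUE, length(v)))
    out$fps <- fps
    return(out)
  }
  joints <- lapply(traj$joints, function(m) {
    cbind(
      approx(traj$time, m[, 1], xout = time, ties = "ordered")$y,
      approx(traj$time, m[, 2], xout = time, ties = "ordered")$y,
      approx(traj$time, m[, 3], xout = time, ties = "ordered")$y
    )
  })
  valid <- lapply(traj$valid, function(v) rep(TRUE, length(time)))
  new_trajectory_set(time, joints, valid, fps, traj$meta)
}

# World-frame offset vectors for a marker whose offset is expressed in the
# local segment frame (lateral, along-segment, anterior->posterior). The
# frame rotates with the segment; for a subject facing the camera, posterior
# is +z when the arm hangs.
segment_frame_offsets <- function(proximal, distal, offset_local) {
  seg <- distal - proximal
  len <- sqrt(rowSums(seg^2))
  e2 <- seg / len
  zhat <- c(0, 0, 1)
  # posterior axis: world z orthogonalized against the segment
  zdot <- e2[, 3]
  e3 <- cbind(-zdot * e2[, 1], -zdot * e2[, 2], 1 - zdot * e2[, 3])
  e3n <- sqrt(rowSums(e3^2))
  degen <- e3n < 1e-9
  e3 <- e3 / ifelse(degen, 1, e3n)
  if (any(degen)) {
    e3[degen, ] <- matrix(zhat, nrow = sum(degen), ncol = 3, byrow = TRUE)
  }
  # lateral axis completes the right-handed frame
  e1 <- cbind(
    e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
    e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
    e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  )
  offset_local[1] * e1 + offset_local[2] * e2 + offset_local[3] * e3
}

apply_marker_offsets <- function(joints, offsets) {
  seg_parent <- list(
    left_elbow = c("left_shoulder", "left_elbow"),
    right_elbow = c("right_shoulder", "right_elbow"),
    left_wrist = c("left_elbow", "left_wrist"),
    right_wrist = c("right_elbow", "right_wrist")
  )
  for (joint in names(offsets)) {
    if (!joint %in% names(joints)) {
      stop("marker offset names unknown joint: ", joint, call. = FALSE)
    }
    off <- offsets[[joint]]
    if (joint %in% names(seg_parent)) {
      pr <- seg_parent[[joint]]
      joints[[joint]] <- joints[[joint]] +
        segment_frame_offsets(joints[[pr[1]]], joints[[pr[2]]], off)
    } else {
      joints[[joint]] <- sweep(joints[[joint]], 2, off, `+`)
    }
  }
  joints
}

#' Observe a trial with the mocap-like reference system
#'
#' Resamples the ground truth to the profile's frame rate (256 fps by
#' default), displaces each marker by its rigid anatomical offset (elbow
#' markers sit on the back of the elbow; offsets are expressed in the local
#' segment frame so they rotate with the limb), and adds i.i.d. Gaussian
#' positional noise. Every frame is valid: optical mocap does not drop
#' markers in this model.
#'
#' @param truth Ground-truth `trajectory_set` from [simulate_truth()].
#' @param profile A [sensor_profile()] with `system = "mocap_like"`.
#' @param config The [trial_config()] that produced `truth`.
#' @return A `trajectory_set` with `meta$system = "mocap_like"`.
#' @export
observe_mocap <- function(truth, profile = sensor_profile("mocap_like"), config) {
  stopifnot(inherits(profile, "sensor_profile"))
  if (profile$system != "mocap_like") {
    stop("`profile$system` must be \"mocap_like\"", call. = FALSE)
  }
  obs <- resample_trajectory(truth, profile$fps)
  obs$joints <- apply_marker_offsets(obs$joints, profile$marker_offsets)
  sdn <- profile$position_noise_sd_at_2m
  n <- n_frames(obs)
  withr::with_seed(derive_seed(config$seed, "mocap", truth$meta$subject_id,
                               truth$meta$exercise, truth$meta$distance), {
    if (sdn > 0) {
      for (j in names(obs$joints)) {
        obs$joints[[j]] <- obs$joints[[j]] + matrix(rnorm(3 * n, sd = sdn), ncol = 3)
      }
    }
  })
  obs$meta$system <- "mocap_like"
  obs
}

#' Observe a trial with the SDK-like depth-camera system
#'
#' Resamples the ground truth to the depth camera's frame rate (30 fps by
#' default) and adds i.i.d. Gaussian noise whose per-axis sd grows with
#' camera distance as `position_noise_sd_at_2m * (distance/2)^exponent`.
#' Frames in which the exercising arm's angular speed exceeds
#' `dropout_speed_threshold` lose the elbow and wrist of that arm (both
#' marked invalid) with probability `dropout_probability`, emulating
#' motion-blur detection failures. Dropouts are seeded and reproducible.
#'
#' @inheritParams observe_mocap
#' @param profile A [sensor_profile()] with `system = "sdk_like"`.
#' @return A `trajectory_set` with `meta$system = "sdk_like"` and invalid
#'   flags on dropped joints.
#' @export
observe_sdk <- function(truth, profile = sensor_profile("sdk_like"), config) {
  stopifnot(inherits(profile, "sensor_profile"), inherits(config, "trial_config"))
  if (profile$system != "sdk_like") {
    stop("`profile$system` must be \"sdk_like\"", call. = FALSE)
  }
  obs <- resample_trajectory(truth, profile$fps)
  d <- truth$meta$distance
  sdn <- profile$position_noise_sd_at_2m * (d / 2.0)^profile$noise_distance_exponent
  n <- n_frames(obs)
  prof <- abduction_profile(obs$time, config$script, config$subject)
  fast <- abs(prof$speed) > profile$dropout_speed_threshold
  arm_prefix <- if (config$script$exercise == "SAL") "left" else "right"
  drop_joints <- paste0(arm_prefix, c("_elbow", "_wrist"))
  withr::with_seed(derive_seed(config$seed, "sdk", truth$meta$subject_id,
                               truth$meta$exercise, truth$meta$distance), {
    if (sdn > 0) {
      for (j in names(obs$joints)) {
        obs$joints[[j]] <- obs$joints[[j]] + matrix(rnorm(3 * n, sd = sdn), ncol = 3)
      }
    }
    dropped <- fast & (runif(n) < profile$dropout_probability)
  })
  for (j in drop_joints) obs$valid[[j]][dropped] <- FALSE
  obs$meta$system <- "sdk_like"
  obs
}
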