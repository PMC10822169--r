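# Shared fixtures: a small fast trial for unit tests (2 reps, 2 s each) and
# noise-free sensor profiles for geometry checks.

quick_subject <- function(id = "S1", height = 1.70, rep_duration = 2) {
  subject_model(id, height = height, rep_duration = rep_duration)
}

quick_script <- function(exercise = "SAL", n_reps = 2, rest = 0.5) {
  exercise_script(exercise, n_reps = n_reps, rest_duration = rest)
}

quick_config <- function(distance = 2.0, seed = 1L, exercise = "SAL",
                         subject = quick_subject()) {
  trial_config(subject, quick_script(exercise), distance, seed = seed)
}

clean_mocap_profile <- function(offset = 0) {
  sensor_profile("mocap_like", position_noise_sd_at_2m = 0,
                 marker_offsets = if (offset == 0) list() else
                   list(left_elbow = c(0, 0, offset),
                        right_elbow = c(0, 0, offset)))
}

clean_sdk_profile <- function(dropout_probability = 0, noise = 0, ...) {
  sensor_profile("sdk_like", position_noise_sd_at_2m = noise,
                 dropout_probability = dropout_probability, ...)
}

# A random (but anatomically non-degenerate) pose for property tests.
random_pose <- function() {
  chest <- c(runif(1, -0.2, 0.2), runif(1, 0.8, 1.6), runif(1, 1.5, 3.5))
  lsh <- chest + c(runif(1, 0.15, 0.35), runif(1, -0.1, 0.1), runif(1, -0.1, 0.1))
  rsh <- chest + c(runif(1, -0.35, -0.15), runif(1, -0.1, 0.1), runif(1, -0.1, 0.1))
  rand_dir <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  lel <- lsh + 0.30 * rand_dir()
  rel <- rsh + 0.30 * rand_dir()
  lwr <- lel + 0.25 * rand_dir()
  rwr <- rel + 0.25 * rand_dir()
  pose(list(
    chest = chest, c7 = chest + c(0, 0, 0.1),
    left_ear = chest + c(0.07, 0.3, 0), right_ear = chest + c(-0.07, 0.3, 0),
    left_shoulder = lsh, right_shoulder = rsh,
    left_elbow = lel, right_elbow = rel,
    left_wrist = lwr, right_wrist = rwr
  ))
}

# Independent scalar angle oracle (coded separately from the package path).
oracle_angle <- function(u, v) {
  cosv <- sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)))
  acos(min(1, max(-1, cosv))) * 180 / pi
}

oracle_alpha <- function(p, arm) {
  jn <- if (arm == "L") c("left_shoulder", "left_elbow") else
    c("right_shoulder", "right_elbow")
  sh <- p$positions[jn[1], ]
  ch <- p$positions["chest", ]
  vs <- c(sh[1], ch[2], ch[3])
  oracle_angle(p$positions[jn[2], ] - vs, c(0, -1, 0))
}

oracle_beta <- function(p, arm) {
  pre <- if (arm == "L") "left" else "right"
  sh <- p$positions[paste0(pre, "_shoulder"), ]
  el <- p$positions[paste0(pre, "_elbow"), ]
  wr <- p$positions[paste0(pre, "_wrist"), ]
  oracle_angle(sh - el, wr - el)
}

oracle_gamma <- function(p, arm) {
  pre <- if (arm == "L") "left" else "right"
  sh <- p$positions[paste0(pre, "_shoulder"), ]
  ch <- p$positions["chest", ]
  vs <- c(sh[1], ch[2], ch[3])
  el <- p$positions[paste0(pre, "_elbow"), ]
  s <- p$positions["right_shoulder", ] - p$positions["left_shoulder", ]
  nrm <- c(s[2] * 0 - s[3] * (-1), s[3] * 0 - s[1] * 0, s[1] * (-1) - s[2] * 0)
  oracle_angle(el - vs, nrm)
}

# Build a trajectory_set from a list of poses on a uniform grid.
poses_to_trajectory <- function(poses, fps = 30, meta = list(system = "test")) {
  n <- length(poses)
  joints <- lapply(rownames(poses[[1]]$positions), function(j) {
    t(vapply(poses, function(p) p$positions[j, ], numeric(3)))
  })
  names(joints) <- rownames(poses[[1]]$positions)
  trajectory_set(time = (seq_len(n) - 1) / fps, joints = joints, fps = fps,
                 meta = meta)
}
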