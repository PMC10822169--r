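#' Angle between two 3D vectors
#'
#' The primitive behind all three joint angles: the arccosine of the clamped
#' normalized dot product, in degrees. Symmetric in its arguments and
#' invariant to positive rescaling of either vector.
#'
#' @param u,v Numeric length-3 vectors, or matrices with 3 columns for
#'   row-wise evaluation.
#' @return Angle(s) in degrees, in \[0, 180\].
#' @examples
#' vector_angle(c(1, 0, 0), c(0, 1, 0)) # 90
#' vector_angle(c(5, 0, 0), c(1, 0, 0)) # 0
#' @export
vector_angle <- function(u, v) {
  if (is.matrix(u) || is.matrix(v)) {
    if (!is.matrix(u)) u <- matrix(u, nrow = nrow(v), ncol = 3, byrow = TRUE)
    if (!is.matrix(v)) v <- matrix(v, nrow = nrow(u), ncol = 3, byrow = TRUE)
    return(vangle_rows(u, v))
  }
  stopifnot(length(u) == 3, length(v) == 3)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate geometry: zero-length vector", call. = FALSE)
  }
  acos(clamp1(sum(u * v) / (nu * nv))) * 180 / pi
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

# Row-wise vector angle, degrees. Errors on zero-length rows.
vangle_rows <- function(U, V) {
  nu <- sqrt(rowSums(U^2))
  nv <- sqrt(rowSums(V^2))
  bad <- which(nu == 0 | nv == 0)
  if (length(bad) > 0) {
    stop("degenerate geometry: zero-length vector at frame ", bad[1], call. = FALSE)
  }
  acos(clamp1(rowSums(U * V) / (nu * nv))) * 180 / pi
}

arm_joint_names <- function(arm) {
  arm <- match.arg(arm, c("L", "R"))
  prefix <- if (arm == "L") "left" else "right"
  list(
    shoulder = paste0(prefix, "_shoulder"),
    elbow = paste0(prefix, "_elbow"),
    wrist = paste0(prefix, "_wrist")
  )
}

pose_point <- function(p, joint, require_valid = TRUE) {
  if (!joint %in% rownames(p$positions)) {
    stop("pose has no joint named `", joint, "`", call. = FALSE)
  }
  if (require_valid && !isTRUE(p$valid[[joint]])) {
    stop("joint `", joint, "` is not valid in this frame; apply locf_fill() first",
         call. = FALSE)
  }
  p$positions[joint, ]
}

#' Construct the virtual shoulder marker
#'
#' The two measurement systems place their shoulder landmarks differently,
#' so a constructed joint is used to make them commensurable: it keeps the
#' physical shoulder's lateral (x) coordinate but takes the chest marker's
#' height (y) and depth (z). Both systems then measure the same shoulder
#' angle.
#'
#' @param p A [pose()].
#' @param arm `"L"` or `"R"`.
#' @return A length-3 numeric point (x, y, z) in meters.
#' @examples
#' p <- pose(list(chest = c(0, 1.3, 2.05), left_shoulder = c(0.2, 1.4, 2.0)))
#' make_virtual_shoulder(p, "L") # c(0.2, 1.3, 2.05)
#' @export
make_virtual_shoulder <- function(p, arm = c("L", "R")) {
  arm <- match.arg(arm)
  jn <- arm_joint_names(arm)
  sh <- pose_point(p, jn$shoulder)
  ch <- pose_point(p, "chest")
  c(sh[[1]], ch[[2]], ch[[3]])
}

#' Shoulder abduction angle (alpha)
#'
#' Angle between the arm vector (virtual shoulder to elbow) and the
#' body-down direction: 0 degrees with the arm hanging, 90 degrees with the
#' arm horizontal. Body-down is the world vertical (0, -1, 0) — subjects
#' stand upright, and the marker set has no pelvis landmark from which to
#' estimate a trunk axis.
#'
#' @inheritParams make_virtual_shoulder
#' @param endpoint Arm-vector endpoint: `"elbow"` (default; with the elbow
#'   extended the choice is immaterial) or `"wrist"`.
#' @return Angle in degrees, \[0, 180\].
#' @export
shoulder_alpha <- function(p, arm = c("L", "R"), endpoint = c("elbow", "wrist")) {
  arm <- match.arg(arm)
  endpoint <- match.arg(endpoint)
  jn <- arm_joint_names(arm)
  vs <- make_virtual_shoulder(p, arm)
  tip <- pose_point(p, jn[[endpoint]])
  vector_angle(tip - vs, c(0, -1, 0))
}

#' Elbow extension angle (beta)
#'
#' Angle at the elbow between the upper arm (elbow to physical shoulder) and
#' the forearm (elbow to wrist): 180 degrees when the arm is fully extended.
#' Uses the physical shoulder, not the virtual one — the elbow angle is a
#' property of the true limb segments.
#'
#' @inheritParams make_virtual_shoulder
#' @return Angle in degrees, \[0, 180\].
#' @export
elbow_beta <- function(p, arm = c("L", "R")) {
  arm <- match.arg(arm)
  jn <- arm_joint_names(arm)
  sh <- pose_point(p, jn$shoulder)
  el <- pose_point(p, jn$elbow)
  wr <- pose_point(p, jn$wrist)
  vector_angle(sh - el, wr - el)
}

# Frontal-plane normal from a pair of shoulder rows (matrices). Unit cross
# product of (right shoulder - left shoulder) with world down; rows where
# the shoulders coincide fall back to the camera depth axis (0, 0, 1),
# appropriate for a camera-facing subject.
frontal_normal_rows <- function(lsh, rsh) {
  S <- rsh - lsh
  N <- cbind(S[, 3], 0, -S[, 1]) # cross(S, c(0,-1,0))
  nn <- sqrt(rowSums(N^2))
  degen <- nn < 1e-12
  if (any(degen)) {
    N[degen, 1] <- 0
    N[degen, 3] <- 1
  }
  N
}

#' Arm-body transverse angle (gamma)
#'
#' Angle between the arm vector (virtual shoulder to elbow) and the normal
#' to the participant's frontal plane: 90 degrees while the arm stays in the
#' frontal plane, approaching 0 as the arm points along the depth axis. The
#' normal is estimated per frame as the unit cross product of the
#' shoulder-to-shoulder vector with world down; if that is degenerate (or a
#' shoulder is missing) it falls back to the camera depth axis.
#'
#' @inheritParams make_virtual_shoulder
#' @return Angle in degrees, \[0, 180\].
#' @export
arm_gamma <- function(p, arm = c("L", "R")) {
  arm <- match.arg(arm)
  jn <- arm_joint_names(arm)
  vs <- make_virtual_shoulder(p, arm)
  el <- pose_point(p, jn$elbow)
  both_sh <- isTRUE(p$valid[["left_shoulder"]]) && isTRUE(p$valid[["right_shoulder"]])
  if (both_sh) {
    N <- frontal_normal_rows(
      matrix(p$positions["left_shoulder", ], 1),
      matrix(p$positions["right_shoulder", ], 1)
    )[1, ]
  } else {
    N <- c(0, 0, 1)
  }
  vector_angle(el - vs, N)
}

#' Fill missing joint observations by last observation carried forward
#'
#' When a tracker fails to detect a joint in a frame, the joint's position
#' from the last successful detection is reused until detection resumes.
#' Frames before a required joint's first valid detection have nothing to
#' carry forward and are dropped from the output. Per-joint `filled` flags
#' record which observations were substituted, so downstream angle samples
#' can be marked.
#'
#' @param traj A `trajectory_set`.
#' @param required_joints Character vector of joints that must be present in
#'   every output frame; defaults to all joints in `traj`.
#' @return A `trajectory_set` with all required joints valid in every frame
#'   and `filled` flags set where a position was carried forward.
#' @examples
#' # a joint that drops out mid-trial keeps its last seen position
#' @export
locf_fill <- function(traj, required_joints = names(traj$joints)) {
  stopifnot(inherits(traj, "trajectory_set"))
  missing_joints <- setdiff(required_joints, names(traj$joints))
  if (length(missing_joints) > 0) {
    stop("unknown required joints: ", paste(missing_joints, collapse = ", "),
         call. = FALSE)
  }
  never <- required_joints[!vapply(traj$valid[required_joints], any, logical(1))]
  if (length(never) > 0) {
    stop("unrecoverable trial: joint(s) never valid: ",
         paste(never, collapse = ", "), call. = FALSE)
  }
  start <- max(vapply(traj$valid[required_joints],
                      function(v) which(v)[1], numeric(1)))
  keep <- seq(start, n_frames(traj))
  time <- traj$time[keep]
  joints <- lapply(traj$joints, function(m) m[keep, , drop = FALSE])
  valid <- lapply(traj$valid, function(v) v[keep])
  filled <- lapply(traj$filled, function(f) f[keep])
  for (j in required_joints) {
    v <- valid[[j]]
    if (!all(v)) {
      src <- cummax(ifelse(v, seq_along(v), 0L)) # last valid index per frame
      joints[[j]] <- joints[[j]][src, , drop = FALSE]
      filled[[j]] <- filled[[j]] | !v
      valid[[j]] <- rep(TRUE, length(v))
    }
  }
  new_trajectory_set(time, joints, valid, traj$fps, traj$meta, filled = filled)
}

#' Compute the per-frame angle series for one arm
#'
#' Evaluates alpha (shoulder abduction, via the virtual shoulder), beta
#' (elbow extension) and gamma (arm-body transverse) for every frame of a
#' trajectory. The trajectory must already be gap-filled ([locf_fill()]);
#' a sample's `filled` flag is true when any contributing joint position was
#' carried forward in that frame.
#'
#' @param traj A `trajectory_set` with valid chest, both shoulders, and the
#'   arm's elbow and wrist in every frame.
#' @param arm `"L"` or `"R"`.
#' @param endpoint Arm-vector endpoint for alpha/gamma (`"elbow"` default).
#' @return An `angle_series`: list with `samples` (tibble of `time`,
#'   `alpha`, `beta`, `gamma`, `filled`), `arm`, `fps` and `meta`.
#' @examples
#' s <- subject_model("S1", 1.70)
#' tr <- simulate_truth(trial_config(s, exercise_script("SAL"), 2.0))
#' as <- compute_angle_series(tr, "L")
#' max(as$samples$alpha) # peak abduction
#' @export
compute_angle_series <- function(traj, arm = c("L", "R"),
                                 endpoint = c("elbow", "wrist")) {
  arm <- match.arg(arm)
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(traj, "trajectory_set"))
  jn <- arm_joint_names(arm)
  required <- c("chest", "left_shoulder", "right_shoulder", jn$elbow, jn$wrist)
  not_valid <- required[!vapply(traj$valid[required], all, logical(1))]
  if (length(not_valid) > 0) {
    frame <- which(!traj$valid[[not_valid[1]]])[1]
    stop("invalid `", not_valid[1], "` at frame ", frame,
         "; apply locf_fill() before computing angles", call. = FALSE)
  }
  chest <- traj$joints$chest
  sh <- traj$joints[[jn$shoulder]]
  el <- traj$joints[[jn$elbow]]
  wr <- traj$joints[[jn$wrist]]
  vsh <- cbind(sh[, 1], chest[, 2], chest[, 3])
  tip <- if (endpoint == "elbow") el else wr
  A <- tip - vsh
  alpha <- vangle_rows(A, matrix(c(0, -1, 0), nrow(A), 3, byrow = TRUE))
  beta <- vangle_rows(sh - el, wr - el)
  N <- frontal_normal_rows(traj$joints$left_shoulder, traj$joints$right_shoulder)
  gamma <- vangle_rows(el - vsh, N)
  filled <- Reduce(`|`, traj$filled[required])
  structure(
    list(
      samples = tibble(time = traj$time, alpha = alpha, beta = beta,
                       gamma = gamma, filled = filled),
      arm = arm, fps = traj$fps, meta = traj$meta
    ),
    class = "angle_series"
  )
}

#' @exportS3Method base::print
print.angle_series <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<angle_series> arm %s | %s | %s | %d samples @ %g fps | alpha [%.1f, %.1f] deg\n",
    x$arm, m$subject_id %||% "?", m$system %||% "?", nrow(x$samples), x$fps,
    min(x$samples$alpha), max(x$samples$alpha)
  ))
  invisible(x)
}
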