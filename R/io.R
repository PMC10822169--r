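TRAJECTORY_HEADER <- c("time_s", "joint", "x_m", "y_m", "z_m", "valid")

format_num <- function(x) sprintf("%.10g", x)

meta_header_lines <- function(meta, fps) {
  kv <- c(
    subject_id = meta$subject_id %||% "", exercise = meta$exercise %||% "",
    distance = format_num(meta$distance %||% NA_real_),
    system = meta$system %||% "", fps = format_num(fps),
    seed = format_num(meta$seed %||% NA_real_)
  )
  paste0("# ", names(kv), "=", kv)
}

parse_meta_header <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(as.list(vals), keys)
}

#' Write a trajectory set to a long-format CSV
#'
#' One joint observation per row (`time_s, joint, x_m, y_m, z_m, valid`),
#' preceded by a commented `# key=value` header block carrying the trial
#' metadata (subject, exercise, distance, system, fps, seed). Positions are
#' written with enough digits for a lossless (<= 1e-9 m) round trip.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- n_frames(traj)
  joints <- names(traj$joints)
  df <- data.frame(
    time_s = rep(traj$time, times = length(joints)),
    joint = rep(joints, each = n),
    x_m = unlist(lapply(traj$joints, function(m) m[, 1]), use.names = FALSE),
    y_m = unlist(lapply(traj$joints, function(m) m[, 2]), use.names = FALSE),
    z_m = unlist(lapply(traj$joints, function(m) m[, 3]), use.names = FALSE),
    valid = as.integer(unlist(traj$valid, use.names = FALSE))
  )
  df <- df[order(df$time_s, df$joint), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header_lines(traj$meta, traj$fps), con)
  writeLines(paste(TRAJECTORY_HEADER, collapse = ","), con)
  writeLines(sprintf("%.10g,%s,%.10g,%.10g,%.10g,%d",
                     df$time_s, df$joint, df$x_m, df$y_m, df$z_m, df$valid), con)
  invisible(path)
}

#' Read a trajectory set from a long-format CSV
#'
#' Inverse of [write_trajectory()]. Rows may appear in any order within a
#' timestamp; every timestamp must carry every joint exactly once, time must
#' be non-decreasing across frames, joint names must be known, and `valid`
#' must be 0/1 — violations are parse errors, not silent partial loads.
#'
#' @param path File path.
#' @return A `trajectory_set`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_raw <- parse_meta_header(path)
  for (key in c("system", "fps")) {
    if (is.null(meta_raw[[key]])) {
      stop("malformed header: missing `# ", key, "=` line in ", path, call. = FALSE)
    }
  }
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(df), TRAJECTORY_HEADER)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(TRAJECTORY_HEADER, collapse = ","), call. = FALSE)
  }
  if (anyNA(df$time_s) || anyNA(df$x_m) || anyNA(df$y_m) || anyNA(df$z_m)) {
    stop("parse error in ", path, ": non-numeric or truncated rows", call. = FALSE)
  }
  unknown <- setdiff(unique(df$joint), JOINT_NAMES)
  if (length(unknown) > 0) {
    first_line <- which(df$joint == unknown[1])[1]
    stop("unknown joint `", unknown[1], "` near data row ", first_line,
         " of ", path, call. = FALSE)
  }
  if (!all(df$valid %in% c(0L, 1L))) {
    stop("parse error in ", path, ": `valid` must be 0 or 1", call. = FALSE)
  }
  time <- sort(unique(df$time_s))
  if (is.unsorted(time)) stop("non-monotone time in ", path, call. = FALSE)
  joints_present <- unique(df$joint)
  tab <- table(df$time_s)
  if (any(tab != length(joints_present))) {
    stop("parse error in ", path,
         ": incomplete frame(s) — every timestamp needs every joint",
         call. = FALSE)
  }
  df <- df[order(df$time_s, df$joint), ]
  n <- length(time)
  joints <- list()
  valid <- list()
  for (j in sort(joints_present)) {
    sub <- df[df$joint == j, ]
    joints[[j]] <- cbind(sub$x_m, sub$y_m, sub$z_m)
    valid[[j]] <- sub$valid == 1L
  }
  ord <- intersect(JOINT_NAMES, names(joints))
  meta <- list(
    subject_id = meta_raw$subject_id %||% NA_character_,
    exercise = meta_raw$exercise %||% NA_character_,
    distance = as.numeric(meta_raw$distance %||% NA),
    system = meta_raw$system,
    seed = as.numeric(meta_raw$seed %||% NA)
  )
  new_trajectory_set(time, joints[ord], valid[ord],
                     fps = as.numeric(meta_raw$fps), meta = meta)
}

#' Write an angle series to CSV
#'
#' Columns `time_s, alpha_deg, beta_deg, gamma_deg, filled` with the same
#' commented metadata header as trajectory files plus the arm.
#'
#' @param series An `angle_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta_header_lines(series$meta, series$fps),
               paste0("# arm=", series$arm)), con)
  s <- series$samples
  writeLines("time_s,alpha_deg,beta_deg,gamma_deg,filled", con)
  writeLines(sprintf("%.10g,%.10g,%.10g,%.10g,%d",
                     s$time, s$alpha, s$beta, s$gamma, as.integer(s$filled)), con)
  invisible(path)
}

#' Read an angle series from CSV
#'
#' @param path File path written by [write_angle_series()].
#' @return An `angle_series`.
#' @export
read_angle_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta_raw <- parse_meta_header(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  expected <- c("time_s", "alpha_deg", "beta_deg", "gamma_deg", "filled")
  if (!identical(names(df), expected)) {
    stop("malformed angle file ", path, call. = FALSE)
  }
  structure(
    list(
      samples = tibble(time = df$time_s, alpha = df$alpha_deg,
                       beta = df$beta_deg, gamma = df$gamma_deg,
                       filled = df$filled == 1L),
      arm = meta_raw$arm %||% NA_character_,
      fps = as.numeric(meta_raw$fps),
      meta = list(
        subject_id = meta_raw$subject_id %||% NA_character_,
        exercise = meta_raw$exercise %||% NA_character_,
        distance = as.numeric(meta_raw$distance %||% NA),
        system = meta_raw$system %||% NA_character_,
        seed = as.numeric(meta_raw$seed %||% NA)
      )
    ),
    class = "angle_series"
  )
}
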