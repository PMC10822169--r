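#' Resample an angle series onto a uniform grid
#'
#' Linear interpolation of alpha/beta/gamma onto a uniform grid at
#' `target_fps` spanning the series' own time range (no extrapolation). The
#' `filled` flag is carried conservatively: a resampled point is flagged
#' when either bracketing source sample was gap-filled.
#'
#' @param series An `angle_series`.
#' @param target_fps Target frame rate (frames/second).
#' @return An `angle_series` at `target_fps`.
#' @export
resample_series <- function(series, target_fps) {
  stopifnot(inherits(series, "angle_series"), target_fps > 0)
  s <- series$samples
  if (nrow(s) < 2) {
    stop("cannot resample a series with fewer than 2 samples", call. = FALSE)
  }
  time <- seq(ceiling(s$time[1] * target_fps),
              floor(s$time[nrow(s)] * target_fps)) / target_fps
  interp <- function(y) approx(s$time, y, xout = time, ties = "ordered")$y
  filled <- interp(as.numeric(s$filled)) > 0
  structure(
    list(
      samples = tibble(
        time = time,
        alpha = interp(s$alpha), beta = interp(s$beta), gamma = interp(s$gamma),
        filled = filled
      ),
      arm = series$arm, fps = target_fps, meta = series$meta
    ),
    class = "angle_series"
  )
}

# Normalized cross-correlation of two equal-rate signals at integer shift k
# (test[i + k] against reference[i]); returns NA when either overlap segment
# is constant.
shift_correlation <- function(ref, test, k) {
  n <- length(ref)
  i <- seq(max(1, 1 - k), min(n, length(test) - k))
  if (length(i) < 2) return(NA_real_)
  r <- ref[i]
  t <- test[i + k]
  if (sd(r) == 0 || sd(t) == 0) return(NA_real_)
  cor(r, t)
}

#' Synchronize a test series against a reference series
#'
#' The two measurement systems are not hardware-synchronized, so a residual
#' time offset is estimated by maximizing the cross-correlation of the
#' mean-removed alpha signals over integer sample shifts within
#' `+/- max_lag` seconds. The same shift is then applied to beta and gamma
#' of the trial, and both series are trimmed to their overlap. Alignment
#' never changes sample values, only indexing. Ties (including the
#' degenerate constant-signal case) resolve toward the smallest absolute
#' lag, preferring zero.
#'
#' @param reference `angle_series` from the reference (mocap-like) system.
#' @param test `angle_series` from the system under test (SDK-like). Both
#'   series must share the same frame rate (see [resample_series()]).
#' @param max_lag Maximum lag magnitude searched, in seconds (default 2).
#' @param min_overlap_s Minimum admissible overlap after shifting, in
#'   seconds (default 1; roughly one repetition's rise time).
#' @return An `aligned_trial`: list with `pairs` (tibble of `angle`, `time`,
#'   `reference`, `test`, `filled`), the recovered `lag` in seconds (positive
#'   = test delayed relative to reference), `fps`, `arm` and `meta`.
#' @export
synchronize <- function(reference, test, max_lag = 2, min_overlap_s = 1) {
  stopifnot(inherits(reference, "angle_series"), inherits(test, "angle_series"))
  if (abs(reference$fps - test$fps) > 1e-9) {
    stop("series must share a frame rate; resample first", call. = FALSE)
  }
  fps <- reference$fps
  K <- floor(max_lag * fps)
  ref_a <- reference$samples$alpha
  test_a <- test$samples$alpha
  lags <- seq(-K, K)
  cc <- vapply(lags, function(k) shift_correlation(ref_a, test_a, k), numeric(1))
  if (all(is.na(cc))) {
    best <- 0L
  } else {
    top <- which(cc >= max(cc, na.rm = TRUE) - 1e-12)
    best <- lags[top][order(abs(lags[top]), lags[top])][1]
  }
  n <- length(ref_a)
  i <- seq(max(1, 1 - best), min(n, length(test_a) - best))
  if (length(i) < min_overlap_s * fps) {
    stop("overlap after synchronization is shorter than ", min_overlap_s,
         " s", call. = FALSE)
  }
  rs <- reference$samples[i, ]
  ts <- test$samples[i + best, ]
  pairs <- dplyr::bind_rows(lapply(c("alpha", "beta", "gamma"), function(a) {
    tibble(
      angle = a, time = rs$time,
      reference = rs[[a]], test = ts[[a]],
      filled = ts$filled
    )
  }))
  structure(
    list(pairs = pairs, lag = best / fps, fps = fps,
         arm = test$arm, meta = test$meta),
    class = "aligned_trial"
  )
}

#' Extract one angle's aligned pair from a synchronized trial
#'
#' @param trial An `aligned_trial` from [synchronize()].
#' @param angle `"alpha"`, `"beta"` or `"gamma"`.
#' @return A tibble (`time`, `reference`, `test`, `filled`) with attributes
#'   `angle`, `arm` and `meta`.
#' @export
aligned_pair <- function(trial, angle = c("alpha", "beta", "gamma")) {
  angle <- match.arg(angle)
  stopifnot(inherits(trial, "aligned_trial"))
  out <- trial$pairs[trial$pairs$angle == angle,
                     c("time", "reference", "test", "filled")]
  attr(out, "angle") <- angle
  attr(out, "arm") <- trial$arm
  attr(out, "meta") <- trial$meta
  out
}

#' @exportS3Method base::print
print.aligned_trial <- function(x, ...) {
  cat(sprintf(
    "<aligned_trial> arm %s | lag %.3f s | %d samples/angle @ %g fps\n",
    x$arm, x$lag, nrow(x$pairs) / 3, x$fps
  ))
  invisible(x)
}
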