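#' Anthropometric segment ratios
#'
#' Fixed fractions of standing height used to derive upper-limb segment
#' lengths and torso landmark heights when only height is known. Values are
#' conventional anthropometric-table ratios; the validation analyses are
#' insensitive to their exact values because both observation systems share
#' the same underlying skeleton.
#'
#' @format Named numeric vector with elements `upper_arm`, `forearm`,
#'   `shoulder_half_width`, `chest_height`, `ear_height`, `ear_half_width`.
#' @export
anthropometric_ratios <- c(
  upper_arm           = 0.186,
  forearm             = 0.146,
  shoulder_half_width = 0.129,
  chest_height        = 0.720,
  ear_height          = 0.930,
  ear_half_width      = 0.065
)

#' Construct a subject model
#'
#' Builds the anthropometric description of one participant. Segment lengths
#' (upper arm, forearm) and landmark heights (shoulder, chest, ear) are
#' derived deterministically from standing height via
#' [anthropometric_ratios], so two subjects with the same height share a
#' skeleton geometry.
#'
#' @param subject_id Character label, e.g. `"S1"`.
#' @param height Standing height in meters; must lie in \[1.3, 2.2\].
#' @param sex Optional `"Female"`/`"Male"` label (descriptive only).
#' @param age Optional age in years (descriptive only).
#' @param bmi Optional body-mass index in kg/m^2 (descriptive only).
#' @param rep_duration Duration in seconds of one abduction repetition for
#'   this subject (subjects differ in movement speed); default 4 s.
#'
#' @return An object of class `subject_model`: a list with the identifying
#'   fields plus derived `upper_arm_length`, `forearm_length`,
#'   `shoulder_half_width` and `chest_height` (all meters).
#' @examples
#' s <- subject_model("S1", height = 1.59, sex = "Female", age = 22, bmi = 23.73)
#' s$upper_arm_length
#' @export
subject_model <- function(subject_id, height, sex = NA_character_, age = NA_real_,
                          bmi = NA_real_, rep_duration = 4) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height < 1.3 || height > 2.2) {
    stop("`height` must be a single value in [1.3, 2.2] meters", call. = FALSE)
  }
  if (!is.numeric(rep_duration) || rep_duration <= 0) {
    stop("`rep_duration` must be a positive duration in seconds", call. = FALSE)
  }
  r <- anthropometric_ratios
  structure(
    list(
      subject_id = subject_id,
      sex = sex,
      age = age,
      height = height,
      bmi = bmi,
      upper_arm_length = r[["upper_arm"]] * height,
      forearm_length = r[["forearm"]] * height,
      shoulder_half_width = r[["shoulder_half_width"]] * height,
      chest_height = r[["chest_height"]] * height,
      rep_duration = rep_duration
    ),
    class = "subject_model"
  )
}

#' @exportS3Method base::print
print.subject_model <- function(x, ...) {
  cat(sprintf(
    "<subject_model> %s: height %.2f m, upper arm %.3f m, forearm %.3f m\n",
    x$subject_id, x$height, x$upper_arm_length, x$forearm_length
  ))
  invisible(x)
}

#' Packaged participant roster
#'
#' Loads the 14-participant demographic roster (subject id, sex, age, height,
#' BMI) that ships with the package, mirroring the study cohort used
#' throughout the examples and the synthetic validation runs.
#'
#' @return A tibble with columns `subject`, `sex`, `age`, `height_m`,
#'   `bmi`.
#' @examples
#' demographics_roster()
#' @export
demographics_roster <- function() {
  path <- system.file("extdata", "participant_demographics.csv",
                      package = "shoulderkin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    sex = readr::col_character(),
                    age = readr::col_double(),
                    height_m = readr::col_double(),
                    bmi = readr::col_double()
                  ))
}

#' Population standard deviation
#'
#' Divide-by-N standard deviation, the package-wide convention for reported
#' spreads (matching how cohort summary rows are printed in this field's
#' demographic tables). [stats::sd()] (divide-by-N-1) remains available where
#' a sample estimate is wanted.
#'
#' @param x Numeric vector.
#' @return The population sd of `x`.
#' @examples
#' sd_pop(c(4, 6))  # 1, where sd() gives sqrt(2)
#' @export
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

#' Summarize cohort demographics
#'
#' Computes the cohort "Average" row: mean and population sd of age, height
#' and BMI across the roster.
#'
#' @param roster A roster tibble as returned by [demographics_roster()].
#' @return A tibble with columns `variable`, `mean`, `sd` (population).
#' @examples
#' demographics_summary(demographics_roster())
#' @export
demographics_summary <- function(roster = demographics_roster()) {
  stopifnot(all(c("age", "height_m", "bmi") %in% names(roster)))
  tibble(
    variable = c("age", "height_m", "bmi"),
    mean = c(mean(roster$age), mean(roster$height_m), mean(roster$bmi)),
    sd = c(sd_pop(roster$age), sd_pop(roster$height_m), sd_pop(roster$bmi))
  )
}

#' Build subject models for a roster
#'
#' @param roster Roster tibble (see [demographics_roster()]).
#' @param rep_durations Optional numeric vector of per-subject repetition
#'   durations in seconds (recycled); default 4 s for everyone.
#' @return A named list of [subject_model()] objects.
#' @export
cohort_subjects <- function(roster = demographics_roster(), rep_durations = 4) {
  rep_durations <- rep_len(rep_durations, nrow(roster))
  out <- lapply(seq_len(nrow(roster)), function(i) {
    subject_model(
      subject_id = roster$subject[i],
      height = roster$height_m[i],
      sex = roster$sex[i],
      age = roster$age[i],
      bmi = roster$bmi[i],
      rep_duration = rep_durations[i]
    )
  })
  names(out) <- roster$subject
  out
}
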