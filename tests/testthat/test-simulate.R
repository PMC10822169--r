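test_that("abduction profile hits the scripted peak mid-repetition and rests at zero", {
  sub <- quick_subject()
  script <- quick_script(n_reps = 2, rest = 0.5)
  tr <- simulate_truth(trial_config(sub, script, 2.0))
  prof <- abduction_profile(tr$time, script, sub)
  expect_equal(max(prof$alpha), 90) # peak on-grid at mid-repetition
  # rests: before first rep and between reps
  expect_true(all(prof$alpha[tr$time < 0.5] == 0))
  between <- tr$time > 2.5 + 1e-9 & tr$time < 3.0 - 1e-9
  expect_true(all(prof$alpha[between] == 0))
})

test_that("noiseless truth stays in the frontal plane with an extended elbow", {
  tr <- simulate_truth(quick_config())
  for (j in c("left_shoulder", "left_elbow", "left_wrist")) {
    expect_equal(max(abs(tr$joints[[j]][, 3] - 2.0)), 0)
  }
  # collinearity: wrist - elbow is parallel to elbow - shoulder
  ua <- tr$joints$left_elbow - tr$joints$left_shoulder
  fa <- tr$joints$left_wrist - tr$joints$left_elbow
  cross_norm <- abs(ua[, 1] * fa[, 2] - ua[, 2] * fa[, 1])
  expect_lt(max(cross_norm), 1e-12)
  # contralateral arm hangs vertically
  expect_equal(max(abs(tr$joints$right_elbow[, 1] - tr$joints$right_shoulder[, 1])), 0)
})

test_that("simulation is deterministic under a fixed config seed", {
  t1 <- simulate_trial(quick_config(seed = 7))
  t2 <- simulate_trial(quick_config(seed = 7))
  expect_identical(t1$mocap$joints, t2$mocap$joints)
  expect_identical(t1$sdk$joints, t2$sdk$joints)
  expect_identical(t1$sdk$valid, t2$sdk$valid)
  t3 <- simulate_trial(quick_config(seed = 8))
  expect_false(identical(t1$sdk$joints$left_elbow, t3$sdk$joints$left_elbow))
})

test_that("invalid exercise scripts are rejected", {
  expect_error(exercise_script("SAL", peak_abduction = 190), "180")
  expect_error(exercise_script("SAL", rep_duration = 0), "positive")
  expect_error(exercise_script("SAL", n_reps = 0), "positive integer")
})

test_that("zero-offset zero-noise mocap observation equals resampled truth", {
  cfg <- quick_config()
  tr <- simulate_truth(cfg)
  obs <- observe_mocap(tr, clean_mocap_profile(), cfg)
  expect_equal(obs$joints, tr$joints, tolerance = 1e-12)
  expect_true(all(unlist(obs$valid)))
})

test_that("posterior elbow marker offset shifts beta by the offset-triangle angle", {
  # closed form: beta = 180 - atan(c/ua) - atan(c/fa); frozen for
  # h = 1.70 m, c = 0.03 m before implementation
  cfg <- quick_config()
  tr <- simulate_truth(cfg)
  obs <- observe_mocap(tr, clean_mocap_profile(offset = 0.03), cfg)
  beta <- compute_angle_series(obs, "L")$samples$beta
  expect_equal(max(abs(beta - 167.688268140392)), 0, tolerance = 1e-6)
})

test_that("empirical marker noise sd matches the profile within 10 percent", {
  sub <- quick_subject(rep_duration = 4)
  cfg <- trial_config(sub, exercise_script("SAL", n_reps = 5), 2.0, seed = 11)
  tr <- simulate_truth(cfg)
  prof <- sensor_profile("mocap_like", position_noise_sd_at_2m = 0.002,
                         marker_offsets = list())
  obs <- observe_mocap(tr, prof, cfg)
  # static torso joints isolate the additive noise; > 1e4 samples
  resid <- c(obs$joints$chest - tr$joints$chest,
             obs$joints$c7 - tr$joints$c7)
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.002) / 0.002, 0.10)
})

test_that("sdk noise grows with distance by the configured power law", {
  sub <- quick_subject(rep_duration = 4)
  sd_at <- function(d) {
    cfg <- trial_config(sub, exercise_script("SAL", n_reps = 5), d, seed = 3)
    tr <- simulate_truth(cfg)
    obs <- observe_sdk(tr, clean_sdk_profile(noise = 0.008), cfg)
    sd(c(obs$joints$chest - cbind(0, sub$chest_height - 1, d)[rep(1, n_frames(obs)), ],
         obs$joints$c7 - cbind(0, sub$chest_height - 1, d + 0.10)[rep(1, n_frames(obs)), ]))
  }
  ratio <- sd_at(3.5) / sd_at(2.0)
  expect_equal(ratio, (3.5 / 2.0)^1.5, tolerance = 0.1)
  # monotone in distance
  expect_lt(sd_at(2.0), sd_at(2.5))
  expect_lt(sd_at(2.5), sd_at(3.5))
})

test_that("dropouts are confined to fast frames and scale with probability", {
  cfg <- quick_config(seed = 5)
  tr <- simulate_truth(cfg)
  sub <- cfg$subject

  none <- observe_sdk(tr, clean_sdk_profile(dropout_probability = 0), cfg)
  expect_true(all(unlist(none$valid)))

  always <- observe_sdk(tr, sensor_profile(
    "sdk_like", position_noise_sd_at_2m = 0,
    dropout_speed_threshold = 10, dropout_probability = 1), cfg)
  speed <- abs(abduction_profile(always$time, cfg$script, sub)$speed)
  expect_identical(always$valid$left_elbow, !(speed > 10))
  expect_identical(always$valid$left_wrist, !(speed > 10))
  # the contralateral arm is never dropped
  expect_true(all(always$valid$right_elbow))

  n_invalid <- function(p, thr = 60) {
    obs <- observe_sdk(tr, sensor_profile(
      "sdk_like", position_noise_sd_at_2m = 0,
      dropout_speed_threshold = thr, dropout_probability = p), cfg)
    sum(!obs$valid$left_elbow)
  }
  expect_true(n_invalid(0.2) <= n_invalid(0.6))
  expect_true(n_invalid(0.6) <= n_invalid(1.0))
  # lower threshold exposes at least as many frames
  expect_true(n_invalid(1.0, thr = 80) <= n_invalid(1.0, thr = 40))
})

test_that("sensor profile guards its parameter space", {
  expect_error(sensor_profile("sdk_like", dropout_probability = 1.5), "0, 1")
  expect_error(sensor_profile("sdk_like",
                              marker_offsets = list(left_elbow = c(0, 0, 1))),
               "empty")
  expect_error(sensor_profile("mocap_like", position_noise_sd_at_2m = -1), ">= 0")
  expect_error(trial_config(quick_subject(), quick_script(), distance = 0),
               "positive")
})
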