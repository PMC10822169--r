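test_that("vector_angle matches anchors and the frozen high-precision oracle", {
  expect_equal(vector_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle(c(5, 0, 0), c(1, 0, 0)), 0)
  expect_equal(vector_angle(c(1, 0, 0), c(-2, 0, 0)), 180)
  # frozen from an independent arccos evaluation of (1,2,3) vs (-2,4,-1)
  expect_equal(vector_angle(c(1, 2, 3), c(-2, 4, -1)), 79.923462871446,
               tolerance = 1e-12)
  expect_error(vector_angle(c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("vector_angle is symmetric and scale-invariant", {
  withr::with_seed(42, {
    for (i in 1:200) {
      u <- rnorm(3)
      v <- rnorm(3)
      a <- vector_angle(u, v)
      expect_gte(a, 0)
      expect_lte(a, 180)
      expect_equal(a, vector_angle(v, u))
      expect_equal(a, vector_angle(3.7 * u, 0.01 * v))
    }
  })
})

test_that("virtual shoulder takes lateral coordinate from the shoulder, rest from chest", {
  p <- pose(list(chest = c(0.0, 1.3, 2.05), left_shoulder = c(0.2, 1.4, 2.0)))
  expect_equal(make_virtual_shoulder(p, "L"), c(0.2, 1.3, 2.05))
  # degenerate coincidence
  p2 <- pose(list(chest = c(0.1, 1.2, 2.0), left_shoulder = c(0.1, 1.2, 2.0)))
  expect_equal(make_virtual_shoulder(p2, "L"), c(0.1, 1.2, 2.0))
  # property: virtual point always lies in the chest's transverse-depth plane
  withr::with_seed(1, {
    for (i in 1:1000) {
      rp <- random_pose()
      vs <- make_virtual_shoulder(rp, "R")
      expect_identical(vs[2:3], unname(rp$positions["chest", 2:3]))
    }
  })
})

test_that("virtual shoulder signals unresolvable frames", {
  p <- pose(list(chest = c(0, 1.3, 2), left_shoulder = c(0.2, 1.4, 2)),
            valid = c(chest = FALSE, left_shoulder = TRUE))
  expect_error(make_virtual_shoulder(p, "L"), "locf_fill")
})

test_that("alpha anchors: hanging 0, horizontal 90, constructed 37", {
  base <- list(chest = c(0, 1.2, 2), left_shoulder = c(0.2, 1.2, 2),
               left_elbow = c(0.2, 0.9, 2))
  expect_equal(shoulder_alpha(pose(base), "L"), 0)
  base$left_elbow <- c(0.5, 1.2, 2)
  expect_equal(shoulder_alpha(pose(base), "L"), 90)
  # inverse construction: elbow at 37 degrees from vertical in frontal plane
  th <- 37 * pi / 180
  base$left_elbow <- c(0.2 + 0.3 * sin(th), 1.2 - 0.3 * cos(th), 2)
  expect_equal(shoulder_alpha(pose(base), "L"), 37, tolerance = 1e-12)
})

test_that("beta anchors: extended 180, right angle 90, composition oracle", {
  p <- pose(list(chest = c(0, 1.2, 2), left_shoulder = c(0.2, 1.2, 2),
                 left_elbow = c(0.5, 1.2, 2), left_wrist = c(0.8, 1.2, 2)))
  expect_equal(elbow_beta(p, "L"), 180)
  p2 <- pose(list(chest = c(0, 1.2, 2), left_shoulder = c(0.2, 1.2, 2),
                  left_elbow = c(0.5, 1.2, 2), left_wrist = c(0.5, 0.9, 2)))
  expect_equal(elbow_beta(p2, "L"), 90)
  withr::with_seed(2, {
    for (i in 1:100) {
      rp <- random_pose()
      sh <- rp$positions["right_shoulder", ]
      el <- rp$positions["right_elbow", ]
      wr <- rp$positions["right_wrist", ]
      expect_equal(elbow_beta(rp, "R"), vector_angle(sh - el, wr - el))
    }
  })
})

test_that("gamma anchors: in-plane 90, along-normal 0, 20-degree tilt 70", {
  base <- list(chest = c(0, 1.2, 2), left_shoulder = c(0.2, 1.2, 2),
               right_shoulder = c(-0.2, 1.2, 2), left_elbow = c(0.5, 1.2, 2))
  expect_equal(arm_gamma(pose(base), "L"), 90)
  base$left_elbow <- c(0.2, 1.2, 2.3) # straight along depth (the normal)
  expect_equal(arm_gamma(pose(base), "L"), 0)
  # 20 degrees out of plane toward the camera: gamma = 90 + 20 or 70 by side;
  # check complementarity against the in-plane construction
  th <- 20 * pi / 180
  base$left_elbow <- c(0.2 + 0.3 * cos(th) , 1.2, 2 - 0.3 * sin(th))
  g <- arm_gamma(pose(base), "L")
  expect_equal(min(g, 180 - g), 70, tolerance = 1e-12)
})

test_that("angle computations match the independent oracle on random poses", {
  withr::with_seed(99, {
    for (i in 1:500) {
      rp <- random_pose()
      for (arm in c("L", "R")) {
        expect_equal(shoulder_alpha(rp, arm), oracle_alpha(rp, arm),
                     tolerance = 1e-9)
        expect_equal(elbow_beta(rp, arm), oracle_beta(rp, arm),
                     tolerance = 1e-9)
        expect_equal(arm_gamma(rp, arm), oracle_gamma(rp, arm),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("series path agrees with per-pose path", {
  withr::with_seed(17, {
    poses <- replicate(50, random_pose(), simplify = FALSE)
    traj <- poses_to_trajectory(poses)
    as <- compute_angle_series(traj, "L")
    per_pose <- vapply(poses, shoulder_alpha, numeric(1), arm = "L")
    expect_equal(as$samples$alpha, per_pose, tolerance = 1e-12)
    expect_equal(as$samples$beta,
                 vapply(poses, elbow_beta, numeric(1), arm = "L"),
                 tolerance = 1e-12)
    expect_equal(as$samples$gamma,
                 vapply(poses, arm_gamma, numeric(1), arm = "L"),
                 tolerance = 1e-12)
  })
})

test_that("left and right computations are mirror-symmetric", {
  mirror_pose <- function(p) {
    pos <- p$positions
    pos[, 1] <- -pos[, 1]
    swap <- rownames(pos)
    swap <- ifelse(grepl("^left_", swap), sub("^left_", "right_", swap),
                   ifelse(grepl("^right_", swap), sub("^right_", "left_", swap),
                          swap))
    rownames(pos) <- swap
    pose(pos[rownames(p$positions), ])
  }
  withr::with_seed(23, {
    for (i in 1:100) {
      rp <- random_pose()
      mp <- mirror_pose(rp)
      expect_equal(shoulder_alpha(rp, "L"), shoulder_alpha(mp, "R"),
                   tolerance = 1e-12)
      expect_equal(elbow_beta(rp, "L"), elbow_beta(mp, "R"), tolerance = 1e-12)
      expect_equal(arm_gamma(rp, "L"), arm_gamma(mp, "R"), tolerance = 1e-12)
    }
  })
})

test_that("noiseless simulated trial yields the textbook angle traces", {
  tr <- simulate_truth(quick_config())
  as <- compute_angle_series(tr, "L")
  expect_equal(max(as$samples$alpha), 90)
  expect_equal(min(as$samples$alpha), 0)
  expect_lt(max(abs(as$samples$beta - 180)), 1e-5)
  expect_lt(max(abs(as$samples$gamma - 90)), 1e-6)
})

test_that("LOCF fills gaps from the last valid detection", {
  tr <- simulate_truth(quick_config())
  # no-op on fully valid input
  expect_identical(locf_fill(tr)$joints, tr$joints)
  # frames 10-14 invalid elbow carry the frame-9 position
  tr2 <- tr
  tr2$valid$left_elbow[10:14] <- FALSE
  f <- locf_fill(tr2)
  for (i in 10:14) {
    expect_equal(f$joints$left_elbow[i, ], tr$joints$left_elbow[9, ])
  }
  expect_true(all(f$filled$left_elbow[10:14]))
  expect_false(any(f$filled$left_elbow[-(10:14)]))
  # leading invalid frames are dropped
  tr3 <- tr
  tr3$valid$left_wrist[1:5] <- FALSE
  f3 <- locf_fill(tr3)
  expect_equal(n_frames(f3), n_frames(tr) - 5)
  expect_equal(f3$time[1], tr$time[6])
  # never-valid joint is unrecoverable
  tr4 <- tr
  tr4$valid$left_wrist[] <- FALSE
  expect_error(locf_fill(tr4), "unrecoverable")
  # idempotence
  expect_identical(locf_fill(f)$joints, f$joints)
  expect_identical(locf_fill(f)$filled, f$filled)
})

test_that("a LOCF-frozen elbow produces an alpha plateau", {
  tr <- simulate_truth(quick_config())
  span <- 300:400 # mid-repetition, arm moving
  tr$valid$left_elbow[span] <- FALSE
  tr$valid$left_wrist[span] <- FALSE
  f <- locf_fill(tr)
  as <- compute_angle_series(f, "L")
  frozen <- as$samples$alpha[span]
  expect_equal(max(frozen) - min(frozen), 0, tolerance = 1e-9)
  expect_true(all(as$samples$filled[span]))
})

test_that("angle computation refuses un-filled invalid frames", {
  tr <- simulate_truth(quick_config())
  tr$valid$left_elbow[100] <- FALSE
  expect_error(compute_angle_series(tr, "L"), "frame 100")
})
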