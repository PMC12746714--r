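test_that("demonstrations are internally consistent and seed-reproducible", {
  # noiseless, jitter-free repetitions are identical and their end-effector
  # channels equal forward kinematics of the joint channels
  reps <- make_pick_place_demos("A", 3, noise_sd = 0, seed = 1,
                                speed_jitter_sd = 0, phase_jitter_sd = 0)
  expect_identical(unclass(reps[[1]])[, ], unclass(reps[[2]])[, ])
  jm <- unclass(reps[[1]])[, 1:7]
  ee <- unclass(reps[[1]])[, 8:10]
  expect_equal(ee, forward_kinematics(jm), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identical seeds give bit-identical noisy output
  a <- make_pick_place_demos("B", 4, seed = 33)
  b <- make_pick_place_demos("B", 4, seed = 33)
  expect_identical(lapply(a, unclass), lapply(b, unclass))

  # channel-role bookkeeping
  info <- channel_info(reps[[1]])
  expect_equal(sum(info$role == "joint"), 7)
  expect_equal(nrow(info), 25)
  expect_false("cue" %in% info$role)
})

test_that("the two skills are far better separated than the noise floor", {
  a <- make_pick_place_demos("A", 5, seed = 1)
  b <- make_pick_place_demos("B", 5, seed = 2)
  mean_a <- Reduce(`+`, lapply(a, unclass)) / 5
  mean_b <- Reduce(`+`, lapply(b, unclass)) / 5
  sep <- mean((mean_a - mean_b)^2)
  noise <- mean(vapply(a, function(tr) mean((unclass(tr) - mean_a)^2),
                       numeric(1)))
  expect_gt(sep, 10 * noise)
})

test_that("joint locks hold the faulty joint and never touch earlier steps", {
  tr <- inject_joint_lock("A", 5, 3, 10, noise_sd = 0, seed = 2,
                          speed_jitter_sd = 0, phase_jitter_sd = 0)
  nom <- make_pick_place_demos("A", 1, noise_sd = 0, seed = 2,
                               speed_jitter_sd = 0, phase_jitter_sd = 0)[[1]]
  fault <- attr(tr, "fault")
  expect_equal(fault$fault_step, 6)
  expect_equal(unclass(tr)[1:6, ], unclass(nom)[1:6, ], ignore_attr = TRUE)
  # stuck at desired + overshoot for the rest of the trial
  expect_equal(unname(unclass(tr)[7:15, 5]),
               rep(unname(unclass(nom)[7, 5]) + 10, 9))
  # minor distal fault: no collision
  expect_false(fault$collided)

  # a severe proximal overshoot drives the arm into the floor and spikes
  # the force/torque channels at the crossing step
  sev <- inject_joint_lock("A", 2, 2, 40, noise_sd = 0, seed = 2,
                           speed_jitter_sd = 0, phase_jitter_sd = 0)
  expect_true(attr(sev, "fault")$collided)
  ft_cols <- which(attr(sev, "roles") == "ft")
  expect_gt(max(abs(unclass(sev)[, ft_cols])), 10)
})

test_that("faults that miss the object make the grasp fail", {
  tr <- inject_joint_lock("A", 1, 1, -15, noise_sd = 0, seed = 3,
                          speed_jitter_sd = 0, phase_jitter_sd = 0)
  expect_true(attr(tr, "fault")$grasp_failed)
  # no load is carried: gripper force and force/torque stay at zero
  expect_equal(max(abs(unclass(tr)[7:13, 12:25])), 0)
  expect_equal(unname(unclass(tr)[7:13, 11]), rep(1, 7))  # aperture open
})

test_that("collision impulses decay geometrically and keep kinematics", {
  base <- make_pick_place_demos("A", 1, noise_sd = 0, seed = 4,
                                speed_jitter_sd = 0, phase_jitter_sd = 0)[[1]]
  same <- inject_collision(base, 3, rep(0, 7))
  expect_equal(unclass(same)[, ], unclass(base)[, ], tolerance = 1e-12)

  hit <- inject_collision(base, 3, c(0, 0, 5, 0, 0, 0, 0), decay = 0.5)
  dev <- abs(unclass(hit)[, 3] - unclass(base)[, 3])
  expect_equal(which.max(dev), 7)  # impulse lands at step 6 (0-based)
  expect_true(all(diff(dev[7:15]) < 0))
  expect_equal(unclass(hit)[, 8:10],
               forward_kinematics(unclass(hit)[, 1:7]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("follow-through plans mirror across the start-target line", {
  ds <- make_followthrough_dataset("planning_only", n_trials = 2, seed = 5)
  cw <- ds$plans$cw$path
  ccw <- ds$plans$ccw$path
  expect_equal(cw[, 1], -ccw[, 1], tolerance = 1e-9)
  expect_equal(cw[, 2], ccw[, 2], tolerance = 1e-9)
  # the noiseless lateral bow peaks at the configured amplitude
  expect_equal(max(abs(cw[, 1])), ds$amplitude, tolerance = 1e-3)
  # joint channels invert through planar forward kinematics
  expect_equal(two_link_fk(ds$plans$cw$joints), cw, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("cue channels are one-hot from onset and silent before", {
  pe <- make_followthrough_dataset("planning_and_execution", n_trials = 1,
                                   seed = 6)
  expect_equal(pe$cue_onset, 0)
  cue <- pe$plans$cw$cue
  expect_true(all(cue[, 1] == 1) && all(cue[, 2] == 0))

  eo <- make_followthrough_dataset("execution_only", n_trials = 1, seed = 6)
  expect_equal(eo$cue_onset, 8)
  cue_eo <- eo$plans$ccw$cue
  expect_equal(unname(cue_eo[1, ]), c(0, 0))
  expect_true(all(cue_eo[1:8, ] == 0))
  expect_true(all(cue_eo[9:15, 2] == 1))
  # noisy trials keep exact one-hot cue channels
  tr <- eo$trials[[1]]
  expect_true(all(unclass(tr)[, 5:6] %in% c(0, 1)))
})

test_that("Z-score normalisation round-trips and standardises", {
  trials <- make_pick_place_demos("A", 4, seed = 7)
  norm <- zscore_normalise(trials)
  pooled <- do.call(rbind, lapply(norm$trials, unclass))
  expect_equal(max(abs(colMeans(pooled))), 0, tolerance = 1e-9)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 25), tolerance = 1e-9)
  back <- zscore_denormalise(norm$trials[[1]], norm$scaling)
  expect_equal(unclass(back)[, ], unclass(trials[[1]])[, ], tolerance = 1e-9)

  # constant channels map to zero under the sd floor
  const <- lapply(1:3, function(i) {
    sm_sequence(matrix(c(1, 1, 1, rnorm(3)), 3, 2,
                       dimnames = list(NULL, c("a", "b"))),
                roles = c("joint", "joint"))
  })
  cn <- zscore_normalise(const)
  expect_equal(unname(unclass(cn$trials[[1]])[, 1]), rep(0, 3))
})
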