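#' Kinematic arm specification
#'
#' A serial-chain kinematic proxy for a 7-joint manipulator. Each joint
#' rotates about a fixed local axis and each link extends along the local z
#' axis. The plant is purely kinematic: demonstrations are scripted joint
#' waypoints, and the end-effector channels are computed by forward
#' kinematics, mirroring a learning-from-demonstration pipeline in which
#' end-effector goals are converted to joint angles and recorded.
#'
#' @param n_joints number of joints (default 7).
#' @param link_lengths link lengths in metres, one per joint.
#' @param axes rotation axis of each joint, `"x"`, `"y"` or `"z"`.
#' @param joint_limits 2-column matrix of lower/upper limits in degrees.
#' @param floor_z height (m) below which the end-effector is flagged as
#'   colliding with the floor.
#' @return An `arm_spec` list.
#' @export
arm_spec <- function(n_joints = 7L,
                     link_lengths = c(0.333, 0.316, 0.0825, 0.384,
                                      0.0825, 0.088, 0.107),
                     axes = c("z", "y", "z", "y", "z", "y", "z"),
                     joint_limits = cbind(rep(-170, n_joints),
                                          rep(170, n_joints)),
                     floor_z = 0.02) {
  stopifnot(length(link_lengths) == n_joints, all(link_lengths > 0),
            length(axes) == n_joints, all(axes %in% c("x", "y", "z")),
            nrow(joint_limits) == n_joints,
            all(joint_limits[, 1] < joint_limits[, 2]))
  structure(list(n_joints = as.integer(n_joints), link_lengths = link_lengths,
                 axes = axes, joint_limits = joint_limits, floor_z = floor_z),
            class = "arm_spec")
}

rot_axis <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
         y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
         z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}

#' Forward kinematics
#'
#' @param joints_deg vector of joint angles in degrees (or a matrix with one
#'   configuration per row).
#' @param arm an [arm_spec()].
#' @return End-effector position in metres: a length-3 vector, or a
#'   `n x 3` matrix for matrix input.
#' @export
forward_kinematics <- function(joints_deg, arm = arm_spec()) {
  if (is.matrix(joints_deg)) {
    out <- t(apply(joints_deg, 1, forward_kinematics, arm = arm))
    colnames(out) <- c("ee_x", "ee_y", "ee_z")
    return(out)
  }
  stopifnot(length(joints_deg) == arm$n_joints)
  th <- joints_deg * pi / 180
  R <- diag(3)
  p <- c(0, 0, 0)
  for (i in seq_len(arm$n_joints)) {
    R <- R %*% rot_axis(arm$axes[i], th[i])
    p <- p + R %*% c(0, 0, arm$link_lengths[i])
  }
  drop(p)
}

# scripted joint keyframes (degrees) for the two pick-and-place skills;
# columns are joints, rows are keyframes anchored at the named steps.
# flexion values keep the grasp/place approach ~0.08-0.16 m above the floor,
# so only locks on proximal joints (large end-effector levers) can drive the
# arm into the floor
pick_place_keyframes <- function(skill) {
  steps <- c(0, 3, 6, 8, 11, 13, 14)
  A <- rbind(
    c(  0, 15.0,   0, 40.0,   0, 35.0,   0),   # home
    c( 35, 37.1,  10, 61.9,   5, 45.4,  10),   # above pick
    c( 35, 51.2,  10, 75.9,   5, 56.1,  10),   # grasp (t = 3 s)
    c( 35, 33.0,  10, 57.8,   5, 41.2,  10),   # lift
    c(-40, 33.0, -10, 57.8,  -5, 41.2, -10),   # above place
    c(-40, 49.5, -10, 72.6,  -5, 54.4, -10),   # place / release
    c(-40, 37.1, -10, 59.4,  -5, 45.4, -10))   # retreat
  B <- rbind(
    c(  0, 15.0,   0, 40.0,   0, 35.0,   0),
    c(-50, 41.2, -15, 66.0,  -8, 49.5, -12),
    c(-50, 54.5, -15, 78.4,  -8, 59.4, -12),
    c(-50, 34.6, -15, 59.4,  -8, 42.9, -12),
    c( 55, 34.6,  15, 59.4,   8, 42.9,  12),
    c( 55, 52.0,  15, 74.2,   8, 56.1,  12),
    c( 55, 38.0,  15, 61.0,   8, 46.2,  12))
  list(steps = steps, frames = if (skill == "A") A else B)
}

pick_place_channel_info <- function() {
  tibble::tibble(
    channel = c(paste0("joint", 1:7), "ee_x", "ee_y", "ee_z",
                "grip_aperture", "grip_force_l", "grip_force_r",
                paste0(rep(c("f_l", "t_l", "f_r", "t_r"), each = 3),
                       rep(c("x", "y", "z"), 4))),
    role = c(rep("joint", 7), rep("ee", 3), rep("gripper", 3), rep("ft", 12)))
}

grasp_window <- function(n_steps = 15L) 7:13  # steps 6..12 (0-based), grasp to place

# noiseless 15 x 25 sensorimotor sequence for one skill. `warp` models
# trial-to-trial execution-timing variability (teleoperated repetitions are
# never perfectly paced): the keyframe timeline is evaluated at
# step * speed + phase instead of step
nominal_pick_place <- function(skill = c("A", "B"), arm = arm_spec(),
                               n_steps = 15L, warp = NULL) {
  skill <- match.arg(skill)
  kf <- pick_place_keyframes(skill)
  steps <- seq_len(n_steps) - 1L
  wpos <- if (is.null(warp)) steps else {
    pmin(pmax(steps * warp$speed + warp$phase, 0), n_steps - 1L)
  }
  joints <- sapply(seq_len(arm$n_joints), function(j) {
    approx(kf$steps, kf$frames[, j], xout = wpos)$y
  })
  ee <- forward_kinematics(joints, arm)
  grasped <- wpos >= 5.5 & wpos <= 12.5   # grasp..place on the warped timeline
  aperture <- ifelse(grasped, 0.2, 1.0)
  load_ramp <- ifelse(grasped, 1.0, 0.0)
  # smooth half-step ramp into and out of the grasp for the force profile
  grip_force <- 5 * load_ramp
  ft_profile <- c(0.4, 0.25, 2.5, 0.06, 0.09, 0.03,   # left sensor f(xyz), t(xyz)
                  -0.35, 0.3, 2.4, -0.05, 0.08, -0.04) # right sensor
  ft <- outer(load_ramp, ft_profile)
  vals <- cbind(joints, ee, aperture, grip_force, grip_force, ft)
  info <- pick_place_channel_info()
  colnames(vals) <- info$channel
  list(values = vals, info = info, joints = joints, wpos = wpos)
}

draw_warp <- function(speed_jitter_sd, phase_jitter_sd) {
  list(speed = 1 + rnorm(1, 0, speed_jitter_sd),
       phase = rnorm(1, 0, phase_jitter_sd))
}

# per-channel noise sd: fraction of each channel's dynamic range across the
# two skills' nominal sequences (so both skills share one noise scale)
default_noise_sd <- function(arm = arm_spec(), frac = 0.02) {
  both <- rbind(nominal_pick_place("A", arm)$values,
                nominal_pick_place("B", arm)$values)
  rng <- apply(both, 2, function(v) diff(range(v)))
  frac * pmax(rng, 1e-3)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(expr)
}

add_channel_noise <- function(values, noise_sd) {
  values + matrix(rnorm(length(values), 0, rep(noise_sd, each = nrow(values))),
                  nrow(values), ncol(values))
}

resolve_noise_sd <- function(noise_sd, n_chan, arm) {
  if (is.null(noise_sd)) noise_sd <- default_noise_sd(arm)
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, n_chan)
  stopifnot(length(noise_sd) == n_chan, all(noise_sd >= 0))
  noise_sd
}

#' Generate pick-and-place demonstrations
#'
#' Scripted 15-step, 25-channel sensorimotor sequences at 2 Hz: seven joint
#' angles interpolated through reach / grasp (t = 3 s) / lift / transport /
#' place waypoints, end-effector coordinates from forward kinematics, gripper
#' state switching at grasp and release, force/torque channels carrying a
#' load profile while grasping, and i.i.d. Gaussian observation noise per
#' channel. Skills `"A"` and `"B"` differ in pick and place locations.
#'
#' @param skill `"A"` or `"B"`.
#' @param n_reps number of repetitions (default 10).
#' @param noise_sd per-channel noise standard deviation; `NULL` (default)
#'   uses 2% of each channel's dynamic range, a scalar applies to all
#'   channels.
#' @param speed_jitter_sd,phase_jitter_sd trial-to-trial execution-timing
#'   variability: each repetition runs the movement at a speed factor
#'   `N(1, speed_jitter_sd)` with a phase offset `N(0, phase_jitter_sd)`
#'   steps (defaults 0.04 and 0.15, i.e. a few percent of pace and
#'   ~75 ms of onset jitter). Set both to 0 for perfectly timed trials.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param arm an [arm_spec()].
#' @return List of `n_reps` [sm_sequence()] objects.
#' @export
make_pick_place_demos <- function(skill = c("A", "B"), n_reps = 10,
                                  noise_sd = NULL, seed = 1L,
                                  arm = arm_spec(),
                                  speed_jitter_sd = 0.04,
                                  phase_jitter_sd = 0.15) {
  skill <- match.arg(skill)
  noise_sd <- resolve_noise_sd(noise_sd, 25L, arm)
  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      warp <- draw_warp(speed_jitter_sd, phase_jitter_sd)
      nom <- nominal_pick_place(skill, arm, warp = warp)
      sm_sequence(add_channel_noise(nom$values, noise_sd),
                  channels = nom$info$channel, roles = nom$info$role,
                  dt = 0.5, skill = skill, trial_id = r)
    })
  })
}

numeric_jacobian <- function(joints_deg, arm, h = 0.1) {
  J <- matrix(0, 3, arm$n_joints)
  for (j in seq_len(arm$n_joints)) {
    up <- joints_deg; up[j] <- up[j] + h
    dn <- joints_deg; dn[j] <- dn[j] - h
    J[, j] <- (forward_kinematics(up, arm) - forward_kinematics(dn, arm)) /
      (2 * h)
  }
  J  # metres per degree
}

# damped-least-squares differential IK: move the free joints to bring the
# end-effector back to `target_ee` while `locked` stays fixed
compensate_lock <- function(joints_deg, locked, target_ee, arm,
                            damping = 0.02, iters = 4, cap_deg = 30) {
  q <- joints_deg
  free <- setdiff(seq_len(arm$n_joints), locked)
  start <- q[free]
  for (k in seq_len(iters)) {
    e <- target_ee - forward_kinematics(q, arm)
    if (sqrt(sum(e^2)) < 1e-4) break
    Jf <- numeric_jacobian(q, arm)[, free, drop = FALSE]
    dq <- drop(t(Jf) %*% solve(Jf %*% t(Jf) + damping^2 * diag(3), e))
    q[free] <- q[free] + dq
  }
  # joint-velocity cap relative to the commanded step
  q[free] <- start + pmin(pmax(q[free] - start, -cap_deg), cap_deg)
  pmin(pmax(q, arm$joint_limits[, 1]), arm$joint_limits[, 2])
}

#' Inject a joint-lock fault
#'
#' From the step at `t_fault_s` onward, joint `joint` overshoots its desired
#' angle at that step by `overshoot_deg` and stays stuck there, while the
#' remaining joints keep tracking their own nominal references (joint-space
#' position control). End-effector channels are recomputed by forward
#' kinematics; if the
#' faulty configuration drives the end-effector below the floor, a
#' collision force spike (10x the grasp load, halving each step) is added
#' to the force/torque channels. Steps before the fault are untouched.
#' Observation noise is added after fault construction.
#'
#' @inheritParams make_pick_place_demos
#' @param joint locked joint index, 1..7.
#' @param t_fault_s fault onset time in seconds.
#' @param overshoot_deg signed overshoot in degrees.
#' @param grasp_tolerance_m maximum end-effector displacement (metres) from
#'   the nominal grasp pose at grasp time for the pick to succeed; a fault
#'   that displaces the hand further misses the object, so the gripper stays
#'   open and the force/torque load profile never appears.
#' @return An [sm_sequence()] with an attached `fault` attribute
#'   (`joint`, `t_fault_s`, `overshoot_deg`, `fault_step` 0-based,
#'   `collided`, `grasp_failed`).
#' @param compensate should the remaining joints track the nominal
#'   end-effector path after the fault (default `FALSE`, matching a
#'   joint-space position controller whose per-joint references are fixed
#'   at demonstration time)? When `TRUE`, compensation starts one step
#'   after the fault (the controller's reaction delay), emulating an
#'   end-effector-servoing controller on a redundant arm.
#' @export
inject_joint_lock <- function(skill = c("A", "B"), joint, t_fault_s,
                              overshoot_deg, noise_sd = NULL, seed = 1L,
                              arm = arm_spec(), grasp_tolerance_m = 0.05,
                              compensate = FALSE,
                              speed_jitter_sd = 0.04,
                              phase_jitter_sd = 0.15) {
  skill <- match.arg(skill)
  warp <- with_seed(seed, draw_warp(speed_jitter_sd, phase_jitter_sd))
  nom <- nominal_pick_place(skill, arm, warp = warp)
  n_steps <- nrow(nom$values)
  fault_step <- as.integer(round(t_fault_s / 0.5))
  if (fault_step < 0 || fault_step >= n_steps) {
    abort("`t_fault_s` must fall within the trial.")
  }
  stopifnot(joint >= 1, joint <= arm$n_joints)

  joints <- nom$joints
  stuck <- joints[fault_step + 1, joint] + overshoot_deg
  joints[(fault_step + 1):n_steps, joint] <- stuck
  if (compensate && fault_step + 2 <= n_steps) {
    nom_ee <- nom$values[, arm$n_joints + 1:3]
    for (s in (fault_step + 2):n_steps) {
      joints[s, ] <- compensate_lock(joints[s, ], joint, nom_ee[s, ], arm)
      joints[s, joint] <- stuck
    }
  }
  ee <- forward_kinematics(joints, arm)

  vals <- nom$values
  vals[, 1:arm$n_joints] <- joints
  vals[, arm$n_joints + 1:3] <- ee

  # a fault before the pick that leaves the hand off the object's pose
  # makes the grasp fail: no load is ever carried. Windows follow the
  # trial's own (possibly time-warped) execution.
  grasp_step <- which.min(abs(nom$wpos - 6)) - 1L  # 0-based
  grasp_failed <- FALSE
  if (fault_step <= grasp_step) {
    displacement <- sqrt(sum((ee[grasp_step + 1L, ] -
                                nom$values[grasp_step + 1L,
                                           arm$n_joints + 1:3])^2))
    if (displacement > grasp_tolerance_m) {
      grasp_failed <- TRUE
      gw <- which(nom$wpos >= 5.5 & nom$wpos <= 12.5)
      grip_cols <- which(nom$info$role == "gripper")
      vals[gw, grip_cols[1]] <- 1.0       # aperture stays open
      vals[gw, grip_cols[-1]] <- 0        # no finger forces
      vals[gw, nom$info$role == "ft"] <- 0  # no load profile
    }
  }

  collided <- FALSE
  below <- which(ee[, 3] < arm$floor_z & seq_len(n_steps) > fault_step)
  if (length(below) > 0) {
    collided <- TRUE
    spike_mag <- 10 * 5  # 10x grasp load amplitude
    ft_cols <- which(nom$info$role == "ft")
    k <- seq(below[1], n_steps)
    decay <- spike_mag * 0.5^(k - below[1])
    for (i in seq_along(k)) {
      vals[k[i], ft_cols] <- vals[k[i], ft_cols] +
        decay[i] * rep(c(0, 0, 1, 0.1, 0.1, 0), 2)
    }
  }

  noise_sd <- resolve_noise_sd(noise_sd, ncol(vals), arm)
  out <- with_seed(seed + 1L, {
    sm_sequence(add_channel_noise(vals, noise_sd),
                channels = nom$info$channel, roles = nom$info$role,
                dt = 0.5, skill = skill, trial_id = NA_integer_)
  })
  attr(out, "fault") <- list(joint = as.integer(joint), t_fault_s = t_fault_s,
                             overshoot_deg = overshoot_deg,
                             fault_step = fault_step, collided = collided,
                             grasp_failed = grasp_failed)
  out
}

#' Inject an impulsive collision disturbance
#'
#' Adds a transient to the joint channels at time `t_s` that decays
#' geometrically over subsequent steps (a proxy for an object striking the
#' arm), and recomputes the end-effector channels from the perturbed joints.
#'
#' @param sequence an [sm_sequence()] with the pick-and-place channel layout.
#' @param t_s impulse time in seconds.
#' @param impulse_deg length-7 vector of joint-angle impulses in degrees.
#' @param decay per-step geometric decay factor of the transient.
#' @param arm an [arm_spec()].
#' @return The perturbed [sm_sequence()].
#' @export
inject_collision <- function(sequence, t_s, impulse_deg, decay = 0.5,
                             arm = arm_spec()) {
  stopifnot(inherits(sequence, "sm_seq"), length(impulse_deg) == arm$n_joints)
  n_steps <- nrow(sequence)
  step0 <- as.integer(round(t_s / attr(sequence, "dt")))
  if (step0 < 0 || step0 >= n_steps) abort("`t_s` must fall within the trial.")
  vals <- unclass(sequence)[, , drop = FALSE]
  jc <- role_columns(sequence, "joint")
  for (s in seq(step0, n_steps - 1)) {
    vals[s + 1, jc] <- vals[s + 1, jc] + impulse_deg * decay^(s - step0)
  }
  vals[, role_columns(sequence, "ee")] <- forward_kinematics(vals[, jc], arm)
  with_values(sequence, vals)
}
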