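#' Follow-through (context-cued reaching) dataset
#'
#' A planar reaching task modelled on human force-field experiments in which
#' opposing perturbations are signalled by a visual context cue. Each context
#' (`"cw"`, `"ccw"`) has a pre-defined optimal compensatory plan: the
#' straight start-to-target path plus a half-sine lateral bow of the
#' configured amplitude, bowing leftward for the clockwise field and
#' rightward for the counter-clockwise field (the two plans are mirror
#' images across the start-target line). Joint channels come from 2-link
#' planar inverse kinematics and the context is carried by one-hot cue
#' channels.
#'
#' The three cue-availability conditions differ in when the cue can inform
#' the movement:
#' * `planning_only` — cue active from step 0; movement is the bowed
#'   start-to-target path only.
#' * `planning_and_execution` — cue active from step 0; the follow-through
#'   leg to the context's secondary target is appended.
#' * `execution_only` — the cue switches on mid-movement (step
#'   `ceiling(T/2)`), so the first observations carry no context.
#'
#' @param condition one of `"planning_only"`, `"planning_and_execution"`,
#'   `"execution_only"`.
#' @param contexts which contexts to generate (default both).
#' @param n_trials noisy demonstration trials per context (default 12).
#' @param noise_sd observation noise sd on end-effector and joint channels;
#'   `NULL` (default) uses 2% of each channel's dynamic range. Cue channels
#'   are never noisy (they stay one-hot).
#' @param seed integer seed.
#' @param n_steps sequence length (default 15 steps at 2 Hz).
#' @param amplitude lateral bow amplitude in metres (default 0.02, i.e. a
#'   2 cm maximum compensatory deviation).
#' @return An `ft_dataset` list: `trials` (list of [sm_sequence()], skill
#'   label = context), `plans` (noiseless per-context value matrices),
#'   `S`, `T_pt`, `secondary` targets, `amplitude`, `cue_onset` (0-based),
#'   `condition`.
#' @export
make_followthrough_dataset <- function(condition = c("planning_only",
                                                     "planning_and_execution",
                                                     "execution_only"),
                                       contexts = c("cw", "ccw"),
                                       n_trials = 12, noise_sd = NULL,
                                       seed = 1L, n_steps = 15L,
                                       amplitude = 0.02) {
  condition <- match.arg(condition)
  stopifnot(all(contexts %in% c("cw", "ccw")), n_trials >= 0)
  S <- c(0, 0)
  T_pt <- c(0, 0.10)
  secondary <- list(
    cw = T_pt + 0.05 * c(sin(-40 * pi / 180), cos(-40 * pi / 180)),
    ccw = T_pt + 0.05 * c(sin(40 * pi / 180), cos(40 * pi / 180)))
  cue_onset <- if (condition == "execution_only") as.integer(ceiling(n_steps / 2)) else 0L

  plans <- lapply(setNames(contexts, contexts), function(ctx) {
    followthrough_plan(ctx, condition, S, T_pt, secondary[[ctx]], n_steps,
                       amplitude, cue_onset)
  })

  info <- followthrough_channel_info()
  if (is.null(noise_sd)) {
    pooled <- do.call(rbind, lapply(plans, function(p) p$values))
    rng <- apply(pooled, 2, function(v) diff(range(v)))
    noise_sd <- 0.02 * pmax(rng, 1e-4)
  } else if (length(noise_sd) == 1) {
    noise_sd <- rep(noise_sd, nrow(info))
  }
  noise_sd[info$role == "cue"] <- 0

  trials <- with_seed(seed, {
    unlist(lapply(contexts, function(ctx) {
      lapply(seq_len(n_trials), function(r) {
        sm_sequence(add_channel_noise(plans[[ctx]]$values, noise_sd),
                    channels = info$channel, roles = info$role,
                    dt = 0.5, skill = ctx, trial_id = r)
      })
    }), recursive = FALSE)
  })

  structure(list(condition = condition, contexts = contexts, trials = trials,
                 plans = plans, S = S, T_pt = T_pt, secondary = secondary,
                 amplitude = amplitude, cue_onset = cue_onset,
                 n_steps = as.integer(n_steps), noise_sd = noise_sd),
            class = "ft_dataset")
}

followthrough_channel_info <- function() {
  tibble::tibble(channel = c("ee_x", "ee_y", "shoulder", "elbow",
                             "cue_cw", "cue_ccw"),
                 role = c("ee", "ee", "joint", "joint", "cue", "cue"))
}

# compensation sign on the +90-degree normal of the S->T line:
# the clockwise field is compensated leftward (+normal), counter-clockwise
# rightward (-normal)
context_sign <- function(context) if (context == "cw") 1 else -1

followthrough_plan <- function(context, condition, S, T_pt, ST, n_steps,
                               amplitude, cue_onset) {
  u <- (T_pt - S) / sqrt(sum((T_pt - S)^2))
  n_hat <- c(-u[2], u[1])  # +90 degree rotation
  followthrough <- condition == "planning_and_execution"
  n_main <- if (followthrough) 10L else n_steps
  s_frac <- seq(0, 1, length.out = n_main)
  main <- t(sapply(s_frac, function(s) {
    S + s * (T_pt - S) + context_sign(context) * amplitude * sin(pi * s) * n_hat
  }))
  path <- main
  if (followthrough) {
    s2 <- seq(0, 1, length.out = n_steps - n_main + 1)[-1]
    leg <- t(sapply(s2, function(s) T_pt + s * (ST - T_pt)))
    path <- rbind(main, leg)
  }
  joints <- two_link_ik(path)
  cue <- matrix(0, n_steps, 2)
  active <- (cue_onset + 1):n_steps
  cue[active, if (context == "cw") 1 else 2] <- 1
  vals <- cbind(path, joints, cue)
  colnames(vals) <- followthrough_channel_info()$channel
  list(values = vals, path = path, joints = joints, cue = cue,
       context = context)
}

#' Two-link planar arm kinematics
#'
#' Inverse and forward kinematics for the planar 2-link arm behind the
#' follow-through task (shoulder at `base`, elbow-up solution, angles in
#' degrees).
#'
#' @param points `n x 2` matrix of end-effector positions (metres).
#' @param l1,l2 link lengths (metres).
#' @param base shoulder position.
#' @return `two_link_ik()`: `n x 2` matrix of shoulder/elbow angles
#'   (degrees); `two_link_fk()`: `n x 2` matrix of positions.
#' @export
two_link_ik <- function(points, l1 = 0.3, l2 = 0.25, base = c(0, -0.4)) {
  points <- matrix(points, ncol = 2)
  rel <- sweep(points, 2, base)
  r2 <- rowSums(rel^2)
  c_el <- pmin(1, pmax(-1, (r2 - l1^2 - l2^2) / (2 * l1 * l2)))
  elbow <- -acos(c_el)  # elbow-up
  shoulder <- atan2(rel[, 2], rel[, 1]) -
    atan2(l2 * sin(elbow), l1 + l2 * cos(elbow))
  cbind(shoulder, elbow) * 180 / pi
}

#' @rdname two_link_ik
#' @param joints_deg `n x 2` matrix of shoulder/elbow angles in degrees.
#' @export
two_link_fk <- function(joints_deg, l1 = 0.3, l2 = 0.25, base = c(0, -0.4)) {
  joints_deg <- matrix(joints_deg, ncol = 2)
  th <- joints_deg * pi / 180
  x <- base[1] + l1 * cos(th[, 1]) + l2 * cos(th[, 1] + th[, 2])
  y <- base[2] + l1 * sin(th[, 1]) + l2 * sin(th[, 1] + th[, 2])
  cbind(x, y)
}

#' @export
print.ft_dataset <- function(x, ...) {
  cat(sprintf("<ft_dataset> condition %s: %d trials (%s), %d steps, cue onset step %d\n",
              x$condition, length(x$trials),
              paste(x$contexts, collapse = "/"), x$n_steps, x$cue_onset))
  invisible(x)
}
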