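#' Fit a nearest-rank percentile energy threshold
#'
#' Fault detection is out-of-distribution detection on the monitoring
#' signal: a threshold is set at a percentile of the signal's distribution
#' during normal (fault-free) operation. The nearest-rank definition
#' (the `ceiling(p/100 * n)`-th order statistic) makes the false-positive
#' arithmetic exact: at most `(100 - p)%` of the fitted values lie strictly
#' above the threshold, with equality when `n * (100 - p) / 100` is an
#' integer and the values are distinct.
#'
#' @param normal_values pooled per-step monitoring values from fault-free
#'   trials (at least 20, all finite).
#' @param percentile percentile in (0, 100], default 95 (a 5% false-positive
#'   rate).
#' @return An `energy_threshold` list with `percentile`, `threshold`, `n_fit`.
#' @export
fit_threshold <- function(normal_values, percentile = 95) {
  if (length(normal_values) == 0) abort("`normal_values` must be non-empty.")
  stopifnot(all(is.finite(normal_values)), percentile > 0, percentile <= 100,
            length(normal_values) >= 20)
  n <- length(normal_values)
  k <- ceiling(percentile / 100 * n)
  structure(list(percentile = percentile,
                 threshold = sort(normal_values)[k],
                 n_fit = n),
            class = "energy_threshold")
}

#' @export
print.energy_threshold <- function(x, ...) {
  cat(sprintf("<energy_threshold> p%g of %d values: %.6g\n",
              x$percentile, x$n_fit, x$threshold))
  invisible(x)
}

#' Write / read a threshold as JSON
#' @param x an `energy_threshold`.
#' @param path file path.
#' @export
write_threshold_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_json
#' @export
read_threshold_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "energy_threshold")
}

#' Detect a fault from a monitoring trace
#'
#' A trial is flagged as faulty as soon as any step's monitoring value
#' exceeds the threshold.
#'
#' @param energies per-step monitoring values.
#' @param threshold an [fit_threshold()] object (or a scalar).
#' @param from_step first step (0-based) eligible for detection; defaults to
#'   0. Grid evaluations only count crossings at or after the fault step.
#' @return A list with `detected` and `detection_step` (0-based; `NA` if not
#'   detected).
#' @export
detect_fault <- function(energies, threshold, from_step = 0L) {
  stopifnot(all(is.finite(energies)))
  thr <- if (inherits(threshold, "energy_threshold")) threshold$threshold
         else threshold
  idx <- which(energies > thr & (seq_along(energies) - 1L) >= from_step)
  if (length(idx) == 0) list(detected = FALSE, detection_step = NA_integer_)
  else list(detected = TRUE, detection_step = as.integer(idx[1] - 1L))
}

#' Isolate the faulty channel
#'
#' Returns the joint channel with the largest absolute observation
#' prediction error over the trial from the detection step onward
#' (`window = "from_detection"`, the default: isolation is a per-trial
#' judgement), or at the detection step alone
#' (`window = "at_detection"`). Ties break towards the lowest joint index.
#'
#' @param channel_errors `T x C` matrix of per-step absolute errors with
#'   channel column names.
#' @param detection_step 0-based detection step.
#' @param roles channel roles (length `C`).
#' @param window isolation window (see above).
#' @return The isolated joint channel name.
#' @export
isolate_fault <- function(channel_errors, detection_step, roles,
                          window = c("from_detection", "at_detection")) {
  window <- match.arg(window)
  if (is.na(detection_step)) abort("isolation requires a detection.")
  jc <- which(roles == "joint")
  rows <- if (window == "at_detection") detection_step + 1L
          else (detection_step + 1L):nrow(channel_errors)
  errs <- apply(channel_errors[rows, jc, drop = FALSE], 2, max)
  colnames(channel_errors)[jc[which.max(errs)]]
}

#' Build a full fault report
#'
#' Combines detection and isolation for one monitored trial into the
#' standard report consumed by the grid evaluation.
#'
#' @inheritParams isolate_fault
#' @inheritParams detect_fault
#' @return A `fault_report` list: `energies`, `detected`, `detection_step`,
#'   `channel_errors`, `isolated_channel` (argmax over all channels) and
#'   `isolated_joint` (argmax over joint channels), the last two present
#'   only when detected.
#' @export
fault_report <- function(energies, channel_errors, threshold, roles,
                         from_step = 0L,
                         window = c("from_detection", "at_detection")) {
  window <- match.arg(window)
  det <- detect_fault(energies, threshold, from_step)
  isolated_channel <- NA_character_
  isolated_joint <- NA_character_
  if (det$detected) {
    rows <- if (window == "at_detection") det$detection_step + 1L
            else (det$detection_step + 1L):nrow(channel_errors)
    peak <- apply(channel_errors[rows, , drop = FALSE], 2, max)
    isolated_channel <- colnames(channel_errors)[which.max(peak)]
    isolated_joint <- isolate_fault(channel_errors, det$detection_step,
                                    roles, window)
  }
  structure(list(energies = energies, detected = det$detected,
                 detection_step = det$detection_step,
                 channel_errors = channel_errors,
                 isolated_channel = isolated_channel,
                 isolated_joint = isolated_joint),
            class = "fault_report")
}

#' Monitor a trial with the network's energy
#'
#' Maps a raw-unit trial into the model's normalised units, runs clamped
#' online inference, and returns the per-step converged energies and
#' absolute observation prediction errors — the Neural ASM monitoring
#' signals.
#'
#' @param model a trained [tpc_model()].
#' @param trial an [sm_sequence()] in original units.
#' @param scaling the training-set `scaling` from [zscore_normalise()].
#' @return A `tpc_monitor` (see [online_recall()]).
#' @export
monitor_trial <- function(model, trial, scaling) {
  online_recall(model, zscore_apply(trial, scaling))
}

#' Per-channel signal statistics for the Z-score baseline
#'
#' The traditional associative-skill-memory baseline stores, for each known
#' skill, signal statistics from its demonstrations and scores new
#' observations by their normalised deviation,
#' `eps = (x_it - mean) / sd`. The default `"per_step"` stores the expected
#' signal trace and spread per (time step, channel) — skill memories keep
#' sensory statistics aligned to the movement phase; `"per_step_mean"`
#' keeps the per-step trace but normalises by the per-channel standard
#' deviation; `"pooled"` pools both statistics over time steps (the most
#' literal reading of a per-channel normalisation).
#'
#' @param demos named list (one entry per skill) of lists of
#'   [sm_sequence()] demonstrations (at least 2 per skill).
#' @param granularity `"per_step"` (default), `"per_step_mean"` or
#'   `"pooled"`.
#' @param sd_floor lower bound applied to every standard deviation.
#' @return A `channel_stats` object.
#' @export
channel_stats <- function(demos, granularity = c("per_step", "per_step_mean",
                                                 "pooled"),
                          sd_floor = 1e-6) {
  granularity <- match.arg(granularity)
  stopifnot(is.list(demos), !is.null(names(demos)))
  stats <- lapply(demos, function(trials) {
    if (length(trials) < 2) abort("need >= 2 demonstrations per skill.")
    arr <- lapply(trials, as_value_matrix)
    if (granularity == "pooled") {
      pooled <- do.call(rbind, arr)
      list(mean = colMeans(pooled),
           sd = pmax(apply(pooled, 2, sd), sd_floor))
    } else {
      n_steps <- nrow(arr[[1]])
      m <- s <- matrix(0, n_steps, ncol(arr[[1]]))
      for (t in seq_len(n_steps)) {
        slice <- do.call(rbind, lapply(arr, function(a) a[t, ]))
        m[t, ] <- colMeans(slice)
        s[t, ] <- pmax(apply(slice, 2, sd), sd_floor)
      }
      colnames(m) <- colnames(s) <- colnames(arr[[1]])
      if (granularity == "per_step_mean") {
        pooled <- do.call(rbind, arr)
        list(mean = m, sd = pmax(apply(pooled, 2, sd), sd_floor))
      } else {
        list(mean = m, sd = s)
      }
    }
  })
  structure(list(stats = stats, granularity = granularity,
                 sd_floor = sd_floor,
                 channels = colnames(as_value_matrix(demos[[1]][[1]])),
                 roles = attr(demos[[1]][[1]], "roles")),
            class = "channel_stats")
}

#' Z-score baseline monitoring statistic
#'
#' Scores a trial against the stored statistics of the (externally supplied)
#' true skill: per step and channel `z = (x - mean) / sd`, with the per-step
#' detection statistic `sum_i z_i^2` and per-channel `|z|` for isolation.
#' Unlike the energy monitor, this baseline must be told which skill is
#' being performed.
#'
#' @param observed an [sm_sequence()] in original units.
#' @param stats a [channel_stats()] object.
#' @param skill the true skill label (must exist in `stats`).
#' @return A `zscore_monitor` list: `statistic` (length `T`),
#'   `channel_errors` (`T x C` matrix of `|z|`).
#' @export
zscore_baseline <- function(observed, stats, skill) {
  stopifnot(inherits(stats, "channel_stats"))
  if (!skill %in% names(stats$stats)) {
    abort(paste0("unknown skill label: ", skill))
  }
  X <- as_value_matrix(observed)
  st <- stats$stats[[skill]]
  if (stats$granularity == "pooled") {
    z <- sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
  } else if (stats$granularity == "per_step_mean") {
    stopifnot(nrow(X) == nrow(st$mean))
    z <- sweep(X - st$mean, 2, st$sd, "/")
  } else {
    stopifnot(nrow(X) == nrow(st$mean))
    z <- (X - st$mean) / st$sd
  }
  colnames(z) <- stats$channels
  structure(list(statistic = rowSums(z^2), channel_errors = abs(z)),
            class = "zscore_monitor")
}

#' Reactive correction by tracking predicted proprioception
#'
#' The skill memory's predicted joint trajectory (2 Hz) is linearly
#' interpolated to the low-level controller rate (40 Hz) and tracked by a
#' proportional controller that drives the plant's joint angles toward it,
#' i.e. the controller minimises proprioceptive prediction error in joint
#' configuration space. An impulsive disturbance decays geometrically at
#' rate `1 - gain` per low-level step.
#'
#' @param predicted_joints `T x n_joints` matrix of predicted joint angles
#'   (degrees) at the skill-memory rate.
#' @param gain proportional gain in (0, 1].
#' @param disturbance_step low-level step (0-based) at which an impulse is
#'   applied, or `NULL` for none.
#' @param disturbance_deg length-`n_joints` impulse in degrees.
#' @param dt_high low-level control interval in seconds (default 1/40).
#' @param dt sampling interval of the predicted trajectory (default 0.5).
#' @return A tibble with one row per low-level step and joint: `low_step`,
#'   `time_s`, `joint`, `reference`, `actual`, `error`.
#' @export
reactive_correct <- function(predicted_joints, gain = 0.5,
                             disturbance_step = NULL, disturbance_deg = NULL,
                             dt_high = 1 / 40, dt = 0.5) {
  if (gain <= 0) abort("`gain` must be positive.")
  predicted_joints <- as.matrix(predicted_joints)
  n_joints <- ncol(predicted_joints)
  t_ref <- (seq_len(nrow(predicted_joints)) - 1) * dt
  t_high <- seq(0, max(t_ref), by = dt_high)
  ref <- sapply(seq_len(n_joints), function(j) {
    approx(t_ref, predicted_joints[, j], xout = t_high)$y
  })
  q <- matrix(0, length(t_high), n_joints)
  q[1, ] <- ref[1, ]
  for (k in seq_len(length(t_high) - 1)) {
    q[k + 1, ] <- q[k, ] + gain * (ref[k, ] - q[k, ])
    if (!is.null(disturbance_step) && k == disturbance_step) {
      q[k + 1, ] <- q[k + 1, ] + disturbance_deg
    }
  }
  jn <- colnames(predicted_joints)
  if (is.null(jn)) jn <- paste0("joint", seq_len(n_joints))
  tibble::tibble(
    low_step = rep(seq_along(t_high) - 1L, n_joints),
    time_s = rep(t_high, n_joints),
    joint = rep(jn, each = length(t_high)),
    reference = as.vector(ref),
    actual = as.vector(q),
    error = as.vector(q - ref))
}

#' Systematic fault-grid evaluation
#'
#' Generates one joint-lock trial per grid cell (locked joint x fault time x
#' overshoot), monitors it with both the energy detector and the Z-score
#' baseline, and reports detection and isolation per trial. Skills alternate
#' across cells so both stored skills are exercised. A trial counts as
#' detected when the monitoring value crosses its threshold at or after the
#' fault step; isolation is correct when the argmax joint channel matches
#' the locked joint.
#'
#' @param model a trained [tpc_model()].
#' @param scaling training-set channel scaling (see [zscore_normalise()]).
#' @param stats a [channel_stats()] baseline (or `NULL` to skip it).
#' @param nasm_threshold,baseline_threshold fitted [fit_threshold()] objects.
#' @param joints,fault_times,overshoots grid axes (defaults: joints 1..7,
#'   1 to 6 s in 0.5 s steps, overshoots of 5, 10 and 15 degrees of either
#'   sign; zero overshoot is excluded by construction — a lock with no
#'   overshoot at the goal is not a detectable fault on this plant).
#' @param noise_sd observation noise passed to [inject_joint_lock()].
#' @param seed base seed; each cell derives its own trial seed.
#' @param arm an [arm_spec()].
#' @return A tibble (class `fault_grid_eval`) with columns `method`, `skill`,
#'   `joint`, `fault_time_s`, `overshoot_deg`, `collided`, `detected`,
#'   `detection_step`, `isolated_joint`, `correct_isolation`.
#' @export
evaluate_fault_grid <- function(model, scaling, stats,
                                nasm_threshold, baseline_threshold = NULL,
                                joints = 1:7,
                                fault_times = seq(1, 6, by = 0.5),
                                overshoots = c(-15, -10, -5, 5, 10, 15),
                                noise_sd = NULL, seed = 1L,
                                arm = arm_spec()) {
  if (any(overshoots == 0)) abort("zero overshoot cells are excluded by design.")
  grid <- tidyr::expand_grid(joint = joints, fault_time_s = fault_times,
                             overshoot_deg = overshoots)
  grid$skill <- ifelse(seq_len(nrow(grid)) %% 2 == 1, "A", "B")
  roles <- pick_place_channel_info()$role
  joint_names <- pick_place_channel_info()$channel[roles == "joint"]

  rows <- purrr::pmap_dfr(grid, function(joint, fault_time_s, overshoot_deg,
                                         skill) {
    cell_seed <- (seed * 1000L +
                    which(joints == joint) * 101L +
                    which(fault_times == fault_time_s) * 13L +
                    which(overshoots == overshoot_deg)) %% .Machine$integer.max
    trial <- inject_joint_lock(skill, joint, fault_time_s, overshoot_deg,
                               noise_sd = noise_sd, seed = cell_seed,
                               arm = arm)
    fault_step <- attr(trial, "fault")$fault_step
    collided <- attr(trial, "fault")$collided
    truth <- joint_names[joint]

    mon <- monitor_trial(model, trial, scaling)
    rep_n <- fault_report(mon$energies, mon$channel_errors, nasm_threshold,
                          roles, from_step = fault_step)
    out <- tibble::tibble(
      method = "neural_asm", skill = skill, joint = joint,
      fault_time_s = fault_time_s, overshoot_deg = overshoot_deg,
      collided = collided, detected = rep_n$detected,
      detection_step = rep_n$detection_step,
      isolated_joint = rep_n$isolated_joint,
      correct_isolation = rep_n$detected && identical(rep_n$isolated_joint, truth))

    if (!is.null(stats)) {
      zb <- zscore_baseline(trial, stats, skill)
      rep_b <- fault_report(zb$statistic, zb$channel_errors,
                            baseline_threshold, roles, from_step = fault_step)
      out <- dplyr::bind_rows(out, tibble::tibble(
        method = "zscore_baseline", skill = skill, joint = joint,
        fault_time_s = fault_time_s, overshoot_deg = overshoot_deg,
        collided = collided, detected = rep_b$detected,
        detection_step = rep_b$detection_step,
        isolated_joint = rep_b$isolated_joint,
        correct_isolation = rep_b$detected && identical(rep_b$isolated_joint, truth)))
    }
    out
  })
  class(rows) <- c("fault_grid_eval", class(rows))
  rows
}

#' Summarise a fault-grid evaluation
#'
#' @param results a [evaluate_fault_grid()] tibble.
#' @return One row per method: `n_trials`, `detection_rate`,
#'   `isolation_accuracy` (correct isolations over all trials, detected or
#'   not).
#' @export
summarise_fault_grid <- function(results) {
  results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     detection_rate = mean(.data$detected),
                     isolation_accuracy = mean(.data$correct_isolation),
                     .groups = "drop")
}
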