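#' Train a skill memory on demonstrations
#'
#' Convenience wrapper over the full memorisation pipeline: Z-score
#' normalise the demonstrations, build a network from a seed, and memorise
#' all skills jointly.
#'
#' @param demos list of [sm_sequence()] demonstrations (all skills mixed).
#' @param n_hidden hidden units (default 256).
#' @param epochs presentations of the full skill set.
#' @param seed integer seed for weight initialisation.
#' @param ... further arguments passed to [tpc_config()].
#' @return A `skill_memory` list: `model` (trained [tpc_model()]),
#'   `scaling` (channel statistics used for normalisation), `n_demos`.
#' @export
train_skill_memory <- function(demos, n_hidden = 256L, epochs = 1000L,
                               seed = 1L, ...) {
  norm <- zscore_normalise(demos)
  cfg <- tpc_config(n_obs = ncol(demos[[1]]), n_hidden = n_hidden,
                    epochs_per_skill = epochs, seed = seed, ...)
  model <- tpc_model(cfg, channels = colnames(demos[[1]]),
                     roles = attr(demos[[1]], "roles"))
  model <- memorise(model, norm$trials)
  structure(list(model = model, scaling = norm$scaling,
                 n_demos = length(demos)),
            class = "skill_memory")
}

#' @export
print.skill_memory <- function(x, ...) {
  cat(sprintf("<skill_memory> trained on %d demonstrations\n", x$n_demos))
  print(x$model)
  invisible(x)
}

#' End-to-end fault detection and isolation experiment
#'
#' Runs the full pick-and-place pipeline: generate demonstrations for the
#' two skills, memorise them, fit energy and baseline thresholds on
#' held-out fault-free trials, evaluate the joint-lock fault grid with both
#' methods, and (optionally) sweep the false-positive rate.
#'
#' @param seed master seed; demonstration, held-out and grid seeds are
#'   derived from it.
#' @param n_hidden hidden units of the skill memory.
#' @param epochs training epochs (default 200, the reduced budget used for
#'   the scaled-down evaluation).
#' @param n_reps demonstrations per skill (default 10).
#' @param percentile detection percentile (default 95, i.e. 5% FPR).
#' @param fpr_sweep optional vector of additional false-positive rates (in
#'   percent, e.g. `1:5`) to sweep.
#' @param joints,fault_times,overshoots grid axes (see
#'   [evaluate_fault_grid()]).
#' @param stat_granularity baseline statistic granularity (see
#'   [channel_stats()]).
#' @return A `fault_experiment` list: `memory` (the [train_skill_memory()]
#'   fit), `stats`, `thresholds`, `normal_energies`, `normal_statistic`,
#'   `grid` (per-trial tibble), `summary` (per-method rates), and
#'   `fpr_sweep` (per-FPR summary tibble or `NULL`).
#' @export
run_fault_experiment <- function(seed = 1L, n_hidden = 256L, epochs = 200L,
                                 n_reps = 10L, percentile = 95,
                                 fpr_sweep = NULL,
                                 joints = 1:7,
                                 fault_times = seq(1, 6, by = 0.5),
                                 overshoots = c(-15, -10, -5, 5, 10, 15),
                                 stat_granularity = "per_step") {
  demos <- list(A = make_pick_place_demos("A", n_reps, seed = seed),
                B = make_pick_place_demos("B", n_reps, seed = seed + 1L))
  memory <- train_skill_memory(c(demos$A, demos$B), n_hidden = n_hidden,
                               epochs = epochs, seed = seed)

  # held-out fault-free trials for threshold calibration
  held <- list(A = make_pick_place_demos("A", n_reps, seed = seed + 2L),
               B = make_pick_place_demos("B", n_reps, seed = seed + 3L))
  normal_energies <- unlist(lapply(c(held$A, held$B), function(tr) {
    monitor_trial(memory$model, tr, memory$scaling)$energies
  }))
  stats <- channel_stats(demos, granularity = stat_granularity)
  normal_statistic <- unlist(lapply(names(held), function(sk) {
    unlist(lapply(held[[sk]], function(tr) {
      zscore_baseline(tr, stats, sk)$statistic
    }))
  }))

  thr_n <- fit_threshold(normal_energies, percentile)
  thr_b <- fit_threshold(normal_statistic, percentile)
  grid <- evaluate_fault_grid(memory$model, memory$scaling, stats, thr_n,
                              thr_b, joints = joints,
                              fault_times = fault_times,
                              overshoots = overshoots, seed = seed)
  summary <- summarise_fault_grid(grid)

  sweep_tbl <- NULL
  if (!is.null(fpr_sweep)) {
    sweep_tbl <- purrr::map_dfr(fpr_sweep, function(fpr) {
      g <- evaluate_fault_grid(memory$model, memory$scaling, stats,
                               fit_threshold(normal_energies, 100 - fpr),
                               fit_threshold(normal_statistic, 100 - fpr),
                               joints = joints, fault_times = fault_times,
                               overshoots = overshoots, seed = seed)
      dplyr::mutate(summarise_fault_grid(g), fpr_percent = fpr,
                    .before = 1)
    })
  }

  structure(list(memory = memory, stats = stats,
                 thresholds = list(neural_asm = thr_n, zscore_baseline = thr_b),
                 normal_energies = normal_energies,
                 normal_statistic = normal_statistic,
                 grid = grid, summary = summary, fpr_sweep = sweep_tbl),
            class = "fault_experiment")
}

#' @export
print.fault_experiment <- function(x, ...) {
  cat("<fault_experiment>\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.fault_experiment <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = c("detection_rate", "isolation_accuracy"),
                       id_cols = c()) |>
    dplyr::mutate(n_trials = x$summary$n_trials[1], .before = 1)
}

# fresh noisy cue observations for recall, drawn from a dataset's plan
recall_cues <- function(dataset, context, reps, cue_length, seed) {
  plan <- dataset$plans[[context]]$values
  with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      noisy <- add_channel_noise(plan, dataset$noise_sd)
      noisy[seq_len(cue_length), , drop = FALSE]
    })
  })
}

recalled_ee_path <- function(pred_denorm, model_kind, info) {
  if (model_kind == "s_to_m") {
    two_link_fk(pred_denorm)       # predicted joints -> planar positions
  } else {
    pred_denorm[, info$role == "ee", drop = FALSE]
  }
}

#' Follow-through memory-separation experiment
#'
#' For each cue-availability condition and seed: generate the follow-through
#' dataset, train the skill memory and both recurrent baselines on the same
#' normalised trials, recall offline from first-step cues (averaging the
#' recalled trajectory over `recall_reps` noisy cue draws per context), and
#' score the directional compensatory deviation of each averaged path.
#'
#' @param conditions which cue conditions to run (default all three).
#' @param seeds integer seeds (default `1:6`).
#' @param n_hidden hidden units for every network.
#' @param tpc_epochs skill-memory training epochs per condition.
#' @param rnn_trials baseline training presentations.
#' @param rnn_optimiser optimiser for the baselines (see [rnn_config()]).
#' @param rnn_lr baseline learning rate (default 1e-3 with Adam, which
#'   converges within the 1200-presentation budget at this problem size).
#' @param n_trials demonstration trials per context.
#' @param recall_reps noisy cue draws averaged per recall (default 24).
#' @param cue_length cued steps `T_n` for the skill memory (default 1,
#'   matching the baselines' first-step-only input).
#' @param models which models to evaluate.
#' @return A `followthrough_experiment` list: `dcd` (tibble `model`,
#'   `condition`, `seed`, `context`, `dcd`), `separation` (the
#'   [memory_separation_test()] summary), `amplitude`, and `fits` (per
#'   condition and seed, the trained models and dataset).
#' @export
run_followthrough_experiment <- function(conditions = c("planning_only",
                                                        "planning_and_execution",
                                                        "execution_only"),
                                         seeds = 1:6, n_hidden = 64L,
                                         tpc_epochs = 400L,
                                         rnn_trials = 2400L,
                                         rnn_optimiser = "adam",
                                         rnn_lr = 1e-3,
                                         n_trials = 12L, recall_reps = 24L,
                                         cue_length = 1L,
                                         models = c("tpc", "s_to_m",
                                                    "sm_to_sm")) {
  info <- followthrough_channel_info()
  fits <- list()
  rows <- list()
  amplitude <- NULL
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    fits[[cond]] <- list()
    for (seed in seeds) {
      ds <- make_followthrough_dataset(cond, n_trials = n_trials,
                                       seed = seed * 1000L + ci)
      amplitude <- ds$amplitude
      norm <- zscore_normalise(ds$trials)
      fit <- list(dataset = ds, scaling = norm$scaling)

      if ("tpc" %in% models) {
        cfg <- tpc_config(n_obs = nrow(info), n_hidden = n_hidden,
                          epochs_per_skill = tpc_epochs, seed = seed)
        fit$tpc <- memorise(tpc_model(cfg, channels = info$channel,
                                      roles = info$role),
                            norm$trials, epochs = tpc_epochs)
      }
      for (kind in intersect(models, c("s_to_m", "sm_to_sm"))) {
        rcfg <- rnn_config(kind, info$channel, info$role,
                           n_hidden = n_hidden, n_trials = rnn_trials,
                           lr = rnn_lr,
                           optimiser = rnn_optimiser, seed = seed)
        fit[[kind]] <- train_bptt(rcfg, norm$trials)
      }
      fits[[cond]][[as.character(seed)]] <- fit

      for (ctx in ds$contexts) {
        cues <- recall_cues(ds, ctx, recall_reps, cue_length,
                            seed = seed * 7919L + ci)
        for (mk in models) {
          paths <- lapply(cues, function(cue) {
            cue_n <- zscore_apply(cue, norm$scaling)
            if (mk == "tpc") {
              pred <- offline_recall(fit$tpc, cue_n, ds$n_steps)$predicted
              idx <- seq_len(ncol(pred))
            } else {
              pred <- offline_recall_rnn(fit[[mk]], cue_n[1, ], ds$n_steps)
              idx <- fit[[mk]]$config$output_idx
            }
            zscore_denormalise(pred, norm$scaling[idx, ])
          })
          mean_path <- Reduce(`+`, paths) / length(paths)
          ee <- recalled_ee_path(mean_path, mk, info)
          rows[[length(rows) + 1]] <- tibble::tibble(
            model = mk, condition = cond, seed = seed, context = ctx,
            dcd = dcd(ee, ds$S, ds$T_pt, ctx)$value)
        }
      }
    }
  }
  dcd_tbl <- dplyr::bind_rows(rows)
  structure(list(dcd = dcd_tbl,
                 separation = memory_separation_test(dcd_tbl),
                 amplitude = amplitude, fits = fits),
            class = "followthrough_experiment")
}

#' @export
print.followthrough_experiment <- function(x, ...) {
  cat("<followthrough_experiment>\n")
  print(x$separation)
  invisible(x)
}

#' Speed-accuracy experiment
#'
#' Probes recall accuracy as a function of the number of cued inference
#' iterations, using trained planning-condition fits (the skill memory's
#' "preparation time" knob), and the matching flat probe of the recurrent
#' baselines.
#'
#' @param fits the `fits` entry of a [run_followthrough_experiment()] for
#'   one condition (a list keyed by seed), or `NULL` to train fresh
#'   planning-only fits.
#' @param seeds seeds to use when training fresh fits.
#' @param iteration_grid inference iteration counts to probe.
#' @param cue_length cued steps for the skill memory.
#' @param ... passed to [run_followthrough_experiment()] when training
#'   fresh fits.
#' @return A `speed_accuracy_experiment` list: `curve` (tibble `model`,
#'   `seed`, `inference_iters`, `recall_mse`) and `median_curve`.
#' @export
run_speed_accuracy <- function(fits = NULL, seeds = 1:6,
                               iteration_grid = c(1, 2, 5, 10, 30, 100),
                               cue_length = 1L, ...) {
  if (is.null(fits)) {
    fits <- run_followthrough_experiment(conditions = "planning_only",
                                         seeds = seeds, ...)$fits$planning_only
  }
  info <- followthrough_channel_info()
  score_idx <- which(info$role %in% c("ee", "joint"))
  rows <- purrr::imap_dfr(fits, function(fit, seed_chr) {
    seed <- as.integer(seed_chr)
    ds <- fit$dataset
    out <- list()
    for (ctx in ds$contexts) {
      plan_n <- zscore_apply(ds$plans[[ctx]]$values, fit$scaling)
      if (!is.null(fit$tpc)) {
        cur <- speed_accuracy_curve(fit$tpc,
                                    plan_n[seq_len(cue_length), , drop = FALSE],
                                    plan_n, iteration_grid,
                                    channels = score_idx)
        out[[length(out) + 1]] <- dplyr::mutate(cur, model = "tpc",
                                                seed = seed, context = ctx)
      }
      for (kind in intersect(names(fit), c("s_to_m", "sm_to_sm"))) {
        cur <- speed_accuracy_probe(fit[[kind]], plan_n[1, ], plan_n,
                                    iteration_grid)
        out[[length(out) + 1]] <- dplyr::mutate(cur, model = kind,
                                                seed = seed, context = ctx)
      }
    }
    dplyr::bind_rows(out)
  })
  curve <- rows |>
    dplyr::group_by(.data$model, .data$seed, .data$inference_iters) |>
    dplyr::summarise(recall_mse = mean(.data$recall_mse), .groups = "drop")
  median_curve <- curve |>
    dplyr::group_by(.data$model, .data$inference_iters) |>
    dplyr::summarise(median_mse = median(.data$recall_mse), .groups = "drop")
  structure(list(curve = curve, median_curve = median_curve),
            class = "speed_accuracy_experiment")
}

#' @export
print.speed_accuracy_experiment <- function(x, ...) {
  cat("<speed_accuracy_experiment>\n")
  print(tidyr::pivot_wider(x$median_curve, names_from = "inference_iters",
                           values_from = "median_mse"))
  invisible(x)
}

#' Read and validate an experiment configuration
#'
#' Experiment configurations are plain YAML with a `task` field
#' (`"faults"`, `"followthrough"` or `"speed_accuracy"`) plus parameter
#' overrides for the corresponding `run_*` function; [run_experiment()]
#' dispatches on the task. A stored configuration plus a seed reproduces a
#' run exactly.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$task) ||
      !cfg$task %in% c("faults", "followthrough", "speed_accuracy")) {
    abort("config must set task to faults, followthrough or speed_accuracy.")
  }
  cfg
}

#' @rdname read_experiment_config
#' @param config a configuration list.
#' @param seed master seed (overrides any seed in the config).
#' @param out_dir optional output directory; when given, result tables are
#'   written as CSV, thresholds as JSON and models via [write_model()], with
#'   a `manifest.json` recording the resolved configuration and seed.
#' @export
run_experiment <- function(config, seed = 1L, out_dir = NULL) {
  task <- config$task
  pars <- config[setdiff(names(config), c("task", "seed", "seeds"))]
  result <- switch(task,
    faults = do.call(run_fault_experiment, c(list(seed = seed), pars)),
    followthrough = do.call(run_followthrough_experiment,
                            c(list(seeds = seed + 0:5), pars)),
    speed_accuracy = do.call(run_speed_accuracy,
                             c(list(seeds = seed + 0:5), pars)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(task = task, seed = seed, config = config,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (task == "faults") {
      write.csv(result$grid, file.path(out_dir, "fault_grid.csv"),
                row.names = FALSE)
      write.csv(result$summary, file.path(out_dir, "summary.csv"),
                row.names = FALSE)
      write_threshold_json(result$thresholds$neural_asm,
                           file.path(out_dir, "threshold_neural_asm.json"))
      write_threshold_json(result$thresholds$zscore_baseline,
                           file.path(out_dir, "threshold_baseline.json"))
      write_model(result$memory$model, file.path(out_dir, "model.rds"))
    } else if (task == "followthrough") {
      write.csv(result$dcd, file.path(out_dir, "dcd.csv"), row.names = FALSE)
      write.csv(result$separation, file.path(out_dir, "separation.csv"),
                row.names = FALSE)
    } else {
      write.csv(result$curve, file.path(out_dir, "speed_accuracy.csv"),
                row.names = FALSE)
      write.csv(result$median_curve,
                file.path(out_dir, "speed_accuracy_median.csv"),
                row.names = FALSE)
    }
  }
  result
}
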