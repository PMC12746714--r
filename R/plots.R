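#' @export
autoplot.tpc_model <- function(object, ...) {
  ggplot(object$energy_curve, aes(x = .data$epoch, y = .data$mean_energy)) +
    geom_line(colour = "#2c7fb8") +
    labs(x = "epoch", y = "mean per-step energy",
         title = "Memorisation energy curve") +
    theme_minimal()
}

#' @export
autoplot.tpc_monitor <- function(object, threshold = NULL, dt = 0.5, ...) {
  df <- tibble::tibble(step = seq_along(object$energies) - 1L,
                       time_s = (seq_along(object$energies) - 1L) * dt,
                       energy = object$energies)
  p <- ggplot(df, aes(x = .data$time_s, y = .data$energy)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "time (s)", y = "energy", title = "Monitoring energy trace") +
    theme_minimal()
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "energy_threshold")) threshold$threshold
           else threshold
    p <- p + geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "#d95f02")
  }
  p
}

#' @export
autoplot.fault_grid_eval <- function(object, ...) {
  df <- object |>
    dplyr::group_by(.data$method, .data$joint, .data$fault_time_s) |>
    dplyr::summarise(detection_rate = mean(.data$detected), .groups = "drop")
  ggplot(df, aes(x = .data$fault_time_s, y = factor(.data$joint),
                 fill = .data$detection_rate)) +
    geom_tile() +
    facet_wrap(~.data$method) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "fault time (s)", y = "locked joint", fill = "detection rate") +
    theme_minimal()
}

#' @export
autoplot.followthrough_experiment <- function(object, ...) {
  ggplot(object$dcd, aes(x = .data$condition, y = .data$dcd,
                         colour = .data$model)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                 position = position_dodge(width = 0.4)) +
    labs(y = "directional compensatory deviation (m)", x = NULL) +
    theme_minimal()
}

#' @export
autoplot.speed_accuracy_experiment <- function(object, ...) {
  ggplot(object$median_curve, aes(x = .data$inference_iters,
                                  y = .data$median_mse,
                                  colour = .data$model)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "inference iterations (preparation time)",
         y = "median recall MSE") +
    theme_minimal()
}

#' Plot recalled against demonstrated end-effector paths
#'
#' @param paths named list of `n x 2` end-effector paths (metres).
#' @param S,T_pt start and target points to annotate.
#' @return A ggplot object.
#' @export
plot_ee_paths <- function(paths, S = NULL, T_pt = NULL) {
  df <- purrr::imap_dfr(paths, function(p, nm) {
    tibble::tibble(label = nm, x = p[, 1], y = p[, 2],
                   step = seq_len(nrow(p)))
  })
  p <- ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_path() + geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)") +
    theme_minimal()
  if (!is.null(S)) {
    anno <- tibble::tibble(x = c(S[1], T_pt[1]), y = c(S[2], T_pt[2]),
                           what = c("S", "T"))
    p <- p + geom_point(data = anno, aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 4, size = 3) +
      geom_text(data = anno, aes(x = .data$x, y = .data$y,
                                 label = .data$what),
                inherit.aes = FALSE, nudge_x = 0.004)
  }
  p
}
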