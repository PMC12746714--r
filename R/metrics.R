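#' Directional compensatory deviation (DCD)
#'
#' Quantifies whether a recalled reach deviates in the direction that would
#' correctly compensate the context's force field. With unit vector `u`
#' along the start-target line and `n` its +90-degree rotation, the signed
#' perpendicular deviation at step `t` is `d_t = n . (P_t - S)`; the DCD is
#' the deviation of maximum magnitude over the pre-target window — the
#' steps up to the path's closest approach to the target, so a
#' follow-through leg past the target cannot dominate — projected onto the
#' axis of correct compensation, `c * d_t*`. The compensation sign `c` maps
#' the context's correct direction onto `n`: `+1` for the clockwise field
#' (compensated leftward, i.e. along `+n`), `-1` for the counter-clockwise
#' field. Positive DCD means the trajectory bows the right way; a bow of
#' amplitude `a` in the wrong direction scores `-a`.
#'
#' @param path `n x 2` matrix of end-effector points.
#' @param S,T_pt start and target points (length-2).
#' @param context `"cw"` or `"ccw"`.
#' @return A `dcd_result` list: `value`, `context`, `sign`, `deviations`
#'   (per-step signed perpendicular deviation), `window` (indices scored),
#'   `S`, `T_pt`.
#' @export
dcd <- function(path, S, T_pt, context = c("cw", "ccw")) {
  context <- match.arg(context)
  path <- matrix(path, ncol = 2)
  if (nrow(path) < 2) abort("`path` needs at least 2 points.")
  if (all(S == T_pt)) abort("`S` and `T_pt` must differ.")
  u <- (T_pt - S) / sqrt(sum((T_pt - S)^2))
  n_hat <- c(-u[2], u[1])
  rel <- sweep(path, 2, S)
  d <- drop(rel %*% n_hat)
  dist_T <- sqrt(rowSums(sweep(path, 2, T_pt)^2))
  window <- seq_len(which.min(dist_T))
  sgn <- context_sign(context)
  peak <- which.max(abs(d[window]))
  structure(list(value = sgn * d[window][peak], context = context, sign = sgn,
                 deviations = d, window = window, S = S, T_pt = T_pt),
            class = "dcd_result")
}

#' @export
print.dcd_result <- function(x, ...) {
  cat(sprintf("<dcd> %.5f (%s context, %d of %d steps scored)\n",
              x$value, x$context, length(x$window), length(x$deviations)))
  invisible(x)
}

#' Recall mean squared error
#'
#' @param predicted,truth matrices (or [sm_sequence()]) of equal dimensions.
#' @param channels optional channel names (or column indices) to score; the
#'   default scores every column.
#' @return A list with `total` (mean over the scored channels) and
#'   `per_channel` (tibble `channel`, `mse`).
#' @export
recall_mse <- function(predicted, truth, channels = NULL) {
  predicted <- as_value_matrix(predicted)
  truth <- as_value_matrix(truth)
  if (!all(dim(predicted) == dim(truth))) {
    abort("`predicted` and `truth` must have identical dimensions.")
  }
  if (!is.null(channels)) {
    predicted <- predicted[, channels, drop = FALSE]
    truth <- truth[, channels, drop = FALSE]
  }
  sq <- (predicted - truth)^2
  cn <- colnames(sq)
  if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(sq)))
  list(total = mean(sq),
       per_channel = tibble::tibble(channel = cn, mse = colMeans(sq)))
}

#' Memory-separation summary across seeds
#'
#' Summarises per-seed DCD values for each model and condition: the mean
#' DCD and a one-sided Wilcoxon signed-rank test of DCD > 0 across seeds
#' (each seed contributes its mean over contexts). Planning conditions are
#' expected significantly positive; the execution-only condition is not.
#'
#' @param dcd_tbl tibble with columns `model`, `condition`, `seed`,
#'   `context`, `dcd`.
#' @param alpha significance level (default 0.05).
#' @return Tibble with one row per model and condition: `n_seeds`,
#'   `mean_dcd`, `p_value`, `significant`.
#' @export
memory_separation_test <- function(dcd_tbl, alpha = 0.05) {
  dcd_tbl |>
    dplyr::group_by(.data$model, .data$condition, .data$seed) |>
    dplyr::summarise(dcd = mean(.data$dcd), .groups = "drop") |>
    dplyr::group_by(.data$model, .data$condition) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      mean_dcd = mean(.data$dcd),
      p_value = suppressWarnings(
        wilcox.test(.data$dcd, mu = 0, alternative = "greater",
                    exact = TRUE)$p.value),
      .groups = "drop") |>
    dplyr::mutate(significant = .data$p_value < alpha)
}

#' Speed-accuracy curve of the skill memory
#'
#' Expresses a stored skill with different numbers of cued inference
#' iterations (the model's "motor preparation time") and scores the recall
#' error of each expression; fewer iterations leave the hidden state
#' incompletely inferred and recall less accurate.
#'
#' @param model a trained [tpc_model()].
#' @param cue cue matrix (first `T_n` normalised observations).
#' @param truth full normalised ground-truth sequence.
#' @param iteration_grid inference iteration counts to probe.
#' @param channels optional channel subset to score.
#' @return Tibble with `inference_iters` and `recall_mse`.
#' @export
speed_accuracy_curve <- function(model, cue, truth,
                                 iteration_grid = c(1, 2, 5, 10, 30, 100),
                                 channels = NULL) {
  truth <- as_value_matrix(truth)
  purrr::map_dfr(iteration_grid, function(it) {
    rec <- offline_recall(model, cue, nrow(truth), inference_iters = it)
    tibble::tibble(inference_iters = it,
                   recall_mse = recall_mse(rec$predicted, truth,
                                           channels)$total)
  })
}
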