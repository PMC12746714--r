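#' Configuration of the recurrent (BPTT) baselines
#'
#' Two sequence-to-sequence baselines bracket the skill memory in the
#' follow-through comparison: a sensory-to-motor network (`"s_to_m"`: input
#' = sensory channels, output = motor channels) and a
#' sensorimotor-to-sensorimotor network (`"sm_to_sm"`: all channels to all
#' channels). Both are vanilla tanh recurrent cells trained by
#' backpropagation through time in the offline-recall regime itself: the
#' network receives a real input only at the first time step — zeros
#' afterwards for `s_to_m`, its own fed-back predictions for `sm_to_sm` —
#' and is trained to reproduce the remaining sequence. They share the skill
#' memory's hidden size, learning rate, iteration budget and batch size, but
#' have no iterative-inference phase.
#'
#' @param kind `"s_to_m"` or `"sm_to_sm"`.
#' @param channels channel names of the sequences the model will see.
#' @param roles channel roles (see [sm_sequence()]); motor = `"joint"`,
#'   sensory = everything else.
#' @param n_hidden hidden units (default 256).
#' @param lr learning rate (default 1e-4).
#' @param n_trials training presentations (default 1200).
#' @param optimiser `"sgd"` (plain stochastic gradient descent, default) or
#'   `"adam"`.
#' @param seed integer seed for weight initialisation.
#' @return An `rnn_config` list.
#' @export
rnn_config <- function(kind = c("s_to_m", "sm_to_sm"), channels, roles,
                       n_hidden = 256L, lr = 1e-4, n_trials = 1200L,
                       optimiser = c("sgd", "adam"), seed = 1L) {
  kind <- match.arg(kind)
  optimiser <- match.arg(optimiser)
  stopifnot(length(channels) == length(roles), n_hidden >= 1, lr > 0)
  motor <- which(roles == "joint")
  sensory <- which(roles != "joint")
  if (kind == "s_to_m") {
    input_idx <- sensory
    output_idx <- motor
  } else {
    input_idx <- seq_along(channels)
    output_idx <- seq_along(channels)
  }
  structure(list(kind = kind, channels = channels, roles = roles,
                 input_idx = input_idx, output_idx = output_idx,
                 n_hidden = as.integer(n_hidden), lr = lr,
                 n_trials = as.integer(n_trials), optimiser = optimiser,
                 seed = as.integer(seed)),
            class = "rnn_config")
}

rnn_init <- function(config) {
  with_seed(config$seed, {
    list(W_xh = kaiming_uniform(config$n_hidden, length(config$input_idx)),
         W_hh = kaiming_uniform(config$n_hidden, config$n_hidden),
         W_hy = kaiming_uniform(length(config$output_idx), config$n_hidden))
  })
}

# forward pass in the offline-recall regime; returns predictions and, when
# keep = TRUE, the internal activities needed for BPTT
rnn_forward <- function(w, config, x0, horizon, keep = FALSE) {
  n_in <- length(config$input_idx)
  n_out <- length(config$output_idx)
  H <- matrix(0, horizon, config$n_hidden)   # h_1 .. h_{T-1} in rows 2..T
  U <- matrix(0, horizon, n_in)              # input actually fed at each step
  Y <- matrix(0, horizon, n_out)
  Y[1, ] <- x0[config$output_idx]
  U[1, ] <- x0[config$input_idx]
  h <- numeric(config$n_hidden)
  for (t in 2:horizon) {
    u <- U[t - 1, ]
    h <- tanh(drop(w$W_xh %*% u) + drop(w$W_hh %*% h))
    H[t, ] <- h
    Y[t, ] <- drop(w$W_hy %*% h)
    if (t < horizon) {
      if (config$kind == "sm_to_sm") U[t, ] <- Y[t, ]  # autoregressive feedback
      # s_to_m: zero sensory input after the first step (U stays 0)
    }
  }
  if (keep) list(Y = Y, H = H, U = U) else Y
}

# gradients of the mean-squared recall loss by backpropagation through time,
# including the feedback path through fed-back predictions for sm_to_sm
rnn_bptt_grads <- function(w, config, fwd, target) {
  horizon <- nrow(target)
  n_out <- length(config$output_idx)
  denom <- (horizon - 1) * n_out
  gW_xh <- matrix(0, nrow(w$W_xh), ncol(w$W_xh))
  gW_hh <- matrix(0, nrow(w$W_hh), ncol(w$W_hh))
  gW_hy <- matrix(0, nrow(w$W_hy), ncol(w$W_hy))
  da_next <- numeric(config$n_hidden)
  for (t in horizon:2) {
    dy <- 2 * (fwd$Y[t, ] - target[t, ]) / denom
    if (config$kind == "sm_to_sm" && t < horizon) {
      dy <- dy + drop(t(w$W_xh) %*% da_next)  # Y[t] was the next step's input
    }
    gW_hy <- gW_hy + dy %o% fwd$H[t, ]
    dh <- drop(t(w$W_hy) %*% dy) + drop(t(w$W_hh) %*% da_next)
    da <- dh * (1 - fwd$H[t, ]^2)
    gW_xh <- gW_xh + da %o% fwd$U[t - 1, ]
    h_prev <- if (t > 2) fwd$H[t - 1, ] else numeric(config$n_hidden)
    gW_hh <- gW_hh + da %o% h_prev
    da_next <- da
  }
  list(W_xh = gW_xh, W_hh = gW_hh, W_hy = gW_hy)
}

#' Train a recurrent baseline by backpropagation through time
#'
#' Presents the (normalised) sequences one at a time in round-robin order
#' for `n_trials` presentations, minimising the mean squared error of the
#' recalled sequence against the demonstration. Fixed seeds give
#' bit-reproducible training.
#'
#' @param config an [rnn_config()].
#' @param sequences list of [sm_sequence()] (or matrices) in normalised units.
#' @param n_trials override of the config's presentation budget.
#' @return An `rnn_model` list with the weights, config and a `loss_curve`
#'   tibble.
#' @export
train_bptt <- function(config, sequences, n_trials = NULL) {
  stopifnot(inherits(config, "rnn_config"))
  n_trials <- if (is.null(n_trials)) config$n_trials else as.integer(n_trials)
  mats <- lapply(sequences, as_value_matrix)
  if (length(mats) == 0) abort("`sequences` must be non-empty.")
  w <- rnn_init(config)
  adam <- config$optimiser == "adam"
  if (adam) {
    m <- v <- lapply(w, function(x) x * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  }
  losses <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    X <- mats[[(k - 1L) %% length(mats) + 1L]]
    fwd <- rnn_forward(w, config, X[1, ], nrow(X), keep = TRUE)
    target <- X[, config$output_idx, drop = FALSE]
    losses[k] <- mean((fwd$Y[-1, , drop = FALSE] - target[-1, , drop = FALSE])^2)
    if (!is.finite(losses[k])) {
      abort(sprintf("training diverged at trial %d", k))
    }
    g <- rnn_bptt_grads(w, config, fwd, target)
    for (nm in names(w)) {
      if (adam) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^k)
        vhat <- v[[nm]] / (1 - b2^k)
        w[[nm]] <- w[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      } else {
        w[[nm]] <- w[[nm]] - config$lr * g[[nm]]
      }
    }
  }
  structure(list(config = config, W_xh = w$W_xh, W_hh = w$W_hh,
                 W_hy = w$W_hy,
                 loss_curve = tibble::tibble(trial = seq_len(n_trials),
                                             loss = losses)),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("<rnn_model> %s, %d hidden, trained %d trials (final loss %.4g)\n",
              x$config$kind, x$config$n_hidden, nrow(x$loss_curve),
              tail(x$loss_curve$loss, 1)))
  invisible(x)
}

#' @export
tidy.rnn_model <- function(x, ...) x$loss_curve

#' @export
glance.rnn_model <- function(x, ...) {
  tibble::tibble(kind = x$config$kind, n_hidden = x$config$n_hidden,
                 optimiser = x$config$optimiser,
                 trials = nrow(x$loss_curve),
                 final_loss = tail(x$loss_curve$loss, 1))
}

#' Offline recall from a recurrent baseline
#'
#' Generates the output sequence from the first-step observation alone:
#' `sm_to_sm` feeds its own predictions back autoregressively, `s_to_m`
#' receives zero sensory input after the first step.
#'
#' @param model a trained [train_bptt()] model.
#' @param first_obs full observation vector at step 0 (normalised units).
#' @param horizon number of steps to produce.
#' @return A `horizon x n_output` matrix; row 1 carries the observed output
#'   channels of `first_obs`.
#' @export
offline_recall_rnn <- function(model, first_obs, horizon) {
  stopifnot(inherits(model, "rnn_model"), horizon >= 1)
  if (horizon == 1) {
    out <- matrix(first_obs[model$config$output_idx], 1)
    colnames(out) <- model$config$channels[model$config$output_idx]
    return(out)
  }
  w <- list(W_xh = model$W_xh, W_hh = model$W_hh, W_hy = model$W_hy)
  Y <- rnn_forward(w, model$config, first_obs, horizon)
  colnames(Y) <- model$config$channels[model$config$output_idx]
  Y
}

#' Speed-accuracy probe of a recurrent baseline
#'
#' The baselines have no iterative-inference phase, so there is no
#' "preparation time" knob to turn: the probe recalls once and reports the
#' same error for every requested iteration count, formalising the
#' prediction that no speed-accuracy trade-off exists for these models.
#'
#' @param model a trained [train_bptt()] model.
#' @param first_obs full observation vector at step 0 (normalised units).
#' @param target matrix of the ground-truth sequence (normalised units, all
#'   channels).
#' @param iteration_grid requested "inference iteration" counts.
#' @return Tibble with `inference_iters` and a constant `recall_mse`.
#' @export
speed_accuracy_probe <- function(model, first_obs, target,
                                 iteration_grid = c(2, 100)) {
  target <- as_value_matrix(target)
  Y <- offline_recall_rnn(model, first_obs, nrow(target))
  truth <- target[, model$config$output_idx, drop = FALSE]
  err <- mean((Y[-1, , drop = FALSE] - truth[-1, , drop = FALSE])^2)
  tibble::tibble(inference_iters = iteration_grid, recall_mse = err)
}
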