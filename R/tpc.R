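#' Configuration of the temporal predictive coding network
#'
#' The two-layer network stores every skill in one pair of weight matrices:
#' `W_H` (`n_hidden x n_hidden`) predicts the next hidden state from the
#' current one, and `W_F` (`n_obs x n_hidden`) predicts the observation from
#' the hidden state. Learning minimises, per time step, the energy
#' \deqn{F_\mu = \|z^\mu - W_H f(\hat z^{\mu-1})\|^2 + \|x^\mu - W_F f(z^\mu)\|^2}
#' by iterative (explicit-Euler) descent on the hidden activities followed by
#' local, Hebbian-like weight updates.
#'
#' @param n_obs number of observation channels.
#' @param n_hidden number of hidden value neurons (default 256).
#' @param activation `"tanh"` (default) or `"linear"`; the linear choice
#'   exists so inference can be checked against a closed-form solve.
#' @param inference_lr step size of the value-neuron dynamics (default 1e-2).
#' @param inference_iters iterations of the value-neuron dynamics per time
#'   step (default 100).
#' @param weight_lr learning rate for `W_H` and `W_F` (default 1e-4).
#' @param epochs_per_skill full-sequence presentations per skill (default
#'   1000); one epoch presents every skill once in round-robin order.
#' @param batch_size trials per weight update (default 1; the only supported
#'   value, kept explicit for transparency).
#' @param seed integer seed controlling weight initialisation.
#' @return A `tpc_config` list.
#' @export
tpc_config <- function(n_obs, n_hidden = 256L, activation = c("tanh", "linear"),
                       inference_lr = 1e-2, inference_iters = 100L,
                       weight_lr = 1e-4, epochs_per_skill = 1000L,
                       batch_size = 1L, seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(n_obs >= 1, n_hidden >= 1, inference_iters >= 1,
            inference_lr > 0, weight_lr > 0, epochs_per_skill >= 0,
            batch_size == 1L)
  structure(list(n_obs = as.integer(n_obs), n_hidden = as.integer(n_hidden),
                 activation = activation, inference_lr = inference_lr,
                 inference_iters = as.integer(inference_iters),
                 weight_lr = weight_lr,
                 epochs_per_skill = as.integer(epochs_per_skill),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "tpc_config")
}

act_fun <- function(name) if (name == "tanh") tanh else identity
act_deriv_fun <- function(name) {
  if (name == "tanh") function(v) 1 - tanh(v)^2 else function(v) rep(1, length(v))
}
act_code <- function(name) if (name == "tanh") 1L else 0L

kaiming_uniform <- function(n_out, n_in) {
  bound <- sqrt(6 / n_in)
  matrix(runif(n_out * n_in, -bound, bound), n_out, n_in)
}

#' Create a (untrained) temporal predictive coding model
#'
#' Weights are drawn with Kaiming-uniform initialisation from the seed stored
#' in the configuration, so model construction is bit-reproducible.
#'
#' @param config a [tpc_config()].
#' @param channels optional character vector of observation channel names.
#' @param roles optional character vector of channel roles (see
#'   [sm_sequence()]).
#' @return A `tpc_model` object.
#' @export
tpc_model <- function(config, channels = NULL, roles = NULL) {
  stopifnot(inherits(config, "tpc_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  W_H <- kaiming_uniform(config$n_hidden, config$n_hidden)
  W_F <- kaiming_uniform(config$n_obs, config$n_hidden)
  structure(list(W_H = W_H, W_F = W_F, config = config,
                 channels = channels, roles = roles,
                 epochs_trained = 0L,
                 energy_curve = tibble::tibble(epoch = integer(),
                                               mean_energy = numeric())),
            class = "tpc_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tpc_model <- function(x, ...) {
  cat(sprintf("<tpc_model> %d hidden, %d observation channels, %s activation\n",
              x$config$n_hidden, x$config$n_obs, x$config$activation))
  cat(sprintf("  trained for %d epochs%s\n", x$epochs_trained,
              if (x$epochs_trained > 0)
                sprintf(" (final mean energy %.4g)",
                        tail(x$energy_curve$mean_energy, 1)) else ""))
  invisible(x)
}

#' Per-step network state and energy
#'
#' `step_state()` assembles the prediction errors and energy for given hidden
#' and observation activities; `step_energy()` evaluates the energy
#' \eqn{\|\epsilon_z\|^2 + \|\epsilon_x\|^2} directly. These are the
#' quantities descended during inference and learning.
#'
#' @param x observation vector (length `n_obs`).
#' @param z hidden value-neuron vector (length `n_hidden`).
#' @param z_prev converged hidden state of the previous step.
#' @param model a [tpc_model()].
#' @return `step_state()` returns a `tpc_state` list with `z`, `z_prev`, `x`,
#'   `eps_z`, `eps_x` and `energy`; `step_energy()` returns a non-negative
#'   scalar.
#' @export
step_state <- function(x, z, z_prev, model) {
  cfg <- model$config
  if (length(x) != cfg$n_obs || length(z) != cfg$n_hidden ||
      length(z_prev) != cfg$n_hidden) {
    abort("vector lengths do not match the model's dimensions.")
  }
  f <- act_fun(cfg$activation)
  eps_z <- z - drop(model$W_H %*% f(z_prev))
  eps_x <- x - drop(model$W_F %*% f(z))
  structure(list(x = x, z = z, z_prev = z_prev, eps_z = eps_z, eps_x = eps_x,
                 energy = sum(eps_z^2) + sum(eps_x^2)),
            class = "tpc_state")
}

#' @rdname step_state
#' @param state a `tpc_state` from [step_state()].
#' @export
step_energy <- function(state) {
  stopifnot(inherits(state, "tpc_state"))
  sum(state$eps_z^2) + sum(state$eps_x^2)
}

#' Iterative hidden-state inference at one time step
#'
#' Runs `iters` explicit-Euler steps of the value-neuron dynamics
#' \deqn{\dot z \propto -\epsilon_z + f'(z) \odot W_F^\top \epsilon_x}
#' starting from the temporal prediction \eqn{W_H f(z_{prev})} (so the
#' hidden-temporal error is zero at initialisation).
#'
#' @inheritParams step_state
#' @param iters number of iterations (defaults to the config value).
#' @param lr inference step size (defaults to the config value).
#' @return A list with `z` (converged hidden state) and `energies` (energy at
#'   initialisation and after each iteration, length `iters + 1`).
#' @export
infer_hidden <- function(x, z_prev, model, iters = NULL, lr = NULL) {
  cfg <- model$config
  iters <- if (is.null(iters)) cfg$inference_iters else as.integer(iters)
  lr <- if (is.null(lr)) cfg$inference_lr else lr
  stopifnot(iters >= 1)
  if (length(x) != cfg$n_obs || length(z_prev) != cfg$n_hidden) {
    abort("vector lengths do not match the model's dimensions.")
  }
  out <- tpc_infer_cpp(x, z_prev, model$W_H, model$W_F, iters, lr,
                       act_code(cfg$activation))
  list(z = drop(out$z), energies = drop(out$energies))
}

#' Local weight update at one time step
#'
#' Applies the Hebbian-like gradient step on the per-step energy:
#' `W_H <- W_H + lr * eps_z %o% f(z_prev)` and
#' `W_F <- W_F + lr * eps_x %o% f(z)`. The update touches nothing but the two
#' weight matrices and depends only on quantities local to step `mu` and the
#' converged state of step `mu - 1`.
#'
#' @param state a `tpc_state` holding the converged activities for the step.
#' @param model a [tpc_model()].
#' @param lr learning rate (defaults to the config's `weight_lr`).
#' @return The updated `tpc_model`.
#' @export
update_weights <- function(state, model, lr = NULL) {
  stopifnot(inherits(state, "tpc_state"))
  lr <- if (is.null(lr)) model$config$weight_lr else lr
  f <- act_fun(model$config$activation)
  model$W_H <- model$W_H + lr * (state$eps_z %o% f(state$z_prev))
  model$W_F <- model$W_F + lr * (state$eps_x %o% f(state$z))
  model
}

as_value_matrix <- function(x) {
  if (inherits(x, "sm_seq")) unclass(x)[, , drop = FALSE] else as.matrix(x)
}

#' Memorise a set of sensorimotor sequences
#'
#' The memorisation phase: for each epoch and each sequence, sweep the time
#' steps in order, infer the hidden state at each step (starting each
#' sequence from a zero previous hidden state), apply the local weight
#' updates, and carry the converged hidden state forward. Skills are
#' interleaved within each epoch, so a single weight set stores all of them
#' jointly. The mean converged per-step energy (recorded after inference,
#' before the weight update) is appended to the model's energy curve.
#'
#' @param model a [tpc_model()].
#' @param sequences list of [sm_sequence()] objects (or plain matrices) with
#'   a common channel layout; expected in Z-score-normalised units (see
#'   [zscore_normalise()]).
#' @param epochs number of presentations of the full skill set (defaults to
#'   the config's `epochs_per_skill`).
#' @param engine `"cpp"` (default) or `"r"`; the R path is a step-by-step
#'   reference used to validate the compiled sweep.
#' @return The trained `tpc_model` with an updated `energy_curve`.
#' @export
memorise <- function(model, sequences, epochs = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs_per_skill else as.integer(epochs)
  if (length(sequences) == 0) abort("`sequences` must be non-empty.")
  mats <- lapply(sequences, as_value_matrix)
  if (any(vapply(mats, ncol, 1L) != cfg$n_obs)) {
    abort("all sequences must have `n_obs` channels.")
  }
  if (epochs == 0) return(model)

  if (engine == "cpp") {
    fit <- tpc_memorise_cpp(mats, model$W_H, model$W_F, epochs,
                            cfg$inference_iters, cfg$inference_lr,
                            cfg$weight_lr, act_code(cfg$activation))
    model$W_H <- fit$W_H
    model$W_F <- fit$W_F
    energies <- as.numeric(fit$epoch_energy)
  } else {
    energies <- numeric(epochs)
    n_steps <- sum(vapply(mats, nrow, 1L))
    for (e in seq_len(epochs)) {
      acc <- 0
      for (X in mats) {
        z_prev <- numeric(cfg$n_hidden)
        for (mu in seq_len(nrow(X))) {
          inf <- infer_hidden(X[mu, ], z_prev, model)
          st <- step_state(X[mu, ], inf$z, z_prev, model)
          acc <- acc + st$energy
          model <- update_weights(st, model)
          z_prev <- inf$z
        }
      }
      energies[e] <- acc / n_steps
    }
  }
  start <- model$epochs_trained
  model$epochs_trained <- start + epochs
  model$energy_curve <- dplyr::bind_rows(
    model$energy_curve,
    tibble::tibble(epoch = start + seq_len(epochs), mean_energy = energies))
  model
}

#' Offline (cued, then ballistic) recall
#'
#' The recall phase with frozen weights: the hidden state is iteratively
#' inferred from the first `T_n` cued ground-truth observations (the
#' queries), after which the remainder of the sequence is generated
#' ballistically by the forward pass `z <- W_H f(z)`, `x <- W_F f(z)` — the
#' fixed point of the observation-settling dynamics in this two-layer model.
#'
#' @param model a trained [tpc_model()].
#' @param cue matrix (or [sm_sequence()]) of the first `T_n` observation
#'   vectors, in the model's normalised units.
#' @param horizon total number of steps `T` to produce (`T > T_n`).
#' @param inference_iters optional override of the number of inference
#'   iterations used on the cued steps (the "preparation time" knob probed by
#'   the speed-accuracy analysis).
#' @return A `tpc_recall` list: `predicted` (`T x n_obs`, including the
#'   retrieved observations over the cue window), `energies` (converged
#'   energy per step; identically zero on ballistic steps, where no
#'   observation is clamped), `cue_length` and `inference_iters_used`.
#' @export
offline_recall <- function(model, cue, horizon, inference_iters = NULL) {
  cfg <- model$config
  cue <- as_value_matrix(cue)
  T_n <- nrow(cue)
  if (T_n < 1 || T_n >= horizon) {
    abort("need 1 <= cue length < horizon.")
  }
  iters <- if (is.null(inference_iters)) cfg$inference_iters
           else as.integer(inference_iters)
  f <- act_fun(cfg$activation)
  predicted <- matrix(0, horizon, cfg$n_obs)
  energies <- numeric(horizon)
  z_prev <- numeric(cfg$n_hidden)
  for (mu in seq_len(T_n)) {
    inf <- infer_hidden(cue[mu, ], z_prev, model, iters = iters)
    z_prev <- inf$z
    predicted[mu, ] <- drop(model$W_F %*% f(inf$z))
    energies[mu] <- tail(inf$energies, 1)
  }
  for (mu in seq(T_n + 1, horizon)) {
    z_prev <- drop(model$W_H %*% f(z_prev))
    predicted[mu, ] <- drop(model$W_F %*% f(z_prev))
  }
  if (!is.null(model$channels)) colnames(predicted) <- model$channels
  structure(list(predicted = predicted, energies = energies,
                 cue_length = T_n, inference_iters_used = iters),
            class = "tpc_recall")
}

#' Online (clamped, one-step-ahead) recall and monitoring
#'
#' At each step the ground-truth observation is clamped, the hidden state is
#' inferred, and the model emits its prediction for the next step. The
#' converged per-step energy is the monitoring signal used for fault
#' detection, and the absolute observation prediction errors
#' \eqn{|\epsilon_x|} are the per-channel signal used for fault isolation.
#'
#' @param model a trained [tpc_model()].
#' @param observed an [sm_sequence()] or matrix with at least 2 steps, in the
#'   model's normalised units.
#' @return A `tpc_monitor` list: `predictions` (`(T-1) x n_obs`, row `mu` is
#'   the prediction for step `mu + 1`), `energies` (length `T`),
#'   `channel_errors` (`T x n_obs` matrix of `|eps_x|`).
#' @export
online_recall <- function(model, observed) {
  cfg <- model$config
  X <- as_value_matrix(observed)
  if (nrow(X) < 2) abort("`observed` must have at least 2 steps.")
  f <- act_fun(cfg$activation)
  T_len <- nrow(X)
  energies <- numeric(T_len)
  channel_errors <- matrix(0, T_len, cfg$n_obs)
  predictions <- matrix(0, T_len - 1, cfg$n_obs)
  z_prev <- numeric(cfg$n_hidden)
  for (mu in seq_len(T_len)) {
    inf <- infer_hidden(X[mu, ], z_prev, model)
    st <- step_state(X[mu, ], inf$z, z_prev, model)
    energies[mu] <- st$energy
    channel_errors[mu, ] <- abs(st$eps_x)
    z_prev <- inf$z
    if (mu < T_len) {
      z_next <- drop(model$W_H %*% f(inf$z))
      predictions[mu, ] <- drop(model$W_F %*% f(z_next))
    }
  }
  cn <- if (!is.null(model$channels)) model$channels else colnames(X)
  colnames(channel_errors) <- cn
  colnames(predictions) <- cn
  structure(list(predictions = predictions, energies = energies,
                 channel_errors = channel_errors),
            class = "tpc_monitor")
}

#' @export
tidy.tpc_model <- function(x, ...) x$energy_curve

#' @export
glance.tpc_model <- function(x, ...) {
  tibble::tibble(n_hidden = x$config$n_hidden, n_obs = x$config$n_obs,
                 activation = x$config$activation,
                 epochs_trained = x$epochs_trained,
                 final_energy = if (x$epochs_trained > 0)
                   tail(x$energy_curve$mean_energy, 1) else NA_real_)
}

#' Save / load a fitted model
#'
#' Round-trips the full model object (weights, configuration, seed, channel
#' names, energy curve) bit-exactly through R's native serialisation.
#'
#' @param model a [tpc_model()] (or any fitted object from this package).
#' @param path file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the object.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
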