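# Shared fixtures. Heavy experiment objects are trained once per test run
# and cached, so several end-to-end checks can share one fit.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small linear-activation model with writable weights
linear_model <- function(n_obs = 3, n_hidden = 4, seed = 7, iters = 100,
                         lr = 1e-2) {
  cfg <- tpc_config(n_obs = n_obs, n_hidden = n_hidden, activation = "linear",
                    inference_iters = iters, inference_lr = lr, seed = seed)
  tpc_model(cfg)
}

# scalar model with unit weights for hand-computed cases
scalar_model <- function(W_H = 1, W_F = 1, activation = "linear") {
  cfg <- tpc_config(n_obs = 1, n_hidden = 1, activation = activation, seed = 1)
  m <- tpc_model(cfg)
  m$W_H <- matrix(W_H, 1, 1)
  m$W_F <- matrix(W_F, 1, 1)
  m
}

# a tiny trained memory over the two pick-and-place skills, for unit tests
# that need a functioning (not necessarily accurate) fitted model
tiny_skill_memory <- function() {
  cached("tiny_memory", function() {
    demos <- c(make_pick_place_demos("A", 3, seed = 11),
               make_pick_place_demos("B", 3, seed = 12))
    train_skill_memory(demos, n_hidden = 32, epochs = 40, seed = 5)
  })
}

# full-scale fault experiment shared by the end-to-end checks
acceptance_fault_experiment <- function() {
  cached("fault_experiment", function() {
    run_fault_experiment(seed = 1, epochs = 1000)
  })
}

# full follow-through experiment shared by the memory-separation and
# speed-accuracy checks
acceptance_followthrough <- function() {
  cached("followthrough", function() {
    run_followthrough_experiment(seeds = 1:6)
  })
}

expect_finite <- function(x) expect_true(all(is.finite(x)))

# per-step mean of a list of sm_seq trials, as a trial with the same layout
with_values_helper <- function(trials) {
  m <- Reduce(`+`, lapply(trials, unclass)) / length(trials)
  sm_sequence(m, channels = colnames(trials[[1]]),
              roles = attr(trials[[1]], "roles"),
              dt = attr(trials[[1]], "dt"))
}
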