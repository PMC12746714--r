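test_that("per-step energy matches its definition and scales quadratically", {
  m <- linear_model()
  set.seed(1)
  z_prev <- rnorm(4)
  # zero-error configuration: z at the temporal prediction, x at the
  # top-down prediction
  z <- drop(m$W_H %*% z_prev)
  x <- drop(m$W_F %*% z)
  st <- step_state(x, z, z_prev, m)
  expect_equal(st$energy, 0)

  # 1-d hand-computed case: z_prev = 0, z = 0.5, x = 1, unit weights
  sm <- scalar_model()
  st1 <- step_state(x = 1, z = 0.5, z_prev = 0, sm)
  expect_equal(st1$energy, 0.5)

  # scaling both error vectors by 2 (holding predictions fixed) quadruples
  # the energy
  st2 <- step_state(x = drop(sm$W_F %*% 1) + 2 * (1 - 0.5),
                    z = drop(sm$W_H %*% 0) + 2 * 0.5, z_prev = 0, sm)
  expect_equal(st2$energy, 4 * st1$energy)

  expect_error(step_state(x = c(1, 2), z = 0.5, z_prev = 0, sm), "dimension")
})

test_that("inference reduces to the temporal prediction when W_F is zero", {
  m <- linear_model()
  m$W_F <- m$W_F * 0
  set.seed(2)
  z_prev <- rnorm(4)
  inf <- infer_hidden(rnorm(3), z_prev, m, iters = 2000)
  expect_equal(inf$z, drop(m$W_H %*% z_prev), tolerance = 1e-10)
})

test_that("linear-activation inference matches the closed-form solve", {
  m <- linear_model(iters = 5000)
  set.seed(3)
  x <- rnorm(3)
  z_prev <- rnorm(4)
  inf <- infer_hidden(x, z_prev, m)
  z_star <- solve(diag(4) + crossprod(m$W_F),
                  drop(m$W_H %*% z_prev) + drop(t(m$W_F) %*% x))
  expect_equal(inf$z, drop(z_star), tolerance = 1e-6)
})

test_that("the inference update follows the negative energy gradient", {
  cfg <- tpc_config(n_obs = 3, n_hidden = 4, seed = 9)
  m <- tpc_model(cfg)
  set.seed(4)
  for (rep in 1:5) {
    x <- rnorm(3)
    z_prev <- rnorm(4)
    z <- rnorm(4)
    st <- step_state(x, z, z_prev, m)
    analytic <- -st$eps_z + (1 - tanh(z)^2) * drop(t(m$W_F) %*% st$eps_x)
    numeric <- vapply(seq_along(z), function(i) {
      zp <- z; zp[i] <- zp[i] + 1e-6
      zm <- z; zm[i] <- zm[i] - 1e-6
      -(step_state(x, zp, z_prev, m)$energy -
          step_state(x, zm, z_prev, m)$energy) / 4e-6
    }, numeric(1))
    expect_lt(max(abs(analytic - numeric)) / max(abs(numeric)), 1e-4)
  }
})

test_that("energy is non-increasing across inference iterations", {
  set.seed(5)
  for (act in c("tanh", "linear")) {
    cfg <- tpc_config(n_obs = 3, n_hidden = 4, activation = act,
                      inference_lr = 1e-2, seed = 21)
    m <- tpc_model(cfg)
    inf <- infer_hidden(rnorm(3), rnorm(4), m, iters = 200)
    expect_true(all(diff(inf$energies) <= 1e-12))
  }
})

test_that("weight updates are local outer products on the energy gradient", {
  # zero errors leave the weights untouched
  m <- linear_model()
  z_prev <- rnorm(4)
  z <- drop(m$W_H %*% z_prev)
  st <- step_state(drop(m$W_F %*% z), z, z_prev, m)
  m2 <- update_weights(st, m, lr = 0.1)
  expect_identical(m2$W_H, m$W_H)
  expect_identical(m2$W_F, m$W_F)

  # 1-d hand case: eps_z forced 0.5 with f(z_prev) = 0 -> dW_H = 0;
  # eps_x = 0.5 with f(z) = 0.5, lr = 0.1 -> dW_F = 0.025
  sm <- scalar_model()
  st1 <- step_state(x = 0.5 + 0.5, z = 0.5, z_prev = 0, sm)
  expect_equal(st1$eps_z, 0.5)
  expect_equal(st1$eps_x, 0.5)
  sm2 <- update_weights(st1, sm, lr = 0.1)
  expect_equal(sm2$W_H[1, 1] - sm$W_H[1, 1], 0)
  expect_equal(sm2$W_F[1, 1] - sm$W_F[1, 1], 0.025)

  # update direction = negative finite-difference gradient of the energy
  cfg <- tpc_config(n_obs = 3, n_hidden = 4, seed = 13)
  mt <- tpc_model(cfg)
  set.seed(6)
  x <- rnorm(3); z <- rnorm(4); z_prev <- rnorm(4)
  st <- step_state(x, z, z_prev, mt)
  up <- update_weights(st, mt, lr = 1)
  dW_H <- up$W_H - mt$W_H
  dW_F <- up$W_F - mt$W_F
  num_grad <- function(which, i, j) {
    mp <- mt; mp[[which]][i, j] <- mp[[which]][i, j] + 1e-6
    mm <- mt; mm[[which]][i, j] <- mm[[which]][i, j] - 1e-6
    (step_state(x, z, z_prev, mp)$energy -
       step_state(x, z, z_prev, mm)$energy) / 2e-6
  }
  for (idx in list(c(1, 1), c(2, 3), c(4, 2))) {
    expect_equal(dW_H[idx[1], idx[2]],
                 -num_grad("W_H", idx[1], idx[2]) / 2, tolerance = 1e-4)
  }
  for (idx in list(c(1, 1), c(2, 3), c(3, 4))) {
    expect_equal(dW_F[idx[1], idx[2]],
                 -num_grad("W_F", idx[1], idx[2]) / 2, tolerance = 1e-4)
  }
})

test_that("memorisation descends energy and the compiled sweep matches R", {
  # constant sequence, linear activation: mean epoch energy non-increasing
  X <- matrix(rep(c(0.3, -0.2), each = 6), 6, 2)
  cfg <- tpc_config(n_obs = 2, n_hidden = 3, activation = "linear",
                    inference_iters = 30, weight_lr = 1e-2, seed = 2)
  m <- memorise(tpc_model(cfg), list(X), epochs = 50)
  expect_true(all(diff(m$energy_curve$mean_energy) <= 1e-10))

  # zero epochs: model unchanged
  m0 <- tpc_model(cfg)
  expect_identical(memorise(m0, list(X), epochs = 0)$W_H, m0$W_H)

  # compiled sweep agrees with the step-by-step R reference
  set.seed(7)
  seqs <- list(matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2))
  cfg2 <- tpc_config(n_obs = 2, n_hidden = 3, inference_iters = 20, seed = 3)
  fc <- memorise(tpc_model(cfg2), seqs, epochs = 3, engine = "cpp")
  fr <- memorise(tpc_model(cfg2), seqs, epochs = 3, engine = "r")
  expect_equal(fc$W_H, fr$W_H, tolerance = 1e-12)
  expect_equal(fc$W_F, fr$W_F, tolerance = 1e-12)
  expect_equal(fc$energy_curve$mean_energy, fr$energy_curve$mean_energy,
               tolerance = 1e-12)

  expect_error(memorise(tpc_model(cfg2), list()), "non-empty")
})

test_that("offline recall reproduces a memorised short sequence", {
  # a smooth, z-scored 5-step trajectory (white noise is not a sensorimotor
  # sequence; trajectories are smooth)
  t5 <- 0:4
  X <- scale(cbind(sin(2 * pi * t5 / 8), cos(2 * pi * t5 / 8)))[, ]
  cfg <- tpc_config(n_obs = 2, n_hidden = 64, weight_lr = 5e-3, seed = 4)
  m <- memorise(tpc_model(cfg), list(X), epochs = 500)
  rec <- offline_recall(m, X[1, , drop = FALSE], 5)
  mse <- recall_mse(rec$predicted, X)
  expect_true(all(mse$per_channel$mse < 0.1))
  expect_equal(rec$cue_length, 1)
  expect_true(all(rec$energies >= 0))
  expect_error(offline_recall(m, X, 5), "cue length")
})

test_that("three jointly stored skills each recall from a two-step cue", {
  t6 <- 0:5
  skills <- list(
    scale(cbind(sin(2 * pi * t6 / 10), cos(2 * pi * t6 / 10)))[, ],
    scale(cbind(t6^1.5, rev(t6)))[, ],
    scale(cbind(cos(2 * pi * t6 / 12), t6))[, ])
  cfg <- tpc_config(n_obs = 2, n_hidden = 64, weight_lr = 5e-3, seed = 6)
  m <- memorise(tpc_model(cfg), skills, epochs = 800)
  for (X in skills) {
    rec <- offline_recall(m, X[1:2, ], nrow(X))
    expect_true(all(recall_mse(rec$predicted, X)$per_channel$mse < 0.1))
  }
})

test_that("recall with an untrained zero-weight network is silent", {
  cfg <- tpc_config(n_obs = 3, n_hidden = 4, seed = 10)
  m <- tpc_model(cfg)
  m$W_H <- m$W_H * 0
  m$W_F <- m$W_F * 0
  rec <- offline_recall(m, matrix(rnorm(3), 1), 6)
  expect_equal(rec$predicted, matrix(0, 6, 3))
})

test_that("cueing selects the matching skill memory", {
  fit <- tiny_skill_memory()
  demos_a <- make_pick_place_demos("A", 1, seed = 31)[[1]]
  demos_b <- make_pick_place_demos("B", 1, seed = 32)[[1]]
  na <- zscore_apply(demos_a, fit$scaling)
  nb <- zscore_apply(demos_b, fit$scaling)
  rec <- offline_recall(fit$model, unclass(na)[1:2, ], 15)
  mse_a <- recall_mse(rec$predicted, na)$total
  mse_b <- recall_mse(rec$predicted, nb)$total
  expect_lt(mse_a, mse_b)
})

test_that("online recall emits one-step-ahead predictions and energies", {
  fit <- tiny_skill_memory()
  trial <- zscore_apply(make_pick_place_demos("A", 1, seed = 41)[[1]],
                        fit$scaling)
  mon <- online_recall(fit$model, unclass(trial)[1:2, ])
  expect_equal(nrow(mon$predictions), 1)
  expect_length(mon$energies, 2)
  expect_finite(mon$energies)

  # a memorised sequence is less surprising than a channel-permuted copy
  full <- online_recall(fit$model, trial)
  set.seed(9)
  perm <- unclass(trial)[, sample(ncol(trial))]
  scrambled <- online_recall(fit$model, perm)
  expect_lt(mean(full$energies), mean(scrambled$energies))
})

test_that("models serialise bit-exactly", {
  fit <- tiny_skill_memory()
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(fit$model, path)
  back <- read_model(path)
  expect_identical(back$W_H, fit$model$W_H)
  expect_identical(back$W_F, fit$model$W_F)
  expect_identical(back$config, fit$model$config)
})

test_that("model construction is reproducible from its seed", {
  cfg <- tpc_config(n_obs = 5, n_hidden = 8, seed = 99)
  expect_identical(tpc_model(cfg)$W_H, tpc_model(cfg)$W_H)
  expect_identical(tpc_model(cfg)$W_F, tpc_model(cfg)$W_F)
})
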