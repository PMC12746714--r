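test_that("directional compensatory deviation matches analytic paths", {
  S <- c(0, 0); T_pt <- c(0, 0.1)
  s <- seq(0, 1, length.out = 2001)
  straight <- cbind(0 * s, 0.1 * s)
  expect_equal(dcd(straight, S, T_pt, "cw")$value, 0, tolerance = 1e-12)

  a <- 0.02
  bow_left <- cbind(-a * sin(pi * s), 0.1 * s)  # +normal of the S->T line
  expect_equal(dcd(bow_left, S, T_pt, "cw")$value, a, tolerance = 1e-6)
  expect_equal(dcd(bow_left, S, T_pt, "ccw")$value, -a, tolerance = 1e-6)
  bow_right <- cbind(a * sin(pi * s), 0.1 * s)
  expect_equal(dcd(bow_right, S, T_pt, "cw")$value, -a, tolerance = 1e-6)

  expect_error(dcd(straight, S, S, "cw"), "must differ")
})

test_that("DCD is invariant to rigid motions and mirrors with the path", {
  set.seed(1)
  S <- c(0.3, -0.2); T_pt <- c(0.1, 0.4)
  s <- seq(0, 1, length.out = 101)
  u <- (T_pt - S) / sqrt(sum((T_pt - S)^2))
  n_hat <- c(-u[2], u[1])
  path <- t(sapply(s, function(si) {
    S + si * (T_pt - S) + 0.03 * sin(pi * si) * n_hat + 0.002 * rnorm(2)
  }))
  base <- dcd(path, S, T_pt, "cw")$value
  for (rep in 1:3) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- rnorm(2)
    moved <- sweep(path %*% t(R), 2, shift, "+")
    expect_equal(dcd(moved, drop(R %*% S) + shift, drop(R %*% T_pt) + shift,
                     "cw")$value, base, tolerance = 1e-9)
  }
  # mirroring the path across the S-T line negates the DCD
  d <- drop(sweep(path, 2, S) %*% n_hat)
  mirrored <- path - 2 * d %o% n_hat
  expect_equal(dcd(mirrored, S, T_pt, "cw")$value, -base, tolerance = 1e-9)
})

test_that("the DCD window stops at the closest approach to the target", {
  S <- c(0, 0); T_pt <- c(0, 0.1)
  s <- seq(0, 1, length.out = 51)
  main <- cbind(-0.01 * sin(pi * s), 0.1 * s)
  # follow-through leg with a huge lateral excursion past the target
  leg <- cbind(seq(-0.002, -0.08, length.out = 20),
               seq(0.102, 0.14, length.out = 20))
  d <- dcd(rbind(main, leg), S, T_pt, "cw")
  expect_equal(d$value, 0.01, tolerance = 1e-4)
  expect_equal(max(d$window), 51)
})

test_that("recall error is a plain mean of squared differences", {
  A <- matrix(0, 4, 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(recall_mse(A, A)$total, 0)
  B <- A; B[, 2] <- 0.3
  r <- recall_mse(B, A)
  expect_equal(unname(r$per_channel$mse), c(0, 0.09))
  expect_equal(r$total, 0.045)
  # hand-computed 3 x 2 case
  P <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  Q <- matrix(c(2, 2, 1, 4, 4, 8), 3, 2)
  expect_equal(recall_mse(P, Q)$total, (1 + 0 + 4 + 0 + 1 + 4) / 6)
  expect_error(recall_mse(A, A[1:2, ]), "identical dimensions")
})

test_that("memory-separation testing behaves under clear and null signals", {
  pos <- tidyr::expand_grid(model = "m", condition = "planning_only",
                            seed = 1:6, context = c("cw", "ccw"))
  pos$dcd <- 0.02
  out <- memory_separation_test(pos)
  expect_true(out$significant)
  expect_equal(out$mean_dcd, 0.02)

  null <- pos
  null$dcd <- ifelse(null$seed %% 2 == 0, -0.01, 0.01)  # symmetric about 0
  null$condition <- "execution_only"
  out0 <- memory_separation_test(null)
  expect_false(out0$significant)
})

test_that("the speed-accuracy curve runs the recall at each iteration count", {
  fit <- tiny_skill_memory()
  trial <- zscore_apply(make_pick_place_demos("A", 1, seed = 51)[[1]],
                        fit$scaling)
  one <- speed_accuracy_curve(fit$model, unclass(trial)[1:2, ], trial,
                              iteration_grid = 7)
  expect_equal(nrow(one), 1)
  expect_equal(one$inference_iters, 7)
  expect_finite(one$recall_mse)
})
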