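test_that("nearest-rank thresholds make the false-positive arithmetic exact", {
  thr <- fit_threshold(1:20, 95)
  expect_equal(thr$threshold, 19)
  expect_equal(mean(1:20 > thr$threshold), 0.05)

  thr100 <- fit_threshold(1:20, 100)
  expect_equal(thr100$threshold, 20)
  expect_equal(mean(1:20 > thr100$threshold), 0)

  expect_error(fit_threshold(numeric(0), 95), "non-empty")

  # property: for distinct values and integer n * (100 - p) / 100, the
  # fraction above the threshold is exactly (100 - p)%
  set.seed(1)
  for (rep in 1:5) {
    vals <- rnorm(200)
    for (p in c(90, 95, 99)) {
      t <- fit_threshold(vals, p)
      expect_equal(mean(vals > t$threshold), (100 - p) / 100)
    }
  }
})

test_that("detection flags the first crossing at or after the fault", {
  expect_false(detect_fault(c(0.1, 0.2, 0.3), 1)$detected)
  d <- detect_fault(c(0.1, 0.2, 5, 0.2), 1)
  expect_true(d$detected)
  expect_equal(d$detection_step, 2)
  # crossings before from_step are ignored
  d2 <- detect_fault(c(5, 0.2, 0.2, 9), 1, from_step = 1)
  expect_equal(d2$detection_step, 3)
})

test_that("isolation takes the largest joint-channel error, lowest index on ties", {
  roles <- c(rep("joint", 7), rep("ee", 3))
  errs <- matrix(0, 4, 10,
                 dimnames = list(NULL, c(paste0("joint", 1:7), "x", "y", "z")))
  errs[3, 5] <- 2
  errs[3, 9] <- 9  # larger error on a non-joint channel must be ignored
  expect_equal(isolate_fault(errs, 2, roles), "joint5")
  # tie between joints 2 and 6 resolves to the lower index
  errs[3, 5] <- 0
  errs[3, 2] <- 1
  errs[3, 6] <- 1
  expect_equal(isolate_fault(errs, 2, roles), "joint2")
  expect_error(isolate_fault(errs, NA_integer_, roles), "detection")
})

test_that("the Z-score baseline statistic matches its definition", {
  demos <- list(A = make_pick_place_demos("A", 4, seed = 1),
                B = make_pick_place_demos("B", 4, seed = 2))
  stats <- channel_stats(demos)
  expect_equal(stats$granularity, "per_step")
  # scoring the stored per-step mean gives a zero statistic
  mean_trial <- with_values_helper(demos$A)
  z <- zscore_baseline(mean_trial, stats, "A")
  expect_equal(max(abs(z$statistic)), 0, tolerance = 1e-12)
  expect_error(zscore_baseline(mean_trial, stats, "C"), "unknown skill")

  # 1-channel hand case: mean 1, sd 0.5, x = 2 -> z = 2, statistic 4
  hand <- structure(list(
    stats = list(S = list(mean = 1, sd = 0.5)),
    granularity = "pooled", sd_floor = 1e-6,
    channels = "c1", roles = "joint"), class = "channel_stats")
  hz <- zscore_baseline(matrix(2, 1, 1, dimnames = list(NULL, "c1")),
                        hand, "S")
  expect_equal(unname(hz$channel_errors[1, 1]), 2)
  expect_equal(hz$statistic, 4)

  # the sd floor prevents division blow-ups on constant channels
  const <- lapply(1:3, function(i) {
    sm_sequence(matrix(1, 3, 1, dimnames = list(NULL, "c")), roles = "joint")
  })
  cs <- channel_stats(list(K = const))
  expect_true(all(cs$stats$K$sd >= 1e-6))
  zc <- zscore_baseline(const[[1]], cs, "K")
  expect_finite(zc$statistic)
})

test_that("reactive correction tracks the prediction and absorbs impulses", {
  ref <- matrix(seq(0, 14), 15, 7)  # smooth ramp on every joint
  clean <- reactive_correct(ref, gain = 0.5)
  # no disturbance: tracking error stays at the (zero) noise floor after
  # the controller settles
  late <- subset(clean, low_step > 40)
  expect_lt(max(abs(late$error)), 0.26)

  dist <- reactive_correct(ref, gain = 0.5, disturbance_step = 200,
                           disturbance_deg = c(0, 0, 5, 0, 0, 0, 0))
  j3 <- subset(dist, joint == "joint3")
  post <- j3$error[j3$low_step >= 200 & j3$low_step <= 220]
  expect_gt(abs(post[1]), 4)          # impulse lands
  expect_lt(max(abs(tail(post, 1))), 0.5)  # decays within 20 low-level steps
  expect_error(reactive_correct(ref, gain = 0), "gain")
})

test_that("a gross fault on a one-cell grid is always caught", {
  fit <- tiny_skill_memory()
  held <- c(make_pick_place_demos("A", 2, seed = 21),
            make_pick_place_demos("B", 2, seed = 22))
  energies <- unlist(lapply(held, function(tr) {
    monitor_trial(fit$model, tr, fit$scaling)$energies
  }))
  thr <- fit_threshold(energies, 95)
  demos <- list(A = make_pick_place_demos("A", 3, seed = 11),
                B = make_pick_place_demos("B", 3, seed = 12))
  stats <- channel_stats(demos)
  stat_thr <- fit_threshold(unlist(lapply(names(demos), function(sk) {
    unlist(lapply(demos[[sk]], function(tr) {
      zscore_baseline(tr, stats, sk)$statistic
    }))
  })), 95)
  grid <- evaluate_fault_grid(fit$model, fit$scaling, stats, thr, stat_thr,
                              joints = 2, fault_times = 2, overshoots = 90,
                              seed = 1)
  expect_equal(nrow(grid), 2)  # both methods
  expect_true(all(grid$detected))
  expect_error(
    evaluate_fault_grid(fit$model, fit$scaling, stats, thr, stat_thr,
                        joints = 2, fault_times = 2, overshoots = 0),
    "zero overshoot")
  smry <- summarise_fault_grid(grid)
  expect_equal(smry$detection_rate, c(1, 1))
})

test_that("thresholds round-trip through JSON", {
  thr <- fit_threshold(rnorm(50), 95)
  path <- withr::local_tempfile(fileext = ".json")
  write_threshold_json(thr, path)
  back <- read_threshold_json(path)
  expect_equal(back$threshold, thr$threshold)
  expect_equal(back$n_fit, thr$n_fit)
})
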