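test_that("epoch averaging over identical cycles returns any single cycle", {
  prot <- build_protocol()
  base <- activation_model(prot)
  ep <- average_epochs(list(base, base), prot)
  expect_length(ep$values, 200)
  expect_equal(sum(ep$task), 100)
  # constant input -> flat zero epoch after re-zeroing
  epc <- average_epochs(list(rep(4.2, prot$frames_per_run)), prot)
  expect_equal(epc$values, rep(0, 200))
  expect_equal(epc$se, rep(0, 200))
})

test_that("averaging reduces white noise as 1/sqrt(cycles x channels)", {
  prot <- build_protocol()
  ratios <- sapply(1:10, function(s) {
    set.seed(s)
    chans <- lapply(1:4, function(i) rnorm(prot$frames_per_run))
    full <- average_epochs(chans, prot, n_cycles = 5)
    single <- average_epochs(chans[1], prot, n_cycles = 1)
    sd(full$values) / sd(single$values)
  })
  expect_equal(mean(ratios), 1 / sqrt(20), tolerance = 0.15)
})

test_that("epoch window bounds are enforced", {
  prot <- build_protocol()
  expect_error(average_epochs(list(rnorm(1100)), prot, n_cycles = 6), "cycles")
  short <- build_protocol(baseline_s = 9, n_cycles = 1)
  expect_error(average_epochs(list(rnorm(short$frames_per_run)), short),
               "before the start")
})

test_that("SM is the median task-rest difference excluding the early task", {
  ep <- epoch_fixture(task_level = 1, pre_level = 0.2)
  expect_equal(feature_SM(ep), 0.8)
  expect_equal(feature_SM(epoch_fixture(0, 0)), 0)
  # ramp epoch: compare against a direct median evaluation
  ep2 <- epoch_fixture()
  ep2$values <- seq(0, 1, length.out = 200)
  task_late <- ep2$task & ep2$time_s >= 10
  hand <- median(ep2$values[task_late]) - median(ep2$values[ep2$time_s < 0])
  expect_equal(feature_SM(ep2), hand)
})

test_that("SS is the least-squares slope of the early task window", {
  ep <- epoch_fixture(0, 0)
  ep$values <- pmax(0, ep$time_s) * 0.05 # ramp at 0.05 uM/s from onset
  expect_equal(feature_SS(ep), 0.05, tolerance = 1e-12)
  expect_equal(feature_SS(epoch_fixture(0, 0)), 0)
  # noisy ramp vs normal-equation oracle
  ep3 <- epoch_fixture(noise_sd = 0.2, seed = 41)
  sel <- ep3$task & ep3$time_s < 16
  tt <- ep3$time_s[sel]; yy <- ep3$values[sel]
  hand <- sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  expect_equal(feature_SS(ep3), hand, tolerance = 1e-12)
  expect_error(feature_SS(ep3, slope_window_s = 40), "exceeds")
})

test_that("CNR relates the task shift to rest variability", {
  ep <- epoch_fixture(task_level = 1, pre_level = 0, noise_sd = 0)
  ep$values[ep$time_s < 0] <- rep(c(-0.5, 0.5), 25) # rest mean 0, sd ~0.505
  hand <- (mean(ep$values[ep$task]) - mean(ep$values[ep$time_s < 0])) /
    sd(ep$values[ep$time_s < 0])
  expect_equal(feature_CNR(ep), hand, tolerance = 1e-12)
  # statistically identical task and rest -> CNR near zero
  ep2 <- epoch_fixture(0, 0, noise_sd = 1, seed = 42)
  expect_lt(abs(feature_CNR(ep2)), 1)
  expect_error(feature_CNR(epoch_fixture(1, 0)), "degenerate")
})

test_that("r is the Pearson correlation with the activation-model epoch", {
  prot <- build_protocol()
  model_series <- activation_model(prot)
  ep <- average_epochs(list(model_series), prot)
  expect_equal(feature_r(ep, prot), 1.0, tolerance = 1e-9)
  neg <- ep; neg$values <- -ep$values
  expect_equal(feature_r(neg, prot), -1.0, tolerance = 1e-9)
  # independent Pearson formula on a noisy epoch
  ep2 <- epoch_fixture(noise_sd = 0.3, seed = 43, task_level = 1)
  mod <- trfnirs:::model_epoch(prot, ep2)
  hand <- sum((ep2$values - mean(ep2$values)) * (mod$values - mean(mod$values))) /
    sqrt(sum((ep2$values - mean(ep2$values))^2) *
         sum((mod$values - mean(mod$values))^2))
  expect_equal(feature_r(ep2, prot), hand, tolerance = 1e-12)
})

test_that("features are offset-invariant and equivariant under scaling", {
  prot <- build_protocol()
  ep <- epoch_fixture(task_level = 0.8, noise_sd = 0.2, seed = 44)
  f0 <- extract_features(ep, prot)
  shifted <- ep; shifted$values <- ep$values + 3
  fs <- extract_features(shifted, prot)
  expect_equal(fs$SM, f0$SM, tolerance = 1e-10)
  expect_equal(fs$SS, f0$SS, tolerance = 1e-10)
  expect_equal(fs$CNR, f0$CNR, tolerance = 1e-10)
  expect_equal(fs$r, f0$r, tolerance = 1e-10)
  scaled <- ep; scaled$values <- 2.5 * ep$values
  fa <- extract_features(scaled, prot)
  expect_equal(fa$SM, 2.5 * f0$SM, tolerance = 1e-10)
  expect_equal(fa$SS, 2.5 * f0$SS, tolerance = 1e-10)
  expect_equal(fa$CNR, f0$CNR, tolerance = 1e-10)
  expect_equal(fa$r, f0$r, tolerance = 1e-10)
})

test_that("noise-free epochs flow through extraction via the degenerate path", {
  prot <- build_protocol()
  f <- extract_features(average_epochs(list(rep(0, 1100)), prot), prot)
  expect_equal(f$SM, 0)
  expect_equal(f$SS, 0)
  expect_true(f$degenerate)
})

test_that("responder and non-responder feature distributions separate", {
  prot <- build_protocol()
  feats <- function(responder, seeds) sapply(seeds, function(s) {
    prof <- participant_profile("X", responder = responder)
    r <- trfnirs:::simulate_concentration_run(prot, prof, "yes", seed = s)
    cl <- lapply(r$hbo2_by_channel, function(x) clean_timecourse(x)$values)
    extract_features(average_epochs(cl, prot), prot)$r
  })
  yes_r <- feats(TRUE, 1:8)
  no_r <- feats(FALSE, 11:18)
  gap <- (mean(yes_r) - mean(no_r)) /
    sqrt((var(yes_r) + var(no_r)) / 2)
  expect_gt(gap, 1)
})
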