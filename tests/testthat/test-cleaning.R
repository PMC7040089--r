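test_that("motion detection flags spikes and nothing on quiet signals", {
  expect_equal(detect_motion(rep(1, 100)), rep(FALSE, 100))
  set.seed(21)
  x <- rnorm(1100)
  spike_at <- 500:506 # ~2 s at 0.3-s sampling
  x[spike_at] <- x[spike_at] + 20 * c(1, -1, 1, -1, 1, -1, 1)
  mask <- detect_motion(x)
  expect_true(all(mask[spike_at]))
  expect_lt(mean(mask[-spike_at]), 0.05)
  # infinite threshold flags nothing
  expect_equal(sum(detect_motion(x, k = Inf)), 0)
  expect_error(detect_motion(c(1, 2), window_s = 3, sampling_period_s = 1),
               "shorter")
})

test_that("moving SD matches a hand-computed window", {
  x <- c(1, 4, 2, 8, 5, 7)
  msd <- trfnirs:::moving_sd(x, 3)
  expect_equal(msd[3], sd(c(4, 2, 8)))
  expect_equal(msd[1], sd(c(1, 4)))
})

test_that("motion correction removes a step artifact and is near-idempotent", {
  set.seed(22)
  n <- 600
  x <- rnorm(n, sd = 0.05)
  A <- 5
  seg <- 300:320
  x[seg] <- x[seg] + A # step artifact inside the mask
  mask <- rep(FALSE, n); mask[seg] <- TRUE
  cs <- correct_motion(x, mask)
  expect_equal(cs$values[-seg], x[-seg]) # unflagged samples untouched
  expect_lt(max(abs(cs$values[seg])), 0.05 * A)
  # re-running detection on the corrected signal finds almost nothing
  mask2 <- detect_motion(cs$values)
  expect_lt(mean(mask2), 0.01)
  expect_error(correct_motion(x, rep(TRUE, n)), "entire")
  # empty mask is the identity
  expect_equal(correct_motion(x, rep(FALSE, n))$values, x)
})

test_that("cosine detrending removes slow components and keeps fast ones", {
  n <- 1100; dt <- 0.3 # 330-s record
  tt <- (seq_len(n) - 0.5) * dt
  expect_equal(highpass_detrend(rep(3.7, n))$values, rep(0, n),
               tolerance = 1e-12)
  slow <- sin(2 * pi * tt / 512)
  fast <- sin(2 * pi * tt / 10)
  # oracle: numeric projection onto the retained cosine basis
  proj_resid <- function(x, cutoff = 128) {
    kmax <- floor(2 * n * dt / cutoff)
    X <- cbind(1, sapply(seq_len(kmax), function(k)
      cos(pi * k * (seq_len(n) - 0.5) / n)))
    x - X %*% solve(crossprod(X), crossprod(X, x))
  }
  rs <- highpass_detrend(slow)$values
  expect_lt(sqrt(mean(rs^2)) / sqrt(mean(slow^2)), 0.10)
  expect_equal(rs, drop(proj_resid(slow)), tolerance = 1e-8)
  rf <- highpass_detrend(fast)$values
  expect_gt(sqrt(mean(rf^2)) / sqrt(mean(fast^2)), 0.95)
  expect_error(highpass_detrend(rnorm(100), sampling_period_s = 0.3,
                                cutoff_period_s = 128), "shorter")
})

test_that("detrending is an idempotent linear projection", {
  set.seed(23)
  x <- cumsum(rnorm(1100)) * 0.01
  y <- rnorm(1100)
  d1 <- highpass_detrend(x)$values
  expect_equal(highpass_detrend(d1)$values, d1, tolerance = 1e-10)
  expect_equal(highpass_detrend(2 * x + y)$values,
               2 * d1 + highpass_detrend(y)$values, tolerance = 1e-10)
})

test_that("hemodynamic smoothing has unit gain, returns its kernel, and scales noise", {
  n <- 400
  expect_equal(smooth_hrf(rep(2.5, n))$values, rep(2.5, n), tolerance = 1e-12)
  imp <- rep(0, n); imp[200] <- 1
  sm <- smooth_hrf(imp)$values
  expect_equal(which.max(sm), 200)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  # kernel shape: symmetric Gaussian with the configured FWHM
  sigma <- 4 / (2 * sqrt(2 * log(2))) / 0.3
  r <- ceiling(4 * sigma)
  kern <- exp(-0.5 * ((-r):r / sigma)^2); kern <- kern / sum(kern)
  expect_equal(sm[(200 - r):(200 + r)], kern, tolerance = 1e-9)
  # white-noise variance reduction equals sum of squared weights
  ratio <- sapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(1100)
    var(smooth_hrf(x)$values) / var(x)
  })
  expect_equal(mean(ratio), sum(kern^2), tolerance = 0.1)
})

test_that("the full cleaning chain preserves length and records provenance", {
  set.seed(24)
  x <- rnorm(1100)
  cs <- clean_timecourse(x)
  expect_length(cs$values, 1100)
  expect_equal(vapply(cs$provenance, `[[`, character(1), "step"),
               c("correct_motion", "highpass_detrend", "smooth_hrf"))
})
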