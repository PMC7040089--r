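test_that("truncation window follows the rise/fall threshold rule", {
  counts <- c(2, 12, 40, 100, 70, 30, 8, 1)
  f <- dtof_frame(counts, 0:8)
  w <- truncate_window(f) # 10% of 100 = 10 -> first bin 2; 1% = 1 -> last bin 8
  expect_equal(unname(w), c(2, 8))
  expect_true(w[1] <= which.max(counts) && w[2] >= which.max(counts))
  # single nonzero bin
  expect_equal(unname(truncate_window(dtof_frame(c(0, 5, 0), 0:3))), c(2, 2))
  # zero thresholds keep the full support
  expect_equal(unname(truncate_window(f, 0, 0)), c(1, 8))
  expect_error(truncate_window(dtof_frame(rep(0, 4), 0:4)), "empty")
})

test_that("mean time-of-flight is the windowed count-weighted first moment", {
  f <- dtof_frame(c(0, 1, 2, 1, 0), seq(-0.5, 4.5, by = 1))
  expect_equal(mean_time_of_flight(f, c(1, 5)), 2.0)
  g <- dtof_frame(c(0, 1, 2, 1, 0), seq(4.5, 9.5, by = 1)) # shifted +5 ps
  expect_equal(mean_time_of_flight(g, c(1, 5)), 7.0)
  # brute-force oracle on a random 50-bin histogram
  set.seed(7)
  counts <- rpois(50, 40)
  edges <- seq(0, 500, by = 10)
  h <- dtof_frame(counts, edges)
  w <- truncate_window(h)
  idx <- w[1]:w[2]
  centers <- (edges[-1] + edges[-51]) / 2
  brute <- sum(counts[idx] * centers[idx]) / sum(counts[idx])
  expect_equal(mean_time_of_flight(h), brute, tolerance = 1e-12)
  expect_error(mean_time_of_flight(dtof_frame(c(1, 0, 0), 0:3), c(2, 3)),
               "zero counts")
})

test_that("count scale leaves the mean unchanged", {
  set.seed(8)
  counts <- rpois(64, 30)
  edges <- seq(0, 640, by = 10)
  m1 <- mean_time_of_flight(dtof_frame(counts, edges))
  m2 <- mean_time_of_flight(dtof_frame(counts * 37, edges))
  expect_equal(m1, m2)
})

test_that("vectorised per-frame moments agree with the scalar path", {
  set.seed(9)
  edges <- seq(0, 1000, by = 20)
  centers <- (edges[-1] + edges[-51]) / 2
  counts <- t(sapply(1:20, function(i)
    rpois(50, 50 * exp(-((1:50) - 15 - i %% 5)^2 / 40))))
  m <- trfnirs:::mtof_matrix(counts, centers, edge_interp = FALSE)
  for (i in c(1, 7, 20)) {
    f <- dtof_frame(counts[i, ], edges)
    w <- truncate_window(f)
    expect_equal(m$first[i], unname(w[1]))
    expect_equal(m$last[i], unname(w[2]))
    expect_equal(m$t_mean[i], mean_time_of_flight(f, w))
  }
})

test_that("delta series is referenced to the baseline mean", {
  edges <- seq(0, 100, by = 10)
  fr <- rbind(matrix(rep(c(0, 0, 1, 5, 9, 5, 1, 0, 0, 0), 5),
                     5, byrow = TRUE))
  s <- delta_mtof_series(fr, edges, baseline_frames = 3)
  expect_equal(s$delta_t, rep(0, 5)) # constant frames
  s1 <- delta_mtof_series(fr, edges, baseline_frames = 1)
  expect_equal(s1$t_mean_baseline, s1$t_mean[1])
  expect_error(delta_mtof_series(fr, edges, baseline_frames = 9), "baseline")
  # a shifted block changes delta_t by the shift
  fr2 <- fr
  fr2[4:5, ] <- fr[4:5, c(2:10, 1)] # advance one bin = -10 ps
  s2 <- delta_mtof_series(fr2, edges, baseline_frames = 3)
  expect_equal(s2$delta_t[4:5], c(-10, -10))
})

test_that("time-axis shift of all frames leaves delta_t unchanged", {
  set.seed(10)
  edges <- seq(0, 1000, by = 20)
  counts <- t(sapply(1:10, function(i)
    rpois(50, 80 * exp(-((1:50) - 12 - i %% 3)^2 / 30))))
  s1 <- delta_mtof_series(counts, edges, baseline_frames = 4)
  s2 <- delta_mtof_series(counts, edges + 500, baseline_frames = 4)
  expect_equal(s1$delta_t, s2$delta_t, tolerance = 1e-12)
})

test_that("brain absorption steps appear in delta_t at the sensitivity-predicted size", {
  rec <- mc_records_fixture()
  acq <- acquisition_config()
  tmpl <- run_template_fixture()
  dmua <- 1e-4
  irf <- trfnirs:::make_irf_fft(acq)
  base <- pmax(trfnirs:::irf_convolve(tmpl$B, irf), 0)
  pert <- pmax(trfnirs:::irf_convolve(tmpl$B * exp(-tmpl$Lb * dmua), irf), 0)
  counts <- rbind(matrix(rep(base, 5), 5, byrow = TRUE),
                  matrix(rep(pert, 5), 5, byrow = TRUE))
  s <- delta_mtof_series(counts, acq$bin_edges_ps, baseline_frames = 5)
  predicted <- windowed_mtsf(rec, acq,
                             delta_grid = dmua)$mtsf * dmua
  expect_lt(s$delta_t[10], 0)
  expect_equal(mean(s$delta_t[6:10]), predicted, tolerance = 0.05)
})
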