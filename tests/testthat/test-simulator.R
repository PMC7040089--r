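test_that("hemodynamic time courses follow truth and amplitude", {
  prot <- build_protocol()
  prof <- participant_profile("P01", amp_hbo2 = 1, amp_hb = -0.3)
  no <- hemodynamic_timecourse(prot, "no", prof)
  expect_equal(no$delta_hbo2, rep(0, 1100))
  expect_equal(no$delta_hb, rep(0, 1100))
  yes <- hemodynamic_timecourse(prot, "yes", prof)
  expect_gt(max(yes$delta_hbo2), 0)
  expect_lt(min(yes$delta_hb), -0.2)
  # non-responders produce nothing even for "yes"
  nr <- participant_profile("P02", responder = FALSE)
  expect_equal(hemodynamic_timecourse(prot, "yes", nr)$delta_hbo2,
               rep(0, 1100))
})

test_that("long task blocks plateau at the stated amplitude", {
  prot <- build_protocol(baseline_s = 30, n_cycles = 1, answer_s = 60,
                         rest_s = 30)
  prof <- participant_profile("P01", amp_hbo2 = 1, amp_hb = -0.3)
  yes <- hemodynamic_timecourse(prot, "yes", prof)
  # end of a 60-s block: convolution of the unit-area kernel has converged
  plateau_frames <- prot$answer_onset_frames[1] + 150:199
  expect_equal(mean(yes$delta_hbo2[plateau_frames]), 1, tolerance = 0.01)
})

test_that("generated epochs correlate perfectly with the feature model", {
  prot <- build_protocol()
  prof <- participant_profile("P01", amp_hbo2 = 0.5, amp_hb = -0.15)
  yes <- hemodynamic_timecourse(prot, "yes", prof)
  ep <- average_epochs(list(yes$delta_hbo2), prot)
  expect_equal(feature_r(ep, prot), 1.0, tolerance = 1e-9)
})

test_that("noise-free 'no' runs give identical frames and zero delta", {
  prot <- build_protocol(n_cycles = 2)
  prof <- participant_profile("P01")
  tmpl <- run_template_fixture()
  run <- simulate_run(prot, prof, "no", tmpl, seed = 51, noise = FALSE)
  cts <- run$counts[[1]][["830"]]
  expect_true(all(cts[1, ] == t(cts[sample(nrow(cts), 5), ])))
  s <- delta_mtof_series(cts, run$bin_edges_ps,
                         baseline_frames = prot$frames_baseline)
  expect_equal(s$delta_t, rep(0, prot$frames_per_run), tolerance = 1e-9)
})

test_that("simulated runs are reproducible for a fixed seed", {
  prot <- build_protocol(n_cycles = 1)
  prof <- participant_profile("P01")
  tmpl <- run_template_fixture()
  r1 <- simulate_run(prot, prof, "yes", tmpl, seed = 52)
  r2 <- simulate_run(prot, prof, "yes", tmpl, seed = 52)
  expect_identical(r1$counts, r2$counts)
  r3 <- simulate_run(prot, prof, "yes", tmpl, seed = 53)
  expect_false(identical(r1$counts, r3$counts))
})

test_that("frame-to-frame moment noise matches Poisson counting statistics", {
  prot <- build_protocol(baseline_s = 60, n_cycles = 0) # 200 identical frames
  prof <- participant_profile("P01",
                              noise_scales = list(drift = 0, cardiac = 0,
                                                  mayer = 0, cerebral_lfo = 0,
                                                  motion_rate = 0))
  tmpl <- run_template_fixture()
  run <- simulate_run(prot, prof, "no", tmpl, seed = 54, noise = TRUE)
  cts <- run$counts[[1]][["830"]]
  # counting-statistics law Var(<t>) = Var(t)/N holds for a fixed window;
  # evaluate all frames in the window of the mean frame so per-frame
  # threshold jitter does not enter
  expected_frame <- colMeans(cts)
  f <- dtof_frame(expected_frame, run$bin_edges_ps)
  w <- truncate_window(f)
  idx <- w[1]:w[2]
  centers <- trfnirs:::bin_centers(run$bin_edges_ps)[idx]
  t_mean <- drop(cts[, idx] %*% centers) / rowSums(cts[, idx])
  observed <- var(t_mean)
  cc <- expected_frame[idx]
  mu <- sum(cc * centers) / sum(cc)
  predicted <- (sum(cc * (centers - mu)^2) / sum(cc)) / sum(cc)
  expect_equal(observed, predicted, tolerance = 0.2)
})

test_that("cohort manifests are deterministic and match their RNG stream", {
  tmplless <- simulate_cohort(master_seed = 61, mode = "concentration")
  again <- simulate_cohort(master_seed = 61, mode = "concentration")
  expect_identical(tmplless$manifest, again$manifest)
  expect_equal(nrow(tmplless$manifest), 18 * 4)
  expect_true(all(table(tmplless$manifest$participant) == 4))
  # every participant answers yes to exactly 2 of 4 questions
  yes_per <- tapply(tmplless$manifest$truth == "yes",
                    tmplless$manifest$participant, sum)
  expect_true(all(yes_per == 2))
  # responder draws reproduce a brute-force replay of the same stream
  set.seed(61)
  brute <- logical(18)
  for (p in 1:18) {
    brute[p] <- runif(1) >= 0.12
    amp <- rnorm(1, 0.5, 0.15)
    while (amp < 0.1) amp <- rnorm(1, 0.5, 0.15)
    rnorm(1) # hrf peak draw
    rnorm(4) # noise scale draws
    sample(c("yes", "yes", "no", "no"))
    sample.int(.Machine$integer.max - 1, 4)
  }
  realized <- tapply(tmplless$manifest$responder,
                     tmplless$manifest$participant, unique)
  expect_equal(as.vector(realized[sprintf("P%02d", 1:18)]), brute)
})

test_that("cohort constraints are enforced", {
  expect_error(simulate_cohort(n_participants = 1, master_seed = 1,
                               mode = "concentration"), "at least 2")
  expect_error(simulate_cohort(non_responder_frac = 1, master_seed = 1,
                               mode = "concentration"), "non_responder_frac")
  expect_error(simulate_cohort(master_seed = 1, mode = "dtof"), "template")
})

test_that("a noiseless separable cohort decodes perfectly", {
  plan <- simulate_cohort(n_participants = 6, non_responder_frac = 0,
                          master_seed = 62, mode = "concentration")
  runs <- list()
  for (i in seq_len(nrow(plan$manifest)))
    runs[[i]] <- realize_run(plan, i, noise = FALSE)
  for (i in seq_along(runs)) runs[[i]]$question_index <- plan$manifest$question_index[i]
  cr <- structure(list(runs = runs, protocol = plan$protocol,
                       manifest = plan$manifest), class = "cohort_runs")
  feats <- features_from_runs(cr, plan$protocol)
  res <- loocv(feats, c("SM", "r"), "svm")
  expect_equal(res$accuracy, 100)
})
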