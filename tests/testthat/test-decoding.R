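test_that("exactly 15 feature subsets are enumerated in deterministic order", {
  subs <- feature_subsets()
  expect_length(subs, 15)
  expect_equal(subs[[1]], "SM")
  expect_equal(subs[[15]], c("SM", "SS", "CNR", "r"))
  expect_equal(lengths(subs), c(rep(1, 4), rep(2, 6), rep(3, 4), 4))
  expect_length(unique(vapply(subs, paste, "", collapse = "+")), 15)
})

test_that("well-separated classes are decoded perfectly by both methods", {
  rec <- separable_records_fixture()
  for (m in c("svm", "lda")) {
    res <- loocv(rec, method = m)
    expect_equal(res$accuracy, 100)
    expect_equal(res$sensitivity, 100)
    expect_equal(res$specificity, 100)
  }
})

test_that("confusion-matrix identities hold on every result", {
  set.seed(71)
  rec <- null_records_fixture(32, seed = 71)
  res <- loocv(rec, c("SM", "CNR"), "lda")
  cm <- res$confusion
  expect_equal(sum(cm), res$n)
  expect_equal(res$accuracy, 100 * (cm["yes", "yes"] + cm["no", "no"]) / res$n)
  expect_equal(res$sensitivity, 100 * cm["yes", "yes"] / sum(cm["yes", ]))
  expect_equal(res$specificity, 100 * cm["no", "no"] / sum(cm["no", ]))
})

test_that("label swap exchanges sensitivity and specificity", {
  set.seed(72)
  rec <- null_records_fixture(30, seed = 72)
  rec$SM <- rec$SM + ifelse(rec$truth == "yes", 1, 0) # make it learnable
  a <- loocv(rec, "SM", "lda")
  swapped <- rec
  swapped$truth <- ifelse(rec$truth == "yes", "no", "yes")
  b <- loocv(swapped, "SM", "lda")
  expect_equal(b$accuracy, a$accuracy)
  expect_equal(b$sensitivity, a$specificity)
  expect_equal(b$specificity, a$sensitivity)
})

test_that("permutation-null accuracy sits at chance", {
  accs <- sapply(1:100, function(s) {
    rec <- null_records_fixture(24, seed = 1000 + s)
    loocv(rec, method = "lda")$accuracy
  })
  expect_gt(mean(accs), 40)
  expect_lt(mean(accs), 60)
})

test_that("LDA folds match a hand-executed pooled-discriminant walk-through", {
  # 6 records, one feature; one ambiguous point near the boundary
  rec <- data.frame(participant = sprintf("P%d", 1:6),
                    question_index = rep(1:2, 3),
                    SM = c(0.0, 0.2, 0.4, 1.0, 1.2, 0.5),
                    SS = 0, CNR = 0, r = 0,
                    truth = c("no", "no", "no", "yes", "yes", "yes"))
  res <- loocv(rec, "SM", "lda")
  hand <- character(6)
  for (i in 1:6) {
    tr <- rec[-i, ]
    x <- (rec$SM[i] - mean(tr$SM)) / sd(tr$SM)
    z <- (tr$SM - mean(tr$SM)) / sd(tr$SM)
    m_yes <- mean(z[tr$truth == "yes"]); m_no <- mean(z[tr$truth == "no"])
    # equal priors, pooled variance: assign to the nearer class mean
    hand[i] <- if (abs(x - m_yes) < abs(x - m_no)) "yes" else "no"
  }
  expect_equal(res$predicted, hand)
})

test_that("subset search reports the argmax and resolves ties deterministically", {
  set.seed(73)
  n <- 40
  rec <- data.frame(participant = sprintf("P%02d", rep(1:10, 4)),
                    question_index = rep(1:4, each = 10),
                    SM = rnorm(n), SS = rnorm(n), CNR = rnorm(n),
                    truth = sample(rep(c("yes", "no"), n / 2)))
  rec$r <- ifelse(rec$truth == "yes", 0.9, -0.5) + rnorm(n, sd = 0.05)
  rep_ <- subset_search(rec, "lda")
  expect_length(rep_$results, 15)
  expect_true("r" %in% rep_$best_subset)
  expect_equal(rep_$best_accuracy, max(rep_$table$accuracy))
  # duplicated informative feature: the earlier, smaller subset must win
  rec2 <- rec
  rec2$SM <- rec$r # SM now duplicates r; "SM" precedes "r" in subset order
  rep2 <- subset_search(rec2, "lda")
  expect_equal(rep2$best_subset, "SM")
})

test_that("single-class folds fall back to the majority class with a flag", {
  rec <- data.frame(participant = sprintf("P%d", 1:5),
                    question_index = 1,
                    SM = c(0, 0.1, 0.2, 0.3, 5), SS = 0, CNR = 0, r = 0,
                    truth = c("no", "no", "no", "no", "yes"))
  res <- loocv(rec, "SM", "lda")
  expect_equal(res$degenerate_folds, 1L)
  expect_equal(res$predicted[5], "no")
  expect_error(loocv(rec[1:4, ], "SM", "lda"), "single-class")
})

test_that("per-question accuracies partition the overall accuracy", {
  rec <- separable_records_fixture(n_per_class = 8)
  overall <- loocv(rec, method = "lda")$accuracy
  pq <- per_question_accuracy(rec, method = "lda")
  counts <- table(factor(rec$question_index, levels = 1:4))
  expect_equal(sum(pq * counts) / sum(counts), overall)
  # an order position with no records is undefined, not zero
  sub <- rec[rec$question_index != 3, ]
  pq2 <- per_question_accuracy(sub, method = "lda")
  expect_true(is.na(pq2[3]))
})

test_that("cycle curves include all subsets and agree with the full search at k = max", {
  plan <- simulate_cohort(n_participants = 8, master_seed = 74,
                          mode = "concentration")
  runs <- process_cohort(plan)
  cc <- cycles_curve(runs, plan$protocol, "lda")
  expect_equal(sort(unique(cc$k)), 1:5)
  expect_equal(sum(cc$k == 5), 15)
  full <- subset_search(features_from_runs(runs, plan$protocol), "lda")
  k5 <- cc[cc$k == 5, ]
  expect_equal(max(k5$accuracy), full$best_accuracy)
  expect_equal(k5$accuracy[k5$at_full_optimum],
               full$table$accuracy[full$table$subset ==
                                     paste(full$best_subset, collapse = "+")])
})
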