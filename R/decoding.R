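FEATURE_ORDER <- c("SM", "SS", "CNR", "r")

#' All non-empty feature subsets
#'
#' The 15 unique combinations of the four oxyhemoglobin features, ordered
#' deterministically: fewest features first, then lexicographically in the
#' fixed feature order SM < SS < CNR < r.  This order is also the tie-break
#' rule of [subset_search()].
#'
#' @return list of character vectors
#' @export
feature_subsets <- function() {
  out <- list()
  for (size in 1:4)
    out <- c(out, utils::combn(FEATURE_ORDER, size, simplify = FALSE))
  out
}

standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(train = scale(train, mu, sdv),
       test = scale(test, mu, sdv))
}

fit_predict <- function(train_x, train_y, test_x, method) {
  if (method == "lda") {
    # collinear feature subsets (e.g. duplicated or constant columns) still
    # yield well-defined predictions; the informational warning would fire
    # once per fold
    fit <- withCallingHandlers(
      MASS::lda(train_x, grouping = train_y, prior = c(0.5, 0.5)),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    as.character(stats::predict(fit, test_x)$class)
  } else {
    fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = 1,
                      scale = FALSE, type = "C-classification")
    as.character(stats::predict(fit, test_x))
  }
}

#' Leave-one-out cross-validated yes/no decoding
#'
#' Each question record is predicted by a classifier trained on all other
#' records; features are standardised by the training fold's mean and SD.
#' Folds whose training set contains a single class predict the training
#' majority class and are flagged.  "yes" is the positive class for
#' sensitivity; "no" for specificity.
#'
#' @param records data frame with columns `truth` ("yes"/"no") and the
#'   feature columns
#' @param subset character vector of feature names to use
#' @param method `"svm"` (linear kernel, C = 1) or `"lda"`
#'   (pooled-covariance discriminant, equal priors)
#' @return a `decoding_result`: `accuracy`, `sensitivity`, `specificity`
#'   (percent), `confusion` (2 x 2), `predicted`, `method`, `subset`
#' @export
loocv <- function(records, subset = FEATURE_ORDER, method = c("svm", "lda")) {
  method <- match.arg(method)
  n <- nrow(records)
  if (n < 2) stop("LOOCV needs at least 2 records")
  y <- factor(as.character(records$truth), levels = c("no", "yes"))
  if (length(unique(y)) < 2) stop("single-class dataset: cannot cross-validate")
  stopifnot(all(subset %in% names(records)))
  X <- as.matrix(records[, subset, drop = FALSE])
  pred <- character(n)
  degenerate_folds <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      pred[i] <- names(which.max(table(ytr)))
      degenerate_folds <- degenerate_folds + 1L
      next
    }
    st <- standardize_train_test(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    pred[i] <- fit_predict(st$train, ytr, st$test, method)
  }
  pred <- factor(pred, levels = c("no", "yes"))
  conf <- table(truth = y, predicted = pred)
  tp <- conf["yes", "yes"]; tn <- conf["no", "no"]
  fn <- conf["yes", "no"]; fp <- conf["no", "yes"]
  structure(list(method = method, subset = subset,
                 accuracy = 100 * (tp + tn) / n,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 confusion = conf,
                 predicted = as.character(pred),
                 degenerate_folds = degenerate_folds,
                 n = n),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("%s [%s]: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (n = %d)\n",
              toupper(x$method), paste(x$subset, collapse = "+"),
              x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Exhaustive feature-subset search
#'
#' Evaluates every non-empty subset of the four features (15 in total) by
#' leave-one-out cross-validation and reports all results plus the best
#' subset.  Accuracy ties are broken by the deterministic subset order:
#' fewest features first, then lexicographic (SM < SS < CNR < r).
#'
#' @inheritParams loocv
#' @return a `subset_search_report`: `results` (list of 15
#'   `decoding_result`s), `best_subset`, `best_accuracy`, `table`
#'   (data frame summary)
#' @export
subset_search <- function(records, method = c("svm", "lda")) {
  method <- match.arg(method)
  subsets <- feature_subsets()
  results <- lapply(subsets, function(s) loocv(records, s, method))
  acc <- vapply(results, `[[`, numeric(1), "accuracy")
  best <- which.max(acc) # which.max returns the first maximum: the tie rule
  tab <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = lengths(subsets),
    accuracy = acc,
    sensitivity = vapply(results, `[[`, numeric(1), "sensitivity"),
    specificity = vapply(results, `[[`, numeric(1), "specificity"))
  structure(list(results = results, method = method,
                 best_subset = subsets[[best]],
                 best_accuracy = acc[best],
                 best_result = results[[best]],
                 table = tab),
            class = "subset_search_report")
}

#' @export
print.subset_search_report <- function(x, ...) {
  cat(sprintf("subset_search (%s): best %s at %.1f%%\n", toupper(x$method),
              paste(x$best_subset, collapse = "+"), x$best_accuracy))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Decoding accuracy as a function of the number of cycles
#'
#' Rebuilds the epochs and features from only the first `k` cycles,
#' `k = 1 ... n_cycles`, re-runs the full subset search at each `k`, and
#' additionally scores, at every `k`, the subset that is optimal with all
#' cycles included.
#'
#' @param runs a `cohort_runs` object (see [process_cohort()]): per-run
#'   oxyhemoglobin series per channel with truth labels
#' @param protocol the `protocol_design`
#' @param method classifier, `"svm"` or `"lda"`
#' @param max_cycles highest cycle count (default: all available)
#' @return a data frame with one row per (k, subset) plus, per k, the
#'   accuracy at the full-cycle optimum subset (`at_full_optimum`)
#' @export
cycles_curve <- function(runs, protocol, method = c("svm", "lda"),
                         max_cycles = protocol$n_cycles) {
  method <- match.arg(method)
  if (max_cycles > protocol$n_cycles) stop("k exceeds available cycles")
  full <- subset_search(features_from_runs(runs, protocol, protocol$n_cycles),
                        method)
  rows <- list()
  for (k in seq_len(max_cycles)) {
    feats <- features_from_runs(runs, protocol, k)
    rep_k <- subset_search(feats, method)
    tab <- rep_k$table
    tab$k <- k
    tab$best <- tab$accuracy == rep_k$best_accuracy &
      tab$subset == paste(rep_k$best_subset, collapse = "+")
    tab$at_full_optimum <- tab$subset == paste(full$best_subset, collapse = "+")
    rows[[k]] <- tab
  }
  out <- do.call(rbind, rows)
  attr(out, "full_optimum_subset") <- full$best_subset
  out
}

#' Per-question decoding accuracy
#'
#' Groups the pooled LOOCV predictions by question order position and
#' reports the accuracy of each position.  Positions with no records are
#' reported as `NA`.  Descriptive only.
#'
#' @inheritParams loocv
#' @param n_positions number of question positions in the session
#' @return named numeric vector of accuracies (percent) per position
#' @export
per_question_accuracy <- function(records, subset = FEATURE_ORDER,
                                  method = c("svm", "lda"), n_positions = 4) {
  method <- match.arg(method)
  res <- loocv(records, subset, method)
  correct <- res$predicted == as.character(records$truth)
  vapply(seq_len(n_positions), function(q) {
    sel <- records$question_index == q
    if (!any(sel)) return(NA_real_)
    100 * mean(correct[sel])
  }, numeric(1))
}
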