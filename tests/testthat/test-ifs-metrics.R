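test_that("metrics reproduce closed-form and printed reference values", {
  # perfect classifier
  m <- compute_metrics(confusion_counts(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$mcc, 1)

  # all-negative baseline on a 218/926 dataset
  b <- compute_metrics(confusion_counts(TP = 0, TN = 926, FP = 0, FN = 218))
  expect_equal(b$accuracy, 926 / 1144)
  expect_equal(round(100 * b$accuracy, 2), 80.94)
  expect_equal(b$mcc, 0)  # zero denominator convention

  # degenerate inputs
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(compute_metrics(confusion_counts(TP = 0, TN = 5, FP = 5,
                                                FN = 0)),
               "sensitivity")
  expect_error(confusion_counts(TP = -1, TN = 0, FP = 0, FN = 2))
})

test_that("metric identities hold for fuzzed confusion counts", {
  withr::with_seed(101, {
    for (rep in 1:200) {
      cc <- confusion_counts(TP = rpois(1, 20) + 1, TN = rpois(1, 50) + 1,
                             FP = rpois(1, 10), FN = rpois(1, 10))
      m <- compute_metrics(cc)
      n_pos <- cc$TP + cc$FN
      n_neg <- cc$TN + cc$FP
      n <- n_pos + n_neg
      expect_equal(m$accuracy,
                   (m$sensitivity * n_pos + m$specificity * n_neg) / n)
      expect_gte(m$mcc, -1)
      expect_lte(m$mcc, 1)
      # class swap: SN and SP trade places, ACC and MCC are invariant
      sw <- compute_metrics(confusion_counts(TP = cc$TN, TN = cc$TP,
                                             FP = cc$FN, FN = cc$FP))
      expect_equal(sw$sensitivity, m$specificity)
      expect_equal(sw$specificity, m$sensitivity)
      expect_equal(sw$accuracy, m$accuracy)
      expect_equal(sw$mcc, m$mcc)
    }
  })
})

test_that("random forest training is deterministic and fits the data", {
  withr::with_seed(55, {
    n <- 40
    y <- rep(c("negative", "positive"), each = n / 2)
    X <- cbind(signal = as.numeric(y == "positive"),
               noise = rnorm(n))
    model <- train_classifier(X, y, seed = 9)
    expect_equal(predict_classifier(model, X), y)
    model2 <- train_classifier(X, y, seed = 9)
    expect_identical(predict_classifier(model2, X),
                     predict_classifier(model, X))
    expect_error(train_classifier(X[1:5, ], rep("positive", 5)),
                 "single class")
  })
})

test_that("jackknife separates well-separated Gaussian clusters", {
  withr::with_seed(77, {
    n <- 40
    y <- rep(c("negative", "positive"), each = n / 2)
    # 6 sd separation: Bayes error far below 1%
    X <- cbind(f = rnorm(n, mean = ifelse(y == "positive", 3, -3)))
    cc <- jackknife_evaluate(X, y, seed = 4)
    m <- compute_metrics(cc)
    expect_gte(m$accuracy, 0.95)
    # accounting identity: every sample predicted exactly once
    expect_equal(cc$TP + cc$FN, sum(y == "positive"))
    expect_equal(cc$TN + cc$FP, sum(y == "negative"))
    # determinism
    cc2 <- jackknife_evaluate(X, y, seed = 4)
    expect_identical(cc, cc2)
  })
})

test_that("stratified k-fold evaluation predicts each sample once", {
  withr::with_seed(31, {
    n <- 60
    y <- rep(c("negative", "positive"), times = c(40, 20))
    X <- cbind(f = rnorm(n, ifelse(y == "positive", 2, -2)), g = rnorm(n))
    cc <- evaluate_classifier(X, y, seed = 2, folds = 5)
    expect_equal(cc$TP + cc$FN, 20)
    expect_equal(cc$TN + cc$FP, 40)
    expect_identical(evaluate_classifier(X, y, seed = 2, folds = 5), cc)
    m <- compute_metrics(cc)
    expect_gte(m$accuracy, 0.9)
  })
})

test_that("larger ensembles do at least as well on noisy planted signal", {
  withr::with_seed(303, {
    mccs <- sapply(1:5, function(rep) {
      n <- 60
      y <- rep(c("negative", "positive"), each = n / 2)
      X <- matrix(rnorm(n * 10), n)
      X[, 1:3] <- X[, 1:3] + ifelse(y == "positive", 0.9, 0)
      one <- compute_metrics(evaluate_classifier(
        X, y, spec = classifier_spec(n_trees = 1), seed = rep,
        folds = 10))$mcc
      many <- compute_metrics(evaluate_classifier(
        X, y, spec = classifier_spec(n_trees = 100), seed = rep,
        folds = 10))$mcc
      c(one = one, many = many)
    })
    expect_gte(mean(mccs["many", ]), mean(mccs["one", ]))
  })
})

test_that("IFS tracks the MCC-optimal prefix of the ranking", {
  withr::with_seed(202, {
    n <- 60
    y <- rep(c("negative", "positive"), each = n / 2)
    X <- cbind(matrix(rnorm(n * 8), n),
               s1 = rnorm(n, ifelse(y == "positive", 2, -2)),
               s2 = rnorm(n, ifelse(y == "positive", 2, -2)))
    colnames(X) <- paste0("f", 1:10)
    r <- mrmr_rank(X, labels = y)
    fit <- ifs_fit(r, X, labels = y, k_max = 10, spec = classifier_spec(),
                   seed = 6, folds = 10)
    expect_s3_class(fit, "ifs_result")
    # optimality: reported optimum equals the max over the stored curve
    expect_equal(fit$optimal_mcc, max(fit$curve$mcc, na.rm = TRUE))
    # ties resolve to the smallest k
    best_ks <- fit$curve$k[which(fit$curve$mcc == fit$optimal_mcc)]
    expect_equal(fit$optimal_k, min(best_ks))
    # monotone bookkeeping: each prefix extends the previous one
    expect_equal(fit$optimal_features$index,
                 r$index[seq_len(fit$optimal_k)])
    # the planted features rank on top and are recovered
    expect_true(all(c("f9", "f10") %in%
                      r$feature[seq_len(fit$optimal_k)]))

    single <- ifs_fit(r, X, labels = y, k_min = 1, k_max = 1, seed = 6,
                      folds = 10)
    expect_equal(nrow(single$curve), 1)
    expect_equal(single$optimal_k, 1)
  })
})

test_that("IFS curves serialize to TSV", {
  withr::with_seed(404, {
    n <- 30
    y <- rep(c("negative", "positive"), each = n / 2)
    X <- cbind(a = rnorm(n, ifelse(y == "positive", 2, -2)), b = rnorm(n))
    r <- mrmr_rank(X, labels = y)
    fit <- ifs_fit(r, X, labels = y, seed = 3, folds = 5)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_ifs(fit, path)
    back <- read.delim(path)
    expect_equal(back$k, fit$curve$k)
    expect_equal(back$mcc, fit$curve$mcc, tolerance = 1e-12)
  })
})
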