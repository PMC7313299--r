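test_that("nearest-neighbour basics: k = 1 and exact-match queries", {
  df <- random_feature_df(20, seed = 41)
  x <- as.matrix(df[, 1:16])
  q <- rnorm(16)
  d <- sqrt(colSums((t(x) - q)^2))
  expect_identical(knn_predict(df, q, k = 1), df$label[which.min(d)])

  expect_identical(knn_predict(df, as.numeric(x[7, ]), k = 1), df$label[7])

  expect_error(knn_predict(df, q, k = 21), "exceeds")
  expect_error(knn_predict(df, q, k = 0), "integer")
})

test_that("predictions are identical to the brute-force distance-sort oracle", {
  for (n in c(5, 12, 30, 50)) {
    df <- random_feature_df(n, seed = 100 + n)
    x <- as.matrix(df[, 1:16])
    set.seed(200 + n)
    queries <- matrix(rnorm(20 * 16), 20, 16)
    for (k in c(1, 3, 5)) {
      if (k > n) next
      got <- knn_predict(df, queries, k = k)
      want <- vapply(1:20, function(i) knn_oracle(x, df$label, queries[i, ], k),
                     character(1))
      expect_identical(got, want)
    }
  }
})

test_that("accuracy and specificity follow their closed forms", {
  expect_equal(accuracy_pct(list(tp = 2, tn = 3, fp = 1, fn = 0)), 500 / 6)
  expect_equal(accuracy_pct(list(tp = 5, tn = 10, fp = 0, fn = 0)), 100)
  expect_equal(accuracy_pct(list(tp = 0, tn = 0, fp = 2, fn = 1)), 0)
  expect_error(accuracy_pct(list(tp = 0, tn = 0, fp = 0, fn = 0)), "undefined")

  expect_equal(specificity_frac(list(tp = 0, tn = 3, fp = 1, fn = 0)), 0.75)
  expect_equal(specificity_frac(list(tp = 1, tn = 4, fp = 0, fn = 2)), 1.0)
  expect_equal(specificity_frac(list(tp = 1, tn = 0, fp = 3, fn = 2)), 0.0)
  expect_error(specificity_frac(list(tp = 1, tn = 0, fp = 0, fn = 2)), "undefined")
})

test_that("one-vs-rest confusion counts partition every instance", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(20:100, 1)
    truth <- sample(c("N", "RBBB", "WPW"), n, replace = TRUE)
    pred <- sample(c("N", "RBBB", "WPW"), n, replace = TRUE)
    cc <- confusion_counts(truth, pred)
    expect_true(all(cc$tp + cc$tn + cc$fp + cc$fn == n))
    expect_equal(sum(cc$tp), sum(truth == pred))
  }
})

test_that("cross-validation is stratified, seeded and bit-reproducible", {
  df <- random_feature_df(60, seed = 43)
  names(df) <- c(feature_names(), "label")
  class(df) <- c("feature_matrix", "data.frame")

  r1 <- cross_validate(df, k = 3, folds = 5, seed = 9)
  r2 <- cross_validate(df, k = 3, folds = 5, seed = 9)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$fold_assignments, r2$fold_assignments)
  expect_equal(r1$average_accuracy, r2$average_accuracy)

  # stratification: every fold holds every class
  for (f in 1:5) {
    expect_setequal(unique(df$label[r1$fold_assignments == f]),
                    unique(df$label))
  }
  # averages are the arithmetic means of the per-class values
  expect_equal(r1$average_accuracy, mean(r1$per_class$accuracy))
  expect_equal(r1$average_specificity, mean(r1$per_class$specificity))

  expect_error(cross_validate(df, folds = 25, seed = 1), ">=")
})

test_that("accuracy is invariant to a rotation of feature space", {
  df <- random_feature_df(90, seed = 44)
  names(df) <- c(feature_names(), "label")
  class(df) <- c("feature_matrix", "data.frame")
  base <- cross_validate(df, k = 5, folds = 5, seed = 2)

  set.seed(45)
  q <- qr.Q(qr(matrix(rnorm(256), 16, 16)))
  rot <- df
  rot[, feature_names()] <- as.matrix(df[, feature_names()]) %*% q
  rotated <- cross_validate(rot, k = 5, folds = 5, seed = 2)
  expect_identical(rotated$predictions, base$predictions)
  expect_equal(rotated$average_accuracy, base$average_accuracy)
})

test_that("training-label noise degrades accuracy monotonically", {
  ds <- generate_dataset(30, noise = zero_noise(), seed = 46)
  fm <- build_feature_matrix(preprocess_records(ds))
  mean_acc <- vapply(c(0, 0.15, 0.4), function(flip) {
    mean(vapply(1:10, function(s) {
      noisy <- fm
      set.seed(500 + s)
      idx <- sample(nrow(fm), round(flip * nrow(fm)))
      noisy$label[idx] <- sample(c("N", "RBBB", "WPW"), length(idx),
                                 replace = TRUE)
      cross_validate(noisy, k = 5, folds = 10, seed = s)$overall_accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_acc) <= 0))
  expect_lt(mean_acc[3], mean_acc[1])
})
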