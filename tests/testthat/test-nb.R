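score_table_from <- function(x, labels, feature = "f1") {
  out <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_along(labels)),
    replicate_id = "avg",
    class_label = factor(labels, levels = c("Ctr", "MCI", "AD", "UNKNOWN"))
  )
  if (is.matrix(x)) {
    colnames(x) <- feature
    cbind(out, tibble::as_tibble(x))
  } else {
    out[[feature]] <- x
    out
  }
}

test_that("a symmetric two-class problem puts the decision boundary at zero", {
  tab <- score_table_from(c(-1.2, -0.8, 0.8, 1.2), c("Ctr", "Ctr", "MCI", "MCI"))
  m <- train_nb(tab, features = "f1")
  newt <- score_table_from(c(-0.01, 0.01), c("Ctr", "MCI"))
  calls <- classify_nb(m, newt)
  expect_equal(as.character(calls$predicted), c("Ctr", "MCI"))
})

test_that("duplicating every row leaves the model parameters unchanged", {
  set.seed(3)
  tab <- score_table_from(rnorm(8), rep(c("Ctr", "AD"), each = 4))
  dup <- tab[rep(seq_len(nrow(tab)), 2), ]
  dup$subject_id <- sprintf("s%02d", seq_len(nrow(dup)))
  m1 <- train_nb(tab, features = "f1")
  m2 <- train_nb(dup, features = "f1")
  expect_equal(m1$mean, m2$mean)
  expect_equal(m1$variance, m2$variance)
  expect_equal(m1$priors, m2$priors)
})

test_that("posteriors match the closed form to 1e-12 on a 1-feature fixture", {
  tab <- score_table_from(
    c(-1.5, -1.0, -0.5, 0.5, 1.0, 1.5),
    rep(c("Ctr", "AD"), each = 3)
  )
  m <- train_nb(tab, features = "f1", priors = "empirical")
  x <- 0.3
  newt <- score_table_from(x, "Ctr")
  calls <- classify_nb(m, newt)
  lik <- function(cl) {
    0.5 * stats::dnorm(x, m$mean[cl, "f1"], sqrt(m$variance[cl, "f1"]))
  }
  post_ctr <- lik("Ctr") / (lik("Ctr") + lik("AD"))
  expect_equal(calls$post_Ctr, post_ctr, tolerance = 1e-12)
  expect_equal(calls$post_Ctr + calls$post_AD, 1, tolerance = 1e-12)
})

test_that("naive Bayes agrees with the e1071 reference on random data", {
  skip_if_not_installed("e1071")
  set.seed(7)
  x <- matrix(rnorm(180), 60, 3)
  labels <- rep(c("Ctr", "MCI", "AD"), length.out = 60)
  x[labels == "AD", 1] <- x[labels == "AD", 1] + 2
  tab <- score_table_from(x, labels, feature = c("f1", "f2", "f3"))
  mine <- train_nb(tab, features = c("f1", "f2", "f3"))
  ref <- e1071::naiveBayes(x, factor(labels))
  calls <- classify_nb(mine, tab)
  ref_pred <- predict(ref, x)
  expect_equal(as.character(calls$predicted), as.character(ref_pred))
  ref_post <- predict(ref, x, type = "raw")
  # e1071 uses the sample-variance convention, so posteriors agree only up
  # to that convention; class calls agree exactly above
  expect_lt(max(abs(calls$post_AD - ref_post[, "AD"])), 0.05)
})

test_that("each training mean vector is classified as its own class", {
  set.seed(9)
  x <- matrix(rnorm(45), 15, 3)
  labels <- rep(c("Ctr", "MCI", "AD"), each = 5)
  x[labels == "MCI", 2] <- x[labels == "MCI", 2] + 3
  x[labels == "AD", 3] <- x[labels == "AD", 3] - 3
  tab <- score_table_from(x, labels, feature = c("f1", "f2", "f3"))
  m <- train_nb(tab, features = c("f1", "f2", "f3"), priors = "uniform")
  centers <- score_table_from(m$mean, c("Ctr", "MCI", "AD"), feature = c("f1", "f2", "f3"))
  expect_equal(as.character(classify_nb(m, centers)$predicted), c("Ctr", "MCI", "AD"))
})

test_that("recall is invariant to positive rescaling of a feature column", {
  set.seed(11)
  x <- matrix(rnorm(40), 20, 2)
  labels <- rep(c("Ctr", "AD"), each = 10)
  x[labels == "AD", ] <- x[labels == "AD", ] + 1.5
  tab <- score_table_from(x, labels, feature = c("f1", "f2"))
  m <- train_nb(tab, features = c("f1", "f2"))
  base <- evaluate_recall(m, tab)$overall_accuracy

  tab2 <- tab
  tab2$f1 <- tab2$f1 * 37.5
  m2 <- train_nb(tab2, features = c("f1", "f2"))
  expect_equal(evaluate_recall(m2, tab2)$overall_accuracy, base)
})

test_that("recall bookkeeping and input validation behave", {
  tab <- score_table_from(c(-1, -2, 1, 2), c("Ctr", "Ctr", "AD", "AD"))
  m <- train_nb(tab, features = "f1")
  r <- evaluate_recall(m, tab)
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$misclassification_rate, 0)
  expect_equal(unname(rowSums(r$confusion)), c(2, 2))

  expect_error(train_nb(tab, features = "nope"), "not in the score table")
  one_row <- score_table_from(c(-1, 1, 2), c("Ctr", "AD", "AD"))
  expect_error(train_nb(one_row, features = "f1"), "at least 2 rows")
  expect_error(classify_nb(m, tab[, 1:3]), "lacks model feature")
})

test_that("recall tracks the Bayes error when separation is dialled down", {
  # one Gaussian feature, two balanced classes at +/- delta with unit sd:
  # Bayes error = pnorm(-delta); delta = 0.6745 gives ~25%
  delta <- stats::qnorm(0.75)
  set.seed(13)
  acc <- vapply(1:50, function(i) {
    n <- 40
    x <- c(rnorm(n, -delta), rnorm(n, delta))
    tab <- score_table_from(x, rep(c("Ctr", "AD"), each = n))
    m <- train_nb(tab, features = "f1")
    xt <- c(rnorm(n, -delta), rnorm(n, delta))
    tt <- score_table_from(xt, rep(c("Ctr", "AD"), each = n))
    evaluate_recall(m, tt)$overall_accuracy
  }, 1)
  expect_lt(abs(mean(acc) - 0.75), 0.05)
})

test_that("feature-subset search returns the separable candidate", {
  set.seed(17)
  sim <- simulate_tears(default_profiles(n_subjects = c(Ctr = 4, MCI = 4, AD = 5)), seed = 17)
  subj <- average_replicates(preprocess_spectra(sim$spectra))
  tab <- build_score_table(subj)

  single <- search_feature_subsets(tab,
    candidate_intervals = "1202-1307",
    candidate_pcs = list(3:6)
  )
  expect_identical(single$intervals, "1202-1307")
  expect_s3_class(single$log, "data.frame")

  res <- search_feature_subsets(tab,
    candidate_intervals = model_intervals(),
    candidate_pcs = list(3:6), budget = 60
  )
  expect_true(res$recall >= single$recall)
  expect_true(all(res$intervals %in% model_intervals()))
  expect_error(search_feature_subsets(tab, character()), "non-empty")
})
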