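test_that("MET values map to the standard three-level classes", {
  expect_equal(as.character(met_to_class(2)), "low")
  expect_equal(as.character(met_to_class(4)), "medium")
  expect_equal(as.character(met_to_class(7)), "high")
  # boundary convention: the table's explicit <=3 and >=6 win
  expect_equal(as.character(met_to_class(3)), "low")
  expect_equal(as.character(met_to_class(6)), "high")
  expect_error(met_to_class(-1), ">= 0")
})

test_that("met_to_class is monotone over a fine MET grid", {
  grid <- seq(0, 12, by = 0.05)
  cls <- as.integer(met_to_class(grid))
  expect_true(all(diff(cls) >= 0))
})

# small well-separated HRV feature set for the SVM unit tests
make_separable_features <- function(n_per_class = 30, seed = 71) {
  set.seed(seed)
  centers <- list(low = c(hr = 70, rr = 857),
                  medium = c(hr = 105, rr = 571),
                  high = c(hr = 150, rr = 400))
  rows <- list(); labs <- character(0)
  for (cl in names(centers)) {
    for (i in seq_len(n_per_class)) {
      hr <- centers[[cl]][["hr"]] + rnorm(1, 0, 3)
      rr <- 60000 / hr
      rows[[length(rows) + 1L]] <- c(mean_hr_bpm = hr, mean_rr_ms = rr,
                                     sdnn_ms = abs(rnorm(1, 30, 5)),
                                     rmssd_ms = abs(rnorm(1, 25, 5)),
                                     pnn50 = runif(1, 0, 0.3),
                                     cv_rr = abs(rnorm(1, 0.04, 0.01)))
      labs <- c(labs, cl)
    }
  }
  list(x = do.call(rbind, rows),
       y = factor(labs, c("low", "medium", "high")))
}

test_that("the RBF SVM separates well-separated intensity classes", {
  d <- make_separable_features()
  clf <- train_intensity_svm(d$x, d$y, seed = 1)
  pred <- predict_intensity(clf, d$x)
  expect_gte(mean(pred == d$y), 0.95)
  # a training vector re-presented gets its own label
  expect_equal(as.character(pred[1]), as.character(d$y[1]))
  # identical vectors in a batch get identical labels
  dup <- predict_intensity(clf, d$x[c(5, 5), ])
  expect_equal(dup[1], dup[2])
})

test_that("training is invariant to row order and tolerates label conflicts", {
  d <- make_separable_features(n_per_class = 20, seed = 72)
  clf1 <- train_intensity_svm(d$x, d$y, seed = 1)
  perm <- sample(nrow(d$x))
  clf2 <- train_intensity_svm(d$x[perm, ], d$y[perm], seed = 1)
  probe <- d$x + matrix(rnorm(length(d$x), 0, 0.1), nrow(d$x))
  expect_equal(as.character(predict_intensity(clf1, probe)),
               as.character(predict_intensity(clf2, probe)))

  # duplicate feature vector with conflicting labels still trains (soft margin)
  xconf <- rbind(d$x, d$x[1, ], d$x[1, ])
  yconf <- factor(c(as.character(d$y), "low", "high"),
                  c("low", "medium", "high"))
  expect_s3_class(train_intensity_svm(xconf, yconf, seed = 1),
                  "intensity_svm")
})

test_that("degenerate SVM inputs are rejected", {
  d <- make_separable_features(n_per_class = 10)
  one <- d$y == "low"
  expect_error(train_intensity_svm(d$x[one, ], d$y[one]), "two classes")
  clf <- train_intensity_svm(d$x, d$y)
  expect_error(predict_intensity(clf, d$x[, 1:3]), "dimension")
  expect_error(svm_config(gamma = 0), "gamma")
  expect_error(svm_config(penalty_C = -1), "penalty_C")
})

test_that("held-out synthetic epochs classify with >= 90% accuracy", {
  sessions <- generate_intensity_sessions(n_epochs = 120, epoch_s = 30,
                                          hr_sd_bpm = 2, seed = 73)
  feats <- t(vapply(sessions, function(s) {
    hrv_features(rr_from_peaks(s$annotation))
  }, numeric(6)))
  labs <- factor(vapply(sessions, function(s) as.character(s$label),
                        character(1)), c("low", "medium", "high"))
  tr <- seq(1, 120, by = 2); te <- seq(2, 120, by = 2)
  clf <- train_intensity_svm(feats[tr, ], labs[tr], seed = 2)
  pred <- predict_intensity(clf, feats[te, ])
  expect_gte(mean(pred == labs[te]), 0.90)
})

test_that("intensity evaluation reproduces aggregate-rate arithmetic", {
  ref <- factor(rep(c("low", "medium", "high"), each = 4),
                c("low", "medium", "high"))
  perfect <- evaluate_intensity(ref, ref)
  expect_equal(perfect$overall_accuracy_pct, 100)
  expect_equal(perfect$per_class$fn_rate_pct, c(0, 0, 0))
  expect_equal(perfect$per_class$fp_rate_pct, c(0, 0, 0))

  wrong <- factor(rep(c("medium", "low", "low"), each = 4),
                  c("low", "medium", "high"))
  allwrong <- evaluate_intensity(wrong, ref)
  expect_equal(allwrong$overall_accuracy_pct, 0)

  expect_equal(average_rates(c(87.5, 90.625, 100, 93.75)), 92.97)
  expect_error(evaluate_intensity(ref[1:3], ref), "lengths differ")
})
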