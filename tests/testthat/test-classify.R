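test_that("confusion matrices count the label pairs", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         classes = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(truth = c("a", "b"),
                                                   predicted = c("a", "b"))),
               ignore_attr = "class")
  # perfect predictions: diagonal
  y <- rep(c("x", "y", "z"), times = c(4, 5, 6))
  cmd <- confusion_matrix(y, y)
  expect_equal(unname(diag(cmd)), c(4, 5, 6))
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)
  # row sums are the true-class frequencies
  set.seed(2)
  pred <- sample(c("x", "y", "z"), length(y), replace = TRUE)
  cmr <- confusion_matrix(y, pred, classes = c("x", "y", "z"))
  expect_equal(unname(rowSums(cmr)), c(4, 5, 6))
  expect_error(confusion_matrix(c("a"), c("q"), classes = "a"), "unknown")
  expect_error(confusion_matrix(c("a", "a"), "a"), "equal length")
})

test_that("report percentages reproduce the worked confusion-matrix cases", {
  # bradycardia row 35/41 correct, normal row 87/95 correct
  truth <- rep(c("bradycardia", "normal"), c(41, 95))
  pred <- c(rep("bradycardia", 35), rep("normal", 6),
            rep("normal", 87), rep("bradycardia", 8))
  rep1 <- class_report(confusion_matrix(truth, pred,
                                        c("bradycardia", "normal")))
  expect_equal(round(rep1$sensitivity[["bradycardia"]], 1), 85.4)
  expect_equal(round(rep1$sensitivity[["normal"]], 1), 91.6)
  # 41 bradycardia with 9 + 7 errors: sensitivity 61%
  t2 <- rep("bradycardia", 41)
  p2 <- c(rep("bradycardia", 25), rep("normal", 9), rep("tachycardia", 7))
  rep2 <- class_report(confusion_matrix(c(t2, "normal", "tachycardia"),
                                        c(p2, "normal", "tachycardia"),
                                        rhythm_classes()))
  expect_equal(round(rep2$sensitivity[["bradycardia"]], 0), 61)
  # 2 errors out of 41: 95.1%; 1 correct out of 41: 2.4%
  p3 <- c(rep("bradycardia", 39), rep("normal", 2))
  rep3 <- class_report(confusion_matrix(c(t2, "normal"), c(p3, "normal"),
                                        c("bradycardia", "normal")))
  expect_equal(round(rep3$sensitivity[["bradycardia"]], 1), 95.1)
  expect_equal(round(rep3$misclassification[["bradycardia"]], 1), 4.9)
  p4 <- c("bradycardia", rep("normal", 40))
  rep4 <- class_report(confusion_matrix(c(t2, "normal"), c(p4, "normal"),
                                        c("bradycardia", "normal")))
  expect_equal(round(rep4$sensitivity[["bradycardia"]], 1), 2.4)
})

test_that("reports match brute-force recomputation from raw labels", {
  set.seed(31)
  for (rep_i in 1:10) {
    k <- sample(2:10, 1)
    classes <- letters[seq_len(k)]
    n <- 200
    truth <- sample(classes, n, replace = TRUE)
    # ensure every class appears as truth
    truth[seq_len(k)] <- classes
    pred <- sample(classes, n, replace = TRUE)
    rp <- class_report(confusion_matrix(truth, pred, classes))
    for (cl in classes) {
      expect_equal(rp$sensitivity[[cl]],
                   100 * sum(truth == cl & pred == cl) / sum(truth == cl))
      np <- sum(pred == cl)
      if (np > 0) {
        expect_equal(rp$precision[[cl]],
                     100 * sum(truth == cl & pred == cl) / np)
      } else {
        expect_true(is.na(rp$precision[[cl]]))
        expect_true(rp$undefined_precision[[cl]])
      }
    }
    expect_equal(rp$accuracy, 100 * mean(truth == pred))
    # accuracy invariant under class-order permutation
    perm <- sample(classes)
    expect_equal(class_report(confusion_matrix(truth, pred, perm))$accuracy,
                 rp$accuracy)
  }
})

test_that("report rows with empty truth classes are rejected", {
  cm <- confusion_matrix(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_error(class_report(cm), "at least one")
})

test_that("k-fold summaries use the sample standard deviation", {
  mk <- function(acc) {
    cmx <- confusion_matrix(c("a", "b"), c("a", "b"))
    r <- class_report(cmx)
    r$accuracy <- acc
    r$sensitivity[] <- acc
    r$precision[] <- acc
    r
  }
  s <- summarize_kfold(list(mk(96), mk(98)))
  expect_equal(unname(s$mean[["accuracy"]]), 97)
  expect_equal(unname(s$sd[["accuracy"]]), sqrt(2), tolerance = 1e-9)
  s0 <- summarize_kfold(list(mk(95), mk(95), mk(95)))
  expect_equal(unname(s0$sd[["accuracy"]]), 0)
  expect_gte(s$mean[["accuracy"]], 96)
  expect_lte(s$mean[["accuracy"]], 98)
  expect_error(summarize_kfold(list(mk(90))), "at least two")
})

test_that("a separable toy image set is learned almost perfectly", {
  dir <- withr::local_tempdir()
  m <- make_toy_image_dataset(dir)
  model <- train_classifier(m, classifier_spec("mlp", feature_size = 8,
                                               hidden = 4, maxit = 200),
                            seed = 5)
  pred <- predict(model, m)
  expect_gte(mean(pred == m$class), 0.99)
  # determinism: identical predictions across two training runs
  model2 <- train_classifier(m, classifier_spec("mlp", feature_size = 8,
                                                hidden = 4, maxit = 200),
                             seed = 5)
  expect_identical(pred, predict(model2, m))
  # row order does not change the fitted model's behavior
  shuf <- m[sample(nrow(m)), ]
  model3 <- train_classifier(shuf, classifier_spec("mlp", feature_size = 8,
                                                   hidden = 4, maxit = 200),
                             seed = 5)
  expect_gte(mean(predict(model3, m) == m$class), 0.99)
})

test_that("the majority baseline sits at chance on balanced classes", {
  dir <- withr::local_tempdir()
  m <- make_toy_image_dataset(dir, n_per_class = 6)
  model <- train_classifier(m, classifier_spec("majority"), seed = 1)
  ev <- evaluate(model, m)
  expect_equal(ev$report$accuracy, 100 / 3, tolerance = 1e-9)
  # a perfect model: accuracy and all sensitivities 100
  mlp <- train_classifier(m, classifier_spec("mlp", feature_size = 8,
                                             hidden = 4), seed = 2)
  ev2 <- evaluate(mlp, m)
  if (ev2$report$accuracy == 100) {
    expect_true(all(ev2$report$sensitivity == 100))
  }
  expect_error(
    train_classifier(m[m$class == "normal", ], classifier_spec("mlp")),
    "two classes")
  expect_error(evaluate(mlp, data.frame(path = "nope.png", class = "weird")),
               "not seen")
})

test_that("missing image files are reported by path", {
  m <- fake_manifest(2)
  expect_error(train_classifier(m, classifier_spec("mlp"), seed = 1),
               "img_0001.png")
})
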