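# Confusion counting, per-class and micro-averaged metrics, exact-match
# accuracy, and the across-seed t-test.

test_that("confusion counts match elementwise comparison and conserve the batch size", {
  truth <- matrix(c(0, 1, 1), 3, 1)
  pred <- matrix(0, 3, 1)
  cc <- confusion_counts(pred, truth)
  expect_equal(unname(unlist(cc[1, c("tp", "tn", "fp", "fn")])), c(0, 1, 0, 2))
  # perfect predictions: no false counts
  set.seed(5)
  t2 <- matrix(rbinom(40, 1, 0.4), 10, 4)
  cc2 <- confusion_counts(t2, t2)
  expect_true(all(cc2$fp == 0) && all(cc2$fn == 0))
  expect_true(all(cc2$tp + cc2$tn + cc2$fp + cc2$fn == 10))
  # swapping predictions and labels swaps fp <-> fn, fixes tp and tn
  p3 <- matrix(rbinom(40, 1, 0.5), 10, 4)
  a <- confusion_counts(p3, t2); b <- confusion_counts(t2, p3)
  expect_equal(a$fp, b$fn); expect_equal(a$fn, b$fp)
  expect_equal(a$tp, b$tp); expect_equal(a$tn, b$tn)
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("per-class formulas with the zero-denominator-absent convention", {
  cc <- data.frame(class = "x", tp = 2, tn = 1, fp = 0, fn = 0)
  class(cc) <- c("confusion_counts", "data.frame")
  m <- per_class_metrics(cc)
  expect_equal(c(m$acc, m$sen, m$spe), c(1, 1, 1))
  # all-negative class, perfect predictions: sensitivity is absent, not 0 or 1
  truth <- matrix(0, 5, 1); pred <- matrix(0, 5, 1)
  m2 <- per_class_metrics(confusion_counts(pred, truth))
  expect_equal(m2$spe, 1)
  expect_true(is.na(m2$sen))
  # doubling all counts leaves the metrics unchanged
  cc3 <- data.frame(class = "x", tp = 3, tn = 4, fp = 2, fn = 1)
  cc6 <- data.frame(class = "x", tp = 6, tn = 8, fp = 4, fn = 2)
  class(cc3) <- class(cc6) <- c("confusion_counts", "data.frame")
  expect_equal(per_class_metrics(cc3)[, -1], per_class_metrics(cc6)[, -1])
})

test_that("micro-average pools counts before applying the formulas", {
  # pooled TP=2, TN=2, FP=0, FN=2 over two classes of 3 images
  cc <- data.frame(class = c("a", "b"), tp = c(1, 1), tn = c(1, 1),
                   fp = c(0, 0), fn = c(1, 1))
  class(cc) <- c("confusion_counts", "data.frame")
  mu <- micro_average(cc)
  expect_equal(unname(mu), c(4 / 6, 2 / 4, 2 / 2))
  # single class: micro equals per-class
  one <- cc[1, ]; class(one) <- c("confusion_counts", "data.frame")
  pc <- per_class_metrics(one)
  expect_equal(unname(micro_average(one)), c(pc$acc, pc$sen, pc$spe))
  # everything correct
  t <- matrix(rbinom(24, 1, 0.5), 6, 4)
  expect_equal(unname(micro_average(confusion_counts(t, t))), c(1, 1, 1))
})

test_that("micro-average equals a brute-force per-image loop on random data", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    truth <- matrix(rbinom(n * 4, 1, 0.35), n, 4)
    pred <- matrix(rbinom(n * 4, 1, 0.45), n, 4)
    oc <- oracle_confusion(pred, truth)
    mu <- micro_average(confusion_counts(pred, truth))
    tp <- sum(oc$tp); tn <- sum(oc$tn); fp <- sum(oc$fp); fn <- sum(oc$fn)
    expect_equal(unname(mu), c((tp + tn) / (tp + tn + fp + fn),
                               tp / (tp + fn), tn / (tn + fp)))
  }
})

test_that("metrics are invariant to image order", {
  set.seed(9)
  truth <- matrix(rbinom(80, 1, 0.3), 20, 4)
  pred <- matrix(rbinom(80, 1, 0.5), 20, 4)
  perm <- sample(20)
  expect_equal(micro_average(confusion_counts(pred, truth)),
               micro_average(confusion_counts(pred[perm, ], truth[perm, ])))
  expect_equal(patient_level_accuracy(pred, truth),
               patient_level_accuracy(pred[perm, ], truth[perm, ]))
})

test_that("patient-level accuracy is exact-match", {
  # three co-occurring diseases, two detected: incorrect
  truth <- matrix(c(1, 1, 1, 0), 1, 4)
  pred <- matrix(c(1, 1, 0, 0), 1, 4)
  expect_equal(patient_level_accuracy(pred, truth), 0)
  # all vectors match
  set.seed(2)
  t <- matrix(rbinom(32, 1, 0.5), 8, 4)
  expect_equal(patient_level_accuracy(t, t), 1)
  # 3 images, exactly one exact match
  truth3 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 1))
  pred3 <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 1, 1))
  expect_equal(patient_level_accuracy(pred3, truth3), 1 / 3)
  # grouped variant: a patient is correct only if every frame matches
  pat <- c("A", "A", "B")
  expect_equal(patient_level_accuracy(pred3, truth3, patient = pat), 0)
  pred3b <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(patient_level_accuracy(pred3b, truth3, patient = pat), 1 / 2)
})

test_that("t-test matches the reference implementation and handles degeneracy", {
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(5, mean = 0.97, sd = 0.002)
    b <- rnorm(5, mean = 0.965, sd = 0.003)
    ours <- metric_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  same <- metric_t_test(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$t, 0)
  expect_false(same$significant)
  # zero variance in both groups
  expect_equal(metric_t_test(c(1, 1), c(1, 1))$p, 1)
  expect_equal(metric_t_test(c(1, 1), c(2, 2))$p, 0)
  # widely separated, tiny variance: significant
  far <- metric_t_test(c(0.99, 0.991, 0.989), c(0.5, 0.501, 0.499))
  expect_true(far$significant)
  expect_lte(far$p, 0.05)
  expect_error(metric_t_test(1, c(1, 2)), "at least 2")
})

test_that("metric report bundles consistent numbers", {
  set.seed(4)
  truth <- matrix(rbinom(60, 1, 0.3), 15, 4)
  pred <- matrix(rbinom(60, 1, 0.4), 15, 4)
  rep <- metric_report(pred, truth)
  expect_equal(unname(rep$micro), unname(micro_average(rep$counts)))
  expect_gte(rep$patient_level, 0); expect_lte(rep$patient_level, 1)
  expect_equal(rep$patient_level == 1, all(pred == truth))
})
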