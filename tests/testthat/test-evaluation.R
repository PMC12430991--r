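test_that("confusion counts are conserved and labeled correctly", {
  truth <- rep(c("Negative", "Neutral", "Positive"), times = c(4, 3, 3))
  cm <- confusion(truth, truth, labels = c("Negative", "Neutral", "Positive"))
  expect_equal(sum(diag(unclass(cm))), 10)
  expect_equal(sum(unclass(cm)), 10)

  empty <- confusion(character(0), character(0), labels = c("a", "b"))
  expect_equal(sum(unclass(empty)), 0)

  expect_error(confusion(c("a", "b"), "a"), "different lengths")
  expect_error(confusion("a", "z", labels = c("a", "b")), "unknown label")
})

test_that("binary wearable counts reproduce the printed classification metrics", {
  # 4720 baseline and 2403 stress samples correct, 289 stress-as-baseline
  # errors, zero false positives, 7412 total
  cm <- confusion_from_counts(rbind(c(4720, 0), c(289, 2403)),
                              labels = c("baseline", "stress"))
  expect_equal(sum(unclass(cm)), 7412)
  met <- class_metrics(cm)
  expect_equal(attr(met, "accuracy"), 7123 / 7412)
  expect_equal(round(attr(met, "accuracy"), 2), 0.96)
  stress <- met[met$class == "stress", ]
  expect_equal(stress$precision, 1.00)
  expect_equal(round(stress$recall, 2), 0.89)
  expect_equal(round(stress$f1, 2), 0.94)
  expect_equal(round(met$f1[met$class == "baseline"], 2), 0.97)
})

test_that("per-class metrics handle empty rows/columns and permute consistently", {
  cm <- confusion_from_counts(rbind(c(5, 0, 0), c(2, 0, 0), c(0, 0, 3)),
                              labels = c("a", "b", "c"))
  met <- class_metrics(cm)
  expect_equal(met$precision[met$class == "b"], 0)  # empty column
  expect_equal(met$recall[met$class == "b"], 0)
  expect_equal(met$f1[met$class == "b"], 0)
  expect_equal(attr(met, "accuracy"), 8 / 10)
  # permuting the label order permutes the metrics consistently
  cmp <- confusion_from_counts(rbind(c(3, 0, 0), c(0, 5, 0), c(0, 2, 0)),
                               labels = c("c", "a", "b"))
  metp <- class_metrics(cmp)
  expect_equal(attr(metp, "accuracy"), attr(met, "accuracy"))
  for (cl in c("a", "b", "c")) {
    expect_equal(metp$f1[metp$class == cl], met$f1[met$class == cl])
  }
  # F1 lies between precision and recall wherever both are positive
  ok <- met$precision > 0 & met$recall > 0
  expect_true(all(met$f1[ok] >= pmin(met$precision, met$recall)[ok] - 1e-12))
  expect_true(all(met$f1[ok] <= pmax(met$precision, met$recall)[ok] + 1e-12))
  expect_error(class_metrics(confusion(character(0), character(0),
                                       labels = "a")), "empty")
})

test_that("ROC handles perfect, uninformative, and degenerate rankings", {
  truth <- c(rep("pos", 5), rep("neg", 5))
  perfect <- roc_ovr(data.frame(pos = c(5:1, -(1:5))), truth, labels = "pos")
  expect_equal(unname(perfect$auc), 1.0)

  flat <- roc_ovr(data.frame(pos = rep(1, 10)), truth, labels = "pos")
  expect_equal(unname(flat$auc), 0.5)
  # tie grouping: one diagonal step from (0,0) to (1,1)
  expect_identical(nrow(flat$points), 2L)

  single <- roc_ovr(data.frame(pos = 1:5), rep("pos", 5), labels = "pos")
  expect_true(is.na(single$auc))
})

test_that("trapezoid AUC equals the Mann-Whitney rank statistic", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    truth <- sample(c("s", "n"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    r <- roc_ovr(data.frame(s = scores), truth, labels = "s")
    expect_equal(unname(r$auc), mw_auc(scores, truth == "s"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  truth <- sample(0:1, 60, replace = TRUE)
  scores <- rnorm(60) + truth
  ours <- roc_ovr(data.frame(`1` = scores, check.names = FALSE), truth,
                  labels = "1")
  ref <- pROC::auc(pROC::roc(truth, scores, direction = "<", quiet = TRUE))
  expect_equal(unname(ours$auc), as.numeric(ref), tolerance = 1e-12)
})

test_that("pearson matches the explicit covariance formula and affine invariance", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson(x, y)
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$n, 5)
  # p value from the t transform
  t_stat <- r_oracle * sqrt(3) / sqrt(1 - r_oracle^2)
  expect_equal(got$p_value, 2 * stats::pt(-abs(t_stat), df = 3),
               tolerance = 1e-12)

  expect_equal(pearson(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson(x, -x)$r, -1.0)
  set.seed(1)
  a <- rnorm(30); b <- rnorm(30) + a
  expect_equal(pearson(3 * a + 7, b)$r, pearson(a, b)$r, tolerance = 1e-12)

  expect_error(pearson(1:5, rep(1, 5)), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("summary stats follow the documented conventions", {
  expect_equal(summary_stats(c(1, 2, 3))$median, 2)
  expect_equal(summary_stats(c(1, 2, 3))$mean, 2)
  expect_equal(summary_stats(c(1, 2, 3, 4))$median, 2.5)  # midpoint for even n
  expect_equal(summary_stats(rep(7, 5))$iqr, 0)
  s <- summary_stats(c(1, 2, 3, 4))
  expect_equal(s$q1, 1.75)  # linear interpolation (type 7)
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("tidy and glance accessors expose the expected columns", {
  cm <- confusion_from_counts(rbind(c(4, 1), c(2, 3)), labels = c("a", "b"))
  td <- tidy(cm)
  expect_named(td, c("truth", "pred", "n"))
  expect_equal(sum(td$n), 10)
  gl <- glance(cm)
  expect_named(gl, c("accuracy", "macro_f1", "n"))
  r <- roc_ovr(data.frame(a = c(3, 2, 1), b = c(1, 2, 3)),
               c("a", "a", "b"), labels = c("a", "b"))
  expect_named(glance(r), c("auc_a", "auc_b"))
  expect_true(all(c("class", "fpr", "tpr") %in% names(tidy(r))))
})
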