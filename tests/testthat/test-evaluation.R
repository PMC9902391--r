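test_that("confusion tallies match a brute-force count", {
  c0 <- confusion_counts(c("DIC", "nonDIC"), c("DIC", "nonDIC"))
  expect_equal(unclass(c0)[c("TP", "TN", "FP", "FN")],
               list(TP = 1, TN = 1, FP = 0, FN = 0))

  truth <- rep("nonDIC", 7)
  expect_equal(confusion_counts(rep("DIC", 7), truth)$FP, 7)

  set.seed(8)
  pred <- sample(c("DIC", "nonDIC"), 100, replace = TRUE)
  tru <- sample(c("DIC", "nonDIC"), 100, replace = TRUE)
  cc <- confusion_counts(pred, tru)
  brute <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in 1:100) {
    key <- if (pred[i] == "DIC" && tru[i] == "DIC") "TP"
           else if (pred[i] == "DIC") "FP"
           else if (tru[i] == "DIC") "FN" else "TN"
    brute[key] <- brute[key] + 1
  }
  expect_equal(unlist(unclass(cc))[names(brute)], brute)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 100)

  expect_error(confusion_counts(character(0), character(0)), "empty")
  expect_error(confusion_counts("DIC", c("DIC", "DIC")), "mismatch")
})

test_that("the five metrics reproduce the published evaluation", {
  r3 <- function(m) lapply(m, round_half_up, digits = 3)
  m1 <- r3(classification_metrics(list(TP = 201, FN = 10, FP = 304,
                                       TN = 10755)))
  expect_equal(m1, list(ACC = 0.972, TPR = 0.953, TNR = 0.973,
                        PPV = 0.398, NPV = 0.999))
  m2 <- r3(classification_metrics(list(TP = 181, FN = 30, FP = 42,
                                       TN = 11017)))
  expect_equal(m2, list(ACC = 0.994, TPR = 0.858, TNR = 0.996,
                        PPV = 0.812, NPV = 0.997))

  all1 <- classification_metrics(list(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_true(all(unlist(all1) == 1))
})

test_that("zero denominators give an explicit undefined marker", {
  m <- classification_metrics(list(TP = 0, FN = 0, FP = 3, TN = 7))
  expect_true(is.na(m$TPR))
  expect_false(is.na(m$TNR))
  m2 <- classification_metrics(list(TP = 2, FN = 1, FP = 0, TN = 0))
  expect_true(is.na(m2$TNR))
})

test_that("cascade projection composes per-class accuracies", {
  expect_equal(round_half_up(
    100 * project_cascade_fpr(45, list(c(0.975, 0.931))), 1), 54.7)
  expect_equal(project_cascade_fpr(45, list(c(1, 1))), 0)
  two <- project_cascade_fpr(45, list(c(0.975, 0.931), c(0.788, 0.867)))
  direct <- (45 * 0.025 * 0.212) / (45 * 0.025 * 0.212 + 0.931 * 0.867)
  expect_equal(two, direct, tolerance = 1e-12)
})

test_that("projection is monotone in both per-class accuracies", {
  base <- project_cascade_fpr(45, list(c(0.9, 0.9)))
  for (d in c(0.02, 0.05)) {
    expect_lt(project_cascade_fpr(45, list(c(0.9 + d, 0.9))), base)
    expect_lt(project_cascade_fpr(45, list(c(0.9, 0.9 + d))), base)
  }
})

test_that("subgroup accuracy reproduces the entangled-chromosome rates", {
  expect_equal(round_half_up(100 * subgroup_accuracy(94, 51), 1), 45.7)
  expect_equal(round_half_up(100 * subgroup_accuracy(94, 21), 1), 77.7)
})

test_that("the formatted table carries every published percentage", {
  c1 <- structure(list(TP = 201, FN = 10, FP = 304, TN = 10755),
                  class = "confusion_counts")
  c2 <- structure(list(TP = 181, FN = 30, FP = 42, TN = 11017),
                  class = "confusion_counts")
  tab <- paste(format_metrics_table("first-stage only" = c1,
                                    "two-stage" = c2), collapse = "\n")
  for (v in c("97.2%", "95.3%", "97.3%", "39.8%", "99.9%",
              "99.4%", "85.8%", "99.6%", "81.2%", "99.7%"))
    expect_match(tab, v, fixed = TRUE)
})
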