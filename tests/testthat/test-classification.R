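sep_data <- function(n = 40, gap = 6, seed = 1) {
  set.seed(seed)
  data.frame(x = c(rnorm(n / 2, 0), rnorm(n / 2, gap)),
             label = factor(rep(c("a", "b"), each = n / 2)))
}

test_that("bagged trees: separable data, determinism, degenerate inputs", {
  d <- sep_data()
  m <- fit_bagged_trees(d, n_trees = 200, seed = 42)
  expect_gte(oob_accuracy(m), 0.9)
  expect_equal(m$n_trees, 200)
  expect_length(m$trees, 200)
  # every sample out-of-bag for at least one of 200 trees
  expect_length(m$no_oob, 0)

  # deterministic under fixed seed
  m2 <- fit_bagged_trees(d, n_trees = 50, seed = 7)
  m3 <- fit_bagged_trees(d, n_trees = 50, seed = 7)
  expect_identical(m2$oob_predictions, m3$oob_predictions)
  expect_identical(m2$feature_importance, m3$feature_importance)

  # n_trees = 1: valid model, OOB undefined for in-bag samples and flagged
  m1 <- fit_bagged_trees(d, n_trees = 1, seed = 1)
  expect_s3_class(m1, "bagged_trees")
  expect_true(length(m1$no_oob) > 0)
  expect_true(all(is.na(m1$oob_predictions[m1$no_oob])))

  expect_error(fit_bagged_trees(d[1:3, ], n_trees = 10, seed = 1),
               class = "qeeg_degenerate_error")
  dc <- d; dc$label <- factor("a", levels = c("a", "b"))
  expect_error(fit_bagged_trees(dc, n_trees = 10, seed = 1),
               class = "qeeg_degenerate_error")
  expect_error(fit_bagged_trees(data.frame(x = rep(1, 10),
                                           label = factor(rep(c("a", "b"), 5))),
                                n_trees = 10, seed = 1),
               class = "qeeg_degenerate_error")

  # predict() on training data of a separable problem is perfect
  expect_equal(as.character(predict(m, d)), as.character(d$label))
})

test_that("label permutation drives OOB accuracy to chance", {
  d <- sep_data()
  accs <- vapply(1:15, function(s) {
    set.seed(1000 + s)
    dp <- d
    dp$label <- sample(dp$label)
    oob_accuracy(fit_bagged_trees(dp, n_trees = 100, seed = s))
  }, 0)
  chance <- 0.5
  se <- sqrt(0.25 / nrow(d)) # binomial SE of an accuracy at n = 40
  expect_lt(abs(mean(accs) - chance), 3 * se)
})

test_that("oob_confusion: binary matrices and multiclass hand tally", {
  d <- sep_data()
  m <- fit_bagged_trees(d, n_trees = 200, seed = 42)
  cm <- oob_confusion(m, positive = "b")
  expect_s3_class(cm, "confusion_matrix")
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, nrow(d))

  # brute-force tally oracle on a synthetic 4-class prediction set
  lv <- c("w", "x", "y", "z")
  truth <- factor(rep(lv, times = c(9, 4, 9, 3)), levels = lv)
  set.seed(3)
  pred <- factor(sample(lv, length(truth), replace = TRUE), levels = lv)
  fake <- structure(list(levels = lv, y = truth, oob_predictions = pred,
                         oob_count = rep(5L, length(truth))),
                    class = "bagged_trees")
  cms <- oob_confusion(fake)
  expect_named(cms, lv)
  for (cl in lv) {
    expect_equal(cms[[cl]]$tp, sum(pred == cl & truth == cl))
    expect_equal(cms[[cl]]$fp, sum(pred == cl & truth != cl))
    expect_equal(cms[[cl]]$fn, sum(pred != cl & truth == cl))
    expect_equal(cms[[cl]]$tn, sum(pred != cl & truth != cl))
  }

  # perfect predictions: 16 pos / 9 neg
  perfect <- structure(list(levels = c("neg", "pos"),
                            y = factor(rep(c("pos", "neg"), c(16, 9)),
                                       levels = c("neg", "pos")),
                            oob_predictions = factor(
                              rep(c("pos", "neg"), c(16, 9)),
                              levels = c("neg", "pos")),
                            oob_count = rep(3L, 25)),
                       class = "bagged_trees")
  cmp <- oob_confusion(perfect)
  expect_equal(c(cmp$tp, cmp$tn, cmp$fp, cmp$fn), c(16, 9, 0, 0))

  # all predicted positive: tn = 0, fp = #negatives
  allpos <- perfect
  allpos$oob_predictions <- factor(rep("pos", 25), levels = c("neg", "pos"))
  cma <- oob_confusion(allpos)
  expect_equal(cma$tn, 0)
  expect_equal(cma$fp, 9)
})

test_that("confusion metrics and chance accuracy reproduce known values", {
  m1 <- confusion_metrics(confusion_matrix(tp = 7, fp = 2, fn = 4, tn = 12))
  expect_equal(m1$accuracy, 0.76)
  expect_equal(m1$sensitivity, 7 / 11, tolerance = 1e-12)   # 0.636
  expect_equal(m1$specificity, 12 / 14, tolerance = 1e-12)  # 0.857

  m2 <- confusion_metrics(confusion_matrix(tp = 12, fp = 6, fn = 4, tn = 3))
  expect_equal(m2$sensitivity, 0.75)
  expect_equal(m2$specificity, 1 / 3, tolerance = 1e-12)

  m3 <- confusion_metrics(confusion_matrix(tp = 5, fp = 0, fn = 0, tn = 5))
  expect_equal(unlist(m3), c(accuracy = 1, sensitivity = 1, specificity = 1))

  # undefined sensitivity is NA, not zero
  m4 <- confusion_metrics(confusion_matrix(tp = 0, fp = 2, fn = 0, tn = 8))
  expect_true(is.na(m4$sensitivity))

  expect_equal(chance_accuracy(rep(c("p", "n"), c(12, 13))), 0.52)
  expect_equal(chance_accuracy(rep(c("s", "c"), c(16, 9))), 0.64)
  expect_equal(chance_accuracy(rep(1:4, c(9, 4, 9, 3))), 0.36)
  # invariant to label renaming
  expect_equal(chance_accuracy(rep(c("A", "B"), c(12, 13))),
               chance_accuracy(rep(c(1, 0), c(12, 13))))
})

test_that("cohort summaries recompute the demographic table", {
  co <- read_cohort(fixture_path("example_cohort.csv"))
  s <- summarize_cohort(co)
  small <- s[s$severity == "small", ]
  expect_equal(small$n, 4)
  expect_equal(small$mean_days_post_onset, 3.25)
  expect_equal(small$mean_nihss, 2.25)
  ctrl <- s[s$severity == "control", ]
  expect_equal(round(ctrl$mean_age, 1), 60.8)
  expect_true(is.na(ctrl$mean_nihss))
  large <- s[s$severity == "large", ]
  expect_equal(round(large$mean_nihss, 2), 11.33)

  # single-member group reports that member's values
  one <- co[co$id %in% c("1", "12"), ]
  s1 <- summarize_cohort(one)
  expect_equal(s1[s1$severity == "large", "mean_nihss"], 10)
  expect_match(attr(s1, "note"), "small")
})

test_that("anova_pes: definition arithmetic and exact balanced case", {
  # two equal groups -> SS_effect 0 -> eta 0, F 0
  a0 <- anova_pes(rep(c(1, 2), 4), rep(c("g1", "g2"), each = 4))
  expect_equal(a0$ss[1], 0)
  expect_equal(a0$F[1], 0)
  expect_equal(a0$partial_eta_sq[1], 0)

  # partial eta^2 = SS_e / (SS_e + SS_err): construct SS 200 / 10
  a1 <- anova_pes(c(1, 2, 3, 4, 11, 12, 13, 14), rep(c("a", "b"), each = 4))
  expect_equal(a1$ss[1], 200)
  expect_equal(a1$ss[2], 10)
  expect_equal(a1$partial_eta_sq[1], 200 / 210)
  expect_equal(a1$F[1], (200 / 1) / (10 / 6))

  # balanced 2x2, zero noise: saturated fit flagged p = 0, eta = 1
  f1 <- rep(c("a", "b"), each = 4)
  f2 <- rep(c("u", "v"), 4)
  mu <- ifelse(f1 == "a", 0, 3) + ifelse(f2 == "u", 0, 1)
  a2 <- anova_pes(mu, f1, f2)
  expect_equal(a2$p[a2$term == "f1"], 0)
  expect_equal(a2$partial_eta_sq[a2$term == "f1"], 1)
  expect_equal(a2$ss[a2$term == "f1:f2"], 0)

  expect_error(anova_pes(1:4, factor(rep("a", 4))),
               class = "qeeg_parameter_error")
})
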