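test_that("ROC-AUC matches hand values and handles ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both")
})

test_that("ROC-AUC equals all-pairs concordance counting on random data", {
  brute <- function(lab, sc) {
    pos <- sc[lab == 1]; neg <- sc[lab == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(77)
  for (k in 1:200) {
    n <- sample(5:50, 1)
    lab <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(roc_auc(lab, sc), brute(lab, sc))
  }
})

test_that("ROC-AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  lab <- sample(0:1, 200, replace = TRUE)
  sc <- rnorm(200) + lab
  expect_equal(roc_auc(lab, sc),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("PR-AUC is average precision", {
  expect_equal(pr_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(pr_auc(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1)), 0.25)
  expect_equal(pr_auc(rep(1, 5), rnorm(5)), 1)
  expect_error(pr_auc(c(0, 0), c(0.1, 0.2)), "no positive")
  # hand case: positives ranked 1st and 3rd -> (1/1 + 2/3)/2
  expect_equal(pr_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), (1 + 2 / 3) / 2)
})

test_that("up/down problems are built with the right polarity", {
  lab <- expr_label(c(2, -2, 0.5, 1.5, -1.2))
  sc <- c(0.8, -0.7, 0.1, 0.6, -0.5)
  ud <- up_down_scores(lab, sc)
  expect_equal(ud$up$labels, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(ud$down$labels, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(ud$down$scores, -sc)
  expect_error(up_down_scores(lab, sc[-1]), "equal length")

  # negating all scores turns each AUC into its complement
  set.seed(3)
  sc2 <- rnorm(5)
  ud2 <- up_down_scores(lab, sc2)
  ud2n <- up_down_scores(lab, -sc2)
  expect_equal(roc_auc(ud2n$up$labels, ud2n$up$scores),
               1 - roc_auc(ud2$up$labels, ud2$up$scores))
  expect_equal(roc_auc(ud2n$down$labels, ud2n$down$scores),
               1 - roc_auc(ud2$down$labels, ud2$down$scores))
})

test_that("per-instance Pearson averages hand-computed correlations", {
  inst <- rep(c("a", "b"), each = 3)
  targ <- c(1, 2, 3, 1, 2, 3)
  pred <- c(targ[1:3], 2, 1, 3)  # r = 1 and r = cor(c(2,1,3), 1:3)
  want <- (1 + cor(c(2, 1, 3), 1:3)) / 2
  expect_equal(pearson_per_instance(inst, pred, targ), want)
  expect_equal(pearson_per_instance(inst, targ, targ), 1)
  expect_equal(pearson_per_instance(inst, -targ, targ), -1)
  expect_warning(
    r <- pearson_per_instance(inst, pred, c(1, 2, 3, 5, 5, 5)), "excluded")
  expect_equal(r, 1)
})

test_that("confusion matrix counts partition pairs and the error rate is opposite calls", {
  sf <- sf_params()
  x <- c(2, 1.5, -2, -1.6, 0.2, 0.4, 3, -0.1, 0.6, 0.8)  # 5 Up/Down truths
  truth <- expr_label(x)
  good <- step_function(x)
  ce <- confusion_and_error(truth, good, sf)
  expect_equal(sum(ce$confusion), 10)
  expect_equal(ce$error_rate, 0)
  flipped <- confusion_and_error(truth, -good, sf)
  expect_equal(flipped$error_rate, 1)

  # 2 opposite mistakes among 5 Up/Down truths -> 0.4
  pred <- good
  pred[1] <- -0.9  # true Up called Down
  pred[3] <- 0.9   # true Down called Up
  ce2 <- confusion_and_error(truth, pred, sf)
  expect_equal(ce2$error_rate, 2 / 5)
  # switchable denominator: all 10 pairs
  ce3 <- confusion_and_error(truth, pred, sf, denominator = "all")
  expect_equal(ce3$error_rate, 0.2)
  expect_error(confusion_and_error(expr_label(c(0, 0.1)), c(0, 0), sf),
               "undefined")
})

test_that("weighted aggregation reproduces hand arithmetic", {
  expect_equal(weighted_aggregate(c(0.5, 1.0), c(1, 3))$mean, 0.875)
  expect_equal(weighted_aggregate(c(0.2, 0.4, 0.9), c(2, 2, 2))$mean,
               round(mean(c(0.2, 0.4, 0.9)), 4))
  expect_error(weighted_aggregate(c(1, 2), c(1, 0)), "positive")
  expect_error(weighted_aggregate(1, c(1, 2)), "equal length")
  agg <- weighted_aggregate(c(0.5, 1.0), c(1, 3))
  expect_equal(agg$sd_unweighted, sd(c(0.5, 1.0)))
  expect_equal(agg$n_total, 4)
})
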