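test_that("confusion matrices count truth rows against predicted columns", {
  labs <- c("AA", "AS", "SS")
  truth <- rep(labs, c(4, 3, 3))
  cm <- confusion_matrix(truth, truth, labs)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  # independent tally on random vectors
  withr::local_seed(50)
  t2 <- sample(labs, 50, replace = TRUE)
  p2 <- sample(labs, 50, replace = TRUE)
  cm2 <- confusion_matrix(t2, p2, labs)
  for (i in labs) for (j in labs)
    expect_equal(cm2[i, j], sum(t2 == i & p2 == j))

  expect_equal(sum(confusion_matrix(character(0), character(0), labs)), 0)
  expect_error(confusion_matrix("AA", "XX", labs), "labels")
})

test_that("aggregation over raters is additive", {
  labs <- c("AA", "AS", "SS")
  withr::local_seed(51)
  truth <- sample(labs, 30, replace = TRUE)
  r1 <- sample(labs, 30, replace = TRUE)
  r2 <- sample(labs, 30, replace = TRUE)
  agg <- confusion_matrix(c(truth, truth), c(r1, r2), labs)
  expect_equal(unclass(agg),
               unclass(confusion_matrix(truth, r1, labs)) +
                 unclass(confusion_matrix(truth, r2, labs)))
})

test_that("binarize collapses classes and validates the positive set", {
  cm <- confusion_matrix(rep(c("AA", "AS", "SS"), c(18, 17, 20)),
                         rep(c("AA", "AS", "SS"), c(18, 17, 20)))
  bc <- binarize(cm, c("AS", "SS"))
  expect_equal(bc$tp, 37); expect_equal(bc$fn, 0)
  expect_equal(bc$fp, 0); expect_equal(bc$tn, 18)
  expect_error(binarize(cm, c("AA", "AS", "SS")), "proper subset")
  expect_error(binarize(cm, character(0)), "proper subset")

  # restriction drops other classes before binarizing (AS vs SS comparison)
  bc2 <- binarize(cm, "SS", restrict = c("AS", "SS"))
  expect_equal(bc2$tp + bc2$fp + bc2$tn + bc2$fn, 37)

  # brute-force tally on a random matrix
  withr::local_seed(52)
  t3 <- sample(c("AA", "AS", "SS"), 60, replace = TRUE)
  p3 <- sample(c("AA", "AS", "SS"), 60, replace = TRUE)
  bc3 <- binarize(confusion_matrix(t3, p3), "SS")
  expect_equal(bc3$tp, sum(t3 == "SS" & p3 == "SS"))
  expect_equal(bc3$fn, sum(t3 == "SS" & p3 != "SS"))
  expect_equal(bc3$fp, sum(t3 != "SS" & p3 == "SS"))
})

test_that("screening metrics use the standard denominators", {
  bc <- structure(list(tp = 37, fn = 0, fp = 0, tn = 18),
                  class = "binary_counts")
  bm <- binary_metrics(bc)
  est <- setNames(bm$estimate, bm$metric)
  expect_equal(unname(est[c("sensitivity", "specificity")]), c(1, 1))

  # arithmetic oracle on random counts
  withr::local_seed(53)
  for (i in 1:10) {
    k <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                          c("tp", "fp", "tn", "fn")))
    if (sum(unlist(k)) == 0) next
    bm <- binary_metrics(structure(k, class = "binary_counts"))
    est <- setNames(bm$estimate, bm$metric)
    with(k, {
      if (tp + fn > 0) expect_equal(unname(est["sensitivity"]), tp / (tp + fn))
      if (fp + tn > 0) expect_equal(unname(est["specificity"]), tn / (fp + tn))
      if (tp + fp > 0) expect_equal(unname(est["ppv"]), tp / (tp + fp))
      if (tn + fn > 0) expect_equal(unname(est["npv"]), tn / (tn + fn))
      expect_equal(unname(est["accuracy"]), (tp + tn) / (tp + fp + tn + fn))
    })
  }

  # zero denominators are flagged undefined, not silently zero
  bm0 <- binary_metrics(structure(list(tp = 0, fn = 0, fp = 3, tn = 7),
                                  class = "binary_counts"))
  expect_true(is.na(bm0$estimate[bm0$metric == "sensitivity"]))
  expect_false(bm0$defined[bm0$metric == "sensitivity"])
})

test_that("Wilson intervals match their closed form and behave", {
  w <- wilson_interval(1.0, 55)
  expect_equal(round(100 * w$lower, 1), 93.5)
  expect_equal(w$upper, 1)
  expect_equal(round(100 * wilson_interval(1.0, 37)$lower, 1), 90.6)
  w3 <- wilson_interval(0.942, 226)
  expect_equal(round(100 * c(w3$lower, w3$upper), 1), c(90.4, 96.6))

  # symmetry about 1/2
  w5 <- wilson_interval(0.5, 40)
  expect_equal(w5$lower, 1 - w5$upper, tolerance = 1e-12)

  # interval contains the Wilson center; width shrinks with n
  widths <- sapply(c(10, 50, 250, 1000), function(n) {
    w <- wilson_interval(0.3, n)
    center <- (0.3 + 1.96^2 / (2 * n)) / (1 + 1.96^2 / n)
    expect_true(w$lower <= center && center <= w$upper)
    w$upper - w$lower
  })
  expect_true(all(diff(widths) < 0))

  # degenerate endpoints exact at p in {0, 1}
  expect_equal(wilson_interval(0, 20)$lower, 0)
  expect_equal(wilson_interval(1, 20)$upper, 1)
  expect_error(wilson_interval(1.2, 10), "p_hat")
  expect_error(wilson_interval(0.5, 0), "n_eff")
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$auc, 1)
  expect_equal(roc_auc(rep(2, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  withr::local_seed(54)
  for (i in 1:25) {
    n <- sample(5:100, 1)
    scores <- sample(seq(0, 5, 0.5), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, mann_whitney_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")

  # curve endpoints and monotonicity
  rc <- roc_auc(rnorm(40), rep(c(TRUE, FALSE), 20))
  expect_equal(c(rc$tpr[1], rc$fpr[1]), c(0, 0))
  expect_equal(c(tail(rc$tpr, 1), tail(rc$fpr, 1)), c(1, 1))
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
})

test_that("Fleiss' kappa matches hand computation and known regimes", {
  # unanimity with >= 2 categories used is exactly 1
  unan <- matrix(rep(c("AA", "SS", "AS", "AA"), each = 5), ncol = 5,
                 byrow = TRUE)
  expect_equal(fleiss_kappa(unan), 1)

  # 4-subject, 3-rater worked table; direct formula gives 0.5:
  # P_i = (1, 1/3, 1/3, 1), Pbar = 2/3, marginals all 1/3, Pe = 1/3
  tab <- rbind(c("A", "A", "A"), c("A", "B", "B"),
               c("B", "B", "C"), c("C", "C", "C"))
  expect_equal(fleiss_kappa(tab), 0.5, tolerance = 1e-12)

  # invariance under category relabeling
  relab <- matrix(c(X = "X", Y = "Y", Z = "Z")[match(tab, c("A", "B", "C"))],
                  nrow = 4)
  expect_equal(fleiss_kappa(relab), fleiss_kappa(tab))

  # near zero for uniform random ratings
  withr::local_seed(55)
  rnd <- matrix(sample(c("AA", "AS", "SS"), 800 * 5, replace = TRUE),
                ncol = 5)
  expect_lt(abs(fleiss_kappa(rnd)), 0.05)

  expect_error(fleiss_kappa(matrix("A", 3, 1)), "2 raters")
  expect_error(fleiss_kappa(matrix(c("A", NA, "B", "A"), 2, 2)), "every rater")
})

test_that("rater summaries aggregate per-rater metrics with mean and SD", {
  labs <- c("AA", "AS", "SS")
  truth <- rep(labs, c(6, 6, 6))
  perfect <- replicate(3, truth, simplify = FALSE)
  rs <- rater_summary(truth, perfect)
  expect_true(all(rs$mean == 1))
  expect_true(all(rs$sd == 0))

  # seeded error rates match direct recomputation
  withr::local_seed(56)
  noisy <- lapply(1:3, function(i) {
    calls <- truth
    flip <- sample(18, 4)
    calls[flip] <- sample(labs, 4, replace = TRUE)
    calls
  })
  rs2 <- rater_summary(truth, noisy)
  sens <- sapply(noisy, function(p) {
    cm <- confusion_matrix(truth, p, labs)
    bc <- binarize(cm, c("AS", "SS"))
    bc$tp / (bc$tp + bc$fn)
  })
  row <- rs2[rs2$comparison == "any_hbs" & rs2$metric == "sensitivity", ]
  expect_equal(row$mean, mean(sens))
  expect_equal(row$sd, sd(sens))

  expect_error(rater_summary(truth, noisy[1]), "2 raters")
  expect_error(rater_summary(truth, list(truth, truth[-1])), "same subjects")
})

test_that("AUC agrees with an established ROC implementation", {
  withr::local_seed(58)
  scores <- c(rnorm(30, 1), rnorm(30, 1.8))
  labels <- rep(c(FALSE, TRUE), each = 30)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
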