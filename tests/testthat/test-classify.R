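test_that("PCA projection behaves on known covariance structure", {
  # data already 2D with variances (4, 1), uncorrelated: PC1 is the
  # high-variance axis with explained fraction 0.8
  set.seed(3)
  n <- 400
  x2 <- cbind(2 * scale(rnorm(n)), scale(rnorm(n)))
  pc <- prcomp(x2, center = TRUE, scale. = FALSE)
  expect_equal(unname(pc$sdev[1L]^2 / sum(pc$sdev^2)), 0.8,
               tolerance = 0.02)
  expect_gt(abs(pc$rotation[1L, 1L]), 0.99)

  tab <- default_population_table()
  for (space in c("linear", "log")) {
    pr <- pca_project(tab, space)
    expect_equal(dim(pr$scores), c(209L, 2L))
    expect_true(all(diff(pr$explained) <= 1e-12))
    expect_equal(sum(pr$explained), 1, tolerance = 1e-12)
    # sign convention: largest-magnitude loading positive
    for (k in 1:2)
      expect_gt(pr$loadings[which.max(abs(pr$loadings[, k])), k], 0)
  }
  # duplicated rows project to identical points
  pr <- pca_project(tab, "log")
  tab2 <- rbind(tab, tab[1L, ])
  class(tab2) <- class(tab); attr(tab2, "space") <- "linear"
  pr2 <- pca_project(tab2, "log")
  expect_equal(pr2$scores[210L, ], pr2$scores[1L, ], tolerance = 1e-10)
})

test_that("accuracy framework worked examples hold", {
  expect_equal(cell_accuracy(rbind(c(1, 1, 1, 1))), 1)
  expect_equal(cell_accuracy(rbind(c(1, 1, 0, 1))), 0.75)
  expect_equal(cell_accuracy(rbind(c(0, 0, 0, 0))), 0)
  expect_error(cell_accuracy(rbind(c(0, 2))), "binary")

  expect_equal(unname(class_accuracy(c(1, 0.5, 0.2), c(-1, -1, 1))),
               c(0.75, 0.2, mean(c(1, 0.5, 0.2))))
  expect_error(class_accuracy(c(1, 1), c(-1, -1)), "both classes")

  a <- c(1.0, 0.9, 0.5)
  lab <- c(-1, -1, -1)
  expect_equal(unname(ratio_above(c(a, 1), c(lab, 1), 0.85))[1L], 2 / 3)
  expect_equal(unname(ratio_above(c(a, 1), c(lab, 1), 0))[3L], 1)
  # inclusive comparison at the threshold itself
  expect_equal(unname(ratio_above(rep(1, 4), c(-1, -1, 1, 1), 1))[3L], 1)
})

test_that("cell-wise and run-wise class accuracy commute exactly", {
  B <- random_binary_matrix(n = 209, runs = 100, seed = 42)
  lab <- random_labels(209, 51, seed = 42)
  a <- cell_accuracy(B)
  A <- class_accuracy(a, lab)
  # run-wise: per-run class accuracy averaged over runs
  for (cls in c(-1, 1)) {
    runwise <- mean(colMeans(B[lab == cls, , drop = FALSE]))
    cellwise <- unname(A[if (cls < 0) "class_A" else "class_B"])
    expect_equal(runwise, cellwise, tolerance = 1e-12)
  }
  # r_a is non-increasing in the threshold, r_0 = 1
  ths <- seq(0, 1, by = 0.05)
  r <- vapply(ths, function(t) ratio_above(a, lab, t)["all"], 0)
  expect_true(all(diff(r) <= 0))
  expect_equal(unname(r[1L]), 1)
})

test_that("ROC AUC equals the Mann-Whitney pair probability", {
  # perfectly ordered scores
  expect_equal(roc_auc(c(1, 2, 10, 20), c(-1, -1, 1, 1)), 1)
  # all ties
  expect_equal(roc_auc(rep(3, 6), rep(c(-1, 1), 3)), 0.5)
  # brute force over all pos/neg pairs: {neg: 1, 3; pos: 2, 4} -> 0.75
  expect_equal(roc_auc(c(1, 3, 2, 4), c(-1, -1, 1, 1)), 0.75)
  # matrix input averages per-run AUCs
  s <- cbind(c(1, 3, 2, 4), c(1, 2, 3, 4))
  expect_equal(roc_auc(s, c(-1, -1, 1, 1)), mean(c(0.75, 1)))
  # property: agrees with pROC on random scores
  set.seed(9)
  sc <- rnorm(60)
  lab <- random_labels(60, 20, seed = 1)
  expect_equal(roc_auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(-1, 1)))),
               tolerance = 1e-12)
  # label flip maps AUC -> 1 - AUC
  expect_equal(roc_auc(sc, -lab), 1 - roc_auc(sc, lab),
               tolerance = 1e-12)
  expect_error(roc_auc(1:3, rep(1, 3)), "both classes")
})

test_that("repeated-CV SVM is deterministic and separates well-separated classes", {
  tab <- separable_table()
  fit1 <- classify_cv(tab, runs = 2, seed = 5)
  fit2 <- classify_cv(tab, runs = 2, seed = 5)
  expect_identical(fit1$B, fit2$B)
  expect_identical(fit1$scores, fit2$scores)
  fit3 <- classify_cv(tab, runs = 2, seed = 6)
  expect_false(identical(fit1$scores, fit3$scores))

  fit <- classify_cv(tab, runs = 10, seed = 1)
  expect_true(all(fit$report$a >= 0.95))
  expect_gte(fit$report$auc, 0.99)
  # every cell predicted exactly once per run
  expect_true(all(!is.na(fit$scores)))
  expect_true(all(fit$B %in% c(0L, 1L)))
  # the report identity between the two summation orders
  expect_equal(unname(fit$report$A_C["class_A"]),
               mean(colMeans(fit$B[fit$labels < 0, ])),
               tolerance = 1e-12)
})

test_that("coef and predict expose a working full-data hyperplane", {
  tab <- separable_table()
  fit <- classify_cv(tab, runs = 2, seed = 1)
  cf <- coef(fit)
  expect_named(cf, c("b", paste0("w_", c("V", "Sigma", "Psi", "Mbar",
                                         "Gbar", "dMrel", "dGrel"))))
  pred <- predict(fit, tab)
  expect_true(all(pred == tab$label))
  # the decision rule is the sign of w.x + b
  x <- scale(log(as.matrix(tab[, c("V", "Sigma", "Psi", "Mbar", "Gbar",
                                   "dMrel", "dGrel")])),
             fit$final_model$center, fit$final_model$scale)
  manual <- drop(x %*% cf[-1L] + cf[1L])
  expect_equal(sign(manual), as.numeric(sign(attr(pred, "score"))),
               tolerance = 1e-9)
})

test_that("fold construction respects stratification and class size", {
  tab <- separable_table()
  small <- tab[c(1:20, 159:163), ]
  class(small) <- class(tab); attr(small, "space") <- "linear"
  expect_error(classify_cv(small, runs = 1, folds = 10, seed = 1),
               "folds")
  fit <- classify_cv(small, runs = 1, folds = 5, seed = 1)
  expect_equal(dim(fit$B), c(25L, 1L))
})

test_that("label permutation yields chance-level accuracy on average", {
  tab <- default_population_table()
  res <- t(vapply(1:4, function(k) {
    tn <- tab
    set.seed(100 + k)
    tn$label <- sample(tab$label)
    f <- classify_cv(tn, runs = 5, seed = k)
    c(f$report$A_C, auc = f$report$auc)
  }, numeric(4L)))
  avg <- colMeans(res)
  expect_gt(avg["all"], 0.35)
  expect_lt(avg["all"], 0.65)
  expect_gt(avg["auc"], 0.4)
  expect_lt(avg["auc"], 0.6)
  # balanced weights keep either class from collapsing on average
  expect_gt(avg["class_A"], 0.3)
  expect_gt(avg["class_B"], 0.3)
})

test_that("downsampled RF training folds shrink the majority class", {
  tab <- weak_signal_table()
  fit <- classify_cv(tab, runs = 2, learner = "rf",
                     rf_mode = "downsample", ntree = 50, seed = 2)
  expect_equal(dim(fit$B), c(209L, 2L))
  # contract check on the downsampling helper itself
  y <- c(rep(-1, 40), rep(1, 5))
  x <- matrix(rnorm(45 * 7), 45, 7)
  set.seed(1)
  run <- acroshape:::cv_run_once(x, y, k = 5, stratified = TRUE,
                                 standardize = TRUE, cost = 1,
                                 class_weights = TRUE, learner = "rf",
                                 rf_mode = "downsample", ntree = 10)
  expect_equal(length(run$pred), 45L)
})
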