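test_that("AUROC equals the pairwise-comparison oracle, with ties half-counted", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 6-point toy vector against the O(n^2) oracle
  p6 <- c(0.9, 0.5, 0.5, 0.4, 0.2, 0.1)
  y6 <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auroc(p6, y6), brute_auroc(p6, y6))
  set.seed(12)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(auroc(p, y), brute_auroc(p, y))
  }
})

test_that("AUPR matches step-integration values and is tie-stable", {
  expect_equal(aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # hand-computed: positives at ranks 1 and 3 -> (1/2)(1) + (1/2)(2/3)
  expect_equal(aupr(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  # prefix-precision oracle valid when scores are distinct
  prefix_ap <- function(p, y) {
    ord <- order(p, decreasing = TRUE)
    y <- y[ord]
    n1 <- sum(y)
    sum((cumsum(y) / seq_along(y))[y == 1]) / n1
  }
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- runif(n)
    expect_equal(aupr(p, y), prefix_ap(p, y))
  }
  # permuting rows within a tie block cannot change the value
  p <- c(0.7, 0.7, 0.7, 0.3, 0.3)
  y <- c(1, 0, 1, 0, 1)
  for (i in 1:5) {
    idx <- sample(5)
    expect_equal(aupr(p[idx], y[idx]), aupr(p, y))
  }
})

test_that("threshold prespecification matches a brute-force scan", {
  # worked example: sens floor reachable with full specificity
  probs <- c(0.9, 0.7, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0)
  thr <- select_threshold(probs, labels, 0.9)
  expect_gt(thr$tau, 0.2)
  expect_lte(thr$tau, 0.6)
  expect_equal(thr$specificity, 1)
  # sens_min 0: pure specificity maximization
  thr0 <- select_threshold(probs, labels, 0)
  expect_equal(thr0$specificity, 1)
  expect_gt(thr0$tau, 0.2)
  # 200 random prediction vectors against the scan oracle
  set.seed(9)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), sample(c(1, 3), 1))
    got <- select_threshold(p, y, 0.9)
    want <- brute_threshold(p, y, 0.9)
    expect_equal(got$tau, want$tau)
    expect_equal(got$specificity, want$spec)
    expect_gte(got$sensitivity, 0.9)
  }
})

test_that("confusion metrics and report are internally consistent", {
  p <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.2)
  y <- c(1, 1, 1, 0, 0, 0)
  ev <- evaluate_predictions(p, y, 0.5)
  expect_equal(sum(ev$confusion), 6)
  expect_equal(ev$sensitivity, 2 / 3)
  expect_equal(ev$specificity, 2 / 3)
  expect_equal(ev$accuracy, 4 / 6)
  expect_equal(ev$f1, 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(sum(ev$confusion_pct), 100)
  expect_warning(auroc(p, rep(1, 6)), "single class")
})

test_that("ridge logistic fit matches a brute-force optimizer", {
  set.seed(2)
  n <- 80
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(plogis(1.2 * x[, 1] - 0.7 * x[, 2]) > runif(n))
  w <- balanced_class_weights(y)
  lambda <- 0.7
  fit <- fit_logistic_l2(x, y, weights = w, lambda = lambda,
                         standardize = FALSE)
  obj <- function(b) {
    eta <- b[1] + x %*% b[2:3]
    sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)) +
      lambda / 2 * sum(b[2:3]^2)
  }
  opt <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(c(fit$intercept, fit$coef), opt$par, tolerance = 1e-4)
  expect_lte(obj(c(fit$intercept, fit$coef)), opt$value + 1e-8)
})

test_that("regularization bounds separable fits and large lambda shrinks", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c(0, 0, 1, 1)
  fit <- fit_logistic_l2(x, y, lambda = 0.5)
  expect_true(is.finite(fit$coef))
  big <- fit_logistic_l2(x, y, lambda = 1e6)
  expect_lt(abs(big$coef), 1e-3)
  p <- predict_segment_proba(big, x)
  expect_equal(as.numeric(p), rep(0.5, 4), tolerance = 1e-3)
})

test_that("probability aggregation to patient-side is a group mean", {
  expect_equal(as.numeric(aggregate_to_side(0.7, "A_L")), 0.7)
  agg <- aggregate_to_side(c(0.2, 0.8), c("A_L", "A_L"))
  expect_equal(as.numeric(agg), 0.5)
  p <- c(0.1, 0.5, 0.9, 0.3)
  g <- c("A", "B", "A", "B")
  a1 <- aggregate_to_side(p, g)
  idx <- c(3, 2, 1, 4)
  a2 <- aggregate_to_side(p[idx], g[idx])
  expect_equal(a1, a2)
})

test_that("split plans partition groups with stratified prevalence", {
  groups <- sprintf("G%02d", 1:40)
  labels <- c(rep(1, 12), rep(0, 28))
  plan <- make_split_plan(groups, labels, test_frac = 0.15, k = 5, seed = 3)
  expect_length(plan$test_groups, 6)
  n_pos_test <- sum(labels[match(plan$test_groups, groups)])
  expect_gte(n_pos_test, 1)
  expect_lte(n_pos_test, 2)
  expect_setequal(c(plan$test_groups, plan$train_groups), groups)
  expect_length(intersect(plan$test_groups, plan$train_groups), 0)
  # folds partition the training groups
  expect_setequal(names(plan$folds), plan$train_groups)
  expect_equal(sort(unique(plan$folds)), 1:5)
  # determinism
  plan2 <- make_split_plan(groups, labels, test_frac = 0.15, k = 5, seed = 3)
  expect_identical(plan, plan2)
  expect_error(make_split_plan(groups[1:8], c(1, rep(0, 7))),
               "too few groups")
})

test_that("out-of-fold predictions cover every training group without leakage", {
  ft <- make_feature_frame(n_groups = 40, n_seg = 5, effect = 1.5, seed = 6)
  glab <- tapply(ft$label, ft$group_key, max)
  plan <- make_split_plan(names(glab), as.integer(glab), seed = 2)
  oof <- collect_oof_predictions(plan, ft, paste0("f", 1:4))
  expect_setequal(unique(oof$side$group_key), plan$train_groups)
  expect_equal(anyDuplicated(oof$side$group_key), 0)
  # segments of each group are scored by the fold not containing it
  seg_counts <- table(oof$segment$group_key)
  expect_true(all(seg_counts == 5))
  # informative data: OOF AUROC clearly above chance
  expect_gt(auroc(oof$side$prob, oof$side$label), 0.8)
})

test_that("standardization statistics come from training rows only", {
  ft <- make_feature_frame(n_groups = 30, n_seg = 4, seed = 8)
  fit <- train_evaluate(ft, feature_cols = paste0("f", 1:4), seed = 4)
  tr_rows <- ft$group_key %in% fit$plan$train_groups
  expect_equal(unname(fit$model$center),
               unname(colMeans(ft[tr_rows, paste0("f", 1:4)])))
  expect_equal(unname(fit$model$scale),
               unname(apply(ft[tr_rows, paste0("f", 1:4)], 2, sd)))
  # threshold came from training OOF predictions only
  expect_identical(fit$threshold$provenance, "train_oof")
  expect_setequal(fit$oof$side$group_key, fit$plan$train_groups)
  expect_length(intersect(fit$plan$test_groups,
                          unique(fit$oof$side$group_key)), 0)
})

test_that("permuted labels drive OOF discrimination to chance", {
  ft <- make_feature_frame(n_groups = 44, n_seg = 5, effect = 2, seed = 10)
  glab <- tapply(ft$label, ft$group_key, max)
  set.seed(77)
  aurocs <- vapply(1:10, function(i) {
    perm <- sample(as.integer(glab))
    names(perm) <- names(glab)
    ft$label <- perm[ft$group_key]
    oof <- cv_oof_predictions(ft, paste0("f", 1:4), seed = i)
    auroc(oof$side$prob, oof$side$label)
  }, 0)
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})
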