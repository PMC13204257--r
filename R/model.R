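# Grouped model development: stratified holdout and stratified grouped
# k-fold at the patient-side level, an L2-regularized logistic regression
# fitted by Newton iteration (the from-scratch core model), segment-to-side
# probability aggregation, out-of-fold threshold prespecification at a
# sensitivity floor, and the metric suite.

# ---- splits ------------------------------------------------------------

# Greedy seeded stratified assignment of groups to k folds: within each
# class, shuffled groups are dealt round-robin, balancing class counts
# across folds.
stratified_group_folds <- function(groups, group_labels, k = 5, seed = 1L) {
  stopifnot(length(groups) == length(group_labels))
  fold <- integer(length(groups))
  names(fold) <- groups
  with_seed(as.integer(seed), {
    for (cls in sort(unique(group_labels))) {
      idx <- which(group_labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  fold
}

#' Build a grouped split plan: stratified holdout plus stratified k-fold
#'
#' Selects about `test_frac` of the patient-side groups as a fixed held-out
#' test set by stratified sampling (at least one group per class forced),
#' then partitions the remaining training groups into `k` folds stratified
#' by group-level label. Groups never straddle a boundary.
#'
#' @param groups Character vector of group keys (one per group).
#' @param group_labels Binary labels, one per group.
#' @param test_frac Fraction of groups held out.
#' @param k Number of cross-validation folds.
#' @param seed RNG seed.
#' @return List of class `split_plan`: `test_groups`, `train_groups`,
#'   `folds` (named integer vector over train groups), `k`, `seed`.
#' @export
make_split_plan <- function(groups, group_labels, test_frac = 0.15, k = 5,
                            seed = 1L) {
  stopifnot(!anyDuplicated(groups))
  group_labels <- as.integer(group_labels)
  n <- length(groups)
  n_test <- max(2L, round(test_frac * n))
  pos <- which(group_labels == 1)
  neg <- which(group_labels == 0)
  n_test_pos <- max(1L, round(n_test * length(pos) / n))
  n_test_neg <- max(1L, n_test - n_test_pos)
  if (length(pos) <= n_test_pos || length(neg) <= n_test_neg)
    stop("too few groups per class for a stratified holdout (",
         length(pos), " positive, ", length(neg), " negative)")
  test_idx <- with_seed(as.integer(seed), {
    c(pos[sample.int(length(pos), n_test_pos)],
      neg[sample.int(length(neg), n_test_neg)])
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  train_labels <- group_labels[train_idx]
  if (min(table(factor(train_labels, levels = 0:1))) < k)
    stop("fewer than k = ", k, " training groups in one class")
  folds <- stratified_group_folds(groups[train_idx], train_labels, k,
                                  seed = as.integer(seed) + 1L)
  structure(list(test_groups = groups[test_idx],
                 train_groups = groups[train_idx],
                 folds = folds, k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

# ---- logistic regression (from scratch) --------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Inverse-frequency class weights
#' @param y Binary labels.
#' @return Per-observation weights, normalized to mean 1.
#' @export
balanced_class_weights <- function(y) {
  y <- as.integer(y)
  w <- ifelse(y == 1, 1 / max(1, sum(y == 1)), 1 / max(1, sum(y == 0)))
  w / mean(w)
}

#' Fit L2-regularized logistic regression by Newton iteration
#'
#' Minimizes the class-weighted negative log-likelihood plus
#' `lambda/2 * ||w||^2` (intercept unpenalized) to a gradient max-norm of
#' `tol`. Inputs are standardized internally using the training statistics,
#' which are stored on the model so prediction applies the identical
#' transform.
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param y Binary labels (0/1).
#' @param weights Per-observation weights (default: inverse class
#'   frequency, mean 1).
#' @param lambda Ridge penalty on standardized coefficients.
#' @param standardize Standardize columns with training mean/SD.
#' @param tol Gradient max-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return List of class `logistic_model`: `coef` (weights on the
#'   standardized scale), `intercept`, `center`, `scale`, `lambda`,
#'   `converged`, `n_iter`.
#' @export
fit_logistic_l2 <- function(x, y, weights = NULL, lambda = 1,
                            standardize = TRUE, tol = 1e-8,
                            max_iter = 100L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% 0:1))
  if (is.null(weights)) weights <- balanced_class_weights(y)
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
  } else {
    center <- rep(0, ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  xa <- cbind(1, xs)
  d <- ncol(xa)
  beta <- numeric(d)
  pen <- c(0, rep(lambda, d - 1))          # intercept unpenalized
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(xa %*% beta)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(xa, weights * (mu - y))) + pen * beta
    if (max(abs(grad)) <= tol) {
      converged <- TRUE
      break
    }
    wdiag <- pmax(weights * mu * (1 - mu), 1e-10)
    hess <- crossprod(xa * wdiag, xa) + diag(pen, d)
    step <- solve(hess, grad)
    # damped Newton: halve until the penalized objective does not increase
    obj <- function(b) {
      e <- drop(xa %*% b)
      sum(weights * (log1p(exp(-abs(e))) + pmax(e, 0) - y * e)) +
        sum(pen * b^2) / 2
    }
    f0 <- obj(beta)
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      if (obj(cand) <= f0 + 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    beta <- beta - alpha * step
  }
  if (!converged) {
    eta <- drop(xa %*% beta)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(xa, weights * (mu - y))) + pen * beta
    if (max(abs(grad)) > 1e-4)
      stop("logistic Newton iteration failed to converge (grad max-norm ",
           format(max(abs(grad))), " after ", max_iter, " iterations)")
  }
  if (any(!is.finite(beta))) stop("non-finite coefficients in logistic fit")
  structure(list(coef = beta[-1], intercept = beta[1], center = center,
                 scale = scale_, lambda = lambda, converged = converged,
                 n_iter = it, feature_names = colnames(x)),
            class = "logistic_model")
}

#' Segment-level predicted probabilities
#' @param model A `logistic_model`.
#' @param x Feature matrix on the raw (unstandardized) scale.
#' @return Probabilities in \[0, 1\].
#' @export
predict_segment_proba <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$coef))
    stop("feature dimension ", ncol(x), " does not match model (",
         length(model$coef), ")")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  sigmoid(drop(xs %*% model$coef) + model$intercept)
}

#' Aggregate segment probabilities to patient-side predictions
#'
#' @param probs Segment probabilities.
#' @param groups Group key per segment.
#' @return Named numeric vector of per-group mean probabilities.
#' @export
aggregate_to_side <- function(probs, groups) {
  stopifnot(length(probs) == length(groups))
  tapply(probs, groups, mean)
}

group_label_table <- function(labels, groups) {
  tab <- tapply(as.integer(labels), groups, function(v) {
    u <- unique(v)
    if (length(u) != 1) stop("inconsistent labels within group")
    u
  })
  tab
}

# ---- out-of-fold machinery ---------------------------------------------

#' Out-of-fold cross-validated predictions on the training groups
#'
#' For each fold, fits the logistic model (standardization refit on the
#' in-fold training rows only) and scores the held-out fold's segments;
#' every training group is scored exactly once, by a model that never saw
#' it. Side probabilities are segment means within group.
#'
#' @param plan A [make_split_plan()].
#' @param features Feature table (training and test rows; only training
#'   groups are used).
#' @param feature_cols Feature column names.
#' @param lambda Ridge penalty.
#' @return List: `segment` (data.frame group_key, label, prob),
#'   `side` (data.frame group_key, label, prob).
#' @export
collect_oof_predictions <- function(plan, features,
                                    feature_cols = NULL, lambda = 1) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  tr <- features[features$group_key %in% plan$train_groups, , drop = FALSE]
  seg_out <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    val_groups <- names(plan$folds)[plan$folds == f]
    fit_rows <- !(tr$group_key %in% val_groups)
    val_rows <- tr$group_key %in% val_groups
    if (!any(val_rows)) next
    stopifnot(!any(fit_rows & val_rows))
    model <- fit_logistic_l2(tr[fit_rows, feature_cols, drop = FALSE],
                             tr$label[fit_rows], lambda = lambda)
    p <- predict_segment_proba(model, tr[val_rows, feature_cols,
                                         drop = FALSE])
    seg_out[[f]] <- data.frame(group_key = tr$group_key[val_rows],
                               label = tr$label[val_rows], prob = p,
                               stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_out)
  side_prob <- aggregate_to_side(seg$prob, seg$group_key)
  side_lab <- group_label_table(seg$label, seg$group_key)
  side <- data.frame(group_key = names(side_prob),
                     label = as.integer(side_lab[names(side_prob)]),
                     prob = as.numeric(side_prob), stringsAsFactors = FALSE)
  list(segment = seg, side = side)
}

#' Prespecify the operating threshold from out-of-fold predictions
#'
#' Candidate thresholds are midpoints between adjacent sorted distinct
#' probabilities plus boundary sentinels. The feasible set holds
#' candidates with sensitivity at least `sens_min`; among those the
#' maximum-specificity threshold is chosen, ties broken toward the lower
#' threshold.
#'
#' @param probs Out-of-fold patient-side probabilities (training only).
#' @param labels Binary side labels.
#' @param sens_min Sensitivity floor (default 0.90).
#' @return List of class `operating_threshold`: `tau`, `sensitivity`,
#'   `specificity` (on the OOF predictions), `sens_min`,
#'   `provenance = "train_oof"`.
#' @export
select_threshold <- function(probs, labels, sens_min = 0.90) {
  labels <- as.integer(labels)
  stopifnot(any(labels == 1), any(labels == 0))
  u <- sort(unique(probs))
  cand <- c(u[1] - 1e-6, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1e-6)
  sens <- vapply(cand, function(tt) {
    sum(probs >= tt & labels == 1) / sum(labels == 1)
  }, 0)
  spec <- vapply(cand, function(tt) {
    sum(probs < tt & labels == 0) / sum(labels == 0)
  }, 0)
  feasible <- which(sens >= sens_min)
  stopifnot(length(feasible) > 0)   # threshold below min prob gives sens 1
  best_spec <- max(spec[feasible])
  pick <- feasible[spec[feasible] == best_spec]
  tau <- min(cand[pick])            # ties toward the lower threshold
  structure(list(tau = tau,
                 sensitivity = sens[cand == tau][1],
                 specificity = spec[cand == tau][1],
                 sens_min = sens_min, provenance = "train_oof"),
            class = "operating_threshold")
}

#' Pooled out-of-fold predictions over a whole cohort
#'
#' Runs stratified grouped k-fold CV over every patient-side group (no
#' holdout) and pools the out-of-fold segment probabilities; each group is
#' scored once, by a model that never trained on it.
#'
#' @param features Feature table.
#' @param feature_cols Feature columns (default: the core six).
#' @param k Folds.
#' @param seed Fold-assignment seed.
#' @param lambda Ridge penalty.
#' @return List: `segment` and `side` data.frames (group_key, label,
#'   prob).
#' @export
cv_oof_predictions <- function(features,
                               feature_cols = feature_config()$core_set,
                               k = 5, seed = 1L, lambda = 1) {
  glab <- group_label_table(features$label, features$group_key)
  folds <- stratified_group_folds(names(glab), as.integer(glab), k, seed)
  fold <- folds[features$group_key]
  seg_out <- vector("list", k)
  for (f in seq_len(k)) {
    va <- fold == f
    if (!any(va)) next
    model <- fit_logistic_l2(features[!va, feature_cols, drop = FALSE],
                             features$label[!va], lambda = lambda)
    p <- predict_segment_proba(model, features[va, feature_cols,
                                               drop = FALSE])
    seg_out[[f]] <- data.frame(group_key = features$group_key[va],
                               label = features$label[va], prob = p,
                               stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg_out)
  side_prob <- aggregate_to_side(seg$prob, seg$group_key)
  side_lab <- group_label_table(seg$label, seg$group_key)
  side <- data.frame(group_key = names(side_prob),
                     label = as.integer(side_lab[names(side_prob)]),
                     prob = as.numeric(side_prob), stringsAsFactors = FALSE)
  list(segment = seg, side = side)
}

# ---- end-to-end convenience -------------------------------------------

#' Train, prespecify the threshold, and evaluate on the held-out test set
#'
#' Implements the complete grouped protocol: stratified holdout and
#' stratified grouped 5-fold CV at the patient-side level; out-of-fold
#' training predictions drive threshold selection; the final model is
#' refit on all training rows and applied once to the held-out test set.
#' Reports metrics at segment and patient-side resolution.
#'
#' @param features Feature table from [feature_table()].
#' @param feature_cols Feature columns to use (default: the core six).
#' @param test_frac Held-out fraction of groups.
#' @param k CV folds.
#' @param lambda Ridge penalty.
#' @param sens_min Sensitivity floor for the operating threshold.
#' @param seed RNG seed for the split plan.
#' @return List of class `screen_fit`: `model`, `plan`, `threshold`, `oof`
#'   (out-of-fold predictions), `test` (list with `segment` and `side`
#'   evaluation reports), `feature_cols`, `lambda`.
#' @export
train_evaluate <- function(features, feature_cols = feature_config()$core_set,
                           test_frac = 0.15, k = 5, lambda = 1,
                           sens_min = 0.90, seed = 1L) {
  glab <- group_label_table(features$label, features$group_key)
  plan <- make_split_plan(names(glab), as.integer(glab),
                          test_frac = test_frac, k = k, seed = seed)
  oof <- collect_oof_predictions(plan, features, feature_cols, lambda)
  thr <- select_threshold(oof$side$prob, oof$side$label, sens_min)
  tr_rows <- features$group_key %in% plan$train_groups
  te_rows <- features$group_key %in% plan$test_groups
  stopifnot(!any(tr_rows & te_rows))
  model <- fit_logistic_l2(features[tr_rows, feature_cols, drop = FALSE],
                           features$label[tr_rows], lambda = lambda)
  p_seg <- predict_segment_proba(model,
                                 features[te_rows, feature_cols,
                                          drop = FALSE])
  y_seg <- features$label[te_rows]
  side_prob <- aggregate_to_side(p_seg, features$group_key[te_rows])
  side_lab <- group_label_table(y_seg, features$group_key[te_rows])
  test <- list(
    segment = evaluate_predictions(p_seg, y_seg, thr$tau),
    side = evaluate_predictions(as.numeric(side_prob),
                                as.integer(side_lab[names(side_prob)]),
                                thr$tau))
  structure(list(model = model, plan = plan, threshold = thr, oof = oof,
                 test = test, feature_cols = feature_cols, lambda = lambda),
            class = "screen_fit")
}
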