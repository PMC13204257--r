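# Univariate feature screening under patient-side grouped cross-validation:
# score-orientation AUROC/AUPR ranking, a single-feature baseline
# classifier ranking over four metrics, the Mann-Whitney/BH consistency
# check on patient-side aggregated values, and cumulative-subset /
# leave-one-feature-out characterizations of the core set.

#' Aggregate a feature table to the patient-side level
#'
#' One row per group, each feature the mean of that group's segments.
#' Labels must be constant within a group.
#'
#' @param features Feature table from [feature_table()].
#' @param feature_cols Feature columns (default all).
#' @return data.frame with group_key, label and mean feature values.
#' @export
aggregate_patient_side <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  glab <- group_label_table(features$label, features$group_key)
  keys <- names(glab)
  agg <- do.call(rbind, lapply(keys, function(g) {
    rows <- features$group_key == g
    colMeans(features[rows, feature_cols, drop = FALSE])
  }))
  out <- data.frame(group_key = keys, label = as.integer(glab),
                    agg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

fold_indices <- function(features, k, seed) {
  glab <- group_label_table(features$label, features$group_key)
  folds <- stratified_group_folds(names(glab), as.integer(glab), k, seed)
  folds[features$group_key]
}

#' Univariate AUROC/AUPR ranking under grouped cross-validation
#'
#' Treats each feature (and its negation) as a continuous score; per fold,
#' computes held-out AUROC and AUPR, averages over folds, and keeps the
#' better orientation per metric. Features are ranked per metric (best =
#' rank 1, average ranks for ties) and the AUROC and AUPR ranks averaged
#' into a single mean rank.
#'
#' @param features Feature table.
#' @param feature_cols Feature columns (default all).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return data.frame (sorted by mean rank, ties by name) with cv_auroc,
#'   cv_aupr, orientation flags, rank_auroc, rank_aupr, mean_rank.
#' @export
univariate_cv_rank <- function(features, feature_cols = NULL, k = 5,
                               seed = 1L) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  fold <- fold_indices(features, k, seed)
  res <- lapply(feature_cols, function(fc) {
    x <- features[[fc]]
    if (!all(is.finite(x)) || stats::sd(x) == 0) {
      return(data.frame(feature = fc, cv_auroc = NA_real_,
                        cv_aupr = NA_real_, flipped_auroc = FALSE,
                        flipped_aupr = FALSE))
    }
    per_fold <- lapply(seq_len(k), function(f) {
      idx <- fold == f
      y <- features$label[idx]
      if (length(unique(y)) < 2) {
        warning("fold ", f, " has a single class; skipped")
        return(NULL)
      }
      c(auroc_pos = auroc(x[idx], y), auroc_neg = auroc(-x[idx], y),
        aupr_pos = aupr(x[idx], y), aupr_neg = aupr(-x[idx], y))
    })
    m <- colMeans(do.call(rbind, Filter(Negate(is.null), per_fold)))
    data.frame(feature = fc,
               cv_auroc = max(m["auroc_pos"], m["auroc_neg"]),
               cv_aupr = max(m["aupr_pos"], m["aupr_neg"]),
               flipped_auroc = m["auroc_neg"] > m["auroc_pos"],
               flipped_aupr = m["aupr_neg"] > m["aupr_pos"])
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  # competition ranking: the best score gets rank 1 and exact ties share
  # it (several screening features are monotone transforms of one another
  # and tie exactly on rank-based metrics); zero-variance/NA features get
  # the worst rank
  rank_worst_na <- function(v) {
    r <- rank(-v, ties.method = "min", na.last = "keep")
    r[is.na(r)] <- length(v)
    r
  }
  tab$rank_auroc <- rank_worst_na(tab$cv_auroc)
  tab$rank_aupr <- rank_worst_na(tab$cv_aupr)
  tab$mean_rank <- (tab$rank_auroc + tab$rank_aupr) / 2
  tab[order(tab$mean_rank, tab$feature), ]
}

grouped_cv_metrics <- function(features, cols, k = 5, seed = 1L,
                               lambda = 1, tau = 0.5) {
  fold <- fold_indices(features, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- fold != f
    va <- fold == f
    y_va <- features$label[va]
    if (length(unique(y_va)) < 2 || length(unique(features$label[tr])) < 2) {
      warning("fold ", f, " unusable (single class); skipped")
      return(NULL)
    }
    m <- fit_logistic_l2(features[tr, cols, drop = FALSE],
                         features$label[tr], lambda = lambda)
    p <- predict_segment_proba(m, features[va, cols, drop = FALSE])
    cm <- confusion_metrics(p, y_va, tau)
    c(auc = auroc(p, y_va), pr_auc = aupr(p, y_va),
      f1 = cm$f1, accuracy = cm$accuracy)
  })
  colMeans(do.call(rbind, Filter(Negate(is.null), per_fold)))
}

#' Single-feature baseline-classifier ranking
#'
#' Trains the baseline logistic classifier on each feature in isolation
#' (fixed hyperparameters across features) under grouped CV, scores
#' held-out folds with AUC, F1, PR-AUC and accuracy, and averages the four
#' per-metric ranks into one mean rank.
#'
#' @param features Feature table.
#' @param feature_cols Feature columns (default all).
#' @param k Folds.
#' @param seed Fold-assignment seed.
#' @param lambda Ridge penalty.
#' @return data.frame with the four metrics, their ranks, and
#'   `mean_rank_4metric`, sorted by mean rank then name.
#' @export
baseline_classifier_rank <- function(features, feature_cols = NULL, k = 5,
                                     seed = 1L, lambda = 1) {
  if (is.null(feature_cols)) feature_cols <- feature_columns(features)
  res <- lapply(feature_cols, function(fc) {
    m <- grouped_cv_metrics(features, fc, k, seed, lambda)
    data.frame(feature = fc, auc = m["auc"], f1 = m["f1"],
               pr_auc = m["pr_auc"], accuracy = m["accuracy"])
  })
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  for (col in c("auc", "f1", "pr_auc", "accuracy")) {
    tab[[paste0("rank_", col)]] <- rank(-tab[[col]], ties.method = "min")
  }
  tab$mean_rank_4metric <- rowMeans(
    tab[, paste0("rank_", c("auc", "f1", "pr_auc", "accuracy"))])
  tab[order(tab$mean_rank_4metric, tab$feature), ]
}

#' Mann-Whitney U tests with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney U test per feature on patient-side aggregated
#' values (positive class first, so U counts pairs where a positive side
#' exceeds a negative side, ties one half), with BH false-discovery-rate
#' correction across the feature family.
#'
#' @param aggregated Output of [aggregate_patient_side()].
#' @param feature_cols Feature columns (default all non-identity columns).
#' @return data.frame with U, p, q (BH), and per-class group counts.
#' @export
mannwhitney_bh <- function(aggregated, feature_cols = NULL) {
  if (is.null(feature_cols))
    feature_cols <- setdiff(colnames(aggregated), c("group_key", "label"))
  y <- as.integer(aggregated$label)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 patient-side groups per class (have ",
         n1, " positive, ", n0, " negative)")
  rows <- lapply(feature_cols, function(fc) {
    x1 <- aggregated[[fc]][y == 1]
    x0 <- aggregated[[fc]][y == 0]
    exact <- n1 <= 8 && n0 <= 8 && !anyDuplicated(c(x1, x0))
    wt <- stats::wilcox.test(x1, x0, alternative = "two.sided",
                             exact = exact, correct = TRUE)
    data.frame(feature = fc, U = unname(wt$statistic), p = wt$p.value,
               n_pos = n1, n_neg = n0)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Cumulative-subset performance curve
#'
#' Cross-validated AUROC of the logistic model on the top-1, top-2, ...
#' top-n ranked feature subsets.
#'
#' @param features Feature table.
#' @param ranked_features Feature names in rank order (best first).
#' @param k Folds.
#' @param seed Fold-assignment seed.
#' @param lambda Ridge penalty.
#' @return data.frame with n_features, features (collapsed names),
#'   cv_auroc.
#' @export
cumulative_subset <- function(features, ranked_features, k = 5, seed = 1L,
                              lambda = 1) {
  out <- lapply(seq_along(ranked_features), function(n) {
    cols <- ranked_features[seq_len(n)]
    m <- grouped_cv_metrics(features, cols, k, seed, lambda)
    data.frame(n_features = n,
               features = paste(cols, collapse = "+"),
               cv_auroc = m["auc"])
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Leave-one-feature-out deltas for the core set
#'
#' Cross-validated AUROC of the full core set minus each feature in turn.
#'
#' @param features Feature table.
#' @param core_set Feature names of the core set.
#' @param k Folds.
#' @param seed Fold-assignment seed.
#' @param lambda Ridge penalty.
#' @return data.frame with the full-set AUROC (`removed = "none"`) and one
#'   row per removed feature, including `delta_auroc` (full minus reduced).
#' @export
leave_one_feature_out <- function(features, core_set, k = 5, seed = 1L,
                                  lambda = 1) {
  full <- grouped_cv_metrics(features, core_set, k, seed, lambda)["auc"]
  rows <- lapply(core_set, function(fc) {
    m <- grouped_cv_metrics(features, setdiff(core_set, fc), k, seed,
                            lambda)
    data.frame(removed = fc, cv_auroc = m["auc"],
               delta_auroc = full - m["auc"])
  })
  tab <- rbind(data.frame(removed = "none", cv_auroc = unname(full),
                          delta_auroc = 0),
               do.call(rbind, rows))
  rownames(tab) <- NULL
  tab
}
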