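# Exact additive attribution for the linear (logistic) model. On the
# log-odds scale a linear model's Shapley values under the
# independent-feature (interventional) convention have the closed form
# phi_i = w_i (x_i - mu_i) with background mu the training feature means;
# additivity base + sum(phi) = predicted log-odds holds to machine
# precision. Probabilities follow by the monotone sigmoid map.

#' Linear SHAP attributions for a fitted logistic model
#'
#' @param model A `logistic_model` from [fit_logistic_l2()].
#' @param x Feature matrix on the raw scale (typically the training rows;
#'   interpretation never touches held-out data).
#' @param background Optional background row (raw scale); defaults to the
#'   model's standardization center, i.e. the training feature means.
#' @return List of class `shap_attribution`: `phi` (n x p matrix of
#'   log-odds contributions), `base_value` (log-odds at the background),
#'   `predicted_logodds`, `x_std` (standardized features),
#'   `feature_names`.
#' @export
linear_shap <- function(model, x, background = NULL) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$coef))
    stop("feature dimension ", ncol(x), " does not match model (",
         length(model$coef), ")")
  if (is.null(background)) background <- model$center
  bg_std <- (background - model$center) / model$scale
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  phi <- sweep(xs, 2, bg_std) * rep(model$coef, each = nrow(xs))
  base <- model$intercept + sum(model$coef * bg_std)
  pred <- drop(xs %*% model$coef) + model$intercept
  colnames(phi) <- model$feature_names
  structure(list(phi = phi, base_value = base, predicted_logodds = pred,
                 x_std = xs, feature_names = model$feature_names),
            class = "shap_attribution")
}

#' Global feature importance from SHAP attributions
#'
#' Orders features by mean absolute contribution and reports a
#' signed-direction summary: the fraction of rows where the contribution's
#' sign matches the sign of the standardized feature value (1 for a
#' feature whose larger values push predictions up).
#'
#' @param attr A `shap_attribution` from [linear_shap()].
#' @return data.frame (descending importance) with mean_abs_phi and
#'   sign_consistency.
#' @export
global_importance <- function(attr) {
  stopifnot(nrow(attr$phi) > 0)
  mean_abs <- colMeans(abs(attr$phi))
  sign_cons <- vapply(seq_len(ncol(attr$phi)), function(j) {
    nz <- attr$phi[, j] != 0 | attr$x_std[, j] != 0
    if (!any(nz)) return(NA_real_)
    mean(sign(attr$phi[nz, j]) == sign(attr$x_std[nz, j]))
  }, 0)
  out <- data.frame(feature = colnames(attr$phi),
                    mean_abs_phi = as.numeric(mean_abs),
                    sign_consistency = sign_cons,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_phi, out$feature), ]
  rownames(out) <- NULL
  out
}
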