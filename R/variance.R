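#' Proportion of a principal component's variance explained by covariates
#'
#' Ordinary least squares of a component's scores on treatment-coded
#' categorical covariates (intercept included, additive, no interactions);
#' returns the coefficient of determination.
#'
#' @param pc_scores Numeric vector of per-cell scores for one component.
#' @param covariates Data frame of categorical covariates (>= 2 levels
#'   each; `n` must exceed the total level count).
#' @return R-squared in `[0, 1]`.
#' @export
pc_regression_r2 <- function(pc_scores, covariates) {
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    covariates[[nm]] <- factor(covariates[[nm]])
    if (nlevels(covariates[[nm]]) < 2) {
      stop("covariate `", nm, "` has fewer than 2 levels")
    }
  }
  if (length(pc_scores) <= sum(vapply(covariates, nlevels, 0L))) {
    stop("not enough observations for the design")
  }
  fit <- stats::lm(pc_scores ~ ., data = covariates)
  ali <- fit$coefficients
  if (anyNA(ali)) {
    bad <- names(ali)[is.na(ali)]
    stop("singular design; collinear term(s): ", paste(bad, collapse = ", "))
  }
  summary(fit)$r.squared
}

#' Variance-weighted proportion of PC variance explained by covariates
#'
#' For the first `k` components: the sum of per-component R-squared values
#' weighted by each component's variance, divided by the total variance of
#' those components. With nested covariate sets the difference between two
#' calls is the share attributable to the added covariate.
#'
#' @param scores Cells x components score matrix (at least `k` columns).
#' @param covariates Data frame of categorical covariates.
#' @param k Components used (default 5).
#' @return List with `weighted_r2` (the headline fraction), per-component
#'   `r2` and `variances`.
#' @export
weighted_variance_explained <- function(scores, covariates, k = 5) {
  if (k < 1) stop("k must be >= 1")
  if (k > ncol(scores)) stop("k exceeds the available components")
  r2 <- vapply(seq_len(k), function(i) {
    pc_regression_r2(scores[, i], covariates)
  }, 0)
  v <- apply(scores[, seq_len(k), drop = FALSE], 2, stats::var)
  if (any(v <= 0)) stop("component with zero variance")
  list(weighted_r2 = sum(r2 * v) / sum(v), r2 = r2, variances = v)
}
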