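## Covariate-adjusted logistic prevalence models with family-clustered
## sandwich variance, marginalized into average adjusted predictions.

#' Fit a covariate-adjusted logistic prevalence model
#'
#' Maximum-likelihood logistic regression of a lifetime disorder status on
#' an exposure indicator and covariates (age, age squared, sex, number of
#' relatives with data), with a cluster-robust sandwich covariance matrix:
#' bread = inverse observed information, meat = outer products of
#' per-family score sums (HC0 form, no small-sample cluster adjustment).
#'
#' @param data data.frame holding the outcome, covariates and cluster label;
#'   rows with missing values must be dropped by the caller.
#' @param outcome name of the 0/1 outcome column.
#' @param covariates character vector of covariate column names (an
#'   intercept is always included).
#' @param cluster name of the family/cluster column.
#' @return a [PrevalenceFit-class].
#' @export
fitPrevalenceModel <- function(data, outcome, covariates = character(),
                               cluster = "family") {
  cols <- c(outcome, covariates, cluster)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[cols])) stop("missing values in model data; drop rows upstream")
  y <- data[[outcome]]
  if (length(unique(y)) < 2L)
    stop("outcome '", outcome, "' has a single class; model is degenerate")
  fml <- stats::reformulate(if (length(covariates)) covariates else "1",
                            response = outcome)
  fit <- glm(fml, family = binomial(), data = data)
  beta <- coef(fit)
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    worst <- names(beta)[which.max(abs(beta))]
    stop("logistic fit failed to converge (suspect separation in '",
         worst, "')")
  }
  cl <- factor(data[[cluster]])
  if (nlevels(cl) < 2L)
    warning("single cluster: sandwich variance is degenerate", call. = FALSE)
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  X <- stats::model.matrix(fit)
  new("PrevalenceFit", beta = beta, V = V, X = X, y = as.numeric(y),
      clusters = cl, converged = fit$converged)
}

#' Marginalized prevalence (average adjusted prediction)
#'
#' Averages the model-predicted probabilities at the observed covariate
#' values over a target group: the whole sample ("general population") or
#' the individuals with an affected relative (the exposed). The standard
#' error uses the delta method with the cluster-robust coefficient
#' covariance: gradient = mean over the group of p(1-p) x.
#'
#' With \code{counterfactual = TRUE}, the exposure column is set to 1 for
#' every row before averaging (marginal standardization to an all-exposed
#' population) instead of averaging within the observed subgroup.
#'
#' @param fit a [PrevalenceFit-class]
#' @param subset logical vector selecting the group (default: all rows).
#' @param counterfactual set the exposure column to 1 for all rows; when
#'   the model has no exposure column this reduces to the observed mode.
#' @param exposure name of the exposure column (counterfactual mode only).
#' @return list with \code{kHat}, \code{se}, \code{n} and \code{subset}
#'   (\code{"population"} or \code{"exposed"}).
#' @export
averageAdjustedPrediction <- function(fit, subset = NULL,
                                      counterfactual = FALSE,
                                      exposure = "exposed") {
  X <- fit@X
  if (counterfactual && exposure %in% colnames(X)) X[, exposure] <- 1
  if (is.null(subset)) subset <- rep(TRUE, nrow(X))
  if (!any(subset)) stop("empty subset for average adjusted prediction")
  Xs <- X[subset, , drop = FALSE]
  p <- plogis(drop(Xs %*% fit@beta))
  grad <- colMeans(p * (1 - p) * Xs)
  se <- sqrt(drop(t(grad) %*% fit@V %*% grad))
  list(kHat = mean(p), se = se, n = nrow(Xs),
       subset = if (all(subset)) "population" else "exposed")
}

#' Nonparametric cluster bootstrap of an average adjusted prediction
#'
#' Resamples whole families with replacement, refits the logistic model
#' and recomputes the marginalized prevalence. Intended as an independent
#' check of the delta-method standard errors, not as the primary
#' uncertainty estimate.
#'
#' @inheritParams fitPrevalenceModel
#' @param subsetCol optional name of a logical column selecting the AAP
#'   group within each resample (default: whole sample).
#' @param B number of bootstrap resamples.
#' @return numeric vector of \code{B} bootstrap prevalence estimates
#'   (resamples with a degenerate outcome are returned as \code{NA}).
#' @export
clusterBootstrapAAP <- function(data, outcome, covariates = character(),
                                cluster = "family", subsetCol = NULL,
                                B = 500) {
  cl <- factor(data[[cluster]])
  fams <- split(seq_len(nrow(data)), cl)
  fml <- stats::reformulate(if (length(covariates)) covariates else "1",
                            response = outcome)
  vapply(seq_len(B), function(b) {
    take <- sample(length(fams), replace = TRUE)
    rows <- unlist(fams[take], use.names = FALSE)
    d <- data[rows, , drop = FALSE]
    if (length(unique(d[[outcome]])) < 2L) return(NA_real_)
    f <- suppressWarnings(glm(fml, family = binomial(), data = d))
    p <- stats::fitted(f)
    if (is.null(subsetCol)) mean(p) else {
      s <- d[[subsetCol]]
      if (!any(s)) NA_real_ else mean(p[s])
    }
  }, numeric(1))
}
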