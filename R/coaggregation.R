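## Recurrence risk ratios with delta-method uncertainty and one-sided
## inference against the null of no familial co-aggregation.

#' Recurrence risk ratio
#'
#' The ratio between the prevalence of a disorder in individuals with an
#' affected relative and the general-population prevalence; a ratio above
#' one indicates shared familial risk. The standard error follows the
#' delta method under independence of numerator and denominator:
#' Var(lambda) = Var(p1)/p0^2 + p1^2 Var(p0)/p0^4. The test is one-sided
#' (H0: lambda = 1 vs H1: lambda > 1) and only the lower bound of the
#' one-sided 95\% confidence interval is reported, on the ratio scale by
#' default.
#'
#' If the exposed group contains no cases (prevalence estimate ~ 0), the
#' estimate is emitted as missing with a warning rather than an error.
#'
#' @param pExposed,pPop prevalence estimates as returned by
#'   [averageAdjustedPrediction()] (lists with \code{kHat} and \code{se}).
#' @param level one-sided confidence level.
#' @param logScale compute the interval on the log-ratio scale instead of
#'   the ratio scale.
#' @return list with \code{lambda}, \code{se}, \code{lower95},
#'   \code{pOneSided}.
#' @export
recurrenceRiskRatio <- function(pExposed, pPop, level = 0.95,
                                logScale = FALSE) {
  p1 <- pExposed$kHat; v1 <- pExposed$se^2
  p0 <- pPop$kHat; v0 <- pPop$se^2
  if (is.na(p1) || p1 <= 0) {
    warning("no cases among the exposed: recurrence risk ratio is missing",
            call. = FALSE)
    return(list(lambda = NA_real_, se = NA_real_, lower95 = NA_real_,
                pOneSided = NA_real_))
  }
  if (is.na(p0) || p0 <= 0) stop("population prevalence must be positive")
  if (v1 < 0 || v0 < 0) stop("nonpositive variance")
  lambda <- p1 / p0
  se <- sqrt(v1 / p0^2 + p1^2 * v0 / p0^4)
  if (se <= 0) stop("nonpositive standard error for the risk ratio")
  z <- qnorm(level)
  if (logScale) {
    seLog <- se / lambda
    lower <- exp(log(lambda) - z * seLog)
    p <- pnorm(log(lambda) / seLog, lower.tail = FALSE)
  } else {
    lower <- lambda - z * se
    p <- pnorm((lambda - 1) / se, lower.tail = FALSE)
  }
  list(lambda = lambda, se = se, lower95 = lower, pOneSided = p)
}
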