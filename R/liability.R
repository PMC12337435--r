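## Familial correlations from the liability threshold model: disease status
## arises when a standard-normal latent liability exceeds a threshold set
## by the lifetime prevalence. Observing the prevalence of disorder A among
## individuals with a relative affected by disorder B identifies the
## cross-relative cross-trait liability correlation a_R * r_f, which is
## inverted for the familial correlation r_f.

#' Liability threshold parameters for a prevalence
#'
#' @param K lifetime prevalence in (0, 1).
#' @return list with \code{K}, the liability threshold \code{t} =
#'   qnorm(1 - K), the normal density at the threshold \code{z}, and the
#'   mean liability of the affected \code{i} = z / K.
#' @examples
#' liabilityParams(0.5)$i  # 2 * dnorm(0) ~ 0.798
#' @export
liabilityParams <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0 || K >= 1)
    stop("prevalence K must lie strictly between 0 and 1")
  t <- qnorm(1 - K)
  z <- dnorm(t)
  list(K = K, t = t, z = z, i = z / K)
}

## upper-right bivariate normal orthant probability P(X > a, Y > b; rho)
.bvnTail <- function(a, b, rho) {
  if (abs(rho) < .Machine$double.eps)
    return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  mvtnorm::pmvnorm(lower = c(a, b), upper = c(Inf, Inf),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::TVPACK(abseps = 1e-12))[1]
}

#' Predicted prevalence in relatives of affected individuals
#'
#' Given liability parameters for the outcome disorder A and the exposure
#' disorder B, the relatedness coefficient a_R and a familial correlation
#' r_f, predicts the prevalence of A among individuals with a relative
#' affected by B.
#'
#' Exact mode evaluates the bivariate-normal tail directly:
#' K_pred = P(X > t_A, Y > t_B; corr = a_R r_f) / K_B with X the proband's
#' liability for A and Y the relative's liability for B. Approximate mode
#' uses the classical truncated-selection threshold shift:
#' t* = (t_A - a_R r_f i_B) / sqrt(1 - a_R^2 r_f^2 i_B (i_B - t_B)),
#' K_pred = 1 - pnorm(t*).
#'
#' @param paramsA,paramsB [liabilityParams()] of the outcome and the
#'   relative's disorder.
#' @param aR relatedness coefficient: 0.5 (first degree) or 0.25 (second).
#' @param rf familial correlation, |rf| < 1.
#' @param mode \code{"exact"} (default) or \code{"approximate"}.
#' @return predicted prevalence in (0, 1).
#' @export
predictedRelativePrevalence <- function(paramsA, paramsB, aR, rf,
                                        mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  if (!aR %in% c(0.5, 0.25))
    stop("relatedness coefficient aR must be 0.5 (first) or 0.25 (second degree)")
  if (abs(rf) >= 1) stop("|rf| must be below 1")
  if (mode == "exact") {
    .bvnTail(paramsA$t, paramsB$t, aR * rf) / paramsB$K
  } else {
    iB <- paramsB$i; tB <- paramsB$t
    denom2 <- 1 - aR^2 * rf^2 * iB * (iB - tB)
    if (denom2 <= 0) stop("approximate mode undefined at this rf")
    tStar <- (paramsA$t - aR * rf * iB) / sqrt(denom2)
    pnorm(tStar, lower.tail = FALSE)
  }
}

#' Solve for the familial correlation from an observed relative prevalence
#'
#' Inverts [predictedRelativePrevalence()] (strictly increasing in rf) by
#' bracketed root finding on (-0.999, 0.999) to tolerance 1e-8.
#'
#' @param kObs observed prevalence of disorder A among individuals with an
#'   affected relative for disorder B.
#' @inheritParams predictedRelativePrevalence
#' @return the familial correlation r_f.
#' @export
solveRf <- function(kObs, paramsA, paramsB, aR,
                    mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  if (is.na(kObs) || kObs <= 0 || kObs >= 1)
    stop("observed prevalence must lie strictly between 0 and 1")
  f <- function(r) predictedRelativePrevalence(paramsA, paramsB, aR, r, mode) - kObs
  lo <- f(-0.999); hi <- f(0.999)
  if (lo > 0 || hi < 0)
    stop(sprintf(paste0("observed prevalence %.4g outside the attainable ",
                        "range [%.4g, %.4g]"),
                 kObs, lo + kObs, hi + kObs))
  uniroot(f, c(-0.999, 0.999), tol = 1e-10)$root
}

#' Familial correlation combined across relative degrees and directions
#'
#' Solves one r_f per available component (first/second degree x which
#' disorder is the outcome), attaches a delta-method standard error
#' propagated through the solver by central finite differences on the
#' prevalence argument, and combines the finite components by
#' inverse-variance weighting. Inference is one-sided (H0: r_f = 0,
#' H1: r_f > 0); only the lower confidence bound is reported.
#'
#' @param components data.frame with columns \code{degree} (\code{"first"}/
#'   \code{"second"}), \code{direction} (\code{"AgivenB"}: prevalence of A
#'   in those with an affected relative for B, or \code{"BgivenA"}),
#'   \code{kObs} and \code{se}. Rows with missing \code{kObs} are skipped.
#' @param paramsA,paramsB [liabilityParams()] of the two disorders
#'   (general-population prevalences).
#' @param mode liability mode passed to the solver.
#' @param level one-sided confidence level.
#' @return list with \code{rf}, \code{se}, \code{lower95},
#'   \code{pOneSided}, \code{mode} and the per-component table
#'   (\code{components}, with \code{rf} and \code{seRf} columns appended);
#'   all-NA result with a warning when no component is solvable.
#' @export
estimateFamilialCorrelation <- function(components, paramsA, paramsB,
                                        mode = c("exact", "approximate"),
                                        level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(components), nrow(components) >= 1L,
            all(c("degree", "direction", "kObs", "se") %in% names(components)))
  comp <- components
  comp$rf <- NA_real_; comp$seRf <- NA_real_
  h <- 1e-4
  for (r in seq_len(nrow(comp))) {
    kObs <- comp$kObs[r]
    if (is.na(kObs) || kObs <= 0 || kObs >= 1) next
    aR <- switch(comp$degree[r], first = 0.5, second = 0.25,
                 stop("degree must be 'first' or 'second'"))
    pOut <- if (comp$direction[r] == "AgivenB") paramsA else paramsB
    pRel <- if (comp$direction[r] == "AgivenB") paramsB else paramsA
    rf <- tryCatch(solveRf(kObs, pOut, pRel, aR, mode), error = function(e) NA)
    if (is.na(rf)) next
    dK <- tryCatch(
      (solveRf(kObs + h, pOut, pRel, aR, mode) -
       solveRf(kObs - h, pOut, pRel, aR, mode)) / (2 * h),
      error = function(e) NA_real_)
    comp$rf[r] <- rf
    comp$seRf[r] <- abs(dK) * comp$se[r]
  }
  ok <- is.finite(comp$rf) & is.finite(comp$seRf) & comp$seRf > 0
  if (!any(ok)) {
    warning("no solvable familial-correlation component", call. = FALSE)
    return(list(rf = NA_real_, se = NA_real_, lower95 = NA_real_,
                pOneSided = NA_real_, mode = mode, components = comp))
  }
  if (!all(c("first", "second") %in% comp$degree[ok]))
    warning("familial correlation combined from a single relative degree",
            call. = FALSE)
  w <- 1 / comp$seRf[ok]^2
  rf <- sum(w * comp$rf[ok]) / sum(w)
  se <- sqrt(1 / sum(w))
  list(rf = rf, se = se,
       lower95 = rf - qnorm(level) * se,
       pOneSided = pnorm(rf / se, lower.tail = FALSE),
       mode = mode, components = comp)
}
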