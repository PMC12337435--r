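## One BH family across the whole test grid: all recurrence-risk-ratio and
## familial-correlation tests are corrected together.

#' Benjamini-Hochberg adjustment with missing-value handling
#'
#' Standard step-up BH adjusted p-values over the non-missing entries;
#' tests that were never computed (missing p) do not enter the family size
#' m. Rejection at adjusted p <= q.
#'
#' @param p vector of one-sided p-values in [0, 1], possibly with NA.
#' @param q false discovery rate.
#' @return list with \code{pAdjusted} (same length as \code{p}) and
#'   \code{significant} (logical, NA where p is missing).
#' @export
bhAdjust <- function(p, q = 0.05) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  list(pAdjusted = adj, significant = adj <= q)
}

#' Assemble the full results table with FDR control
#'
#' Concatenates recurrence-risk-ratio rows and familial-correlation rows
#' into one table and applies a single Benjamini-Hochberg family across all
#' tests (optionally one family per statistic type). For a full design of
#' n_focal x n_disease phenotype pairs this is n_focal*n_disease*2 lambda
#' tests plus n_focal*n_disease r_f tests.
#'
#' @param lambdaTab data.frame of lambda rows with columns \code{outcome},
#'   \code{relative_phenotype}, \code{degree} and \code{p_one_sided}.
#' @param rfTab data.frame of r_f rows with columns \code{phenotype_A},
#'   \code{phenotype_B} and \code{p_one_sided}.
#' @param q false discovery rate.
#' @param family \code{"all"} (one BH family, default) or \code{"per-type"}.
#' @return list with the augmented \code{lambda} and \code{rf} tables (new
#'   columns \code{p_adjusted}, \code{significant}), the combined
#'   \code{tests} table, \code{nTests} (non-missing p only) and \code{q}.
#' @export
assembleResults <- function(lambdaTab, rfTab, q = 0.05,
                            family = c("all", "per-type")) {
  family <- match.arg(family)
  keyL <- paste(lambdaTab$outcome, lambdaTab$relative_phenotype,
                lambdaTab$degree, sep = "|")
  pair <- t(apply(cbind(rfTab$phenotype_A, rfTab$phenotype_B), 1, sort))
  keyR <- paste(pair[, 1], pair[, 2], sep = "|")
  if (anyDuplicated(keyL) || anyDuplicated(keyR))
    stop("duplicate (pair, direction, statistic) rows in the results")

  tests <- data.frame(
    statistic = c(rep("lambda", nrow(lambdaTab)), rep("rf", nrow(rfTab))),
    label = c(paste0(lambdaTab$outcome, " | relative with ",
                     lambdaTab$relative_phenotype),
              paste0(rfTab$phenotype_A, " ~ ", rfTab$phenotype_B)),
    p_one_sided = c(lambdaTab$p_one_sided, rfTab$p_one_sided),
    stringsAsFactors = FALSE)

  if (family == "all") {
    bh <- bhAdjust(tests$p_one_sided, q)
    tests$p_adjusted <- bh$pAdjusted
    tests$significant <- bh$significant
  } else {
    tests$p_adjusted <- NA_real_
    tests$significant <- NA
    for (s in unique(tests$statistic)) {
      ix <- tests$statistic == s
      bh <- bhAdjust(tests$p_one_sided[ix], q)
      tests$p_adjusted[ix] <- bh$pAdjusted
      tests$significant[ix] <- bh$significant
    }
  }
  nl <- nrow(lambdaTab)
  lambdaTab$p_adjusted <- tests$p_adjusted[seq_len(nl)]
  lambdaTab$significant <- tests$significant[seq_len(nl)]
  rfTab$p_adjusted <- tests$p_adjusted[nl + seq_len(nrow(rfTab))]
  rfTab$significant <- tests$significant[nl + seq_len(nrow(rfTab))]
  list(lambda = lambdaTab, rf = rfTab, tests = tests,
       nTests = sum(!is.na(tests$p_one_sided)), q = q)
}
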