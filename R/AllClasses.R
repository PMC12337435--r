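#' @import methods
#' @importFrom stats aggregate ave binomial coef dnorm glm median plogis
#'   pnorm qnorm quantile rnorm runif sd setNames uniroot var vcov
#' @importFrom utils read.delim read.table write.table
NULL

#' Pedigree of a family-based cohort
#'
#' Holds one row per individual with parent links, sex and the family label
#' (connected component of the undirected parent-child graph). Parent
#' references to individuals absent from the input are materialized as
#' placeholder founders that carry no phenotype data. Relationship degrees
#' are derived lazily by recursive kinship computation and cached.
#'
#' @slot individuals data.frame with columns \code{iid}, \code{father},
#'   \code{mother} (character, \code{NA} when unknown), \code{sex}
#'   (factor: male/female/unknown), \code{family} (integer component label),
#'   \code{placeholder} (logical) and internal integer parent indices.
#' @slot cache environment caching per-family degree matrices.
#'
#' @seealso [buildPedigree()], [readPed()], [relationshipDegree()]
#' @export
setClass("Pedigree",
  representation(individuals = "data.frame", cache = "environment"))

setValidity("Pedigree", function(object) {
  ind <- object@individuals
  need <- c("iid", "father", "mother", "sex", "family", "placeholder",
            "fatherIdx", "motherIdx", "generation")
  if (!all(need %in% names(ind)))
    return(paste("missing columns:", paste(setdiff(need, names(ind)), collapse = ", ")))
  if (anyDuplicated(ind$iid))
    return("duplicate individual identifiers")
  if (any(!nzchar(ind$iid)))
    return("empty individual identifier")
  ok <- function(ix) all(is.na(ix) | (ix >= 1 & ix <= nrow(ind)))
  if (!ok(ind$fatherIdx) || !ok(ind$motherIdx))
    return("parent index out of range")
  TRUE
})

#' Lifetime phenotype panel
#'
#' Per-individual lifetime status and analysis age for each phenotype,
#' derived from wave-level assessment records. Status is coded 1 = lifetime
#' case (case at >= 1 assessment), 0 = lifetime control (control at every
#' non-missing assessment), NA = no non-missing assessment. Analysis age is
#' the age at first case assessment for cases and the last age with data
#' for controls.
#'
#' @slot status integer matrix, individuals x phenotypes (1/0/NA).
#' @slot age numeric matrix, same dimensions, analysis age in years.
#'
#' @seealso [buildPhenotypePanel()], [applyExclusions()]
#' @export
setClass("PhenotypePanel",
  representation(status = "matrix", age = "matrix"))

setValidity("PhenotypePanel", function(object) {
  s <- object@status; a <- object@age
  if (!identical(dim(s), dim(a))) return("status and age dimensions differ")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("status matrix must have individual and phenotype dimnames")
  v <- s[!is.na(s)]
  if (length(v) && !all(v %in% c(0L, 1L))) return("status values must be 0/1/NA")
  if (any(is.na(s) != is.na(a)))
    return("analysis age must be present exactly where lifetime status is")
  TRUE
})

#' Fitted prevalence model
#'
#' A maximum-likelihood logistic regression of a lifetime disorder status on
#' the exposure indicator and covariates, with a family-clustered sandwich
#' covariance for the coefficients. Produced by [fitPrevalenceModel()] and
#' consumed by [averageAdjustedPrediction()].
#'
#' @slot beta named coefficient vector.
#' @slot V cluster-robust sandwich covariance of \code{beta}.
#' @slot X model matrix at the observed covariate values.
#' @slot y observed 0/1 outcome.
#' @slot clusters factor of family labels, one per row of \code{X}.
#' @slot converged logical convergence flag.
#' @export
setClass("PrevalenceFit",
  representation(beta = "numeric", V = "matrix", X = "matrix",
                 y = "numeric", clusters = "factor", converged = "logical"))

setValidity("PrevalenceFit", function(object) {
  p <- length(object@beta)
  if (!identical(dim(object@V), c(p, p))) return("V dimension mismatch")
  if (ncol(object@X) != p) return("model matrix / coefficient mismatch")
  if (max(abs(object@V - t(object@V))) > 1e-8) return("V not symmetric")
  if (min(eigen(object@V, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    return("V not positive semidefinite")
  TRUE
})

setMethod("show", "Pedigree", function(object) {
  ind <- object@individuals
  real <- !ind$placeholder
  cat("Pedigree with", sum(real), "individuals",
      sprintf("(+%d placeholder founders)", sum(!real)), "in",
      length(unique(ind$family)), "families\n")
  cat("  sex:", paste(sprintf("%s=%d", levels(ind$sex), table(ind$sex[real])),
                      collapse = ", "), "\n")
})

setMethod("show", "PhenotypePanel", function(object) {
  cat("PhenotypePanel:", nrow(object@status), "individuals x",
      ncol(object@status), "phenotypes\n")
  k <- round(100 * colMeans(object@status == 1L, na.rm = TRUE), 1)
  cat("  lifetime prevalence (%):",
      paste(sprintf("%s=%.1f", colnames(object@status), k), collapse = ", "), "\n")
})

setMethod("show", "PrevalenceFit", function(object) {
  cat("PrevalenceFit:", length(object@y), "observations,",
      nlevels(droplevels(object@clusters)), "family clusters\n")
  print(round(rbind(beta = object@beta, se = sqrt(diag(object@V))), 4))
})

#' @describeIn Pedigree-class number of individuals (placeholders included)
#' @param x,object a \code{Pedigree} or \code{PhenotypePanel}
#' @export
setMethod("length", "Pedigree", function(x) nrow(x@individuals))

#' Accessors
#'
#' \code{individuals()} returns the per-individual table of a
#' \code{Pedigree}; \code{familyIds()} the family component labels;
#' \code{lifetimeStatus()} and \code{analysisAge()} the matrices of a
#' \code{PhenotypePanel}; \code{phenotypes()} the phenotype names.
#'
#' @param object a \code{Pedigree} or \code{PhenotypePanel}
#' @return see individual descriptions
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(object) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setMethod("individuals", "Pedigree", function(object)
  object@individuals[c("iid", "father", "mother", "sex", "family", "placeholder")])

#' @rdname accessors
#' @export
setGeneric("familyIds", function(object) standardGeneric("familyIds"))
#' @rdname accessors
#' @export
setMethod("familyIds", "Pedigree", function(object)
  setNames(object@individuals$family, object@individuals$iid))

#' @rdname accessors
#' @export
setGeneric("lifetimeStatus", function(object) standardGeneric("lifetimeStatus"))
#' @rdname accessors
#' @export
setMethod("lifetimeStatus", "PhenotypePanel", function(object) object@status)

#' @rdname accessors
#' @export
setGeneric("analysisAge", function(object) standardGeneric("analysisAge"))
#' @rdname accessors
#' @export
setMethod("analysisAge", "PhenotypePanel", function(object) object@age)

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setMethod("phenotypes", "PhenotypePanel", function(object) colnames(object@status))
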