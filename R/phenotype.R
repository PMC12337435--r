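## Lifetime status derivation from multi-wave assessment records.
##
## Status coding throughout: 1 = case, 0 = control, NA = missing. An
## individual is a lifetime case if they fulfil the case definition at at
## least one assessment, a lifetime control if they fulfil it at no
## non-missing assessment, and missing if every assessment is missing.

#' Aggregate wave-level statuses into a lifetime status
#'
#' @param status integer vector of per-wave statuses (1/0/NA), any order.
#' @return 1 if any wave is a case, else 0 if any wave is a control, else
#'   \code{NA}. The outcome is invariant to wave order.
#' @examples
#' aggregateLifetime(c(1, 0, NA))  # 1
#' aggregateLifetime(c(0, NA, 0))  # 0
#' @export
aggregateLifetime <- function(status) {
  if (length(status) == 0L || all(is.na(status))) return(NA_integer_)
  if (any(status == 1L, na.rm = TRUE)) 1L else 0L
}

#' Lifetime status of a composite phenotype
#'
#' Combines the lifetime statuses of component phenotypes with the same
#' any-case rule used across waves: complete data on all components is not
#' required to be a control.
#'
#' @param statuses integer vector of component lifetime statuses (1/0/NA).
#' @return 1/0/NA as for [aggregateLifetime()].
#' @export
compositeStatus <- function(statuses) {
  stopifnot(length(statuses) >= 1L)
  aggregateLifetime(statuses)
}

#' Analysis age from wave-level records
#'
#' For lifetime cases, the age at which the case definition was first
#' satisfied; for lifetime controls, the last age at which relevant data
#' were available.
#'
#' @param status per-wave statuses (1/0/NA) in wave order.
#' @param age per-wave assessment ages, same length.
#' @return analysis age in years, or \code{NA} when all waves are missing.
#' @export
assignAnalysisAge <- function(status, age) {
  stopifnot(length(status) == length(age))
  lt <- aggregateLifetime(status)
  if (is.na(lt)) return(NA_real_)
  if (any(!is.na(status) & is.na(age)))
    stop("age missing at a non-missing assessment")
  if (lt == 1L) {
    w <- which(!is.na(status) & status == 1L)
    if (!length(w)) stop("lifetime case without any wave-level case record")
    age[w[1L]]
  } else {
    w <- which(!is.na(status))
    age[w[length(w)]]
  }
}

#' Build a lifetime phenotype panel from assessment records
#'
#' Derives, per (individual, phenotype), the lifetime case/control/missing
#' status and the analysis age from long-format wave-level records.
#'
#' @param records data.frame with columns \code{iid}, \code{phenotype},
#'   \code{wave}, \code{status} (1/0/NA) and \code{age} (years at that
#'   assessment). A missing (iid, phenotype, wave) row is equivalent to a
#'   row with \code{NA} status.
#' @param waves explicit ordered wave labels (earliest first). Defaults to
#'   the order of first appearance in \code{records}; pass the study's wave
#'   list to be explicit.
#' @return a [PhenotypePanel-class].
#' @export
buildPhenotypePanel <- function(records, waves = NULL) {
  need <- c("iid", "phenotype", "wave", "status", "age")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  iid <- as.character(records$iid)
  phen <- as.character(records$phenotype)
  wave <- as.character(records$wave)
  status <- as.integer(records$status)
  age <- as.numeric(records$age)
  if (any(!is.na(status) & !(status %in% c(0L, 1L))))
    stop("status must be 1/0/NA")
  if (any(!is.na(status) & is.na(age)))
    stop("age missing at a non-missing assessment")
  if (any(!is.na(age) & (age < 0 | age > 120)))
    stop("implausible assessment age (outside [0, 120])")
  if (is.null(waves)) waves <- unique(wave)
  if (!all(wave %in% waves)) stop("wave label not in the declared wave order")
  w <- match(wave, waves)

  key <- paste(iid, phen, wave, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate assessment record for (iid, phenotype, wave): ",
         gsub("\r", ", ", d))
  }

  ids <- sort(unique(iid), method = "radix")
  phens <- sort(unique(phen), method = "radix")
  gi <- match(iid, ids); gp <- match(phen, phens)
  g <- (gp - 1L) * length(ids) + gi            # cell index in the matrices

  o <- order(g, w)
  g <- g[o]; status <- status[o]; age <- age[o]

  S <- matrix(NA_integer_, length(ids), length(phens),
              dimnames = list(ids, phens))
  A <- matrix(NA_real_, length(ids), length(phens),
              dimnames = list(ids, phens))

  nm <- which(!is.na(status))
  caseRows <- nm[status[nm] == 1L]
  firstCase <- caseRows[!duplicated(g[caseRows])]
  lastNm <- nm[!duplicated(g[nm], fromLast = TRUE)]

  S[g[lastNm]] <- 0L                           # any data -> provisional control
  S[g[firstCase]] <- 1L
  A[g[lastNm]] <- age[lastNm]                  # controls: last age with data
  A[g[firstCase]] <- age[firstCase]            # cases: age at first case wave
  new("PhenotypePanel", status = S, age = A)
}

#' Add a composite phenotype to a panel
#'
#' Lifetime status follows the any-case rule over components (a case on any
#' component makes a composite case; controls need not have data on every
#' component). Analysis age is the earliest component case age for cases
#' and the latest component analysis age for controls.
#'
#' @param panel a [PhenotypePanel-class]
#' @param name name of the new composite phenotype
#' @param components character vector of existing phenotype names
#' @return a new [PhenotypePanel-class] with the added column.
#' @export
addCompositePhenotype <- function(panel, name, components) {
  miss <- setdiff(components, phenotypes(panel))
  if (length(miss)) stop("unknown phenotype(s): ", paste(miss, collapse = ", "))
  S <- panel@status[, components, drop = FALSE]
  A <- panel@age[, components, drop = FALSE]
  anyCase <- rowSums(S == 1L, na.rm = TRUE) > 0
  anyData <- rowSums(!is.na(S)) > 0
  st <- ifelse(anyCase, 1L, ifelse(anyData, 0L, NA_integer_))
  caseAge <- suppressWarnings(apply(ifelse(!is.na(S) & S == 1L, A, NA), 1, min,
                                    na.rm = TRUE))
  ctrlAge <- suppressWarnings(apply(ifelse(!is.na(S), A, NA), 1, max,
                                    na.rm = TRUE))
  ag <- ifelse(anyCase, caseAge, ifelse(anyData, ctrlAge, NA_real_))
  newS <- cbind(panel@status, matrix(st, ncol = 1, dimnames = list(NULL, name)))
  newA <- cbind(panel@age, matrix(ag, ncol = 1, dimnames = list(NULL, name)))
  new("PhenotypePanel", status = newS, age = newA)
}

#' Sensitivity-analysis exclusions
#'
#' For each target phenotype, sets the status (and analysis age) of
#' individuals who are lifetime cases of any excluding phenotype to
#' missing, removing them from both the case and control pools of that
#' phenotype's analyses. Their data remain available for other phenotypes.
#'
#' @param panel a [PhenotypePanel-class]
#' @param exclusionMap named list: target phenotype -> character vector of
#'   excluding phenotypes.
#' @return a new [PhenotypePanel-class].
#' @export
applyExclusions <- function(panel, exclusionMap) {
  if (length(exclusionMap) == 0L) return(panel)
  all <- unique(c(names(exclusionMap), unlist(exclusionMap)))
  miss <- setdiff(all, phenotypes(panel))
  if (length(miss)) stop("unknown phenotype(s): ", paste(miss, collapse = ", "))
  S <- panel@status; A <- panel@age
  for (target in names(exclusionMap)) {
    ex <- exclusionMap[[target]]
    hit <- rowSums(S[, ex, drop = FALSE] == 1L, na.rm = TRUE) > 0
    S[hit, target] <- NA_integer_
    A[hit, target] <- NA_real_
  }
  new("PhenotypePanel", status = S, age = A)
}

#' Read assessment records / write a phenotype panel
#'
#' Tab-separated files. Records: columns \code{iid}, \code{phenotype},
#' \code{wave}, \code{status} (1/0/NA), \code{age}. Panel output: one row
#' per (iid, phenotype) with \code{lifetime_status} and
#' \code{analysis_age}.
#'
#' @param path file path
#' @return \code{readAssessments}: data.frame of records.
#' @export
readAssessments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(iid = "character", phenotype = "character",
                            wave = "character"))
}

#' @rdname readAssessments
#' @param panel a [PhenotypePanel-class]
#' @export
writePhenotypePanel <- function(panel, path) {
  S <- panel@status; A <- panel@age
  out <- data.frame(iid = rep(rownames(S), ncol(S)),
                    phenotype = rep(colnames(S), each = nrow(S)),
                    lifetime_status = as.vector(S),
                    analysis_age = as.vector(A))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cohort descriptive summary
#'
#' Table-1 style description of a study population: participant count, sex
#' split, age at first assessment, availability and number of first- and
#' second-degree relatives in the dataset, and lifetime case counts per
#' phenotype.
#'
#' @param ped a [Pedigree-class]
#' @param panel a [PhenotypePanel-class]
#' @param records optional assessment records; when given, age at first
#'   assessment is summarized from them (otherwise the earliest analysis
#'   age per individual is used).
#' @return list with elements \code{n}, \code{sex} (counts and percent),
#'   \code{age} (mean, sd), \code{relatives} (percent with >= 1 first-/
#'   second-degree relative in the dataset and median/IQR counts among
#'   those), and \code{phenotypes} (data.frame of case counts and percent
#'   of non-missing).
#' @export
summarizeCohort <- function(ped, panel, records = NULL) {
  S <- lifetimeStatus(panel)
  participant <- rownames(S)[rowSums(!is.na(S)) > 0]
  ind <- ped@individuals[match(participant, ped@individuals$iid), ]
  n <- length(participant)

  if (!is.null(records)) {
    firstAge <- tapply(records$age, records$iid, function(a)
      if (all(is.na(a))) NA_real_ else min(a, na.rm = TRUE))
    ageVec <- unname(firstAge[participant])
  } else {
    ageVec <- suppressWarnings(apply(panel@age[participant, , drop = FALSE],
                                     1, min, na.rm = TRUE))
    ageVec[!is.finite(ageVec)] <- NA_real_
  }

  anyRel <- .relativesAnyData(ped, panel)
  relStats <- lapply(c(first = "first", second = "second"), function(d) {
    cnt <- anyRel[[d]][participant]
    has <- cnt > 0
    list(pctWithRelative = 100 * mean(has),
         nWithRelative = sum(has),
         medianCount = if (any(has)) median(cnt[has]) else NA_real_,
         iqr = if (any(has)) unname(quantile(cnt[has], c(0.25, 0.75))) else c(NA, NA))
  })

  phenTab <- data.frame(
    phenotype = colnames(S),
    nCases = colSums(S[participant, , drop = FALSE] == 1L, na.rm = TRUE),
    nNonMissing = colSums(!is.na(S[participant, , drop = FALSE])),
    row.names = NULL)
  phenTab$pctCases <- 100 * phenTab$nCases / phenTab$nNonMissing

  list(n = n,
       sex = list(counts = table(ind$sex),
                  percent = 100 * proportions(table(ind$sex))),
       age = list(mean = mean(ageVec, na.rm = TRUE),
                  sd = sd(ageVec, na.rm = TRUE)),
       relatives = relStats,
       phenotypes = phenTab)
}

## per-individual count of relatives (by degree) with data on any phenotype
.relativesAnyData <- function(ped, panel) {
  S <- .alignStatus(ped, panel)
  hasData <- rowSums(!is.na(S)) > 0
  n <- nrow(S)
  out <- list(first = setNames(integer(n), rownames(S)),
              second = setNames(integer(n), rownames(S)))
  for (members in .familyIndexList(ped)) {
    if (length(members) < 2L) next
    fd <- .familyPairData(ped, members)
    hd <- hasData[members]
    for (d in 1:2) {
      M <- fd$codes == d
      if (any(M)) out[[c("first", "second")[d]]][members] <- as.integer(M %*% hd)
    }
  }
  out
}
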