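## Pedigree construction, kinship recursion and relative-pair machinery.
##
## Relationship degrees follow the classification used in family-based
## co-aggregation studies: first degree = parent, full sibling, child
## (2*kinship = 0.5); second degree = half-sibling, grandparent/grandchild,
## avuncular (2*kinship = 0.25); everything else related is "other" and does
## not contribute to exposures or relative counts.

.SEX_LEVELS <- c("male", "female", "unknown")

.normSex <- function(x) {
  x <- as.character(x)
  x[x %in% c("1", "M", "m")] <- "male"
  x[x %in% c("2", "F", "f")] <- "female"
  x[is.na(x) | !(x %in% c("male", "female"))] <- "unknown"
  factor(x, levels = .SEX_LEVELS)
}

.normParent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "0" | x == "" | x == "NA")] <- NA_character_
  x
}

#' Build a validated pedigree
#'
#' Constructs a [Pedigree-class] from one record per individual. Parent
#' identifiers that do not occur among the individual identifiers are
#' materialized as placeholder founders (they carry no phenotype data and
#' never contribute to exposures or relative counts). Families are the
#' connected components of the undirected parent-child graph; individuals
#' in different families are unrelated by construction.
#'
#' @param records data.frame with columns \code{iid}, \code{father},
#'   \code{mother} (use \code{NA}, \code{""} or \code{"0"} for an unknown
#'   parent) and \code{sex} (\code{male}/\code{female}/\code{unknown} or
#'   PED codes 1/2/0).
#' @return a [Pedigree-class] object.
#' @examples
#' ped <- buildPedigree(data.frame(
#'   iid = c("F", "M", "C"), father = c(NA, NA, "F"),
#'   mother = c(NA, NA, "M"), sex = c("male", "female", "female")))
#' ped
#' @export
buildPedigree <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  need <- c("iid", "father", "mother", "sex")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  iid <- as.character(records$iid)
  if (any(is.na(iid) | !nzchar(iid))) stop("empty individual identifier")
  dup <- iid[duplicated(iid)]
  if (length(dup))
    stop("duplicate individual identifier(s): ", paste(unique(dup), collapse = ", "))
  father <- .normParent(records$father)
  mother <- .normParent(records$mother)
  if (any(!is.na(father) & father == iid) || any(!is.na(mother) & mother == iid))
    stop("individual listed as its own parent")
  sex <- .normSex(records$sex)

  ## materialize dangling parent references as placeholder founders
  refs <- unique(c(father[!is.na(father)], mother[!is.na(mother)]))
  extra <- setdiff(refs, iid)
  placeholder <- c(rep(FALSE, length(iid)), rep(TRUE, length(extra)))
  if (length(extra)) {
    exSex <- ifelse(extra %in% father, "male",
                    ifelse(extra %in% mother, "female", "unknown"))
    iid <- c(iid, extra)
    father <- c(father, rep(NA_character_, length(extra)))
    mother <- c(mother, rep(NA_character_, length(extra)))
    sex <- factor(c(as.character(sex), exSex), levels = .SEX_LEVELS)
  }
  n <- length(iid)
  idx <- setNames(seq_len(n), iid)
  fatherIdx <- unname(idx[father])
  motherIdx <- unname(idx[mother])

  ## generations by Kahn's algorithm; leftover nodes indicate a cycle
  nParents <- (!is.na(fatherIdx)) + (!is.na(motherIdx))
  ce <- which(!is.na(fatherIdx)); cm <- which(!is.na(motherIdx))
  childOf <- split(c(ce, cm), factor(c(fatherIdx[ce], motherIdx[cm]),
                                     levels = seq_len(n)))
  generation <- rep(NA_integer_, n)
  queue <- integer(n)
  founders <- which(nParents == 0L)
  queue[seq_along(founders)] <- founders
  tailq <- length(founders)
  generation[founders] <- 0L
  remaining <- nParents
  head <- 1L
  while (head <= tailq) {
    u <- queue[head]; head <- head + 1L
    for (v in childOf[[u]]) {
      remaining[v] <- remaining[v] - 1L
      if (remaining[v] == 0L) {
        gpar <- c(generation[fatherIdx[v]], generation[motherIdx[v]])
        generation[v] <- max(gpar, na.rm = TRUE) + 1L
        tailq <- tailq + 1L
        queue[tailq] <- v
      }
    }
  }
  if (anyNA(generation))
    stop("pedigree contains a cycle involving: ",
         paste(iid[is.na(generation)], collapse = ", "))

  ## families = connected components of the undirected parent-child graph
  e1 <- which(!is.na(fatherIdx)); e2 <- which(!is.na(motherIdx))
  edges <- data.frame(from = as.character(c(fatherIdx[e1], motherIdx[e2])),
                      to = as.character(c(e1, e2)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
         vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership
  family <- as.integer(comp[as.character(seq_len(n))])

  ind <- data.frame(iid = iid, father = father, mother = mother, sex = sex,
                    family = family, placeholder = placeholder,
                    fatherIdx = fatherIdx, motherIdx = motherIdx,
                    generation = generation, stringsAsFactors = FALSE)
  rownames(ind) <- iid
  new("Pedigree", individuals = ind, cache = new.env(parent = emptyenv()))
}

#' Read / write PED-like pedigree files
#'
#' Whitespace- or tab-delimited files with columns \code{FID} (optional),
#' \code{IID}, \code{PAT}, \code{MAT}, \code{SEX}; \code{0} or empty denotes
#' a missing parent, sex is coded 1 = male, 2 = female, 0 = unknown. The
#' family column is ignored on input (families are recomputed as graph
#' components).
#'
#' @param path file path.
#' @return \code{readPed}: a [Pedigree-class]; \code{writePed}: the path,
#'   invisibly.
#' @export
readPed <- function(path) {
  tab <- read.table(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("PED file needs at least IID, PAT, MAT, SEX columns")
  if (ncol(tab) >= 5) tab <- tab[, 2:5]   # drop FID
  names(tab) <- c("iid", "father", "mother", "sex")
  buildPedigree(tab)
}

#' @rdname readPed
#' @param ped a [Pedigree-class]
#' @export
writePed <- function(ped, path) {
  ind <- ped@individuals[!ped@individuals$placeholder, ]
  out <- data.frame(FID = ind$family, IID = ind$iid,
                    PAT = ifelse(is.na(ind$father), "0", ind$father),
                    MAT = ifelse(is.na(ind$mother), "0", ind$mother),
                    SEX = c(male = 1L, female = 2L, unknown = 0L)[as.character(ind$sex)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## kinship matrix for one family, members ordered parents-before-children;
## fa/mo are local indices into the member vector (NA = unknown/outside)
.kinshipLocal <- function(fa, mo) {
  m <- length(fa)
  phi <- matrix(0, m, m)
  for (i in seq_len(m)) {
    pf <- fa[i]; pm <- mo[i]
    phi[i, i] <- 0.5 + 0.5 * (if (!is.na(pf) && !is.na(pm)) phi[pf, pm] else 0)
    if (i > 1L) for (j in seq_len(i - 1L)) {
      v <- 0
      if (!is.na(pf)) v <- v + phi[pf, j]
      if (!is.na(pm)) v <- v + phi[pm, j]
      phi[i, j] <- phi[j, i] <- 0.5 * v
    }
  }
  phi
}

## degree codes: 0 none, 1 first, 2 second, 3 other ("related but neither")
.DEG_NONE <- 0L; .DEG_FIRST <- 1L; .DEG_SECOND <- 2L; .DEG_OTHER <- 3L

## per-family degree + relatedness computation with a structure cache:
## families generated from a common template share one computation
.familyPairData <- function(ped, members) {
  ind <- ped@individuals
  m <- length(members)
  faL <- match(ind$fatherIdx[members], members)
  moL <- match(ind$motherIdx[members], members)
  key <- paste0("k", m, ":", paste(ifelse(is.na(faL), 0L, faL), collapse = ","),
                ";", paste(ifelse(is.na(moL), 0L, moL), collapse = ","))
  cache <- ped@cache
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)

  ## compute in topological (parents-first) order, then map back
  ord <- order(ind$generation[members])
  loc <- integer(m); loc[ord] <- seq_len(m)  # member position -> topo position
  faT <- loc[faL[ord]]
  moT <- loc[moL[ord]]
  phiT <- .kinshipLocal(faT, moT)
  phi <- phiT[loc, loc, drop = FALSE]

  A <- 2 * phi
  tol <- 1e-9
  off <- A; diag(off) <- 0
  codes <- matrix(.DEG_NONE, m, m)
  codes[abs(off - 0.5) < tol] <- .DEG_FIRST
  codes[abs(off - 0.25) < tol] <- .DEG_SECOND
  codes[off > tol & abs(off - 0.5) >= tol & abs(off - 0.25) >= tol] <- .DEG_OTHER
  diag(codes) <- .DEG_NONE

  ## sibships that cannot be resolved into full vs half because a parent is
  ## unrecorded are classified conservatively as "other"
  unresolved <- 0L
  if (anyNA(faL) || anyNA(moL)) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      shareF <- !is.na(faL[i]) && !is.na(faL[j]) && faL[i] == faL[j]
      shareM <- !is.na(moL[i]) && !is.na(moL[j]) && moL[i] == moL[j]
      if ((shareF || shareM) &&
          (is.na(faL[i]) || is.na(moL[i]) || is.na(faL[j]) || is.na(moL[j]))) {
        codes[i, j] <- codes[j, i] <- .DEG_OTHER
        unresolved <- unresolved + 1L
      }
    }
  }
  res <- list(codes = codes, A = A, unresolved = unresolved)
  assign(key, res, envir = cache)
  res
}

.familyIndexList <- function(ped) {
  cache <- ped@cache
  if (is.null(cache$famSplit))
    cache$famSplit <- split(seq_len(nrow(ped@individuals)),
                            ped@individuals$family)
  cache$famSplit
}

.warnUnresolved <- function(ped, total) {
  if (total > 0L && is.null(ped@cache$warnedUnresolved)) {
    ped@cache$warnedUnresolved <- TRUE
    warning(total, " sibling pair(s) with incomplete parentage classified as ",
            "degree 'other'", call. = FALSE)
  }
}

#' Relationship degree between two individuals
#'
#' Classifies a pair by recursive kinship coefficient phi: 2*phi = 0.5 is
#' first degree (relatedness coefficient a_R = 0.5), 2*phi = 0.25 second
#' degree (a_R = 0.25); other positive kinship (e.g. first cousins,
#' 2*phi = 0.125) is \code{"other"}; zero kinship or different families is
#' \code{"unrelated"}. Sibling pairs whose full/half status cannot be
#' resolved because a parent is unrecorded are classified as \code{"other"}
#' with a warning. Inbreeding is ignored in the mapping.
#'
#' @param ped a [Pedigree-class]
#' @param i,j individual identifiers, \code{i != j}
#' @return list with elements \code{degree} (one of \code{"first"},
#'   \code{"second"}, \code{"other"}, \code{"unrelated"}) and \code{aR}
#'   (0.5, 0.25 or \code{NA}).
#' @export
relationshipDegree <- function(ped, i, j) {
  ind <- ped@individuals
  ii <- match(i, ind$iid); jj <- match(j, ind$iid)
  if (is.na(ii) || is.na(jj))
    stop("unknown individual: ", paste(c(i, j)[is.na(c(ii, jj))], collapse = ", "))
  if (ii == jj) stop("relationship degree requires two distinct individuals")
  if (ind$family[ii] != ind$family[jj])
    return(list(degree = "unrelated", aR = NA_real_))
  members <- .familyIndexList(ped)[[as.character(ind$family[ii])]]
  fd <- .familyPairData(ped, members)
  .warnUnresolved(ped, fd$unresolved)
  code <- fd$codes[match(ii, members), match(jj, members)]
  degree <- c("unrelated", "first", "second", "other")[code + 1L]
  list(degree = degree,
       aR = if (code == .DEG_FIRST) 0.5 else if (code == .DEG_SECOND) 0.25
            else NA_real_)
}

#' Kinship coefficient between two pedigree members
#'
#' @inheritParams relationshipDegree
#' @return the kinship coefficient phi (probability that two randomly drawn
#'   alleles, one from each individual, are identical by descent).
#' @export
kinshipCoef <- function(ped, i, j) {
  ind <- ped@individuals
  ii <- match(i, ind$iid); jj <- match(j, ind$iid)
  if (is.na(ii) || is.na(jj))
    stop("unknown individual: ", paste(c(i, j)[is.na(c(ii, jj))], collapse = ", "))
  if (ind$family[ii] != ind$family[jj]) return(0)
  members <- .familyIndexList(ped)[[as.character(ind$family[ii])]]
  fd <- .familyPairData(ped, members)
  fd$A[match(ii, members), match(jj, members)] / 2
}

#' Per-family additive relationship matrices
#'
#' Returns, for each family, the matrix A with unit diagonal (inbreeding
#' ignored for founders of a non-inbred cohort; A_uu = 2*phi(u,u)) and
#' A_uv = 2*kinship(u, v): 0.5 for first-degree pairs, 0.25 for
#' second-degree. Used by the liability simulator as the across-relative
#' scaling of familial covariance.
#'
#' @param ped a [Pedigree-class]
#' @return named list (by family label) of symmetric matrices with iid
#'   dimnames.
#' @export
relationshipMatrix <- function(ped) {
  fams <- .familyIndexList(ped)
  ind <- ped@individuals
  lapply(fams, function(members) {
    A <- .familyPairData(ped, members)$A
    dimnames(A) <- list(ind$iid[members], ind$iid[members])
    A
  })
}

## status matrix aligned to pedigree rows (individuals absent from the
## panel, e.g. placeholders, get NA)
.alignStatus <- function(ped, panel) {
  S <- lifetimeStatus(panel)
  ix <- match(ped@individuals$iid, rownames(S))
  out <- S[ix, , drop = FALSE]
  rownames(out) <- ped@individuals$iid
  out
}

## One pass over families computing, for every phenotype and both degrees,
## the number of relatives with data and the any-affected-relative indicator.
.batchRelativeStats <- function(ped, panel, phen = NULL) {
  S <- .alignStatus(ped, panel)
  if (!is.null(phen)) {
    miss <- setdiff(phen, colnames(S))
    if (length(miss)) stop("unknown phenotype(s): ", paste(miss, collapse = ", "))
    S <- S[, phen, drop = FALSE]
  }
  n <- nrow(S); k <- ncol(S)
  zero <- matrix(0L, n, k, dimnames = dimnames(S))
  out <- list(first = list(count = zero, exposed = zero),
              second = list(count = zero, exposed = zero))
  fams <- .familyIndexList(ped)
  unresolved <- 0L
  for (members in fams) {
    if (length(members) < 2L) next
    fd <- .familyPairData(ped, members)
    unresolved <- unresolved + fd$unresolved
    Sg <- S[members, , drop = FALSE]
    nonmiss <- !is.na(Sg)
    case <- nonmiss & Sg == 1L
    for (d in 1:2) {
      M <- fd$codes == d
      if (!any(M)) next
      nm <- c("first", "second")[d]
      out[[nm]]$count[members, ] <- (M %*% nonmiss)
      out[[nm]]$exposed[members, ] <- ((M %*% case) > 0) + 0L
    }
  }
  .warnUnresolved(ped, unresolved)
  out
}

#' Relatives with phenotype data, and exposure indicators
#'
#' \code{countRelativesWithData()} counts, per individual, the relatives of
#' exactly the given degree whose lifetime status for the phenotype is
#' non-missing (the covariate used by the prevalence models).
#' \code{exposureStatus()} is 1 iff at least one such relative is a lifetime
#' case; individuals without relatives in the dataset get 0 and remain in
#' the general-population denominator.
#'
#' @param ped a [Pedigree-class]
#' @param panel a [PhenotypePanel-class]
#' @param phenotype phenotype name present in the panel
#' @param degree \code{"first"} or \code{"second"}
#' @return named integer vector over all pedigree individuals.
#' @export
countRelativesWithData <- function(ped, panel, phenotype,
                                   degree = c("first", "second")) {
  degree <- match.arg(degree)
  bs <- .batchRelativeStats(ped, panel, phenotype)
  bs[[degree]]$count[, phenotype]
}

#' @rdname countRelativesWithData
#' @export
exposureStatus <- function(ped, panel, phenotype,
                           degree = c("first", "second")) {
  degree <- match.arg(degree)
  bs <- .batchRelativeStats(ped, panel, phenotype)
  bs[[degree]]$exposed[, phenotype]
}
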