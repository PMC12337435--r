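## Synthetic cohort generator under the liability threshold model.
##
## Familial covariance is a single matrix C scaled across relatives by the
## additive relationship matrix A (combined genetic + shared-environment
## familial term): latent liabilities per family follow a matrix normal
## with covariance A (x) C for the familial part plus I (x) (R - C) for the
## person-specific residual, R being the within-person cross-trait total
## correlation matrix (unit diagonal). Cross-relative cross-trait liability
## covariance is therefore a_R * C[j, k], so the off-diagonal entries of C
## are exactly the familial correlations r_f the pipeline estimates, and
## the diagonal entries are per-trait familial variance shares.

#' Simulation configuration
#'
#' Defines the synthetic study: family template, phenotypes with target
#' lifetime prevalences, familial variance shares and familial correlation
#' targets, assessment waves with missingness, and the seed.
#'
#' @param nFamilies number of independent families.
#' @param phenotypes data.frame with columns \code{name} and \code{K}
#'   (target lifetime prevalence in (0, 1)).
#' @param rfTargets symmetric matrix of familial correlation targets
#'   (off-diagonal entries of the familial covariance C; diagonal ignored),
#'   or a single number applied to every pair, or NULL for independence.
#' @param familialShares per-trait familial variance share in [0, 1)
#'   (diagonal of C); recycled.
#' @param residualCrossCorr residual (non-familial) within-person
#'   cross-trait correlation added on top of the familial part; recycled
#'   over pairs. The within-person total correlation matrix is
#'   R = C_offdiag + residualCrossCorr with unit diagonal; R - C must stay
#'   positive semidefinite.
#' @param covariateEffects optional per-trait liability effects, a list of
#'   vectors \code{c(age=, age2=, sex=)} on the standardized-age /
#'   female-indicator scale; defaults to zero (closed-form threshold
#'   calibration is then exact).
#' @param waves data.frame with columns \code{name}, \code{offset} (years
#'   after baseline) and \code{missing} (per-wave missingness probability).
#' @param template list with \code{nChildren} and
#'   \code{grandchildrenPerChild}: founder couple, their children (each
#'   with a spouse who marries into the family), and grandchildren.
#' @param ageMeans,ageSd baseline-age normal means per generation
#'   (founders, middle generation, grandchildren) and common SD.
#' @param seed integer seed used by [simulateStudy()].
#' @return a validated configuration (class \code{SimulationConfig}).
#' @export
simulationConfig <- function(nFamilies = 1000,
                             phenotypes = data.frame(
                               name = c("trait_a", "trait_b"),
                               K = c(0.10, 0.15)),
                             rfTargets = 0.30,
                             familialShares = 0.6,
                             residualCrossCorr = 0,
                             covariateEffects = NULL,
                             waves = data.frame(
                               name = c("1A", "2A", "3A"),
                               offset = c(0, 4, 10),
                               missing = c(0.10, 0.20, 0.30)),
                             template = list(nChildren = 2,
                                             grandchildrenPerChild = 2),
                             ageMeans = c(68, 42, 16),
                             ageSd = 5,
                             seed = 1L) {
  stopifnot(nFamilies >= 1, is.data.frame(phenotypes),
            all(c("name", "K") %in% names(phenotypes)),
            all(phenotypes$K > 0 & phenotypes$K < 1),
            all(c("name", "offset", "missing") %in% names(waves)),
            all(waves$missing >= 0 & waves$missing < 1))
  k <- nrow(phenotypes)
  shares <- rep_len(familialShares, k)
  stopifnot(all(shares >= 0 & shares < 1))
  C <- diag(shares, k)
  if (!is.null(rfTargets)) {
    if (is.matrix(rfTargets)) {
      stopifnot(identical(dim(rfTargets), c(k, k)),
                max(abs(rfTargets - t(rfTargets))) < 1e-12)
      C[upper.tri(C)] <- rfTargets[upper.tri(rfTargets)]
      C[lower.tri(C)] <- t(C)[lower.tri(C)]
    } else if (k > 1) {
      C[upper.tri(C)] <- rfTargets
      C[lower.tri(C)] <- rfTargets
    }
  }
  R <- C
  diag(R) <- 1
  R[upper.tri(R)] <- R[upper.tri(R)] + rep_len(residualCrossCorr, sum(upper.tri(R)))
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  .assertPSD(C, "familial covariance")
  .assertPSD(R - C, "residual (within-person) covariance")
  if (template$nChildren < 1) stop("template needs at least one child")
  cfg <- list(nFamilies = as.integer(nFamilies), phenotypes = phenotypes,
              C = C, R = R, covariateEffects = covariateEffects,
              waves = waves, template = template, ageMeans = ageMeans,
              ageSd = ageSd, seed = as.integer(seed))
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

.assertPSD <- function(M, what) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    ij <- which(abs(M) == max(abs(M[upper.tri(M)])), arr.ind = TRUE)[1, ]
    stop(what, " is not positive semidefinite (check the (", ij[1], ",",
         ij[2], ") entry)")
  }
  invisible(TRUE)
}

## symmetric PSD square root (handles zero and rank-deficient matrices
## where a Cholesky factor would fail)
.psdSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate a three-generation pedigree population
#'
#' Generates \code{nFamilies} independent families following the template:
#' a founder couple, \code{nChildren} children each married to a spouse who
#' enters the pedigree as a founder, and \code{grandchildrenPerChild}
#' grandchildren per child. The structure contains parent-offspring and
#' full-sibling (first degree), grandparent-grandchild and avuncular
#' (second degree), and first-cousin ("other") pairs. Deterministic given
#' the configuration.
#'
#' @param cfg a [simulationConfig()].
#' @return a [Pedigree-class].
#' @export
simulatePedigrees <- function(cfg) {
  nF <- cfg$nFamilies
  nC <- cfg$template$nChildren
  nG <- cfg$template$grandchildrenPerChild
  fam <- sprintf("F%06d", seq_len(nF))

  ## spouses only enter the pedigree when they have children in it
  rowsPerFam <- 2L + nC * (if (nG > 0) 2L else 1L) + nC * nG
  iid <- father <- mother <- sex <- character(nF * rowsPerFam)
  pos <- 0L
  put <- function(ids, fa, mo, sx) {
    n <- length(ids)
    iid[pos + seq_len(n)] <<- ids
    father[pos + seq_len(n)] <<- fa
    mother[pos + seq_len(n)] <<- mo
    sex[pos + seq_len(n)] <<- sx
    pos <<- pos + n
  }
  gf <- paste0(fam, "_GF"); gm <- paste0(fam, "_GM")
  put(gf, NA, NA, "male")
  put(gm, NA, NA, "female")
  for (i in seq_len(nC)) {
    ci <- paste0(fam, "_C", i)
    si <- paste0(fam, "_S", i)
    sexC <- if (i %% 2 == 1) "female" else "male"
    sexS <- if (i %% 2 == 1) "male" else "female"
    put(ci, gf, gm, sexC)
    if (nG > 0) put(si, NA, NA, sexS)
    for (j in seq_len(nG)) {
      gij <- paste0(fam, "_G", i, "_", j)
      fa <- if (sexC == "male") ci else si
      mo <- if (sexC == "male") si else ci
      put(gij, fa, mo, if (j %% 2 == 1) "male" else "female")
    }
  }
  buildPedigree(data.frame(iid = iid, father = father, mother = mother,
                           sex = sex, stringsAsFactors = FALSE))
}

## effective generation for age assignment: founders who married into a
## lower generation (spouses) take the generation just above their children
.effectiveGeneration <- function(ped) {
  ind <- ped@individuals
  g <- ind$generation
  childMin <- rep(NA_integer_, nrow(ind))
  for (p in c("fatherIdx", "motherIdx")) {
    ix <- ind[[p]]
    has <- !is.na(ix)
    if (any(has)) {
      m <- tapply(g[has], ix[has], min)
      childMin[as.integer(names(m))] <-
        pmin(childMin[as.integer(names(m))], m, na.rm = TRUE)
    }
  }
  ifelse(!is.na(childMin), pmax(childMin - 1L, 0L), g)
}

#' Simulate multi-wave phenotype records under the liability model
#'
#' Draws per-family latent liabilities with covariance
#' A (x) C + I (x) (R - C), thresholds them at qnorm(1 - K) per trait
#' (numeric quantile calibration when covariate effects are nonzero), and
#' derives wave-level records: lifetime cases become observable cases from
#' a uniformly drawn onset wave onward, every (individual, wave) assessment
#' is missing with the wave's missingness probability, and assessment ages
#' are the baseline age (generation-specific normal) plus the wave offset.
#'
#' Uses the current RNG state; seed via [simulateStudy()] or
#' \code{set.seed()} for reproducibility.
#'
#' @param ped a [Pedigree-class] (typically from [simulatePedigrees()]).
#' @param cfg a [simulationConfig()].
#' @param returnLiability attach the latent liability matrix as attribute
#'   \code{"liability"} (test oracle).
#' @return long-format assessment records (data.frame: iid, phenotype,
#'   wave, status, age), missing assessments omitted.
#' @export
simulatePhenotypes <- function(ped, cfg, returnLiability = FALSE) {
  ind <- ped@individuals
  n <- nrow(ind)
  k <- nrow(cfg$phenotypes)
  traits <- cfg$phenotypes$name
  C <- cfg$C; Resid <- cfg$R - C
  sqC <- .psdSqrt(C)
  sqResid <- .psdSqrt(Resid)

  ## familial component: batch families sharing a template structure
  G <- matrix(0, n, k)
  fams <- .familyIndexList(ped)
  keys <- vapply(fams, function(members) {
    faL <- match(ind$fatherIdx[members], members)
    moL <- match(ind$motherIdx[members], members)
    paste0(length(members), ":", paste(ifelse(is.na(faL), 0L, faL), collapse = ","),
           ";", paste(ifelse(is.na(moL), 0L, moL), collapse = ","))
  }, character(1))
  for (kk in unique(keys)) {
    batch <- fams[keys == kk]
    m <- length(batch[[1L]])
    if (m == 1L) {
      idxAll <- unlist(batch, use.names = FALSE)
      G[idxAll, ] <- matrix(rnorm(length(idxAll) * k), ncol = k) %*% t(sqC)
      next
    }
    A <- .familyPairData(ped, batch[[1L]])$A
    sqA <- .psdSqrt(A)
    Fb <- length(batch)
    Z <- matrix(rnorm(m * k * Fb), nrow = m)           # m x (Fb*k), trait fastest
    LZ <- sqA %*% Z
    arr <- array(LZ, dim = c(m, k, Fb))
    Gmat <- matrix(aperm(arr, c(1, 3, 2)), ncol = k)   # (m*Fb) x k
    idxAll <- unlist(batch, use.names = FALSE)
    G[idxAll, ] <- Gmat %*% t(sqC)
  }

  E <- matrix(rnorm(n * k), n, k) %*% t(sqResid)
  L <- G + E

  ## baseline ages by effective generation
  eg <- .effectiveGeneration(ped)
  mu <- cfg$ageMeans[pmin(eg + 1L, length(cfg$ageMeans))]
  baseAge <- pmin(pmax(rnorm(n, mu, cfg$ageSd), 3), 100)
  sexF <- as.numeric(ind$sex == "female")

  hasEffects <- !is.null(cfg$covariateEffects) &&
    any(unlist(cfg$covariateEffects) != 0)
  if (hasEffects) {
    zAge <- (baseAge - mean(baseAge)) / sd(baseAge)
    for (t in seq_len(k)) {
      eff <- cfg$covariateEffects[[t]]
      if (is.null(eff)) next
      b <- c(age = 0, age2 = 0, sex = 0)
      b[names(eff)] <- eff
      L[, t] <- L[, t] + b["age"] * zAge + b["age2"] * (zAge^2 - 1) +
        b["sex"] * (sexF - 0.5)
    }
  }

  case <- matrix(0L, n, k)
  for (t in seq_len(k)) {
    thr <- if (hasEffects) quantile(L[, t], 1 - cfg$phenotypes$K[t], names = FALSE)
           else qnorm(1 - cfg$phenotypes$K[t])
    case[, t] <- as.integer(L[, t] > thr)
    if (hasEffects) {
      emp <- mean(case[, t])
      if (abs(emp - cfg$phenotypes$K[t]) > 0.002 + 3 * sqrt(cfg$phenotypes$K[t] / n))
        stop("prevalence calibration failed for trait ", traits[t])
    }
  }

  W <- nrow(cfg$waves)
  onset <- matrix(sample.int(W, n * k, replace = TRUE), n, k)
  missW <- matrix(runif(n * W) < rep(cfg$waves$missing, each = n), n, W)

  parts <- vector("list", k * W)
  for (t in seq_len(k)) for (w in seq_len(W)) {
    keep <- !missW[, w]
    st <- as.integer(case[, t] == 1L & onset[, t] <= w)
    parts[[(t - 1L) * W + w]] <- data.frame(
      iid = ind$iid[keep],
      phenotype = traits[t],
      wave = cfg$waves$name[w],
      status = st[keep],
      age = round(baseAge[keep] + cfg$waves$offset[w], 1),
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, parts)
  rownames(rec) <- NULL
  if (returnLiability) {
    dimnames(L) <- list(ind$iid, traits)
    attr(rec, "liability") <- L
  }
  rec
}

#' Simulate a complete study
#'
#' Seeds the RNG from the configuration, simulates the pedigree and the
#' assessment records, and builds the lifetime phenotype panel.
#'
#' @param cfg a [simulationConfig()].
#' @param returnLiability passed to [simulatePhenotypes()].
#' @return list with \code{ped}, \code{records} and \code{panel}.
#' @export
simulateStudy <- function(cfg, returnLiability = FALSE) {
  set.seed(cfg$seed)
  ped <- simulatePedigrees(cfg)
  records <- simulatePhenotypes(ped, cfg, returnLiability = returnLiability)
  panel <- buildPhenotypePanel(records, waves = cfg$waves$name)
  list(ped = ped, records = records, panel = panel)
}
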