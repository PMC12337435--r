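## End-to-end study orchestration: exposures, prevalence models, lambda_R,
## r_f, FDR control and result files.

#' Run the full familial co-aggregation analysis
#'
#' For every ordered (focal, disease) pair and both directions, fits the
#' covariate-adjusted logistic prevalence models (first-degree exposure for
#' the recurrence risk ratio; first- and second-degree for the familial
#' correlation), marginalizes them into average adjusted predictions,
#' computes lambda_R with delta-method uncertainty and r_f by liability
#' inversion, and applies one Benjamini-Hochberg family across all tests.
#'
#' Covariates per model: exposure indicator, analysis age, age squared, sex
#' (female = 1) and the number of relatives of the relevant degree with
#' data on the relative's disorder. Rows with a missing outcome, missing
#' age or unknown sex are dropped listwise per model. Pairs with no exposed
#' cases yield missing estimates with a warning rather than an error.
#'
#' @param ped a [Pedigree-class]
#' @param panel a [PhenotypePanel-class]
#' @param focal character vector of focal disorder names.
#' @param diseases character vector of co-aggregating disease names.
#' @param q false discovery rate for [assembleResults()].
#' @param mode liability inversion mode, \code{"exact"} or
#'   \code{"approximate"}.
#' @param aapMode \code{"observed"} (average fitted probabilities at the
#'   observed covariates within the exposed subgroup; default) or
#'   \code{"counterfactual"} (exposure set to 1 for the whole sample).
#' @param bhFamily \code{"all"} or \code{"per-type"} BH family.
#' @param verbose log per-model sample sizes to stderr.
#' @return list as returned by [assembleResults()], plus \code{modelLog}
#'   (per-model sample sizes and dropped-row counts).
#' @export
runCoaggregationStudy <- function(ped, panel, focal, diseases, q = 0.05,
                                  mode = c("exact", "approximate"),
                                  aapMode = c("observed", "counterfactual"),
                                  bhFamily = "all", verbose = FALSE) {
  mode <- match.arg(mode)
  aapMode <- match.arg(aapMode)
  traits <- unique(c(focal, diseases))
  missing <- setdiff(traits, phenotypes(panel))
  if (length(missing))
    stop("unknown phenotype(s): ", paste(missing, collapse = ", "))
  if (length(intersect(focal, diseases)))
    stop("focal and disease phenotype sets must be disjoint")

  ind <- ped@individuals
  S <- .alignStatus(ped, panel)
  Ag <- panel@age[match(ind$iid, rownames(panel@age)), , drop = FALSE]
  bs <- .batchRelativeStats(ped, panel, traits)
  sexF <- ifelse(ind$sex == "unknown", NA_real_,
                 as.numeric(ind$sex == "female"))

  fits <- new.env(parent = emptyenv())
  log <- list()
  fitOne <- function(outcome, relative, degree) {
    key <- paste(outcome, relative, degree, sep = "|")
    if (!is.null(fits[[key]])) return(fits[[key]])
    d <- data.frame(
      y = S[, outcome],
      exposed = bs[[degree]]$exposed[, relative],
      age = Ag[, outcome],
      sex = sexF,
      nrel = bs[[degree]]$count[, relative],
      family = ind$family)
    keep <- stats::complete.cases(d)
    dropped <- sum(!keep & !ind$placeholder)
    d <- d[keep, , drop = FALSE]
    d$age2 <- d$age^2
    res <- if (sum(d$exposed) == 0 || sum(d$y[d$exposed == 1]) == 0) {
      warning("no exposed cases for outcome '", outcome, "' given relative '",
              relative, "' (", degree, " degree); estimates set missing",
              call. = FALSE)
      NULL
    } else tryCatch({
      fit <- fitPrevalenceModel(d, "y",
                                c("exposed", "age", "age2", "sex", "nrel"),
                                "family")
      pPop <- averageAdjustedPrediction(fit)
      pExp <- if (aapMode == "observed")
        averageAdjustedPrediction(fit, subset = d$exposed == 1)
      else averageAdjustedPrediction(fit, counterfactual = TRUE)
      list(fit = fit, pPop = pPop, pExp = pExp,
           n = nrow(d), nExposed = sum(d$exposed))
    }, error = function(e) {
      warning("model for outcome '", outcome, "' | relative '", relative,
              "' (", degree, "): ", conditionMessage(e), call. = FALSE)
      NULL
    })
    log[[key]] <<- data.frame(outcome = outcome, relative = relative,
                              degree = degree, n = nrow(d),
                              nExposed = sum(d$exposed), dropped = dropped)
    if (verbose)
      message(sprintf("model %s: n=%d exposed=%d dropped=%d", key, nrow(d),
                      sum(d$exposed), dropped))
    fits[[key]] <- list(value = res)
    fits[[key]]
  }

  lambdaRows <- list()
  rfRows <- list()
  for (f in focal) for (dz in diseases) {
    pairFits <- list(
      f1 = fitOne(f, dz, "first")$value,
      d1 = fitOne(dz, f, "first")$value,
      f2 = fitOne(f, dz, "second")$value,
      d2 = fitOne(dz, f, "second")$value)

    for (dir in c("f1", "d1")) {
      ft <- pairFits[[dir]]
      outcome <- if (dir == "f1") f else dz
      relative <- if (dir == "f1") dz else f
      row <- if (is.null(ft)) {
        data.frame(outcome = outcome, relative_phenotype = relative,
                   degree = "first", n_pop = NA_integer_,
                   n_exposed = NA_integer_, K_pop = NA_real_,
                   se_pop = NA_real_, K_exposed = NA_real_,
                   se_exposed = NA_real_, lambda = NA_real_,
                   se_lambda = NA_real_, lower95 = NA_real_,
                   p_one_sided = NA_real_)
      } else {
        lam <- recurrenceRiskRatio(ft$pExp, ft$pPop)
        data.frame(outcome = outcome, relative_phenotype = relative,
                   degree = "first", n_pop = ft$n, n_exposed = ft$nExposed,
                   K_pop = ft$pPop$kHat, se_pop = ft$pPop$se,
                   K_exposed = ft$pExp$kHat, se_exposed = ft$pExp$se,
                   lambda = lam$lambda, se_lambda = lam$se,
                   lower95 = lam$lower95, p_one_sided = lam$pOneSided)
      }
      lambdaRows[[paste(outcome, relative, sep = "|")]] <- row
    }

    ## familial correlation: needs both traits' population prevalences
    if (!is.null(pairFits$f1) && !is.null(pairFits$d1)) {
      pA <- liabilityParams(pairFits$f1$pPop$kHat)
      pB <- liabilityParams(pairFits$d1$pPop$kHat)
      comp <- data.frame(
        degree = c("first", "first", "second", "second"),
        direction = c("AgivenB", "BgivenA", "AgivenB", "BgivenA"),
        kObs = c(pairFits$f1$pExp$kHat, pairFits$d1$pExp$kHat,
                 if (is.null(pairFits$f2)) NA else pairFits$f2$pExp$kHat,
                 if (is.null(pairFits$d2)) NA else pairFits$d2$pExp$kHat),
        se = c(pairFits$f1$pExp$se, pairFits$d1$pExp$se,
               if (is.null(pairFits$f2)) NA else pairFits$f2$pExp$se,
               if (is.null(pairFits$d2)) NA else pairFits$d2$pExp$se),
        stringsAsFactors = FALSE)
      est <- suppressWarnings(
        estimateFamilialCorrelation(comp, pA, pB, mode = mode))
      cw <- est$components
      compCols <- as.list(setNames(
        c(cw$rf, cw$seRf),
        c(paste0("rf_", cw$degree, "_", cw$direction),
          paste0("se_", cw$degree, "_", cw$direction))))
      rfRows[[paste(f, dz, sep = "|")]] <- data.frame(
        phenotype_A = f, phenotype_B = dz, mode = mode, rf = est$rf,
        se = est$se, lower95 = est$lower95, p_one_sided = est$pOneSided,
        compCols, stringsAsFactors = FALSE)
    } else {
      rfRows[[paste(f, dz, sep = "|")]] <- data.frame(
        phenotype_A = f, phenotype_B = dz, mode = mode, rf = NA_real_,
        se = NA_real_, lower95 = NA_real_, p_one_sided = NA_real_)
    }
  }

  lambdaTab <- do.call(rbind, c(lambdaRows, make.row.names = FALSE))
  rfList <- rfRows
  allCols <- unique(unlist(lapply(rfList, names)))
  rfList <- lapply(rfList, function(r) {
    for (cc in setdiff(allCols, names(r))) r[[cc]] <- NA_real_
    r[allCols]
  })
  rfTab <- do.call(rbind, c(rfList, make.row.names = FALSE))

  out <- assembleResults(lambdaTab, rfTab, q = q, family = bhFamily)
  out$mode <- mode
  out$modelLog <- do.call(rbind, c(unname(log), make.row.names = FALSE))
  out
}

#' Run a study from a configuration file
#'
#' Reads a YAML configuration naming the input files and analysis options,
#' runs [runCoaggregationStudy()] and writes the result tables and a run
#' manifest. Configuration keys: \code{pedigree} (PED file),
#' \code{phenotypes} (assessment TSV), \code{waves} (ordered wave labels),
#' \code{focal}, \code{diseases}, optional \code{composites} (name ->
#' component list), optional \code{exclusions} (phenotype -> excluding
#' phenotypes), optional \code{q}, \code{mode}, \code{aap_mode},
#' \code{output_dir}.
#'
#' Output files: \code{lambda.tsv}, \code{rf.tsv}, \code{tests.tsv} and
#' \code{manifest.json} (config hash, row counts, per-model sample sizes).
#' Rerunning with an unchanged configuration reproduces the files exactly.
#'
#' @param configPath path to the YAML configuration.
#' @param outputDir overrides the configuration's \code{output_dir}.
#' @return the [runCoaggregationStudy()] result, invisibly.
#' @export
runStudy <- function(configPath, outputDir = NULL) {
  if (!file.exists(configPath)) stop("config file not found: ", configPath)
  cfg <- yaml::read_yaml(configPath)
  for (keyReq in c("pedigree", "phenotypes", "focal", "diseases"))
    if (is.null(cfg[[keyReq]])) stop("config misses required key '", keyReq, "'")
  base <- dirname(normalizePath(configPath))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  pedPath <- resolve(cfg$pedigree)
  phenPath <- resolve(cfg$phenotypes)
  if (!file.exists(pedPath)) stop("pedigree file not found: ", pedPath)
  if (!file.exists(phenPath)) stop("phenotype file not found: ", phenPath)

  ped <- readPed(pedPath)
  records <- readAssessments(phenPath)
  panel <- buildPhenotypePanel(records,
                               waves = unlist(cfg$waves %||% NULL))
  for (nm in names(cfg$composites %||% list()))
    panel <- addCompositePhenotype(panel, nm, unlist(cfg$composites[[nm]]))
  if (!is.null(cfg$exclusions))
    panel <- applyExclusions(panel, lapply(cfg$exclusions, unlist))

  res <- runCoaggregationStudy(
    ped, panel,
    focal = unlist(cfg$focal), diseases = unlist(cfg$diseases),
    q = cfg$q %||% 0.05,
    mode = cfg$mode %||% "exact",
    aapMode = cfg$aap_mode %||% "observed")

  outDir <- outputDir %||% cfg$output_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, f)
    write.table(tab, file.path(outDir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wr(res$lambda, "lambda.tsv")
  wr(res$rf, "rf.tsv")
  wr(res$tests, "tests.tsv")
  manifest <- list(
    config_md5 = unname(tools::md5sum(configPath)),
    n_tests = res$nTests,
    n_lambda_rows = nrow(res$lambda),
    n_rf_rows = nrow(res$rf),
    q = res$q,
    mode = res$mode,
    models = res$modelLog)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
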