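test_that("pedigree templates produce the declared structures", {
  # 10 trio families (no grandchildren: no married-in spouses either)
  cfgTrio <- simulationConfig(nFamilies = 10,
                              template = list(nChildren = 1,
                                              grandchildrenPerChild = 0))
  pedT <- simulatePedigrees(cfgTrio)
  expect_equal(length(pedT), 30L)
  expect_equal(length(unique(familyIds(pedT))), 10L)

  # default three-generation template: second-degree pairs exist
  ped <- simulatePedigrees(simulationConfig(nFamilies = 2))
  expect_equal(relationshipDegree(ped, "F000001_GF", "F000001_G1_1")$degree,
               "second")
  expect_equal(relationshipDegree(ped, "F000001_C2", "F000001_G1_1")$degree,
               "second")
  expect_equal(relationshipDegree(ped, "F000001_G1_1", "F000001_G2_1")$degree,
               "other")
  expect_error(simulatePedigrees(simulationConfig(
    nFamilies = 1, template = list(nChildren = 0, grandchildrenPerChild = 0))),
    "at least one child")
})

test_that("relationship matrices match path-counting on a family of eight", {
  cfg <- simulationConfig(nFamilies = 1,
                          template = list(nChildren = 2,
                                          grandchildrenPerChild = 1))
  ped <- simulatePedigrees(cfg)
  expect_equal(length(ped), 8L)
  A <- relationshipMatrix(ped)[[1]]
  expect_true(all(diag(A) == 1))
  df <- individuals(ped)
  for (i in rownames(A)) for (j in colnames(A)) {
    if (i == j) next
    expect_equal(A[i, j], 2 * oracleKinship(df, i, j), tolerance = 1e-12,
                 label = paste("A", i, j))
  }
  # canonical entries
  expect_equal(A["F000001_GF", "F000001_C1"], 0.5)
  expect_equal(A["F000001_GF", "F000001_G1_1"], 0.25)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(nFamilies = 50, seed = 123)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(a$records, b$records)
  expect_identical(lifetimeStatus(a$panel), lifetimeStatus(b$panel))
  c <- simulateStudy(simulationConfig(nFamilies = 50, seed = 124))
  expect_false(identical(a$records, c$records))
})

test_that("invalid covariance configurations are rejected", {
  expect_error(simulationConfig(residualCrossCorr = 0.9),
               "positive semidefinite")
  expect_error(simulationConfig(rfTargets = 0.9, familialShares = 0.3),
               "positive semidefinite")
  expect_error(simulationConfig(phenotypes = data.frame(name = "a", K = 1.2)))
})

test_that("lifetime prevalence is calibrated to the target", {
  cfg <- simulationConfig(nFamilies = 10000, seed = 31)
  set.seed(cfg$seed)
  ped <- simulatePedigrees(cfg)
  rec <- simulatePhenotypes(ped, cfg, returnLiability = TRUE)
  L <- attr(rec, "liability")
  fam <- familyIds(ped)
  for (t in 1:2) {
    K <- cfg$phenotypes$K[t]
    case <- as.numeric(L[, t] > qnorm(1 - K))
    famMeans <- tapply(case, fam[rownames(L)], mean)
    se <- sd(famMeans) / sqrt(length(famMeans))   # family-clustered MC SE
    expect_lt(abs(mean(case) - K), 3 * se + 1e-9)
  }
})

test_that("latent liabilities carry the configured covariance structure", {
  cfg <- simulationConfig(nFamilies = 6000, seed = 17)
  set.seed(cfg$seed)
  ped <- simulatePedigrees(cfg)
  rec <- simulatePhenotypes(ped, cfg, returnLiability = TRUE)
  L <- attr(rec, "liability")
  ind <- individuals(ped)

  # within-person: total cross-trait correlation = R[1,2] (= rf target here)
  expect_lt(abs(cor(L[, 1], L[, 2]) - cfg$R[1, 2]), 0.04)
  expect_lt(abs(var(L[, 1]) - 1), 0.04)

  # parent-child (a_R = 0.5): same-trait cov = 0.5 * share,
  # cross-trait cov = 0.5 * rf
  child <- which(!is.na(ind$father))
  pc <- cbind(match(ind$father[child], ind$iid), child)
  expect_lt(abs(cov(L[pc[, 1], 1], L[pc[, 2], 1]) - 0.5 * cfg$C[1, 1]), 0.04)
  expect_lt(abs(cov(L[pc[, 1], 1], L[pc[, 2], 2]) - 0.5 * cfg$C[1, 2]), 0.04)

  # independence when the familial covariance is zero
  cfg0 <- simulationConfig(nFamilies = 6000, rfTargets = 0, seed = 18)
  set.seed(cfg0$seed)
  ped0 <- simulatePedigrees(cfg0)
  L0 <- attr(simulatePhenotypes(ped0, cfg0, returnLiability = TRUE),
             "liability")
  expect_lt(abs(cov(L0[pc[, 1], 1], L0[pc[, 2], 2])), 0.04)
})

test_that("binary statuses of first-degree pairs show the implied tetrachoric correlation", {
  # single trait, familial share 0.6 -> first-degree liability correlation
  # 0.30; estimated from simulated parent-child case statuses
  cfg <- simulationConfig(
    nFamilies = 6000,
    phenotypes = data.frame(name = "tr", K = 0.2),
    rfTargets = NULL, familialShares = 0.6, seed = 41)
  set.seed(cfg$seed)
  ped <- simulatePedigrees(cfg)
  rec <- simulatePhenotypes(ped, cfg, returnLiability = TRUE)
  L <- attr(rec, "liability")
  case <- L[, 1] > qnorm(1 - 0.2)
  ind <- individuals(ped)
  child <- which(!is.na(ind$father))
  pc <- cbind(match(ind$father[child], ind$iid), child)
  p11 <- mean(case[pc[, 1]] & case[pc[, 2]])
  rho <- oracleTetrachoric(p11, mean(case[pc[, 1]]), mean(case[pc[, 2]]))
  expect_lt(abs(rho - 0.30), 0.05)
})

test_that("single designated-relative conditioning recovers the generative rf", {
  # generator/solver consistency at the pair level: prevalence of trait A
  # in children given the father is a trait-B case, inverted with a_R=0.5
  cfg <- simulationConfig(nFamilies = 20000, seed = 53)
  set.seed(cfg$seed)
  ped <- simulatePedigrees(cfg)
  rec <- simulatePhenotypes(ped, cfg, returnLiability = TRUE)
  L <- attr(rec, "liability")
  KA <- cfg$phenotypes$K[1]; KB <- cfg$phenotypes$K[2]
  caseA <- L[, 1] > qnorm(1 - KA)
  caseB <- L[, 2] > qnorm(1 - KB)
  ind <- individuals(ped)
  child <- which(!is.na(ind$father))
  fa <- match(ind$father[child], ind$iid)
  kObs <- mean(caseA[child][caseB[fa]])
  rf <- solveRf(kObs, liabilityParams(KA), liabilityParams(KB), 0.5)
  expect_lt(abs(rf - 0.30), 0.04)
})

test_that("wave records respect onset and missingness semantics", {
  cfg <- simulationConfig(nFamilies = 400, seed = 77)
  sim <- simulateStudy(cfg)
  rec <- sim$records
  # a case never reverts to control after onset
  byIP <- split(rec, paste(rec$iid, rec$phenotype))
  waves <- cfg$waves$name
  bad <- vapply(byIP, function(d) {
    s <- d$status[match(waves, d$wave)]
    s <- s[!is.na(s)]
    any(diff(s) < 0)
  }, logical(1))
  expect_false(any(bad))
  # ages increase with wave offsets
  one <- byIP[[which(vapply(byIP, nrow, 1L) == 3)[1]]]
  o <- match(one$wave, waves)
  expect_true(all(diff(one$age[order(o)]) > 0))
  # missingness close to configured per-wave rates
  tabAll <- length(unique(rec$iid))
  for (w in seq_along(waves)) {
    obs <- sum(rec$wave == waves[w] & rec$phenotype == "trait_a")
    expect_equal(obs / length(ped_ids <- unique(rec$iid)),
                 1 - cfg$waves$missing[w], tolerance = 0.05)
  }
})
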