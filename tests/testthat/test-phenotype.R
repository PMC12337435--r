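test_that("lifetime aggregation follows the any-case rule", {
  expect_equal(aggregateLifetime(c(1L, 0L, NA)), 1L)
  expect_equal(aggregateLifetime(c(0L, NA, 0L)), 0L)
  expect_equal(aggregateLifetime(c(NA, NA)), NA_integer_)
  expect_equal(aggregateLifetime(integer(0)), NA_integer_)
  # order invariance
  set.seed(5)
  for (k in 1:25) {
    v <- sample(c(0L, 1L, NA), sample(1:6, 1), replace = TRUE)
    expect_identical(aggregateLifetime(v), aggregateLifetime(sample(v)))
  }
})

test_that("composite phenotypes keep controls with incomplete component data", {
  expect_equal(compositeStatus(c(0L, NA, 1L)), 1L)
  expect_equal(compositeStatus(c(0L, NA)), 0L)
  expect_equal(compositeStatus(c(NA, NA)), NA_integer_)
  # idempotent and commutative
  expect_equal(compositeStatus(c(1L, 1L)), 1L)
  expect_equal(compositeStatus(c(NA, 0L)), compositeStatus(c(0L, NA)))
})

test_that("analysis age: first case age for cases, last data age for controls", {
  expect_equal(assignAnalysisAge(c(0L, 1L, 1L), c(40, 44, 48)), 44)
  expect_equal(assignAnalysisAge(c(0L, 0L), c(40, 44)), 44)
  expect_true(is.na(assignAnalysisAge(c(NA, NA), c(40, 44))))
  expect_error(assignAnalysisAge(c(0L, 1L), c(40, NA)), "age missing")
})

test_that("panel building derives status and age per (individual, phenotype)", {
  rec <- data.frame(
    iid = c("a", "a", "a", "b", "b", "c"),
    phenotype = "dz",
    wave = c("w1", "w2", "w3", "w1", "w3", "w2"),
    status = c(0L, 1L, 1L, 0L, 0L, NA),
    age = c(40, 44, 48, 30, 36, 50))
  panel <- buildPhenotypePanel(rec, waves = c("w1", "w2", "w3"))
  S <- lifetimeStatus(panel); A <- analysisAge(panel)
  expect_equal(S["a", "dz"], 1L); expect_equal(A["a", "dz"], 44)
  expect_equal(S["b", "dz"], 0L); expect_equal(A["b", "dz"], 36)
  expect_true(is.na(S["c", "dz"])); expect_true(is.na(A["c", "dz"]))

  # wave order comes from the declared list, not the label sort order
  rec2 <- data.frame(iid = "a", phenotype = "dz", wave = c("late", "early"),
                     status = c(0L, 1L), age = c(50, 40))
  p2 <- buildPhenotypePanel(rec2, waves = c("early", "late"))
  expect_equal(analysisAge(p2)["a", "dz"], 40)

  expect_error(buildPhenotypePanel(rbind(rec, rec[1, ])), "duplicate")
  bad <- rec; bad$age[1] <- 150
  expect_error(buildPhenotypePanel(bad), "implausible")
})

test_that("analysis age always lies within the observed assessment ages", {
  set.seed(8)
  n <- 80
  rec <- expand.grid(iid = paste0("i", 1:n), wave = c("w1", "w2", "w3"),
                     stringsAsFactors = FALSE)
  rec$phenotype <- "dz"
  rec$status <- sample(c(0L, 1L, NA), nrow(rec), TRUE)
  rec$age <- round(runif(nrow(rec), 20, 80), 1)
  panel <- buildPhenotypePanel(rec, waves = c("w1", "w2", "w3"))
  A <- analysisAge(panel)
  rng <- tapply(rec$age, rec$iid, range)
  for (i in rownames(A)) {
    if (is.na(A[i, "dz"])) next
    expect_gte(A[i, "dz"], rng[[i]][1]); expect_lte(A[i, "dz"], rng[[i]][2])
  }
})

test_that("composite panel column follows the any-case rule with earliest case age", {
  rec <- data.frame(
    iid = rep(c("a", "b", "c"), each = 2),
    phenotype = rep(c("p1", "p2"), 3),
    wave = "w1",
    status = c(1L, 1L, 0L, NA, NA, NA),
    age = c(50, 42, 33, NA, NA, NA))
  panel <- buildPhenotypePanel(rec, waves = "w1")
  p2 <- addCompositePhenotype(panel, "comp", c("p1", "p2"))
  S <- lifetimeStatus(p2); A <- analysisAge(p2)
  expect_equal(S["a", "comp"], 1L); expect_equal(A["a", "comp"], 42) # earliest case
  expect_equal(S["b", "comp"], 0L); expect_equal(A["b", "comp"], 33)
  expect_true(is.na(S["c", "comp"]))
  expect_error(addCompositePhenotype(panel, "x", "nope"), "unknown")
})

test_that("exclusions blank both case and control pools of the target only", {
  rec <- expand.grid(iid = paste0("i", 1:60), phenotype = c("FM", "RA"),
                     stringsAsFactors = FALSE)
  set.seed(13)
  rec$wave <- "w1"
  rec$status <- sample(c(0L, 1L), nrow(rec), TRUE, prob = c(.7, .3))
  rec$age <- 40
  panel <- buildPhenotypePanel(rec, waves = "w1")
  S0 <- lifetimeStatus(panel)
  out <- applyExclusions(panel, list(FM = "RA"))
  S1 <- lifetimeStatus(out)
  raCase <- !is.na(S0[, "RA"]) & S0[, "RA"] == 1L
  expect_true(all(is.na(S1[raCase, "FM"])))
  expect_identical(S1[!raCase, "FM"], S0[!raCase, "FM"])
  expect_identical(S1[, "RA"], S0[, "RA"])       # other phenotype untouched
  # post-exclusion case count = pre-count minus overlap
  expect_equal(sum(S1[, "FM"] == 1L, na.rm = TRUE),
               sum(S0[, "FM"] == 1L, na.rm = TRUE) -
                 sum(S0[, "FM"] == 1L & raCase, na.rm = TRUE))
  # identity and error cases
  expect_identical(lifetimeStatus(applyExclusions(panel, list())), S0)
  expect_error(applyExclusions(panel, list(FM = "nope")), "unknown")
})

test_that("panel writer emits one row per individual-phenotype", {
  rec <- data.frame(iid = c("a", "b"), phenotype = "dz", wave = "w1",
                    status = c(1L, 0L), age = c(44, 36))
  panel <- buildPhenotypePanel(rec, waves = "w1")
  f <- tempfile(fileext = ".tsv")
  writePhenotypePanel(panel, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$lifetime_status[tab$iid == "a"], 1L)
  unlink(f)
})

test_that("cohort summary equals exhaustive recomputation on a fixture", {
  cfg <- simulationConfig(nFamilies = 120, seed = 99)
  sim <- simulateStudy(cfg)
  sm <- summarizeCohort(sim$ped, sim$panel, records = sim$records)
  S <- lifetimeStatus(sim$panel)
  participants <- rownames(S)[rowSums(!is.na(S)) > 0]
  expect_equal(sm$n, length(participants))
  # sex split
  ind <- individuals(sim$ped)
  expect_equal(unname(sm$sex$counts["male"]),
               sum(ind$sex[match(participants, ind$iid)] == "male"))
  # mean age at first assessment
  firstAge <- tapply(sim$records$age, sim$records$iid, min)
  expect_equal(sm$age$mean, mean(firstAge[participants]), tolerance = 1e-12)
  # per-phenotype case percentages
  expect_equal(sm$phenotypes$pctCases,
               100 * colSums(S[participants, ] == 1, na.rm = TRUE) /
                 colSums(!is.na(S[participants, ])),
               ignore_attr = TRUE)
  # median first-degree relative counts among those with >= 1, against a
  # within-family brute force over pairs
  hasData <- stats::setNames(rowSums(!is.na(S)) > 0, rownames(S))
  fam <- familyIds(sim$ped)
  cnt <- stats::setNames(integer(length(participants)), participants)
  for (i in participants) {
    others <- names(fam)[fam == fam[i] & names(fam) != i]
    for (j in others)
      if (isTRUE(hasData[j]) &&
          relationshipDegree(sim$ped, i, j)$degree == "first")
        cnt[i] <- cnt[i] + 1L
  }
  expect_equal(100 * mean(cnt > 0), sm$relatives$first$pctWithRelative)
  expect_equal(sm$relatives$first$medianCount, median(cnt[cnt > 0]))
})
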