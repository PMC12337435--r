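# Independent oracles and shared fixtures.

# Path-counting kinship for non-inbred pedigrees: phi(i, j) = sum over
# common ancestors A and over pairs of ancestor paths meeting only at A of
# (1/2)^(len_i + len_j + 1). Independent of the package's recursion.
oracleAncestorPaths <- function(parents, x) {
  out <- list(x)
  for (p in parents[[x]]) {
    if (is.na(p)) next
    for (s in oracleAncestorPaths(parents, p)) out <- c(out, list(c(x, s)))
  }
  out
}

oracleKinship <- function(df, i, j) {
  parents <- stats::setNames(
    lapply(seq_len(nrow(df)), function(r)
      c(as.character(df$father[r]), as.character(df$mother[r]))),
    df$iid)
  pi <- oracleAncestorPaths(parents, i)
  pj <- oracleAncestorPaths(parents, j)
  tot <- 0
  for (a in pi) for (b in pj) {
    A <- a[length(a)]
    if (A != b[length(b)]) next
    if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
    tot <- tot + 0.5^(length(a) - 1 + length(b) - 1 + 1)
  }
  tot
}

# Bivariate-normal upper tail by adaptive quadrature (oracle for the exact
# liability mode, independent of mvtnorm).
oracleBvnTail <- function(a, b, rho) {
  if (abs(rho) > 0.999) stop("oracle needs |rho| < 0.999")
  stats::integrate(function(x)
    stats::dnorm(x) *
      stats::pnorm((b - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE),
    lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# Tetrachoric correlation of a 2x2 concordance table by inverting the
# bivariate-normal tail at the observed margins.
oracleTetrachoric <- function(p11, p1., p.1) {
  t1 <- stats::qnorm(1 - p1.); t2 <- stats::qnorm(1 - p.1)
  stats::uniroot(function(r) oracleBvnTail(t1, t2, r) - p11,
                 c(-0.99, 0.99), tol = 1e-9)$root
}

# Hand-built three-generation fixture with full sibs, half sibs,
# avuncular, grandparent and cousin pairs (18 real members, non-inbred).
fixtureRecords <- function() {
  data.frame(
    iid    = c("gf", "gm", "m2", "c1", "c2", "c3", "s1", "s2", "s3",
               "x1", "x2", "y1", "y2", "z1", "u1", "u2", "v1", "w1"),
    father = c(NA, NA, NA, "gf", "gf", "gf", NA, NA, NA,
               "s1", "s1", "c2", "c2", "c3", NA, "u1", "x1", "y1"),
    mother = c(NA, NA, NA, "gm", "gm", "m2", NA, NA, NA,
               "c1", "c1", "s2", "s2", "s3", NA, NA, "u2", "v1"),
    sex    = c(1, 2, 2, 2, 1, 1, 1, 2, 2,
               1, 2, 1, 2, 1, 1, 2, 2, 1),
    stringsAsFactors = FALSE)
}

fixturePedigree <- function() buildPedigree(fixtureRecords())

# single-wave assessment records giving every fixture member a status
fixturePanel <- function(statusMap) {
  ids <- names(statusMap)
  rec <- data.frame(iid = ids, phenotype = "dz", wave = "w1",
                    status = unlist(statusMap, use.names = FALSE),
                    age = seq(30, by = 1, length.out = length(ids)))
  rec <- rec[!is.na(rec$status), , drop = FALSE]   # missing = absent row
  buildPhenotypePanel(rec, waves = "w1")
}

# brute-force relative counting via per-pair degree queries
bruteRelativeStats <- function(ped, panel, phenotype, degree) {
  ids <- individuals(ped)$iid
  S <- lifetimeStatus(panel)
  st <- S[match(ids, rownames(S)), phenotype]
  count <- exposed <- stats::setNames(integer(length(ids)), ids)
  for (i in ids) for (j in ids) {
    if (i == j) next
    d <- suppressWarnings(relationshipDegree(ped, i, j))
    if (d$degree != degree) next
    sj <- st[j]
    if (!is.na(sj)) count[i] <- count[i] + 1L
    if (!is.na(sj) && sj == 1L) exposed[i] <- 1L
  }
  list(count = count, exposed = exposed)
}

# small simulated clustered dataset for prevalence-model tests
simClusteredData <- function(n = 600, nFam = 150, seed = 3) {
  set.seed(seed)
  d <- data.frame(y = stats::rbinom(n, 1, 0.2),
                  exposed = stats::rbinom(n, 1, 0.3),
                  age = stats::runif(n, 20, 70),
                  sex = stats::rbinom(n, 1, 0.5),
                  nrel = stats::rpois(n, 2),
                  family = rep(seq_len(nFam), length.out = n))
  d$age2 <- d$age^2
  d
}
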