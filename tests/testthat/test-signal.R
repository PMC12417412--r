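test_that("buildTables matches a brute-force recount on synthetic data", {
  cfg <- syntheticConfig(nTargetReports = 300, nBackgroundReports = 900,
                         seed = 13)
  vd <- generateDatabase(cfg)
  ids <- selectTargetReports(vd, cfg@targetVaccineName)
  for (unit in c("report", "event")) {
    got <- buildTables(vd, ids, unit = unit)
    want <- bruteTables(vd, ids, unit = unit)
    got <- got[order(got$pt_name), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[order(want$pt_name), ], ignore_attr = TRUE)
  }
  # total a equals the number of distinct (target report, PT) pairs
  got <- buildTables(vd, ids)
  expect_identical(sum(got$a),
                   sum(symptoms(vd)$report_id %in% ids))
  expect_error(buildTables(vd, character()), "empty target")
})

test_that("minimal tables count as expected", {
  vd <- mkTinyVd(1, 1, list("1" = "EVENT X"))
  tab <- buildTables(vd, "T001")
  expect_identical(unlist(tab[tab$pt_name == "EVENT X", c("a", "b", "c", "d")],
                          use.names = FALSE), c(1L, 0L, 0L, 1L))
})

test_that("ROR point estimate and log-normal interval match hand values", {
  expect_equal(rorStat(c(10, 10, 10, 10))$ror, 1.0)
  r <- rorStat(c(25, 75, 100, 900))
  expect_equal(r$ror, 3.0, tolerance = 1e-12)
  expect_equal(r$ror_lo95, 1.8240302, tolerance = 1e-6)
  expect_equal(r$ror_hi95, 4.9341288, tolerance = 1e-6)
  # continuity: zero cell handled on (a+0.5, ...)
  rc <- rorStat(c(0, 10, 5, 100))
  expect_equal(rc$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  # all-zero margin is undefined
  expect_true(is.na(rorStat(c(0, 0, 5, 100))$ror))
})

test_that("PRR and Pearson chi-square match hand values and chisq.test", {
  p0 <- prrStat(c(10, 10, 10, 10))
  expect_equal(p0$prr, 1.0)
  expect_equal(p0$chi2, 0.0)
  p <- prrStat(c(25, 75, 100, 900))
  expect_equal(p$prr, 2.5, tolerance = 1e-12)
  expect_equal(p$chi2, 20.3076923, tolerance = 1e-6)
  expect_equal(p$p_raw, pchisq(p$chi2, 1, lower.tail = FALSE))
  set.seed(4)
  for (i in 1:25) {
    t <- rpois(4, lambda = c(30, 200, 60, 800)) + 1
    expect_equal(prrStat(t)$chi2,
                 unname(suppressWarnings(chisq.test(matrix(t, 2, byrow = TRUE),
                                   correct = FALSE))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("sign(ROR - PRR) = sign(ROR - 1) on all-positive tables", {
  set.seed(6)
  for (i in 1:200) {
    t <- sample.int(500, 4, replace = TRUE)
    r <- rorStat(t)$ror
    p <- prrStat(t)$prr
    expect_equal(sign(round(r - p, 12)), sign(round(r - 1, 12)))
  }
})

test_that("BCPNN: independence limit, large-count limit, shrinkage at a=0", {
  n1 <- 1e4; N <- 1e6; a <- n1 * n1 / N
  ind <- bcpnnIc(c(a, n1 - a, n1 - a, N - 2 * n1 + a))
  expect_lt(abs(ind$ic), 0.01)
  big <- bcpnnIc(c(25e3, 75e3, 100e3, 900e3))
  expect_lt(abs(big$ic - log2(2.2)), 0.01)
  expect_lt(bcpnnIc(c(0, 100, 50, 10000))$ic, 0)
  ic <- bcpnnIc(c(25, 75, 100, 900))
  expect_lt(ic$ic_minus_2sd, ic$ic)
})

test_that("BCPNN closed form agrees with Beta-mean quadrature to 1e-4", {
  pri <- bcpnnPriors()
  quadIc <- function(a, b, c, d) {
    N <- a + b + c + d
    g <- pri@gamma11 * (N + pri@alpha) * (N + pri@beta) /
      ((a + b + pri@alpha1) * (a + c + pri@beta1))
    m11 <- integrate(function(x) x * dbeta(x, a + pri@gamma11,
                                           N - a + g - pri@gamma11),
                     0, 1, rel.tol = 1e-10)$value
    m1 <- integrate(function(x) x * dbeta(x, a + b + pri@alpha1,
                                          N - (a + b) + pri@alpha -
                                            pri@alpha1),
                    0, 1, rel.tol = 1e-10)$value
    m2 <- integrate(function(x) x * dbeta(x, a + c + pri@beta1,
                                          N - (a + c) + pri@beta -
                                            pri@beta1),
                    0, 1, rel.tol = 1e-10)$value
    log2(m11 / (m1 * m2))
  }
  for (t in list(c(25, 75, 100, 900), c(0, 10, 5, 100), c(3, 40, 2, 800),
                 c(120, 30, 40, 60))) {
    expect_equal(bcpnnIc(t)$ic, quadIc(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-4)
  }
})

test_that("MGPS fit: errors, null data, and determinism", {
  expect_error(mgpsFit(data.frame(a = 1, b = 1, c = 1, d = 1)),
               "at least 2")
  En <- seq(1000, 5000, length.out = 200)
  h <- mgpsFit(data.frame(a = round(En), E = En))
  expect_true(h@converged)
  priorMean <- h@pMix * h@alpha1 / h@beta1 +
    (1 - h@pMix) * h@alpha2 / h@beta2
  expect_gt(priorMean, 0.8)
  expect_lt(priorMean, 1.2)
  h2 <- mgpsFit(data.frame(a = round(En), E = En))
  expect_identical(h@loglik, h2@loglik)  # fixed start => deterministic
})

test_that("EBGM shrinks sparse cells and is consistent at large counts", {
  h <- new("MgpsHyperparams", alpha1 = 0.2, beta1 = 0.1, alpha2 = 2,
           beta2 = 4, pMix = 1 / 3, converged = TRUE, loglik = 0)
  sparse <- ebgmStat(data.frame(a = 1, E = 0.25), h)   # a/E = 4, a = 1
  expect_lt(sparse$ebgm, 4)
  big <- ebgmStat(data.frame(a = 10000, E = 2500), h)  # a/E = 4, a large
  expect_gt(big$ebgm, 3.8)
  expect_lt(big$ebgm, 4.2)
  expect_lt(big$ebgm05, big$ebgm)
})

test_that("EBGM05 quantile agrees with a numeric-integration oracle", {
  h <- new("MgpsHyperparams", alpha1 = 0.5, beta1 = 0.7, alpha2 = 3,
           beta2 = 2.5, pMix = 0.4, converged = TRUE, loglik = 0)
  quadQuantile <- function(a, E) {
    # posterior weight via the marginal negative binomials
    l1 <- log(h@pMix) + dnbinom(a, size = h@alpha1,
                                prob = h@beta1 / (h@beta1 + E), log = TRUE)
    l2 <- log1p(-h@pMix) + dnbinom(a, size = h@alpha2,
                                   prob = h@beta2 / (h@beta2 + E),
                                   log = TRUE)
    Qn <- 1 / (1 + exp(l2 - l1))
    dens <- function(x)
      Qn * dgamma(x, h@alpha1 + a, rate = h@beta1 + E) +
      (1 - Qn) * dgamma(x, h@alpha2 + a, rate = h@beta2 + E)
    cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-10,
                                 abs.tol = 1e-12)$value
    up <- qgamma(0.9999, shape = h@alpha2 + a, rate = h@beta2 + E) +
      qgamma(0.9999, shape = h@alpha1 + a, rate = h@beta1 + E)
    uniroot(function(q) cdf(q) - 0.05, lower = 1e-300, upper = up,
            tol = 1e-13)$root
  }
  for (cell in list(c(a = 3, E = 1.2), c(a = 0, E = 2), c(a = 40, E = 10))) {
    got <- ebgmStat(data.frame(a = cell[["a"]], E = cell[["E"]]), h)$ebgm05
    expect_equal(got, quadQuantile(cell[["a"]], cell[["E"]]),
                 tolerance = 1e-4)
    # and the defining property of the quantile
    cdfAt <- function(q) {
      l1 <- log(h@pMix) + dnbinom(cell[["a"]], size = h@alpha1,
                                  prob = h@beta1 / (h@beta1 + cell[["E"]]),
                                  log = TRUE)
      l2 <- log1p(-h@pMix) + dnbinom(cell[["a"]], size = h@alpha2,
                                     prob = h@beta2 / (h@beta2 + cell[["E"]]),
                                     log = TRUE)
      Qn <- 1 / (1 + exp(l2 - l1))
      Qn * pgamma(q, h@alpha1 + cell[["a"]], rate = h@beta1 + cell[["E"]]) +
        (1 - Qn) * pgamma(q, h@alpha2 + cell[["a"]],
                          rate = h@beta2 + cell[["E"]])
    }
    expect_lt(abs(cdfAt(got) - 0.05), 1e-6)
  }
})

test_that("Bayesian estimators shrink toward the null for sparse cells", {
  # null-centred prior (mixture mean exactly 1: 1/3 * 2 + 2/3 * 0.5)
  h <- new("MgpsHyperparams", alpha1 = 0.2, beta1 = 0.1, alpha2 = 2,
           beta2 = 4, pMix = 1 / 3, converged = TRUE, loglik = 0)
  for (a in 1:3) {
    E <- a / 4  # observed/expected = 4 at a sparse count
    eb <- ebgmStat(data.frame(a = a, E = E), h)
    expect_lt(eb$ebgm, 4)
    expect_lte(abs(log(eb$ebgm)), abs(log(4)))
  }
  # IC of a sparse disproportionate table sits between 0 and log2(O/E)
  for (t in list(c(2, 98, 50, 9850), c(3, 97, 60, 11840))) {
    oe <- t[1] * sum(t) / ((t[1] + t[2]) * (t[1] + t[3]))
    ic <- bcpnnIc(t)$ic
    expect_gt(oe, 1)
    expect_gt(ic, 0)
    expect_lt(ic, log2(oe))
  }
})

test_that("BH adjustment matches hand step-up and is monotone/idempotent", {
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand example with distinct adjusted values: p * n / rank, cummin
  expect_equal(bhAdjust(c(0.001, 0.02, 0.9)),
               c(0.003, 0.03, 0.9))
  set.seed(12)
  for (i in 1:20) {
    p <- runif(50)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # monotone in p
  }
  # idempotent on tie-flattened step-up output (general idempotence does
  # not hold for the BH map)
  expect_equal(bhAdjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("classification applies the threshold quartet and the FDR gate", {
  m <- data.frame(a = 2, ror_lo95 = 50, prr = 50, chi2 = 1e4,
                  ic_minus_2sd = 5, ebgm05 = 50, p_adjust = 1e-10)
  expect_false(classifySignals(m)$positive_overall)  # minimum-count gate
  null <- data.frame(a = 1000, ror_lo95 = 0.95, prr = 1, chi2 = 0,
                     ic_minus_2sd = -0.1, ebgm05 = 1, p_adjust = 1)
  cls <- classifySignals(null)
  expect_false(any(unlist(cls[grep("positive", names(cls))])))
  pos <- data.frame(a = 10, ror_lo95 = 1.5, prr = 3, chi2 = 25,
                    ic_minus_2sd = 0.2, ebgm05 = 2.5, p_adjust = 0.01)
  expect_true(classifySignals(pos)$positive_overall)
  # any-of rule
  one <- data.frame(a = 10, ror_lo95 = 1.5, prr = 1, chi2 = 25,
                    ic_minus_2sd = -1, ebgm05 = 1, p_adjust = 0.01)
  expect_false(classifySignals(one)$positive_overall)
  expect_true(classifySignals(one,
                              signalThresholds(rule = "any"))$positive_overall)
})

test_that("SOC aggregation is additive and matches a regroup oracle", {
  cfg <- syntheticConfig(nTargetReports = 400, nBackgroundReports = 1600,
                         seed = 23)
  vd <- generateDatabase(cfg)
  ids <- selectTargetReports(vd, cfg@targetVaccineName)
  m <- setNames(cfg@ptCatalog$soc_name, cfg@ptCatalog$pt_name)
  soc <- aggregateSoc(vd, ids, m)
  # oracle: regroup the brute-force event-unit PT tables
  pt <- bruteTables(vd, ids, unit = "event")
  pt$soc <- unname(m[pt$pt_name])
  aSum <- tapply(pt$a, pt$soc, sum)
  expect_equal(setNames(soc$a, soc$soc_name)[names(aSum)],
               aSum, ignore_attr = TRUE)
  # one PT alone in its SOC carries identical statistics at event unit
  sig <- detectSignals(vd, ids, ptToSoc = m, unit = "event")
  solo <- names(which(table(m[unique(symptoms(vd)$pt_name)]) == 1))
  for (s in solo) {
    i <- match(s, soc$soc_name)
    j <- which(sig$soc_name == s)
    expect_equal(soc$ror[i], sig$ror[j], tolerance = 1e-12)
    expect_equal(soc$ebgm[i], sig$ebgm[j], tolerance = 1e-9)
    expect_equal(soc$ic[i], sig$ic[j], tolerance = 1e-12)
  }
})

test_that("detectSignals output respects the metric orderings", {
  cfg <- syntheticConfig(nTargetReports = 1000, nBackgroundReports = 10000,
                         seed = 19)
  vd <- generateDatabase(cfg)
  ids <- selectTargetReports(vd, cfg@targetVaccineName)
  s <- detectSignals(vd, ids,
                     ptToSoc = setNames(cfg@ptCatalog$soc_name,
                                        cfg@ptCatalog$pt_name))
  expect_true(all(s$ror_lo95 <= s$ror & s$ror <= s$ror_hi95))
  expect_true(all(s$ebgm05 < s$ebgm))
  expect_true(all(s$ic_minus_2sd < s$ic))
  expect_true(all(s$p_adjust >= s$p_raw))
  expect_true(all(s$soc_name %in% c(cfg@ptCatalog$soc_name, "UNCLASSIFIED")))
  expect_s4_class(attr(s, "mgps"), "MgpsHyperparams")
})
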