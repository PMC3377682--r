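test_that("prior sampling honours truncations and degenerate marginals", {
  set.seed(31)
  pr <- defaultPriors()
  d <- samplePrior(pr, 20000)
  expect_true(all(d[, "Td"] >= 350 & d[, "Td"] <= 750))
  expect_true(all(d[, "NW"] >= 1e2 & d[, "NW"] <= 1e5))
  expect_true(all(d[, "pSSR"] >= 0 & d[, "pSSR"] < 0.9 + 1e-12))
  # truncated-normal sample mean matches the closed form
  a <- (350 - 500) / 100
  b <- (750 - 500) / 100
  mTrue <- 500 + 100 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(d[, "Td"]) / sqrt(nrow(d))
  expect_lt(abs(mean(d[, "Td"]) - mTrue), 3 * se)
  # point-mass priors
  pp <- fixedPriors(divergenceModelParams(1000, 2000, 3000, 400, 1e-8))
  dd <- samplePrior(pp, 50)
  expect_true(all(dd[, "NW"] == 1000) && all(dd[, "Td"] == 400))
})

test_that("reference tables have the configured shape and are seed-deterministic", {
  sc <- syntheticScenario(32)
  set.seed(32)
  template <- bundleTemplate(generateControlLoci(sc))
  mk <- function() {
    set.seed(33)
    draws <- samplePrior(defaultPriors(), 40)
    simulateReferenceTable(draws, template, priors = defaultPriors())
  }
  t1 <- mk()
  t2 <- mk()
  expect_equal(nrow(t1@stats), 40)
  expect_false(anyNA(t1@stats))
  expect_identical(t1@stats, t2@stats)
  expect_identical(t1@params, t2@params)
})

test_that("regression adjustment vanishes when the observed vector is in the table", {
  set.seed(34)
  sc <- syntheticScenario(34)
  template <- bundleTemplate(generateControlLoci(sc))
  draws <- samplePrior(defaultPriors(), 120)
  tab <- simulateReferenceTable(draws, template,
                                priors = defaultPriors())
  obs <- tab@stats[7, ]
  post <- suppressWarnings(abcFit(obs, tab, tolerance = 1 / 120))
  expect_equal(nrow(post@adjusted), 1)
  expect_equal(unname(post@adjusted[1, ]), unname(tab@params[7, ]),
               tolerance = 1e-10)
})

test_that("parameters carrying no signal are not shifted by the regression", {
  set.seed(35)
  n <- 30000
  draws <- samplePrior(defaultPriors(), n)
  # statistics independent of every parameter: pure noise
  stats <- matrix(rnorm(n * 9), n,
                  dimnames = list(NULL, divergeScan:::.SUMMARY_STAT_NAMES))
  tab <- new("ReferenceTable", params = draws, stats = stats)
  post <- abcFit(rep(0, 9), tab, tolerance = 0.3,
                 priors = defaultPriors())
  priorSD <- sd(draws[, "Td"])
  shift <- abs(weighted.mean(post@adjusted[, "Td"], post@weights) -
                 mean(post@raw[, "Td"]))
  expect_lt(shift, 0.05 * priorSD)
})

test_that("Epanechnikov weighting zeroes the boundary particle", {
  set.seed(36)
  draws <- samplePrior(defaultPriors(), 1000)
  stats <- matrix(rnorm(9000), 1000,
                  dimnames = list(NULL, divergeScan:::.SUMMARY_STAT_NAMES))
  tab <- new("ReferenceTable", params = draws, stats = stats)
  post <- abcFit(rep(0, 9), tab, tolerance = 0.05)
  expect_equal(min(post@weights), 0)
  expect_equal(sum(post@weights), 1)
})

test_that("ABC recovers the analytic posterior of a conjugate normal toy", {
  # mu ~ N(0,1); observed statistic xbar ~ N(mu, 0.5^2)
  set.seed(37)
  n <- 1e5
  s <- 0.5
  mu <- rnorm(n)
  xbar <- rnorm(n, mu, s)
  tab <- new("ReferenceTable",
             params = matrix(mu, ncol = 1, dimnames = list(NULL, "mu")),
             stats = matrix(xbar, ncol = 1, dimnames = list(NULL, "xbar")))
  obs <- 0.7
  post <- abcFit(c(xbar = obs), tab, tolerance = 1e-2)
  postVar <- 1 / (1 + 1 / s^2)
  postMean <- obs * (1 / s^2) * postVar
  wm <- weighted.mean(post@adjusted[, 1], post@weights)
  wsd <- sqrt(weighted.mean((post@adjusted[, 1] - wm)^2, post@weights))
  expect_lt(abs(wm - postMean) / postMean, 0.05)
  expect_lt(abs(wsd - sqrt(postVar)) / sqrt(postVar), 0.05)
})

test_that("posterior predictive checks flag gross misfit and keep shape", {
  set.seed(38)
  sc <- syntheticScenario(38)
  bundle <- generateControlLoci(sc)
  template <- bundleTemplate(bundle)
  draws <- samplePrior(defaultPriors(), 300)
  tab <- simulateReferenceTable(draws, template,
                                priors = defaultPriors())
  obs <- abcSummaryVector(bundle)
  post <- abcFit(obs, tab, tolerance = 0.05, priors = defaultPriors())
  chk <- posteriorPredictiveCheck(post, template, tab, nPred = 120)
  expect_equal(nrow(chk$pred), 120)
  expect_equal(nrow(chk$rank), 9)
  expect_true(all(chk$rank$p > 0 & chk$rank$p <= 1))
  expect_equal(ncol(chk$pca$prior), 2)
  # an absurd observed vector lands outside every predictive draw
  post2 <- post
  post2@obs <- obs + 1e6
  chk2 <- posteriorPredictiveCheck(post2, template, tab, nPred = 250)
  expect_true(all(chk2$rank$p < 0.01))
})

test_that("rank p-values are calibrated when the observed data come from the predictive", {
  set.seed(39)
  params <- divergenceModelParams(NW = 2e4, NE = 2e4, NAnc = 2e4,
                                  Td = 500, muSeq = 5e-8)
  sc <- syntheticScenario(39)
  template <- bundleTemplate(generateControlLoci(sc))
  template$pairIdx <- as.matrix(expand.grid(
    seq_len(template$nW), template$nW + seq_len(template$nE)))
  nPred <- 120
  pred <- t(replicate(nPred,
                      divergeScan:::.simulateSummaryRow(params, template)))
  trials <- 80
  stat <- "seq_S_pooled"
  j <- match(stat, colnames(pred))
  ps <- replicate(trials, {
    obs <- divergeScan:::.simulateSummaryRow(params, template)[j]
    r <- (sum(pred[, j] <= obs) + 1) / (nPred + 1)
    r
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
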