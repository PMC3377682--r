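mkPosterior <- function(particles, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(particles))
  new("ABCPosterior", raw = particles, adjusted = particles,
      weights = weights / sum(weights), tolerance = 0.01,
      obs = numeric(0), regressionUsed = TRUE)
}

pointPosterior <- function(params, n = 1) {
  v <- vapply(divergeScan:::.PARAM_NAMES, function(p) slot(params, p), 0)
  mkPosterior(matrix(rep(v, each = n), n,
                     dimnames = list(NULL, divergeScan:::.PARAM_NAMES)))
}

test_that("posterior resampling follows the particle weights", {
  params <- divergenceModelParams(1e3, 1e3, 1e3, 500, 1e-8)
  # point mass -> identical draws
  post <- pointPosterior(params)
  d <- resamplePosterior(post, 50)
  expect_equal(nrow(unique(d)), 1)
  # draw frequencies proportional to weights (chi-square GOF)
  set.seed(41)
  particles <- matrix(rep(1:10, 7), 10,
                      dimnames = list(NULL, divergeScan:::.PARAM_NAMES))
  w <- runif(10)
  post2 <- mkPosterior(particles, w)
  d2 <- resamplePosterior(post2, 20000)
  obs <- tabulate(match(d2[, 1], 1:10), 10)
  gof <- chisq.test(obs, p = w / sum(w))
  expect_gt(gof$p.value, 0.01)
  # determinism under a fixed seed
  set.seed(42)
  a <- resamplePosterior(post2, 100)
  set.seed(42)
  b <- resamplePosterior(post2, 100)
  expect_identical(a, b)
  postZero <- post2
  postZero@weights <- rep(0, 10)
  expect_error(resamplePosterior(postZero, 10), "zero")
})

test_that("rank tests use the pseudo-count convention at both extremes", {
  nullv <- seq_len(9999)
  # observed at the median -> two-tailed p ~ 1
  r <- rankTest(5000, nullv)
  expect_gt(r$p, 0.99)
  # observed below every simulation, one-tailed low -> p = 1/10000
  r2 <- rankTest(-1, nullv, tail = "one_tailed_low")
  expect_equal(r2$p, 1 / 10000)
  expect_equal(r2$nUsed, 9999)
  # p is never 0, even above every simulation
  r3 <- rankTest(1e9, nullv)
  expect_gt(r3$p, 0)
  expect_error(rankTest(NA, nullv), "undefined")
})

test_that("rank-test p-values are uniform when the observation comes from the null", {
  set.seed(43)
  ps <- replicate(1000, rankTest(rnorm(1), rnorm(999),
                                 tail = "one_tailed_low")$p)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  ps2 <- replicate(1000, rankTest(rnorm(1), rnorm(999))$p)
  expect_gt(suppressWarnings(ks.test(ps2, "punif"))$p.value, 0.01)
})

test_that("results are invariant to the order of null simulations", {
  set.seed(44)
  nullv <- rnorm(500)
  expect_identical(rankTest(0.3, nullv)$p, rankTest(0.3, sample(nullv))$p)
})

test_that("theta-matched FST testing restricts to the matching window", {
  set.seed(45)
  params <- divergenceModelParams(2e3, 2e3, 2e3, 500, 1e-6)
  post <- pointPosterior(params)
  draws <- resamplePosterior(post, 400)
  null <- geneNullDistribution("g", 800, draws, m = 0, nW = 12, nE = 10)
  expect_equal(nrow(null@stats), 400)
  thetaObs <- median(null@stats[, "thetaW"], na.rm = TRUE)
  # infinite window: identical to the unrestricted rank test
  full <- fstThetaMatchedTest(0.1, thetaObs, null, window = Inf)
  plain <- rankTest(0.1, null, statistic = "fst_geo")
  expect_equal(full$p, plain$p)
  expect_equal(full$nUsed, plain$nUsed)
  # the matched count equals a brute-force count
  win <- 1.5
  ok <- !is.na(null@stats[, "fst_geo"]) &
    abs(null@stats[, "thetaW"] - thetaObs) <= win
  matched <- fstThetaMatchedTest(0.1, thetaObs, null, window = win)
  expect_equal(matched$nUsed, sum(ok))
  # empty window errors
  expect_error(fstThetaMatchedTest(0.1, -50, null, window = 0),
               "no matched")
})

test_that("color-group subsampling honours the stated composition", {
  set.seed(46)
  params <- divergenceModelParams(2e3, 2e3, 2e3, 500, 8e-7)
  post <- pointPosterior(params)
  draws <- resamplePosterior(post, 250)
  # a color group equal to the whole sample reproduces the pooled test
  compAll <- data.frame(color = "orange", West = 12, East = 10,
                        stringsAsFactors = FALSE)
  null <- geneNullDistribution("g", 600, draws, m = 0, nW = 12, nE = 10,
                               colorComp = compAll)
  expect_equal(null@stats[, "D_orange"], null@stats[, "D_pooled"])
  expect_equal(null@stats[, "H_orange"], null@stats[, "H_pooled"])
  ct <- colorGroupTest(0.5, null, statistic = "D", color = "orange")
  pt <- rankTest(0.5, null, statistic = "D_pooled")
  expect_equal(ct$p, pt$p)
  # requesting more sequences than simulated fails
  expect_error(geneNullDistribution("g", 600, draws[1:5, ], nW = 4, nE = 4,
                                    colorComp = data.frame(
                                      color = "red", West = 9, East = 0)),
               "exceeds")
})

test_that("color-group FST nulls match pooled FST nulls for random color mixtures", {
  set.seed(47)
  params <- divergenceModelParams(2e3, 2e3, 2e3, 800, 8e-7)
  post <- pointPosterior(params)
  draws <- resamplePosterior(post, 600)
  comp <- data.frame(color = c("white", "yellow"), West = c(6, 6),
                     East = c(5, 5), stringsAsFactors = FALSE)
  null <- geneNullDistribution("g", 600, draws, m = 0, nW = 12, nE = 10,
                               colorComp = comp)
  mGeo <- mean(null@stats[, "fst_geo"], na.rm = TRUE)
  mCol <- mean(null@stats[, "fst_color"], na.rm = TRUE)
  # colors are random West/East mixtures, so color FST fluctuates around 0
  expect_lt(abs(mCol), 0.02 + abs(mGeo))
})

test_that("the panmictic null has mean FST near zero", {
  set.seed(48)
  params <- divergenceModelParams(2e3, 2e3, 2e3, 0, 8e-7)
  draws <- resamplePosterior(pointPosterior(params), 1500)
  null <- geneNullDistribution("g", 700, draws, m = 0, nW = 12, nE = 10)
  expect_lt(abs(mean(null@stats[, "fst_geo"], na.rm = TRUE)), 0.02)
  # the 95% interval of simulated D under the null contains 0
  q <- quantile(null@stats[, "D_pooled"], c(0.025, 0.975), na.rm = TRUE)
  expect_lt(q[1], 0)
  expect_gt(q[2], 0)
})
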