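test_that("basic statistics on degenerate and hand-checked alignments", {
  # monomorphic: no variation anywhere
  al <- LocusAlignment("m", c(a = "ACGT", b = "ACGT", c = "ACGT"))
  st <- seqStats(al)
  expect_equal(st$S, 0)
  expect_equal(st$thetaW, 0)
  expect_equal(st$pi, 0)
  expect_equal(st$K, 1)
  expect_true(is.na(tajimaD(al)))
  # n = 4, S = 3: thetaW = 3 / (1 + 1/2 + 1/3)
  m <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 0L))
  al2 <- matToAlignment(m, outgroup = FALSE)
  expect_equal(seqStats(al2)$thetaW, 3 / (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-12)
  expect_error(seqStats(LocusAlignment("x", c(a = "ACGT"))), "at least 2")
})

test_that("pi equals the brute-force average over all pairs (n <= 12)", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(4:12, 1)
    m <- randomSiteMatrix(sample(5:40, 1), n)
    expect_equal(seqStats(matToAlignment(m, outgroup = FALSE))$pi,
                 bfPi(m), tolerance = 1e-10)
  }
})

test_that("Tajima's D matches an independent constant-by-constant oracle", {
  # n = 4 with 3 singleton sites
  m <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(0L, 0L, 1L, 0L))
  expect_equal(tajimaD(m), bfTajimaD(m), tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:15) {
    m <- randomSiteMatrix(sample(3:50, 1), sample(4:20, 1))
    expect_equal(tajimaD(m), bfTajimaD(m), tolerance = 1e-12)
  }
  # pi == thetaW numerically -> D = 0: at n = 4, 8 singletons plus 3
  # doubletons give pi = 6 = 11 / a1
  m2 <- rbind(matrix(rep(c(1L, 0L, 0L, 0L), 8), 8, 4, byrow = TRUE),
              matrix(rep(c(1L, 1L, 0L, 0L), 3), 3, 4, byrow = TRUE))
  expect_equal(tajimaD(m2), 0, tolerance = 1e-12)
})

test_that("normalized Fay-Wu H matches the independent variance oracle", {
  # n = 3, one site at derived count 2: unnormalized thetaPi - thetaL
  m <- matrix(c(1L, 1L, 0L), 1, 3)
  st <- divergeScan:::.fayWuStats(m)
  expect_equal(st$Hraw, 2 / 3 - 1, tolerance = 1e-12)
  expect_equal(fayWuHNorm(m), bfFayWuH(m), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:15) {
    m <- randomSiteMatrix(sample(3:50, 1), sample(4:20, 1))
    expect_equal(fayWuHNorm(m), bfFayWuH(m), tolerance = 1e-12)
  }
  # all singletons: thetaPi exceeds thetaL, so H > 0
  m3 <- diag(1L, 20)[1:10, ]
  expect_gt(fayWuHNorm(m3), 0)
})

test_that("Hudson FST: fixed differences, permutations, brute force, duplication", {
  # two groups fixed for distinct haplotypes -> FST = 1
  m <- matrix(rep(c(1L, 0L), c(4, 4)), 3, 8, byrow = TRUE)
  gr <- rep(c("W", "E"), each = 4)
  expect_equal(hudsonFst(m, gr)$value, 1)
  # random labels -> mean FST over permutations ~ 0
  set.seed(14)
  m2 <- randomSiteMatrix(30, 12)
  perms <- replicate(1000, hudsonFst(m2, sample(rep(c("W", "E"),
                                                    each = 6)))$value)
  expect_lt(abs(mean(perms)), 0.02)
  # brute-force pair-loop oracle
  for (rep in 1:10) {
    m3 <- randomSiteMatrix(20, 10)
    gr3 <- rep(c("W", "E"), c(4, 6))
    expect_equal(hudsonFst(m3, gr3)$value, bfHudsonFst(m3, gr3),
                 tolerance = 1e-10)
  }
  # duplicating every sequence within each group leaves FST essentially
  # unchanged (exactly so up to the distinct-pair small-sample factor
  # (n-1)/n -> (2n-1)/(2n) in Hw, which vanishes with group size)
  m4 <- randomSiteMatrix(40, 60)
  gr4 <- rep(c("W", "E"), each = 30)
  m4dup <- m4[, rep(1:60, each = 2)]
  gr4dup <- gr4[rep(1:60, each = 2)]
  expect_equal(hudsonFst(m4, gr4)$value, hudsonFst(m4dup, gr4dup)$value,
               tolerance = 0.02)
  expect_error(hudsonFst(m4, rep("W", 60)), ">= 2 groups")
})

test_that("undefined statistics are flagged NA, never silently zero", {
  m <- matrix(integer(0), 0, 8)
  gr <- rep(c("W", "E"), each = 4)
  expect_true(is.na(hudsonFst(m, gr)$value))   # Hb = 0
  expect_true(is.na(tajimaD(m)))
  expect_true(is.na(fayWuHNorm(m)))
})

mkSSR <- function(genos, name = "ssr") {
  g <- matrix(as.integer(genos), ncol = 2)
  rownames(g) <- if (!is.null(rownames(genos))) rownames(genos)
                 else sprintf("i%02d", seq_len(nrow(g)))
  MicrosatLocus(name, g, motif = 2L, alleleRange = range(g))
}

test_that("microsatellite statistics: degenerate cases and the WC formula oracle", {
  # identical allele frequencies in both groups, many diploids -> FST ~ 0
  set.seed(15)
  n <- 1000
  geno <- matrix(sample(10:13, 2 * 2 * n, replace = TRUE), ncol = 2)
  rownames(geno) <- sprintf("i%04d", 1:(2 * n))
  gr <- setNames(rep(c("W", "E"), each = n), rownames(geno))
  st <- microsatStats(list(mkSSR(geno)), gr)
  expect_lt(abs(st$fstWC), 0.01)
  # groups fixed for different alleles -> FST = 1 and DAS = 1
  geno2 <- cbind(rep(c(10L, 20L), each = 5), rep(c(10L, 20L), each = 5))
  rownames(geno2) <- sprintf("i%02d", 1:10)
  gr2 <- setNames(rep(c("W", "E"), each = 5), rownames(geno2))
  st2 <- microsatStats(list(mkSSR(geno2)), gr2)
  expect_equal(st2$fstWC, 1)
  expect_equal(st2$das, 1)
  expect_equal(unname(st2$meanAlleles), c(1, 1))
  # independent transcription of the Weir-Cockerham (1984) components
  wcOracle <- function(nInd, p, h) {
    r <- 2
    nb <- mean(nInd)
    nc <- (sum(nInd) - sum(nInd^2) / sum(nInd)) / (r - 1)
    pb <- sum(nInd * p) / sum(nInd)
    s2 <- sum(nInd * (p - pb)^2) / ((r - 1) * nb)
    hb <- sum(nInd * h) / sum(nInd)
    a <- nb / nc * (s2 - 1 / (nb - 1) *
                      (pb * (1 - pb) - (r - 1) / r * s2 - hb / 4))
    b <- nb / (nb - 1) * (pb * (1 - pb) - (r - 1) / r * s2 -
                            (2 * nb - 1) / (4 * nb) * hb)
    c(a, b, hb / 2)
  }
  for (rep in 1:10) {
    nInd <- sample(5:30, 2)
    p <- runif(2)
    h <- pmin(runif(2), 2 * p * (1 - p) + 0.1)
    expect_equal(unname(divergeScan:::.wcComponents(nInd, p, h)),
                 wcOracle(nInd, p, h), tolerance = 1e-12)
  }
  # monomorphic locus excluded with a warning
  mono <- mkSSR(cbind(rep(12L, 10), rep(12L, 10)))
  expect_warning(microsatStats(list(mono, mkSSR(geno2)), gr2),
                 "monomorphic")
})

test_that("WC FST recovers the island-model expectation from Beta-distributed frequencies", {
  set.seed(16)
  FSTtrue <- 0.2
  reps <- 200
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    loci <- lapply(1:8, function(l) {
      pbar <- runif(1, 0.2, 0.8)
      ab <- pbar * (1 / FSTtrue - 1)
      bb <- (1 - pbar) * (1 / FSTtrue - 1)
      p12 <- rbeta(2, ab, bb)
      geno <- rbind(
        matrix(rbinom(2 * 40, 1, p12[1]), ncol = 2),
        matrix(rbinom(2 * 40, 1, p12[2]), ncol = 2)) + 10L
      rownames(geno) <- sprintf("i%02d", 1:80)
      mkSSR(geno)
    })
    gr <- setNames(rep(c("W", "E"), each = 40),
                   sprintf("i%02d", 1:80))
    est[r] <- suppressWarnings(microsatStats(loci, gr)$fstWC)
  }
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - FSTtrue), 2 * se + 0.01)
})

test_that("the ABC summary vector has fixed shape and is deterministic", {
  set.seed(17)
  b <- generateControlLoci(syntheticScenario(17))
  v1 <- abcSummaryVector(b)
  v2 <- abcSummaryVector(b)
  expect_identical(v1, v2)
  expect_equal(names(v1), divergeScan:::.SUMMARY_STAT_NAMES)
  expect_false(anyNA(v1))
  # panmixia (Td = 0, equal sizes): both FST entries near 0
  sc <- syntheticScenario(18, params = divergenceModelParams(
    NW = 2e4, NE = 2e4, NAnc = 2e4, Td = 0, muSeq = 5e-8))
  v3 <- abcSummaryVector(generateControlLoci(sc))
  expect_lt(abs(v3[["ssr_fst_wc"]]), 0.05)
  expect_lt(abs(v3[["seq_fst_hudson"]]), 0.2)
})
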