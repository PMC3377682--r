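mkCounts <- function(locus, n, S, D, L)
  data.frame(locus = locus, n = n, S = S, D = D, L = L,
             stringsAsFactors = FALSE)

test_that("HKA counts come from comparable sites only", {
  seqs <- c(a = "ACGTACGTNC", b = "ACGTACGTAC", c = "ACTTACGTAC")
  al <- LocusAlignment("x", seqs, outgroup = "ACGTTCGTAA")
  ct <- hkaCounts(al)
  # column 9 has an N -> 9 comparable sites; column 3 segregates;
  # columns 5 (T vs A) and 10 (C vs A) are fixed differences
  expect_equal(ct$L, 9)
  expect_equal(ct$S, 1)
  expect_equal(ct$D, 2)
  expect_error(hkaCounts(LocusAlignment("y", seqs)), "outgroup")
})

test_that("pairwise HKA is exact on proportional counts and detects deficits", {
  a <- mkCounts("a", 10, 20, 30, 500)
  b <- mkCounts("b", 10, 40, 60, 1000)
  r <- pairwiseHKA(a, b)
  expect_lt(r$chisq, 1e-16)
  expect_equal(r$p, 1)
  # independent transcription of the expectation/variance arithmetic
  oracleChisq <- function(cA, cB) {
    S <- c(cA$S, cB$S); D <- c(cA$D, cB$D)
    an <- sapply(c(cA$n, cB$n), function(n) sum(1 / (1:(n - 1))))
    bn <- sapply(c(cA$n, cB$n), function(n) sum(1 / (1:(n - 1))^2))
    f <- function(T) sum(S) - sum(an * (S + D) / (an + T + 1))
    T <- uniroot(f, c(-0.999, 1e5), tol = 1e-12)$root
    lam <- (S + D) / (an + T + 1)
    ES <- lam * an; ED <- lam * (T + 1)
    sum((S - ES)^2 / (ES + lam^2 * bn)) + sum((D - ED)^2 / (ED + lam^2))
  }
  set.seed(51)
  for (rep in 1:8) {
    cA <- mkCounts("a", sample(5:46, 1), rpois(1, 20) + 1,
                   rpois(1, 60) + 1, 600)
    cB <- mkCounts("b", cA$n, rpois(1, 25) + 1, rpois(1, 80) + 1, 900)
    expect_equal(pairwiseHKA(cA, cB)$chisq, oracleChisq(cA, cB),
                 tolerance = 1e-8)
  }
  # a planted 6-fold polymorphism deficit is significant
  lam <- 10
  an <- sum(1 / (1:45))
  dfc <- pairwiseHKA(
    mkCounts("sel", 46, round(lam * an / 6), round(lam * 5), 900),
    mkCounts("neu", 46, round(lam * an), round(lam * 5), 900))
  expect_gt(dfc$chisq, 3.84)
  expect_lt(dfc$p, 0.05)
  # symmetric in locus order
  expect_equal(pairwiseHKA(a, dfc <- mkCounts("c", 10, 9, 70, 700))$chisq,
               pairwiseHKA(dfc, a)$chisq, tolerance = 1e-12)
})

test_that("chi-square and LRT are invariant to rescaling all locus lengths", {
  a <- mkCounts("a", 20, 15, 40, 500)
  b <- mkCounts("b", 20, 30, 50, 800)
  r1 <- pairwiseHKA(a, b)
  a2 <- a; b2 <- b
  a2$L <- a$L * 10; b2$L <- b$L * 10
  r2 <- pairwiseHKA(a2, b2)
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-12)
  cts <- rbind(a, b, mkCounts("c", 20, 22, 60, 700))
  cts10 <- cts; cts10$L <- cts$L * 10
  f1 <- mlHKA(cts, selected = "a")
  f2 <- mlHKA(cts10, selected = "a")
  expect_equal(f1@lrt, f2@lrt, tolerance = 1e-6)
  expect_equal(unname(f1@theta / f2@theta), rep(10, 3), tolerance = 1e-4)
})

test_that("ML-HKA nests correctly and its LRT is never negative", {
  cts <- rbind(mkCounts("a", 20, 15, 40, 500),
               mkCounts("b", 20, 30, 50, 800),
               mkCounts("c", 20, 22, 60, 700))
  f0 <- mlHKA(cts, selected = character(0))
  expect_equal(f0@lrt, 0)
  expect_equal(unname(f0@k), rep(1, 3))
  set.seed(52)
  for (rep in 1:25) {
    nloc <- 6
    lamL <- runif(nloc, 3, 30)
    an <- sum(1 / (1:19))
    Tt <- runif(1, 1, 8)
    cts <- do.call(rbind, lapply(seq_len(nloc), function(i)
      mkCounts(paste0("l", i), 20, rpois(1, lamL[i] * an),
               rpois(1, lamL[i] * (Tt + 1)), 600)))
    fit <- mlHKA(cts, selected = "l1", nStarts = 3)
    expect_gte(fit@lrt, 0)
    expect_gte(fit@logLik, fit@logLik0)
  }
})

test_that("ML-HKA recovers a planted selection parameter", {
  set.seed(53)
  nloc <- 12
  an <- sum(1 / (1:45))
  Tt <- 5
  kTrue <- 3
  reps <- 30
  khat <- numeric(reps)
  for (r in seq_len(reps)) {
    lamL <- runif(nloc, 5, 25)
    k <- c(kTrue, rep(1, nloc - 1))
    cts <- do.call(rbind, lapply(seq_len(nloc), function(i)
      mkCounts(paste0("l", i), 46, rpois(1, k[i] * lamL[i] * an),
               rpois(1, lamL[i] * (Tt + (1 + k[i]) / 2)), 700)))
    khat[r] <- mlHKA(cts, selected = "l1", nStarts = 3)@k[["l1"]]
  }
  se <- sd(khat) / sqrt(reps)
  expect_lt(abs(mean(khat) - kTrue), 3 * se + 0.2)
})
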