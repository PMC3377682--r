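test_that("default pathway positions keep the canonical order and the cyclase tie", {
  genes <- c("IPI", "PDS", "CRTISO", "LCYB1", "LCYE", "CHXE", "ZEP")
  pos <- pathwayPositions(genes)
  expect_equal(pos[["LCYB1"]], pos[["LCYE"]])
  expect_true(pos[["IPI"]] < pos[["PDS"]] &&
                pos[["PDS"]] < pos[["CRTISO"]] &&
                pos[["CRTISO"]] < pos[["LCYB1"]] &&
                pos[["LCYE"]] < pos[["CHXE"]] &&
                pos[["CHXE"]] < pos[["ZEP"]])
  # single-gene registry is trivially valid
  expect_equal(unname(pathwayPositions("PDS")), 2)
  # an order-preserving override is silent, ZEP stays maximal
  pos2 <- suppressWarnings(pathwayPositions(genes,
                                            overrides = c(ZEP = 12)))
  expect_equal(pos2[["ZEP"]], 12)
  expect_true(all(pos2[["ZEP"]] >= pos2))
  # an order-breaking override only warns
  expect_warning(pathwayPositions(genes, overrides = c(IPI = 99)),
                 "order")
})

test_that("Kendall tau matches brute-force pair enumeration, ties included", {
  expect_equal(kendallTau(1:8, 1:8)$tau, 1)
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties by construction
    y <- rnorm(n)
    expect_equal(kendallTau(x, y)$tau, bfKendallTau(x, y),
                 tolerance = 1e-10)
  }
  # n = 5 with one tie, exact hand case
  x <- c(1, 2, 2, 3, 4)
  y <- c(2, 1, 4, 3, 5)
  expect_equal(kendallTau(x, y)$tau, bfKendallTau(x, y),
               tolerance = 1e-12)
  expect_error(kendallTau(rep(1, 5), 1:5), "all-tied")
})

test_that("tau depends only on rank order", {
  set.seed(72)
  x <- rnorm(15)
  y <- rnorm(15)
  t0 <- kendallTau(x, y)
  t1 <- kendallTau(exp(x), y)
  t2 <- kendallTau(x, 2 * y + 5)
  expect_equal(t0$tau, t1$tau)
  expect_equal(t0$tau, t2$tau)
  expect_equal(t0$p, t1$p)
})

test_that("location tests behave on separation, smallest cases, and match Wilcoxon", {
  up <- data.frame(gene = rep(c("IPI", "PDS"), each = 4),
                   p = runif(8, 0.6, 1))
  down <- data.frame(gene = rep(c("ZEP", "CHXE"), each = 4),
                     p = runif(8, 0, 0.3))
  res <- groupLocationTests(rbind(up, down), alternative = "greater")
  # complete separation: minimal one-sided p for these group sizes
  expect_equal(res$wilcoxon$p,
               suppressWarnings(wilcox.test(up$p, down$p,
                                            alternative = "greater")$p.value))
  expect_lt(res$wilcoxon$p, 0.001)
  expect_lt(res$kruskal$p, 0.05)
  # two groups of one value each: p from the 2-permutation space
  tiny <- data.frame(gene = c("IPI", "ZEP"), p = c(0.9, 0.1))
  r2 <- groupLocationTests(tiny, alternative = "greater")
  expect_equal(r2$wilcoxon$p, 0.5)
  # KW with 2 groups equals the normal-approximation Wilcoxon on untied data
  set.seed(73)
  a <- rnorm(12)
  b <- rnorm(10)
  kw <- kruskal.test(list(a, b))$p.value
  wx <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(kw, wx, tolerance = 1e-12)
  expect_error(groupLocationTests(data.frame(gene = "IPI", p = 0.5)),
               ">= 2")
})

test_that("Kruskal-Wallis p-values are calibrated under identical distributions", {
  set.seed(74)
  ps <- replicate(1000, {
    d <- data.frame(gene = rep(c("a", "b", "c"), each = 30),
                    p = runif(90))
    kruskal.test(d$p, factor(d$gene))$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pathway correlation pools p-values and reports per statistic", {
  set.seed(75)
  genes <- c("IPI", "PDS", "CRTISO", "LCYB1", "LCYE", "CHXE", "ZEP")
  pos <- pathwayPositions(genes)
  # construct p-values that decrease with position
  pv <- do.call(rbind, lapply(genes, function(g) data.frame(
    gene = g, statistic = rep(c("D", "H", "FST"), each = 3),
    sampleSet = "x",
    p = pmin(1, pmax(0, rnorm(9, 1 - pos[[g]] / 8, 0.15))),
    stringsAsFactors = FALSE)))
  corr <- pathwayCorrelation(pv, pos)
  expect_equal(corr$statistic[1], "all")
  expect_lt(corr$tau[1], 0)
  expect_lt(corr$p[1], 0.01)
  expect_setequal(corr$statistic, c("all", "D", "H", "FST"))
})
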