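test_that("degenerate simulator settings behave as the model dictates", {
  paramsNoMut <- divergenceModelParams(NW = 100, NE = 100, NAnc = 100,
                                       Td = 50, muSeq = 0, muSSR = 0)
  set.seed(21)
  o <- simulateSequenceLocus(paramsNoMut, simConfig(5, 5, L = 200))
  expect_equal(nrow(o@mat), 0)
  al <- simulateSequenceLocus(paramsNoMut,
                              simConfig(5, 5, L = 200,
                                        mode = "jukes_cantor",
                                        outTime = 1000))
  expect_equal(length(unique(apply(al@seqs, 1, paste, collapse = ""))), 1)
  ms <- simulateMicrosatLocus(paramsNoMut, simConfig(5, 5),
                              alleleRange = c(10L, 40L))
  expect_true(all(ms@genotypes == 25L))   # founder allele everywhere
})

test_that("identical seeds give identical simulations", {
  params <- divergenceModelParams(NW = 300, NE = 300, NAnc = 300,
                                  Td = 100, muSeq = 1e-5, muSSR = 1e-3)
  run <- function() {
    set.seed(99)
    list(simulateSequenceLocus(params, simConfig(8, 8, L = 300))@mat,
         simulateMicrosatLocus(params, simConfig(8, 8))@genotypes,
         simulateSequenceLocus(params, simConfig(8, 8, L = 300,
                                                 mode = "jukes_cantor",
                                                 outTime = 5000))@seqs)
  }
  expect_identical(run(), run())
})

test_that("single-population segregating sites match the Watterson expectation", {
  # theta = 2 * G * muLocus with G gene copies; aim for theta = 5, n = 10
  G <- 1000
  muLocus <- 5 / (2 * G)
  set.seed(22)
  reps <- 2000
  S <- replicate(reps, nrow(divergeScan:::.cpp_sim_seq_infsites(
    10, 0, G, G, G, 0, muLocus)))
  expected <- 5 * sum(1 / (1:9))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("step sizes follow the generalized stepwise model", {
  params <- divergenceModelParams(NW = 50, NE = 50, NAnc = 50, Td = 0,
                                  muSeq = 0, muSSR = 0.05, pSSR = 0)
  set.seed(23)
  # P = 0: every mutation is a single step, so allele variance matches
  # the strict SMM prediction G * mu (G copies, unit step variance)
  G <- 100
  reps <- 1500
  v <- replicate(reps, {
    g <- divergeScan:::.cpp_sim_ssr(10, 0, G, G, G, 0, 0.05, 0,
                                    -1000L, 1000L, 0L)
    var(as.vector(g))
  })
  expected <- G * 0.05
  se <- sd(v) / sqrt(reps)
  expect_lt(abs(mean(v) - expected), 3 * se)
  # mean squared step grows with pSSR (geometric steps > 1)
  set.seed(24)
  vBig <- replicate(800, {
    g <- divergeScan:::.cpp_sim_ssr(10, 0, G, G, G, 0, 0.05, 0.6,
                                    -5000L, 5000L, 0L)
    var(as.vector(g))
  })
  expect_gt(mean(vBig), mean(v) * 2)
  # alleles always inside the declared range
  set.seed(25)
  ms <- simulateMicrosatLocus(divergenceModelParams(50, 50, 50, 10,
                                                    0, 0.5, 0.5),
                              simConfig(10, 10),
                              alleleRange = c(10L, 14L))
  expect_true(all(ms@genotypes >= 10 & ms@genotypes <= 14))
})

test_that("misorientation flips act site-wise at the requested rate", {
  set.seed(26)
  m <- randomSiteMatrix(10000, 10)
  o <- new("OrientedAlignment", name = "t", mat = m,
           sampleIds = sprintf("s%d", 1:10), nUnorientable = 0L)
  expect_identical(applyMisorientation(o, 0)@mat, m)
  flipped <- applyMisorientation(o, 1)@mat
  expect_identical(flipped, 1L - m)
  part <- applyMisorientation(o, 0.1)@mat
  frac <- mean(rowSums(part != m) > 0)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("population differentiation grows with divergence time", {
  set.seed(27)
  G <- 1000
  meanFst <- vapply(c(0, 500, 5000), function(Td) {
    mean(replicate(400, {
      m <- divergeScan:::.cpp_sim_seq_infsites(8, 8, G, G, G, Td, 2e-3)
      if (nrow(m) == 0) return(NA_real_)
      f <- hudsonFst(m, rep(c("W", "E"), each = 8))$value
      f
    }), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(meanFst) > 0))
  expect_lt(abs(meanFst[1]), 0.03)
  expect_gt(meanFst[3], 0.5)
})

test_that("the simulator agrees with msprime on E[S] and diversity components", {
  G <- 1000
  nW <- nE <- 10
  Td <- 800
  muSite <- 1e-5
  L <- 100
  reps <- 1500
  script <- sprintf('
import msprime, json
dem = msprime.Demography()
dem.add_population(name="W", initial_size=%d)
dem.add_population(name="E", initial_size=%d)
dem.add_population(name="A", initial_size=%d)
dem.add_population_split(time=%d, derived=["W","E"], ancestral="A")
S = []; hw = []; hb = []
idx1 = list(range(%d)); idx2 = list(range(%d, %d))
reps = msprime.sim_ancestry(samples={"W": %d, "E": %d}, demography=dem,
                            ploidy=1, sequence_length=%d,
                            num_replicates=%d, random_seed=12345)
for i, ts in enumerate(reps):
    mts = msprime.sim_mutations(ts, rate=%g, random_seed=i + 1,
                                discrete_genome=False)
    S.append(mts.num_sites)
    hw.append(float(mts.diversity(idx1, span_normalise=False)) / 2 +
              float(mts.diversity(idx2, span_normalise=False)) / 2)
    hb.append(float(mts.divergence([idx1, idx2], span_normalise=False)))
print(json.dumps({"S": sum(S)/len(S), "sdS": (sum((x - sum(S)/len(S))**2
      for x in S)/len(S))**0.5, "hw": sum(hw)/len(hw),
      "hb": sum(hb)/len(hb)}))
', G, G, G, Td, nW, nW, nW + nE, nW, nE, L, reps, muSite)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  ms <- jsonlite::fromJSON(out[length(out)])
  set.seed(28)
  Sv <- hwv <- hbv <- numeric(reps)
  gr <- rep(c("W", "E"), c(nW, nE))
  for (r in seq_len(reps)) {
    m <- divergeScan:::.cpp_sim_seq_infsites(nW, nE, G, G, G, Td,
                                             muSite * L)
    Sv[r] <- nrow(m)
    if (nrow(m)) {
      comp <- divergeScan:::.pairDiffComponents(m, gr)
      hwv[r] <- mean(comp$within)
      hbv[r] <- comp$Hb
    }
  }
  seS <- sqrt(sd(Sv)^2 / reps + ms$sdS^2 / reps)
  expect_lt(abs(mean(Sv) - ms$S), 3 * seS)
  expect_lt(abs(mean(hwv) - ms$hw) / ms$hw, 0.1)
  expect_lt(abs(mean(hbv) - ms$hb) / ms$hb, 0.1)
})
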