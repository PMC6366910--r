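designCodes <- c("backcross", "intercross_F2", "doubled_haploids",
                 "riself2", "risib2", "riself4", "riself8", "riself16",
                 "risib4", "risib8", "do_hs8")

test_that("state spaces have the documented cardinality and order", {
  for (code in designCodes) {
    d <- crossDesign(code)
    S <- nGenotypeStates(d)
    if (code == "do_hs8") {
      expect_equal(S, 8 * 9 / 2)
      expect_equal(nGenotypeStates(d, "X", bothSexes = TRUE), 36 + 8)
      expect_equal(genoStates(d)[1:3], c("AA", "AB", "AC"))
    } else if (code == "intercross_F2") {
      expect_equal(S, 3)           # n(n+1)/2 unordered pairs of 2 founders
    } else if (code == "backcross") {
      expect_equal(S, 2)
      expect_equal(genoStates(d), c("AA", "AB"))
    } else {
      expect_equal(S, d@nFounders) # inbred lines: founder labels
    }
  }
  expect_error(crossDesign("magic19"), "unknown cross design")
})

test_that("initial distributions are the documented ones and sum to 1", {
  expect_equal(unname(initProbs("riself2")), c(0.5, 0.5))
  expect_equal(unname(initProbs("intercross_F2")), c(0.25, 0.5, 0.25))
  p <- initProbs("do_hs8", generation = 5)
  hom <- c("AA", "BB", "CC", "DD", "EE", "FF", "GG", "HH")
  expect_equal(unname(p[hom]), rep(1 / 64, 8))
  expect_equal(unname(p[setdiff(names(p), hom)]), rep(2 / 64, 28))
  expect_error(initProbs("do_hs8"), "generation")
  for (code in designCodes)
    expect_equal(sum(initProbs(code, generation = 5)), 1)
})

test_that("transition matrices are row-stochastic, identity at r = 0, and monotone in r", {
  rgrid <- seq(0, 0.5, by = 0.05)
  for (code in designCodes) {
    offmass <- vapply(rgrid, function(r) {
      Tm <- transitionProbs(code, r, generation = 5)
      expect_lt(max(abs(rowSums(Tm) - 1)), 1e-12)
      expect_gte(min(Tm), 0)
      mean(1 - diag(Tm))
    }, 0)
    Tm0 <- transitionProbs(code, 0, generation = 5)
    expect_equal(unname(Tm0), diag(nrow(Tm0)), tolerance = 1e-12)
    expect_true(all(diff(offmass) > -1e-12))
  }
  expect_error(transitionProbs("backcross", 0.6), "r must be")
  expect_error(transitionProbs("do_hs8", 0.1, generation = 0), "generation")
})

test_that("2-way RIL transitions match the closed forms and the breeding-chain oracle", {
  for (r in seq(0.01, 0.49, by = 0.04)) {
    expect_equal(transitionProbs("riself2", r)[1, 2], 2 * r / (1 + 2 * r),
                 tolerance = 1e-10)
    expect_equal(transitionProbs("risib2", r)[1, 2], 4 * r / (1 + 6 * r),
                 tolerance = 1e-10)
  }
  # validate the closed forms once against the exact two-locus chains
  expect_equal(1 - rilSelfChainSame(0.07), 2 * 0.07 / (1 + 2 * 0.07),
               tolerance = 1e-10)
  expect_equal(1 - rilSibChainSame(0.07), 4 * 0.07 / (1 + 6 * 0.07),
               tolerance = 1e-10)
})

test_that("F2 transitions come from two independent meioses", {
  r <- 0.17
  Tm <- transitionProbs("intercross_F2", r)
  expect_equal(Tm["AA", "AA"], (1 - r)^2)
  expect_equal(Tm["AA", "AB"], 2 * r * (1 - r))
  expect_equal(Tm["AB", "AB"], (1 - r)^2 + r^2)
})

test_that("Markov designs compose across intervals under Haldane combination", {
  r1 <- 0.08; r2 <- 0.21
  r12 <- r1 * (1 - r2) + r2 * (1 - r1)
  for (code in c("backcross", "intercross_F2", "doubled_haploids")) {
    A <- transitionProbs(code, r1) %*% transitionProbs(code, r2)
    B <- transitionProbs(code, r12)
    expect_lt(max(abs(A - B)), 1e-10)
  }
  # the RIL fixation matrices apply between adjacent markers only:
  # composition does NOT hold exactly there
  A <- transitionProbs("riself2", r1) %*% transitionProbs("riself2", r2)
  B <- transitionProbs("riself2", r12)
  expect_gt(max(abs(A - B)), 1e-4)
})

test_that("DO transitions approach the stationary law as generation grows", {
  r <- 0.1
  pi0 <- initProbs("do_hs8", generation = 5)
  tv <- vapply(c(2, 5, 15, 40), function(s) {
    Tm <- transitionProbs("do_hs8", r, generation = s)
    max(abs(drop(pi0 %*% Tm) - pi0))   # stationarity gap
  }, 0)
  expect_lt(max(tv), 1e-12)            # exchangeable model: exactly stationary
  rowdist <- vapply(c(2, 5, 15, 40), function(s) {
    Tm <- transitionProbs("do_hs8", r, generation = s)
    0.5 * sum(abs(Tm[1, ] - pi0))      # TV(row, stationary) shrinks in s
  }, 0)
  expect_true(all(diff(rowdist) < 0))
})

test_that("DO transition matrix matches Monte-Carlo simulation of the breeding scheme", {
  set.seed(42)
  n <- 60000
  for (cfg in list(c(r = 0.05, s = 5), c(r = 0.25, s = 3))) {
    mc <- mppqtl:::.simDoTwoLocus(n, cfg[["r"]], cfg[["s"]])
    psame <- mean(mc[, 1L] == mc[, 2L])
    q <- mppqtl:::.doSameProb(cfg[["r"]], cfg[["s"]])
    se <- sqrt(psame * (1 - psame) / n)
    expect_lt(abs(psame - q), 3 * se + 1e-12)
  }
})

test_that("emission probabilities implement the symmetric error model", {
  eps <- 0.02
  al <- c(1L, 2L)                       # founder A carries A, founder B carries B
  E <- emissionProbs("intercross_F2", al, eps)
  expect_equal(E["AA", "AA"], 1 - eps)
  expect_equal(E["AA", "BB"], eps / 2)
  expect_equal(unname(E[, "missing"]), rep(1, 3))
  expect_equal(unname(rowSums(E[, c("AA", "AB", "BB")])), rep(1, 3))
  expect_equal(E["AB", "notAA"], E["AB", "AB"] + E["AB", "BB"])
  E0 <- emissionProbs("intercross_F2", al, 0)
  expect_equal(unname(E0[, "AA"]), c(1, 0, 0))
  # missing founder allele marginalizes with probability 1/2 per allele
  al8 <- c(1L, 0L, rep(1L, 6))
  E8 <- emissionProbs("do_hs8", al8, 0)
  expect_equal(E8["AB", "AA"], 0.5)    # founder B unknown
  expect_equal(E8["BB", "AA"], 0.5)    # inbred homozygote: single draw
  expect_equal(E8["BB", "AB"], 0)
})

test_that("founder dosage map rows sum to ploidy; DO columns are balanced", {
  M <- founderDosageMap("do_hs8")
  expect_equal(dim(M), c(36L, 8L))
  expect_equal(unname(rowSums(M)), rep(2, 36))
  expect_equal(unname(colSums(M)), rep(9, 8))   # each founder in 9 states
  expect_equal(unname(M["AB", ]), c(1, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(M["AA", ]), c(2, 0, 0, 0, 0, 0, 0, 0))
  MX <- founderDosageMap("do_hs8", "X", sex = "both")
  expect_equal(unname(rowSums(MX)), c(rep(2, 36), rep(1, 8)))
  expect_error(founderDosageMap("nope"), "unknown cross design")
})
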