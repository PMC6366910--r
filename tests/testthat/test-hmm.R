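test_that("insertPseudomarkers subdivides gaps evenly and preserves markers", {
  map <- list("1" = c(mA = 0, mB = 10), "2" = c(mC = 0, mD = 7))
  out <- insertPseudomarkers(map, 5)
  expect_equal(unname(out[["1"]]), c(0, 5, 10))
  expect_equal(unname(out[["2"]]), c(0, 3.5, 7))   # ceil(7/5) = 2 intervals
  expect_true(all(c("mA", "mB") %in% names(out[["1"]])))
  expect_identical(insertPseudomarkers(map, 0), map)
  step <- 2.3
  fine <- insertPseudomarkers(list("1" = c(a = 0, b = 31)), step)[["1"]]
  expect_lte(max(diff(fine)), step + 1e-12)
  expect_error(insertPseudomarkers(map, -1), "step")
})

test_that("forward-backward matches exhaustive path enumeration on toy crosses", {
  set.seed(11)
  cases <- list(
    list(design = "backcross", nmar = 4), list(design = "intercross_F2", nmar = 4),
    list(design = "doubled_haploids", nmar = 4), list(design = "riself2", nmar = 4),
    list(design = "risib4", nmar = 4), list(design = "riself8", nmar = 3),
    list(design = "do_hs8", nmar = 3))
  for (cs in cases) {
    nF <- crossDesign(cs$design)@nFounders
    pos <- cumsum(c(0, runif(cs$nmar - 1, 2, 15)))
    fa <- matrix(sample(1:2, nF * cs$nmar, replace = TRUE), nF, cs$nmar)
    codes <- sample(0:3, cs$nmar, replace = TRUE)
    cross <- makeToyCross(cs$design, matrix(codes, 1L), pos,
                          founderAlleles = if (nF > 2) fa else NULL)
    pr <- calcGenoprob(cross, errorProb = 0.01)
    orc <- exhaustiveHmm(cs$design, codes,
                         lapply(seq_len(cs$nmar), function(t)
                           if (nF > 2) fa[, t] else c(1L, 2L)),
                         pos, 0.01, generation = 5)
    expect_lt(max(abs(orc$post - pr@probs[["1"]][1L, , ])), 1e-10)
    vp <- calcViterbi(cross, errorProb = 0.01)
    expect_equal(as.integer(vp@paths[["1"]][1L, ]), orc$map)
    expect_equal(vp@logProb[1L, 1L], orc$logmax, tolerance = 1e-10)
  }
})

test_that("with all genotypes missing the posterior equals the prior", {
  cross <- makeToyCross("do_hs8", matrix(0L, 2L, 3L), c(0, 10, 25))
  pr <- calcGenoprob(cross)
  init <- initProbs("do_hs8", generation = 5)
  for (t in 1:3)
    expect_equal(pr@probs[["1"]][1L, , t], init, tolerance = 1e-12)
})

test_that("noiseless consistent data give certainty; posteriors always normalize", {
  # non-recombinant backcross heterozygote, errorProb = 0
  cross <- makeToyCross("backcross", matrix(2L, 1L, 4L), c(0, 5, 10, 15))
  pr <- calcGenoprob(cross, errorProb = 0)
  expect_equal(unname(pr@probs[["1"]][1L, "AB", ]), rep(1, 4))
  vp <- calcViterbi(cross, errorProb = 0)
  expect_equal(unname(vp@paths[["1"]][1L, ]), rep(2L, 4))
  # epsilon -> 0 limit approaches certainty for consistent data
  for (eps in c(1e-2, 1e-6)) {
    pr2 <- calcGenoprob(makeToyCross("intercross_F2",
                                     matrix(c(1L, 1L, 3L), 1L), c(0, 4, 30)),
                        errorProb = eps)
    expect_gt(pr2@probs[["1"]][1L, "AA", 1L], 1 - 10 * eps)
  }
  # random simulated crosses keep the normalization invariant
  sim <- simulateCross("riself4", nInd = 20, nChr = 2, chrLength = 40,
                       markerSpacing = 5, errorProb = 0.01, missingRate = 0.1,
                       seed = 5)
  pr3 <- calcGenoprob(sim$cross, errorProb = 0.01)
  for (chr in c("1", "2")) {
    ss <- apply(pr3@probs[[chr]], c(1, 3), sum)
    expect_lt(max(abs(ss - 1)), 1e-8)
    expect_gte(min(pr3@probs[[chr]]), 0)
  }
})

test_that("Viterbi breaks ties toward the lower state index", {
  # no data at all: every constant path is tied; expect state 1
  cross <- makeToyCross("riself2", matrix(0L, 1L, 3L), c(0, 10, 20))
  vp <- calcViterbi(cross)
  expect_equal(unname(vp@paths[["1"]][1L, ]), rep(1L, 3))
})

test_that("pseudomarker positions get prior-propagated probabilities", {
  cross <- makeToyCross("backcross", matrix(c(1L, 1L), 1L), c(0, 10))
  pmap <- insertPseudomarkers(cross@map, 5)
  pr <- calcGenoprob(cross, map = pmap, errorProb = 1e-4)
  expect_equal(dim(pr@probs[["1"]])[3L], 3L)
  # midway position: probability of AA slightly below the flanking certainty
  expect_gt(pr@probs[["1"]][1L, "AA", 2L], 0.98)
  expect_lt(pr@probs[["1"]][1L, "AA", 2L],
            max(pr@probs[["1"]][1L, "AA", c(1L, 3L)]))
})

test_that("allele-dosage collapse divides by ploidy and preserves normalization", {
  # certainty in diplotype AB -> founder dosages (1/2, 1/2)
  arr <- array(0, c(1L, 36L, 2L))
  st <- genoStates("do_hs8")
  arr[1L, match("AB", st), ] <- 1
  gp <- makeProbObject(list("1" = arr), list("1" = c(p1 = 0, p2 = 10)),
                       alleleProb = FALSE)
  ap <- genoprobToAlleleprob(gp)
  expect_equal(unname(ap@probs[["1"]][1L, , 1L]),
               c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  # uniform over the 36 states -> uniform 1/8 over founders
  arr[] <- 1 / 36
  gp2 <- makeProbObject(list("1" = arr), list("1" = c(p1 = 0, p2 = 10)),
                        alleleProb = FALSE)
  expect_equal(unname(genoprobToAlleleprob(gp2)@probs[["1"]][1L, , 1L]),
               rep(1 / 8, 8))
  # homozygote certainty -> dosage 1 on that founder
  arr[] <- 0; arr[1L, match("CC", st), ] <- 1
  gp3 <- makeProbObject(list("1" = arr), list("1" = c(p1 = 0, p2 = 10)),
                        alleleProb = FALSE)
  expect_equal(unname(genoprobToAlleleprob(gp3)@probs[["1"]][1L, "C", 1L]), 1)
  expect_error(genoprobToAlleleprob(genoprobToAlleleprob(gp3)), "already")
})

test_that("X-chromosome arrays split the sexes over the 44-state layout", {
  sim <- simulateCross("do_hs8", nInd = 40, nChr = 1, chrLength = 30,
                       markerSpacing = 5, includeX = TRUE, errorProb = 0.002,
                       seed = 99)
  pr <- calcGenoprob(sim$cross, errorProb = 0.002)
  X <- pr@probs[["X"]]
  expect_equal(dim(X)[2L], 44L)
  male <- sim$cross@sex == "m"
  expect_equal(max(abs(rowSums(X[male, 1:36, 1L]))), 0)
  expect_equal(unname(rowSums(X[male, 37:44, 1L])), rep(1, sum(male)))
  expect_equal(unname(rowSums(X[!male, 1:36, 1L])), rep(1, sum(!male)))
  # unsupported design on X errors
  bad <- makeToyCross("backcross", matrix(1L, 1L, 2L), c(0, 10), chr = "X")
  expect_error(calcGenoprob(bad), "X-chromosome")
})

test_that("markers absent from the map are rejected", {
  cross <- makeToyCross("backcross", matrix(1L, 1L, 3L), c(0, 5, 10))
  names(cross@map[["1"]])[2L] <- "renamed"
  expect_error(calcGenoprob(cross), "not in map")
})

test_that("maximal-marginal reconstruction recovers the simulated DO mosaic", {
  # generation-3 DO population (the early end of typical DO study designs);
  # accuracy decays ~1 point per additional outbreeding generation as the
  # mosaic segments shorten (see the methods vignette)
  sim <- simulateCross("do_hs8", nInd = 200, nChr = 1, chrLength = 100,
                       markerSpacing = 0.5, errorProb = 2e-3, generation = 3,
                       seed = 555)
  pr <- calcGenoprob(sim$cross, errorProb = 2e-3)
  p <- pr@probs[["1"]]
  pos <- unname(sim$cross@map[["1"]])
  pairs <- mppqtl:::.founderPairs(8)
  key <- paste(pairs[1, ], pairs[2, ])
  acc <- 0; tot <- 0
  for (i in seq_len(200)) {
    m <- sim$truth@mosaics[[i]][["1"]]
    fm <- mppqtl:::.founderAt(m$mat, pos)
    fp <- mppqtl:::.founderAt(m$pat, pos)
    ts <- match(paste(pmin(fm, fp), pmax(fm, fp)), key)
    mm <- apply(p[i, , ], 2L, which.max)
    acc <- acc + sum(mm == ts); tot <- tot + length(ts)
  }
  expect_gte(acc / tot, 0.95)
})
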