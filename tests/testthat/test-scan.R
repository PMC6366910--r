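# 6-individual fully informative backcross: probabilities are 0/1 indicators
bcToyProbs <- function(states) {
  n <- length(states)
  arr <- array(0, c(n, 2L, 1L), dimnames = list(NULL, c("AA", "AB"), "m1"))
  arr[cbind(seq_len(n), states, 1L)] <- 1
  makeProbObject(list("1" = arr), list("1" = c(m1 = 0)), design = "backcross")
}

test_that("Haley-Knott LOD matches a direct regression oracle", {
  states <- c(1L, 1L, 1L, 2L, 2L, 2L)
  y <- c(3.1, 2.7, 3.4, 5.0, 4.6, 5.3)
  pr <- bcToyProbs(states)
  sc <- scanQtl(pr, y)
  g <- states - 1
  rss1 <- sum(stats::lm(y ~ g)$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(sc@lod[1L, 1L], 3 * log10(rss0 / rss1), tolerance = 1e-10)
  # orthogonal phenotype: group means equal -> LOD 0
  y0 <- c(-1, 0, 1, -1, 0, 1)
  expect_equal(scanQtl(pr, y0)@lod[1L, 1L], 0, tolerance = 1e-10)
})

test_that("LOD is invariant to affine phenotype and covariate reparameterization", {
  fx <- doFixture()
  set.seed(31)
  y <- simulatePhenotype(fx$sim$cross, fx$sim$truth,
                         qtl = list(list(chr = "1", pos = 20, sdp = 5L,
                                         varExplained = 0.15)), h2 = 0)$pheno
  cv <- cbind(a = rnorm(150), b = rnorm(150))
  s1 <- scanQtl(fx$ap, y, covar = cv)
  s2 <- scanQtl(fx$ap, 3.7 * y - 11, covar = cv)
  expect_equal(s1@lod, s2@lod, tolerance = 1e-8)
  cv2 <- cbind(cv, span = cv[, 1L] - 2 * cv[, 2L])   # inside the span
  s3 <- scanQtl(fx$ap, y, covar = cv2)
  expect_equal(s1@lod, s3@lod, tolerance = 1e-8)
})

test_that("mixed-model scan with identity kinship equals Haley-Knott", {
  fx <- doFixture()
  set.seed(32)
  y <- simulatePhenotype(fx$sim$cross, fx$sim$truth, h2 = 0.3)$pheno
  hk <- scanQtl(fx$ap, y)
  lmm <- scanQtl(fx$ap, y, kinship = diag(nInd(fx$ap)))
  expect_lt(max(abs(hk@lod - lmm@lod)), 1e-8)
  lmm2 <- scanQtl(fx$ap, y, kinship = 3 * diag(nInd(fx$ap)))  # K = cI
  expect_lt(max(abs(hk@lod - lmm2@lod)), 1e-8)
})

test_that("the full model dominates the additive model (nested regressions)", {
  fx <- doFixture()
  set.seed(33)
  y <- simulatePhenotype(fx$sim$cross, fx$sim$truth,
                         qtl = list(list(chr = "1", pos = 30, sdp = 77L,
                                         varExplained = 0.1)), h2 = 0)$pheno
  full <- scanQtl(fx$pr, y)
  add <- scanQtl(fx$ap, y)
  expect_equal(full@df, 35L)
  expect_equal(add@df, 7L)
  expect_true(all(full@lod >= add@lod - 1e-8))
})

test_that("the mixed model absorbs population-structure inflation", {
  # two DO subpopulations bred in separate small colonies (strong drift),
  # phenotype shifted by subpopulation: a pure confounding scenario
  mergeAp <- function(a, b) {
    arrs <- lapply(names(a@probs), function(chr) {
      n1 <- dim(a@probs[[chr]])[1L]
      x <- array(0, c(n1 + dim(b@probs[[chr]])[1L],
                      dim(a@probs[[chr]])[2L], dim(a@probs[[chr]])[3L]))
      x[1:n1, , ] <- a@probs[[chr]]
      x[-(1:n1), , ] <- b@probs[[chr]]
      dimnames(x) <- list(sprintf("i%03d", seq_len(dim(x)[1L])),
                          dimnames(a@probs[[chr]])[[2L]],
                          dimnames(a@probs[[chr]])[[3L]])
      x
    })
    names(arrs) <- names(a@probs)
    makeProbObject(arrs, a@map)
  }
  s1 <- simulateCross("do_hs8", nInd = 80, nChr = 2, chrLength = 40,
                      markerSpacing = 2, errorProb = 0.002, popSize = 16,
                      generation = 10, seed = 81)
  s2 <- simulateCross("do_hs8", nInd = 80, nChr = 2, chrLength = 40,
                      markerSpacing = 2, errorProb = 0.002, popSize = 16,
                      generation = 10, seed = 82)
  ap <- mergeAp(genoprobToAlleleprob(calcGenoprob(s1$cross, errorProb = 0.002)),
                genoprobToAlleleprob(calcGenoprob(s2$cross, errorProb = 0.002)))
  set.seed(83)
  y <- 2 * rep(0:1, each = 80) + rnorm(160)
  hk <- scanQtl(ap, y)
  lmm <- scanQtl(ap, y, kinship = calcKinship(ap, "loco"))
  expect_lt(stats::median(lmm@lod), 0.5 * stats::median(hk@lod))

  # LMM LOD agrees with a direct generalized-least-squares oracle
  Kl <- calcKinship(ap, "loco")
  K <- Kl[["2"]]
  nf <- fitLmmNull(y, matrix(1, 160, 1), K)
  Vi <- solve(nf$h2 * K + (1 - nf$h2) * diag(160))
  G <- ap@probs[["2"]][, , 5L]
  glsRss <- function(X) {
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    drop(t(y - X %*% b) %*% Vi %*% (y - X %*% b))
  }
  lodOracle <- 80 * log10(glsRss(matrix(1, 160, 1)) / glsRss(G))
  idx <- which(lmm@chr == "2")[5L]
  expect_equal(unname(lmm@lod[idx, 1L]), lodOracle, tolerance = 1e-8)
})

test_that("per-position effects match a least-squares oracle, with SEs", {
  fx <- doFixture()
  set.seed(35)
  y <- simulatePhenotype(fx$sim$cross, fx$sim$truth, h2 = 0)$pheno
  cf <- scanCoef(fx$ap, y, chr = "1")
  Z <- fx$ap@probs[["1"]][, , 7L]
  fit <- stats::lm(y ~ Z - 1)
  expect_equal(unname(cf@coef[7L, 1:8]), unname(stats::coef(fit)),
               tolerance = 1e-8)
  expect_equal(unname(cf@se[7L, 1:8]),
               unname(summary(fit)$coefficients[, 2L]), tolerance = 1e-6)
})

test_that("effect recovery on a backcross is within 2 SE of the generating truth", {
  sim <- simulateCross("backcross", nInd = 500, nChr = 1, chrLength = 60,
                       markerSpacing = 3, errorProb = 0, seed = 36)
  pr <- calcGenoprob(sim$cross, errorProb = 1e-4)
  # additive effect 0.8 at the central marker; truth from the mosaic
  D <- mppqtl:::.truthDosage(sim$truth, "1", 30, 2)
  set.seed(36)
  y <- 0.8 * D[, 2L] + rnorm(500)
  cf <- scanCoef(pr, y, chr = "1")
  k <- which.min(abs(cf@pos - 30))
  est <- cf@coef[k, "AB"] - cf@coef[k, "AA"]
  se <- sqrt(cf@se[k, "AB"]^2 + cf@se[k, "AA"]^2)
  expect_lt(abs(est - 0.8), 2 * se)
})

test_that("BLUPs shrink toward zero and reach the documented limits", {
  fx <- doFixture()
  set.seed(37)
  y <- simulatePhenotype(fx$sim$cross, fx$sim$truth,
                         qtl = list(list(chr = "1", pos = 24, sdp = 9L,
                                         varExplained = 0.12)), h2 = 0)$pheno
  cf <- scanCoef(fx$ap, y, chr = "1")
  bl <- scanBlup(fx$ap, y, chr = "1")
  ssF <- rowSums(sweep(cf@coef[, 1:8], 1L, rowMeans(cf@coef[, 1:8]))^2)
  ssB <- rowSums(bl@coef[, 1:8]^2)
  expect_true(all(ssB <= ssF + 1e-8))
  # zero variance ratio: BLUPs exactly 0
  b0 <- scanBlup(fx$ap, y, chr = "1", varRatio = 0)
  expect_equal(max(abs(b0@coef[, 1:8])), 0)
  # variance ratio -> infinity: BLUPs approach the centered fixed effects
  binf <- scanBlup(fx$ap, y, chr = "1", varRatio = 1e9)
  cc <- sweep(cf@coef[, 1:8], 1L, rowMeans(cf@coef[, 1:8]))
  expect_lt(max(abs(binf@coef[, 1:8] - cc)), 1e-4)
})

test_that("constant phenotypes and misaligned inputs are rejected", {
  fx <- doFixture()
  expect_error(scanQtl(fx$ap, rep(1, 150)), "constant")
  expect_error(scanQtl(fx$ap, rnorm(10)), "align")
})

test_that("missing phenotypes are dropped pairwise per column", {
  fx <- doFixture()
  set.seed(38)
  Y <- cbind(p1 = rnorm(150), p2 = rnorm(150))
  rownames(Y) <- fx$sim$cross@ids
  Y[1:10, 2L] <- NA
  sc <- scanQtl(fx$ap, Y)
  sc2 <- scanQtl(fx$ap, Y[, 2L, drop = FALSE][11:150, , drop = FALSE])
  expect_equal(sc@n, c(150L, 140L))
  expect_equal(unname(sc@lod[, 2L]), unname(sc2@lod[, 1L]), tolerance = 1e-10)
})

test_that("findPeaks separates peaks by the LOD-drop rule", {
  lodvec <- c(1, 5, 2, 1.8, 4, 1)
  sc <- new("ScanResult",
            lod = matrix(lodvec, ncol = 1L, dimnames = list(paste0("p", 1:6), "y")),
            chr = rep("1", 6L), pos = as.numeric(1:6), model = "additive",
            df = 7L, n = 100L, method = "hk")
  expect_equal(nrow(findPeaks(sc, threshold = 6)), 0L)
  one <- findPeaks(sc, threshold = 3)            # peakdrop = Inf: single peak
  expect_equal(nrow(one), 1L)
  expect_equal(one$pos, 2)
  two <- findPeaks(sc, threshold = 3, peakdrop = 1.5)
  expect_equal(nrow(two), 2L)
  expect_equal(two$pos, c(2, 5))
})
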