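# Independent oracles used across the test suite.  These deliberately avoid
# the package's forward-backward / Viterbi code paths: they are built only
# from the exported model pieces (initProbs, transitionProbs, emissionProbs)
# plus brute-force enumeration, or from first-principles Markov chains.

haldaneR <- function(d) 0.5 * (1 - exp(-2 * d / 100))

# exhaustive-path posterior and joint-MAP path for one individual
exhaustiveHmm <- function(design, codes, alleles, posCm, errorProb,
                          generation = NULL, chromType = "autosome",
                          sex = "female") {
  init <- initProbs(design, chromType, sex = sex, generation = generation)
  S <- length(init)
  P <- length(codes)
  trans <- lapply(haldaneR(diff(posCm)), function(r)
    transitionProbs(design, r, chromType, generation = generation, sex = sex))
  emis <- lapply(seq_len(P), function(t)
    emissionProbs(design, alleles[[t]], errorProb, chromType,
                  sex = sex)[, codes[t] + 1L])
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), P)))
  w <- init[paths[, 1L]] * emis[[1L]][paths[, 1L]]
  if (P > 1L) for (t in 2:P)
    w <- w * trans[[t - 1L]][cbind(paths[, t - 1L], paths[, t])] *
      emis[[t]][paths[, t]]
  post <- vapply(seq_len(P), function(t)
    as.numeric(tapply(w, factor(paths[, t], levels = seq_len(S)), sum)),
    numeric(S))
  post[is.na(post)] <- 0
  post <- sweep(post, 2L, colSums(post), "/")
  list(post = post,                          # S x P
       map = as.integer(paths[which.max(w), ]),
       logmax = log(max(w)))
}

# exact two-locus chain for 2-way RIL by selfing: haplotypes over founders
# {1,2} at two loci; individual = ordered haplotype pair (16 states)
hapIdx <- function(a, b) (a - 1L) * 2L + b              # 1..4
gameteDist <- function(i1, i2, r) {
  # i: haplotype index 1..4 -> (L, R)
  L <- c(1L, 1L, 2L, 2L); R <- c(1L, 2L, 1L, 2L)
  q <- numeric(4L)
  q[i1] <- q[i1] + (1 - r) / 2
  q[i2] <- q[i2] + (1 - r) / 2
  x <- hapIdx(L[i1], R[i2]); q[x] <- q[x] + r / 2
  x <- hapIdx(L[i2], R[i1]); q[x] <- q[x] + r / 2
  q
}

rilSelfChainSame <- function(r) {
  # ordered pair state = (h1-1)*4 + h2; offspring = two iid gametes
  Tm <- matrix(0, 16L, 16L)
  for (h1 in 1:4) for (h2 in 1:4) {
    q <- gameteDist(h1, h2, r)
    pj <- outer(q, q)                       # pj[g1, g2]
    Tm[(h1 - 1L) * 4L + h2, ] <- as.vector(t(pj))
  }
  p <- numeric(16L); p[(hapIdx(1, 1) - 1L) * 4L + hapIdx(2, 2)] <- 1
  for (k in 1:60) Tm <- Tm %*% Tm           # absorb
  p <- drop(p %*% Tm)
  h1marg <- tapply(p, rep(1:4, each = 4L), sum)
  unname(h1marg[hapIdx(1, 1)] + h1marg[hapIdx(2, 2)])  # P(intact haplotype)
}

rilSibChainSame <- function(r) {
  # individual = ordered hap pair (16); sib pair = (I1, I2): 256 states
  gd <- array(0, c(16L, 4L))
  for (h1 in 1:4) for (h2 in 1:4)
    gd[(h1 - 1L) * 4L + h2, ] <- gameteDist(h1, h2, r)
  Tm <- matrix(0, 256L, 256L)
  for (I1 in 1:16) for (I2 in 1:16) {
    pJ <- as.vector(t(outer(gd[I1, ], gd[I2, ])))      # J=(g1,g2) index
    Tm[(I1 - 1L) * 16L + I2, ] <- as.vector(t(outer(pJ, pJ)))
  }
  f1 <- (hapIdx(1, 1) - 1L) * 4L + hapIdx(2, 2)        # F1 individual
  p <- numeric(256L); p[(f1 - 1L) * 16L + f1] <- 1
  for (k in 1:60) Tm <- Tm %*% Tm
  p <- drop(p %*% Tm)
  h1marg <- tapply(p, rep(1:4, each = 64L), sum)       # first haplotype of I1
  unname(h1marg[hapIdx(1, 1)] + h1marg[hapIdx(2, 2)])
}

# rank-based AUC
rankAuc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
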