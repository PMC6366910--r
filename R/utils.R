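# internal helpers shared across modules

# cM distance -> recombination fraction
.cm2r <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  d <- pmax(d, 0)
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * d / 100)),
         kosambi = 0.5 * tanh(2 * d / 100))
}

# Haldane composition of two recombination fractions
.combineR <- function(r1, r2) r1 * (1 - r2) + r2 * (1 - r1)

# unordered founder pairs in lexicographic order: (1,1),(1,2),...,(1,n),(2,2),...
.founderPairs <- function(n) {
  i <- rep(seq_len(n), times = n - seq_len(n) + 1L)
  j <- unlist(lapply(seq_len(n), function(a) a:n))
  rbind(i, j, deparse.level = 0)
}

.pairLabels <- function(n, letters_ = LETTERS) {
  p <- .founderPairs(n)
  paste0(letters_[p[1L, ]], letters_[p[2L, ]])
}

# observed genotype codes (integer storage)
.GENO_CODES <- c(missing = 0L, AA = 1L, AB = 2L, BB = 3L, notAA = 4L, notBB = 5L)

# consistency of full genotype (rows AA/AB/BB) with observed codes (cols code 1..5)
.CONSISTENT <- local({
  m <- matrix(0, 3L, 5L, dimnames = list(c("AA", "AB", "BB"),
                                         c("AA", "AB", "BB", "notAA", "notBB")))
  m["AA", "AA"] <- 1; m["AB", "AB"] <- 1; m["BB", "BB"] <- 1
  m["AB", "notAA"] <- 1; m["BB", "notAA"] <- 1
  m["AA", "notBB"] <- 1; m["AB", "notBB"] <- 1
  m
})

.isXchr <- function(chrname) toupper(chrname) == "X"

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# stable per-chromosome position names for pseudomarkers
.locName <- function(chr, pos) sprintf("c%s.loc%s", chr, format(pos, trim = TRUE))
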