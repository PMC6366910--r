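#' @include hmm.R
NULL

#' Kinship from founder allele probabilities
#'
#' Relatedness of pairs of individuals as the average, over included
#' positions, of the probability that haplotypes drawn at random from the two
#' individuals carry the same founder: `K[i,j] = mean_t sum_f p_ift p_jft`.
#' With `type = "loco"` one matrix per chromosome is returned, each computed
#' with that chromosome's positions left out (the leave-one-chromosome-out
#' kinship used to avoid proximal contamination in mixed-model scans).
#'
#' @param probs allele-dosage probabilities (see [genoprobToAlleleprob()])
#' @param type "overall" for one genome-wide matrix, "loco" for a list of
#'   per-chromosome leave-one-out matrices
#' @return individuals x individuals symmetric matrix, or a named list of
#'   such matrices for `"loco"`
#' @export
calcKinship <- function(probs, type = c("overall", "loco")) {
  type <- match.arg(type)
  if (!probs@alleleProb)
    probs <- genoprobToAlleleprob(probs)
  chrs <- names(probs@probs)
  if (type == "loco" && length(chrs) < 2L)
    .stopf("LOCO kinship needs at least two chromosomes")
  ids <- dimnames(probs@probs[[1L]])[[1L]]
  n <- dim(probs@probs[[1L]])[1L]
  Ks <- lapply(chrs, function(chr) {
    p <- probs@probs[[chr]]
    d <- dim(p)
    tcrossprod(matrix(p, d[1L], d[2L] * d[3L]))
  })
  npos <- vapply(chrs, function(chr) dim(probs@probs[[chr]])[3L], 0L)
  tot <- Reduce(`+`, Ks)
  if (type == "overall") {
    K <- tot / sum(npos)
    dimnames(K) <- list(ids, ids)
    return(K)
  }
  out <- lapply(seq_along(chrs), function(k) {
    K <- (tot - Ks[[k]]) / (sum(npos) - npos[k])
    dimnames(K) <- list(ids, ids)
    K
  })
  names(out) <- chrs
  out
}

#' Export / import a kinship matrix as delimited text
#'
#' Square CSV with individual IDs as header row and first column; full
#' double precision is preserved.
#'
#' @param K kinship matrix with ID dimnames
#' @param path file path
#' @export
exportKinship <- function(K, path) {
  df <- data.frame(id = rownames(K),
                   apply(K, 2L, function(x) sprintf("%.17g", x)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(K))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exportKinship
#' @export
importKinship <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  K <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  rownames(K) <- df[[1L]]
  if (!identical(rownames(K), colnames(K)))
    .stopf("kinship file is not a square ID-labelled matrix")
  K
}
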