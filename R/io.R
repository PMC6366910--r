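#' @include hmm.R
NULL

.GENO_LETTERS <- c(`0` = "-", `1` = "A", `2` = "H", `3` = "B",
                   `4` = "nA", `5` = "nB")
.FG_LETTERS <- c(`0` = "-", `1` = "A", `2` = "B")

.readTable <- function(path, sep = ",", na = c("-", "NA", "")) {
  utils::read.csv(path, sep = sep, na.strings = na, check.names = FALSE,
                  colClasses = "character")
}

#' Read a cross from a control-file bundle
#'
#' The control file is a JSON document whose fields name the delimited
#' tables of the bundle (mirroring the control-file layout in common use
#' for public cross-data bundles): `crosstype`,
#' `geno`, `founder_geno`, `gmap`, optional `pmap`, `pheno`, `covar`, a
#' `genotypes` code dictionary, `sex` (covariate column and level codes),
#' optional `cross_info` (generation column for DO/HS), `na.strings` and
#' `sep`.  Tables are aligned by individual ID, not row order; the marker
#' sets of genotypes, founder genotypes and map are reconciled to their
#' intersection and every discard is counted in the report attached as
#' `attr(cross, "readReport")`.
#'
#' @param controlPath path to the JSON control file
#' @return an [MppCross-class] object with a `readReport` attribute
#' @export
readCross <- function(controlPath) {
  if (!file.exists(controlPath)) .stopf("control file not found: %s", controlPath)
  ctl <- jsonlite::fromJSON(controlPath)
  dir <- dirname(controlPath)
  pathOf <- function(f) file.path(dir, f)
  need <- c("crosstype", "geno", "gmap")
  if (!all(need %in% names(ctl)))
    .stopf("control file must declare: %s", paste(need, collapse = ", "))
  design <- crossDesign(ctl$crosstype)
  sep <- if (is.null(ctl$sep)) "," else ctl$sep
  na <- if (is.null(ctl$na.strings)) c("-", "NA", "") else ctl$na.strings
  gdict <- if (is.null(ctl$genotypes))
    c(A = 1L, H = 2L, B = 3L, nA = 4L, nB = 5L)
  else unlist(ctl$genotypes)

  for (f in c("geno", "gmap", "founder_geno", "pheno", "covar"))
    if (!is.null(ctl[[f]]) && !file.exists(pathOf(ctl[[f]])))
      .stopf("declared file missing: %s", ctl[[f]])

  gmap <- utils::read.csv(pathOf(ctl$gmap), sep = sep, check.names = FALSE)
  gtab <- .readTable(pathOf(ctl$geno), sep, na)
  ids <- gtab[[1L]]
  if (anyDuplicated(ids)) .stopf("duplicate individual IDs in genotype file")
  gm <- as.matrix(gtab[, -1L, drop = FALSE])

  report <- list()
  # marker reconciliation: intersection of genotypes, map, founder genotypes
  markers <- intersect(colnames(gm), gmap$marker)
  fg <- NULL
  if (!is.null(ctl$founder_geno)) {
    ftab <- .readTable(pathOf(ctl$founder_geno), sep, na)
    fg <- as.matrix(ftab[, -1L, drop = FALSE])
    rownames(fg) <- ftab[[1L]]
    markers <- intersect(markers, colnames(fg))
  }
  report$nMarkersDroppedFromGeno <- ncol(gm) - length(markers)
  report$nMarkersDroppedFromMap <- sum(!gmap$marker %in% markers)
  gmap <- gmap[gmap$marker %in% markers, , drop = FALSE]
  gmap <- gmap[order(match(gmap$chr, unique(gmap$chr)), as.numeric(gmap$pos)), ]

  bad <- setdiff(unique(as.vector(gm[!is.na(gm)])), names(gdict))
  if (length(bad))
    .stopf("unmappable genotype codes: %s", paste(bad, collapse = ", "))
  code <- function(x) {
    out <- gdict[x]
    out[is.na(x)] <- 0L
    as.integer(out)
  }

  chrs <- unique(gmap$chr)
  geno <- map <- founderGeno <- vector("list", length(chrs))
  names(geno) <- names(map) <- names(founderGeno) <- chrs
  for (chr in chrs) {
    mm <- gmap$marker[gmap$chr == chr]
    map[[chr]] <- stats::setNames(as.numeric(gmap$pos[gmap$chr == chr]), mm)
    geno[[chr]] <- matrix(code(gm[, mm, drop = FALSE]), nrow(gm),
                          dimnames = list(ids, mm))
    if (!is.null(fg)) {
      fdict <- c(A = 1L, B = 2L)
      fx <- fg[, mm, drop = FALSE]
      fcode <- fdict[fx]
      fcode[is.na(fx) | is.na(fcode)] <- 0L    # het/missing founder calls -> missing
      founderGeno[[chr]] <- matrix(as.integer(fcode), nrow(fg),
                                   dimnames = list(rownames(fg), mm))
    } else founderGeno[chr] <- list(NULL)
  }

  pmap <- list()
  if (!is.null(ctl$pmap)) {
    pm <- utils::read.csv(pathOf(ctl$pmap), sep = sep, check.names = FALSE)
    pm <- pm[pm$marker %in% markers, , drop = FALSE]
    pmap <- lapply(chrs, function(chr)
      stats::setNames(as.numeric(pm$pos[pm$chr == chr]), pm$marker[pm$chr == chr]))
    names(pmap) <- chrs
  }

  pheno <- matrix(numeric(0), length(ids), 0L, dimnames = list(ids, NULL))
  if (!is.null(ctl$pheno)) {
    ptab <- utils::read.csv(pathOf(ctl$pheno), sep = sep, na.strings = na,
                            check.names = FALSE)
    pm <- as.matrix(ptab[, -1L, drop = FALSE])
    storage.mode(pm) <- "double"
    rownames(pm) <- ptab[[1L]]
    extra <- setdiff(ids, rownames(pm))
    report$nIndWithoutPhenotypes <- length(extra)
    pheno <- matrix(NA_real_, length(ids), ncol(pm),
                    dimnames = list(ids, colnames(pm)))
    common <- intersect(ids, rownames(pm))
    pheno[common, ] <- pm[common, , drop = FALSE]
    report$nPhenoRowsDropped <- sum(!rownames(pm) %in% ids)
  }

  covar <- data.frame(row.names = ids)
  sex <- character(0)
  generation <- integer(0)
  if (!is.null(ctl$covar)) {
    cv <- utils::read.csv(pathOf(ctl$covar), sep = sep, na.strings = na,
                          check.names = FALSE)
    rownames(cv) <- cv[[1L]]
    cv <- cv[, -1L, drop = FALSE]
    covar <- cv[match(ids, rownames(cv)), , drop = FALSE]
    rownames(covar) <- ids
    if (!is.null(ctl$sex)) {
      sc <- ctl$sex$covar
      raw <- as.character(covar[[sc]])
      sex <- rep(NA_character_, length(ids))
      sex[raw == ctl$sex$f] <- "f"
      sex[raw == ctl$sex$m] <- "m"
    }
    if (!is.null(ctl$cross_info)) {
      generation <- as.integer(covar[[ctl$cross_info$covar]])
    }
  }
  cross <- new("MppCross", design = design, geno = geno,
               founderGeno = founderGeno, map = map, pmap = pmap,
               pheno = pheno, covar = covar, sex = sex,
               generation = generation, ids = as.character(ids))
  attr(cross, "readReport") <- report
  cross
}

#' Write a cross as a control-file bundle
#'
#' Inverse of [readCross()]: writes the delimited tables and a JSON control
#' file into `dir`.  Used by the simulator to emit complete, re-readable
#' input bundles.
#'
#' @param cross an [MppCross-class]
#' @param dir output directory (created if needed)
#' @return the control-file path, invisibly
#' @export
writeCrossBundle <- function(cross, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  allmar <- unlist(lapply(cross@map, names), use.names = FALSE)
  gm <- do.call(cbind, cross@geno)
  colnames(gm) <- allmar
  gdf <- data.frame(id = cross@ids,
                    matrix(.GENO_LETTERS[as.character(gm)], nrow(gm),
                           dimnames = list(NULL, allmar)),
                    check.names = FALSE)
  utils::write.csv(gdf, file.path(dir, "geno.csv"), row.names = FALSE, quote = FALSE)

  gmap <- data.frame(marker = allmar,
                     chr = rep(names(cross@map), lengths(cross@map)),
                     pos = unlist(cross@map, use.names = FALSE))
  utils::write.csv(gmap, file.path(dir, "gmap.csv"), row.names = FALSE, quote = FALSE)

  ctl <- list(crosstype = cross@design@code, geno = "geno.csv",
              gmap = "gmap.csv",
              genotypes = list(A = 1L, H = 2L, B = 3L, nA = 4L, nB = 5L),
              na.strings = list("-"), sep = ",")

  hasFG <- !all(vapply(cross@founderGeno, is.null, TRUE))
  if (hasFG) {
    fgm <- do.call(cbind, cross@founderGeno)
    fdf <- data.frame(id = LETTERS[seq_len(nrow(fgm))],
                      matrix(.FG_LETTERS[as.character(fgm)], nrow(fgm),
                             dimnames = list(NULL, allmar)),
                      check.names = FALSE)
    utils::write.csv(fdf, file.path(dir, "founder_geno.csv"),
                     row.names = FALSE, quote = FALSE)
    ctl$founder_geno <- "founder_geno.csv"
  }
  if (ncol(cross@pheno)) {
    pdf <- data.frame(id = cross@ids, cross@pheno, check.names = FALSE)
    utils::write.csv(pdf, file.path(dir, "pheno.csv"), row.names = FALSE, quote = FALSE)
    ctl$pheno <- "pheno.csv"
  }
  cv <- cross@covar
  if (length(cross@sex)) cv$sex <- cross@sex
  if (length(cross@generation)) cv$generation <- cross@generation
  if (ncol(cv)) {
    cdf <- data.frame(id = cross@ids, cv, check.names = FALSE)
    utils::write.csv(cdf, file.path(dir, "covar.csv"), row.names = FALSE, quote = FALSE)
    ctl$covar <- "covar.csv"
    if (length(cross@sex)) ctl$sex <- list(covar = "sex", f = "f", m = "m")
    if (length(cross@generation)) ctl$cross_info <- list(covar = "generation")
  }
  ctlPath <- file.path(dir, "control.json")
  jsonlite::write_json(ctl, ctlPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(ctlPath)
}

#' Export / import genotype probabilities as delimited text
#'
#' Long-format CSV with columns `individual`, `sex`, `chr`, `position`,
#' `pos`, `state`, `prob`, written at full double precision (round trips
#' bit-exactly).  Header comment lines (`#key=value`) carry the design code,
#' the allele-probability flag, the error rate and the map function.  This
#' is also the custom-probability import path for designs without native
#' transition code: any state labels are accepted and preserved in first-
#' appearance order.  Import rejects files whose (individual, position)
#' probability slices deviate from sum 1 by more than `1e-6`.
#'
#' @param probs a [GenotypeProb-class]
#' @param path file path
#' @return `exportGenoprob`: the path, invisibly; `importGenoprob`: a
#'   [GenotypeProb-class]
#' @export
exportGenoprob <- function(probs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#design=%s", probs@design),
               sprintf("#alleleProb=%s", probs@alleleProb),
               sprintf("#errorProb=%.17g", probs@errorProb),
               sprintf("#mapFunction=%s", probs@mapFunction)), con)
  writeLines("individual,sex,chr,position,pos,state,prob", con)
  for (chr in names(probs@probs)) {
    p <- probs@probs[[chr]]
    dn <- dimnames(p)
    d <- dim(p)
    ind <- rep(dn[[1L]], times = d[2L] * d[3L])
    sx <- rep(probs@sex, times = d[2L] * d[3L])
    st <- rep(rep(dn[[2L]], each = d[1L]), times = d[3L])
    po <- rep(dn[[3L]], each = d[1L] * d[2L])
    cm <- rep(probs@map[[chr]], each = d[1L] * d[2L])
    writeLines(sprintf("%s,%s,%s,%s,%.17g,%s,%.17g", ind, sx, chr, po, cm, st,
                       as.vector(p)), con)
  }
  invisible(path)
}

#' @rdname exportGenoprob
#' @export
importGenoprob <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(meta, `[`, "", 2L), vapply(meta, `[`, "", 1L))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        colClasses = c(individual = "character", sex = "character",
                                       chr = "character", position = "character",
                                       pos = "numeric", state = "character",
                                       prob = "numeric"))
  probs <- list(); map <- list(); sexTab <- NULL
  for (chr in unique(df$chr)) {
    dd <- df[df$chr == chr, , drop = FALSE]
    ind <- unique(dd$individual)
    st <- unique(dd$state)
    po <- unique(dd$position)
    ord <- order(dd$pos[match(po, dd$position)])
    po <- po[ord]
    arr <- array(NA_real_, c(length(ind), length(st), length(po)),
                 dimnames = list(ind, st, po))
    arr[cbind(match(dd$individual, ind), match(dd$state, st),
              match(dd$position, po))] <- dd$prob
    if (anyNA(arr)) .stopf("chr %s: incomplete probability table", chr)
    ss <- apply(arr, c(1L, 3L), sum)
    if (any(abs(ss - 1) > 1e-6))
      .stopf("chr %s: probability slices deviate from sum 1 by up to %.3g",
             chr, max(abs(ss - 1)))
    probs[[chr]] <- arr
    map[[chr]] <- stats::setNames(dd$pos[match(po, dd$position)], po)
    if (is.null(sexTab)) sexTab <- dd$sex[match(ind, dd$individual)]
  }
  new("GenotypeProb", probs = probs, map = map,
      design = unname(meta["design"]),
      alleleProb = as.logical(meta["alleleProb"]),
      sex = sexTab, errorProb = as.numeric(meta["errorProb"]),
      mapFunction = unname(meta["mapFunction"]))
}

#' Diagnostics report for a cross
#'
#' Computes per-marker and per-individual missing-data rates, markers
#' monomorphic in the founders (uninformative for haplotype reconstruction),
#' and X-chromosome/sex consistency (males with heterozygous X calls).
#' A clean bundle yields an empty `issues` vector.
#'
#' @param cross an [MppCross-class]
#' @return list with elements `markerMissing`, `indMissing`,
#'   `monomorphicFounderMarkers`, `maleHetX`, `issues`
#' @export
validateCross <- function(cross) {
  allg <- do.call(cbind, cross@geno)
  markerMissing <- colMeans(allg == 0L)
  indMissing <- stats::setNames(rowMeans(allg == 0L), cross@ids)
  mono <- character(0)
  for (chr in names(cross@founderGeno)) {
    fg <- cross@founderGeno[[chr]]
    if (is.null(fg)) next
    obs <- apply(fg, 2L, function(x) length(unique(x[x != 0L])))
    mono <- c(mono, colnames(fg)[obs < 2L])
  }
  maleHetX <- character(0)
  xchr <- names(cross@map)[vapply(names(cross@map), .isXchr, TRUE)]
  if (length(xchr) && length(cross@sex)) {
    for (chr in xchr) {
      g <- cross@geno[[chr]][cross@sex == "m", , drop = FALSE]
      het <- rowSums(g == 2L) > 0L
      maleHetX <- c(maleHetX, rownames(g)[het])
    }
  }
  issues <- character(0)
  if (length(mono))
    issues <- c(issues, sprintf("%d markers monomorphic in founders", length(mono)))
  if (length(maleHetX))
    issues <- c(issues, sprintf("%d males with heterozygous X calls", length(maleHetX)))
  list(markerMissing = markerMissing, indMissing = indMissing,
       monomorphicFounderMarkers = mono, maleHetX = maleHetX, issues = issues)
}
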