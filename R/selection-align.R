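# Protein-guided codon alignment: global protein alignment, then
# back-translation to codon columns.

#' Default protein alignment scoring
#'
#' BLOSUM62 with affine gaps (opening 10, extension 1), the conventional
#' parameterisation for closely related mitochondrial proteins.
#' @return list with elements `matrix` (name of a Biostrings substitution
#'   matrix or an actual matrix), `gapOpening`, `gapExtension`.
#' @export
defaultAlignmentScoring <- function() {
  list(matrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
}

#' Global alignment of two proteins
#'
#' Needleman-Wunsch global alignment with affine gap penalties via
#' Biostrings.  Tie-breaking among equally optimal alignments is
#' deterministic (fixed traceback order of the aligner).
#'
#' @param p1,p2 non-empty protein strings.
#' @param scoring see [defaultAlignmentScoring()].
#' @return list with `a1`, `a2` (gapped rows, "-" for gaps) and `score`.
#' @export
alignProteins <- function(p1, p2, scoring = defaultAlignmentScoring()) {
  if (!nzchar(p1) || !nzchar(p2)) stop("empty protein input")
  subMat <- scoring$matrix
  if (is.character(subMat)) {
    e <- new.env()
    utils::data(list = subMat, package = "Biostrings", envir = e)
    subMat <- get(subMat, envir = e)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = subMat,
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
  list(a1 = as.character(Biostrings::alignedPattern(al)),
       a2 = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Back-translate an aligned protein pair to a codon alignment
#'
#' Each aligned residue column is replaced by its source codon; columns
#' with a gap in either row, or whose codon contains N, or which are stop
#' codons, are dropped (the dropped count is recorded).  Each protein
#' must equal the translation of its CDS (trailing stop ignored).
#'
#' @param aligned list with rows `a1`, `a2` as from [alignProteins()].
#' @param cds1,cds2 the source coding sequences.
#' @param code a [GeneticCode-class] used to verify translations.
#' @param gene gene name stored in the result.
#' @return a [CodonAlignment-class].
#' @export
backTranslateAlignment <- function(aligned, cds1, cds2,
                                   code = geneticCode(5L), gene = "gene") {
  checkOne <- function(a, cds, which) {
    prot <- gsub("-", "", a)
    tr <- translateCodons(cds, code)
    tr <- sub("\\*$", "", tr)
    if (nchar(tr) < nchar(prot))
      stop("protein/CDS mismatch in sequence ", which,
           ": protein longer than translation")
    cmp <- substr(tr, 1L, nchar(prot))
    if (cmp != prot) {
      pos <- which(strsplit(cmp, "")[[1]] != strsplit(prot, "")[[1]])[1]
      stop("protein/CDS mismatch in sequence ", which, " at residue ", pos,
           ": aligned '", substr(prot, pos, pos), "' vs translated '",
           substr(cmp, pos, pos), "'")
    }
  }
  checkOne(aligned$a1, cds1, 1L)
  checkOne(aligned$a2, cds2, 2L)
  r1 <- strsplit(aligned$a1, "")[[1]]
  r2 <- strsplit(aligned$a2, "")[[1]]
  if (length(r1) != length(r2)) stop("aligned rows differ in length")
  cods1 <- .splitCodons(toupper(cds1))
  cods2 <- .splitCodons(toupper(cds2))
  i1 <- cumsum(r1 != "-")
  i2 <- cumsum(r2 != "-")
  keep <- logical(length(r1))
  c1 <- c2 <- character(length(r1))
  stops <- stopCodons(code)
  for (j in seq_along(r1)) {
    if (r1[j] == "-" || r2[j] == "-") next
    x <- cods1[i1[j]]; y <- cods2[i2[j]]
    if (grepl("[^ACGT]", x) || grepl("[^ACGT]", y)) next
    if (x %in% stops || y %in% stops) next
    keep[j] <- TRUE; c1[j] <- x; c2[j] <- y
  }
  if (!any(keep)) stop("no usable codon columns after filtering")
  new("CodonAlignment", gene = gene,
      codons1 = c1[keep], codons2 = c2[keep],
      nCodons = sum(keep), droppedColumns = as.integer(sum(!keep)),
      alignedProteins = c(aligned$a1, aligned$a2))
}

#' Codon alignment of two coding sequences
#'
#' Convenience wrapper: translate, align the proteins, back-translate.
#' @param cds1,cds2 coding sequences.
#' @param code a [GeneticCode-class].
#' @param gene name stored in the result.
#' @param scoring see [defaultAlignmentScoring()].
#' @return a [CodonAlignment-class].
#' @export
codonAlign <- function(cds1, cds2, code = geneticCode(5L), gene = "gene",
                       scoring = defaultAlignmentScoring()) {
  p1 <- sub("\\*$", "", translateCodons(cds1, code))
  p2 <- sub("\\*$", "", translateCodons(cds2, code))
  al <- alignProteins(p1, p2, scoring)
  backTranslateAlignment(al, cds1, cds2, code, gene)
}
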