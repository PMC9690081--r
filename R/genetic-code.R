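#' Construct a genetic code with an RSCU family partition
#'
#' @param tableId NCBI translation table: 1 (standard) or 5 (invertebrate
#'   mitochondrial).
#' @param partition synonymous-family partition used for RSCU.
#'   `"table8-standard"` (default) groups codons by the STANDARD code
#'   regardless of `tableId`: AUA sits in a 3-codon Ile family, AGA/AGG in
#'   the 6-codon Arg family, UCN+AGY form a 6-codon Ser family, and UGA
#'   sits in the 3-codon stop family.  This is the convention found in
#'   published mitogenome codon-usage tables (once UAA/UAG counts are
#'   excluded, a counted UGA in the 3-codon stop family gets RSCU 3).
#'   `"table5-mito"` groups codons by their translation under `tableId`,
#'   the biologically consistent alternative.
#' @return a [GeneticCode-class] object.
#' @examples
#' gc5 <- geneticCode(5L)
#' translateCodons("ATA", gc5)   # "M" under the invertebrate mito code
#' @export
geneticCode <- function(tableId = 5L,
                        partition = c("table8-standard", "table5-mito")) {
  partition <- match.arg(partition)
  tableId <- as.integer(tableId)
  if (!tableId %in% c(1L, 5L))
    stop("supported translation tables: 1 (standard), 5 (invertebrate mitochondrial)")
  codeTab <- Biostrings::getGeneticCode(as.character(tableId))
  starts <- attr(codeTab, "alt_init_codons")
  aa <- as.character(codeTab)
  names(aa) <- names(codeTab)
  starts <- unique(c("ATG", starts))
  famSource <- if (partition == "table8-standard") {
    std <- Biostrings::getGeneticCode("1")
    as.character(std)[match(names(aa), names(std))]
  } else aa
  names(famSource) <- names(aa)
  new("GeneticCode",
      tableId = tableId,
      codonToAa = aa,
      startCodons = starts,
      partitionId = partition,
      family = famSource)
}

#' Stop codons of a GeneticCode
#'
#' Stop codons under the TRANSLATION table (for table 5: TAA, TAG only;
#' TGA is Trp), used for stop-exclusion in codon counting and for pathway
#' exclusion in Ka/Ks counting.
#' @param code a [GeneticCode-class].
#' @return character vector of stop codons.
#' @export
stopCodons <- function(code) names(code@codonToAa)[code@codonToAa == "*"]

#' Family sizes of the RSCU partition
#' @param code a [GeneticCode-class].
#' @return named integer vector, family label -> number of codons.
#' @export
familySizes <- function(code) {
  tab <- table(code@family)
  structure(as.integer(tab), names = names(tab))
}

#' Translate a nucleotide sequence codon-wise
#'
#' Codons containing N (or any character outside ACGT) translate to "X";
#' stop codons translate to "*".  Trailing bases that do not fill a codon
#' are ignored.
#'
#' @param seq nucleotide string (length >= 3).
#' @param code a [GeneticCode-class].
#' @return protein string.
#' @export
translateCodons <- function(seq, code) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n < 1L) stop("sequence must contain at least one full codon")
  cods <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- code@codonToAa[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## ---- internal codon bookkeeping ----------------------------------------

.CODONS <- local({
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(b, each = 4L, times = 4L), rep(b, times = 16L))
})

.PURINES <- c("A", "G")

.isTransition <- function(x, y) {
  (x %in% .PURINES) == (y %in% .PURINES)
}

# cache keyed by code table id for pathway tables etc.
.codonCache <- new.env(parent = emptyenv())

.codonIndex <- function(codon) match(codon, .CODONS)

# all 9 single-nucleotide neighbours of a codon
.codonNeighbors <- function(codon) {
  bases <- c("T", "C", "A", "G")
  out <- character(0)
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      nb <- codon
      substr(nb, p, p) <- b
      out <- c(out, nb)
    }
  }
  out
}
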