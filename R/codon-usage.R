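# Codon counting, RSCU, start/stop profiling, amino-acid usage ranking
# and degenerate-site composition.

.cdsSeqs <- function(cdsList) {
  if (is.data.frame(cdsList)) cdsList <- cdsList$seq
  cdsList <- as.character(unlist(cdsList, use.names = FALSE))
  if (!length(cdsList)) stop("empty CDS list")
  toupper(cdsList)
}

.splitCodons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n < 1L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count codons over a set of coding sequences
#'
#' Counts all codons of all listed CDS (trailing partial codons dropped).
#' Codons containing N (or other non-ACGT letters) are skipped and
#' tallied separately.  With `excludeStopCounts = TRUE` (the default,
#' following the usual "excluding the stop codons" convention of
#' published codon-usage tables), counts for the stop codons of the
#' TRANSLATION table are removed from the totals; under the invertebrate
#' mitochondrial table these are TAA and TAG only, so TGA (Trp) counts
#' are retained.
#'
#' @param cdsList character vector / list of CDS strings, or the
#'   data.frame returned by [extractCDS()].
#' @param code a [GeneticCode-class].
#' @param excludeStopCounts drop stop-codon counts from the totals.
#' @return named integer vector over the 64 codons, with attributes
#'   `n_skipped` (codons containing N), `excluded_stops` and
#'   `n_excluded` (stop codons removed).
#' @export
countCodons <- function(cdsList, code = geneticCode(5L),
                        excludeStopCounts = TRUE) {
  seqs <- .cdsSeqs(cdsList)
  cods <- unlist(lapply(seqs, .splitCodons), use.names = FALSE)
  clean <- grepl("^[ACGT]{3}$", cods)
  nSkip <- sum(!clean)
  counts <- integer(64L)
  names(counts) <- .CODONS
  tab <- table(cods[clean])
  counts[names(tab)] <- as.integer(tab)
  stops <- stopCodons(code)
  nExcluded <- 0L
  if (excludeStopCounts) {
    nExcluded <- sum(counts[stops])
    counts[stops] <- 0L
  }
  structure(counts, n_skipped = nSkip,
            excluded_stops = if (excludeStopCounts) stops else character(0),
            n_excluded = nExcluded)
}

#' Relative synonymous codon usage from codon counts
#'
#' For codon c in a family F of size k, RSCU(c) = k * count(c) /
#' sum(counts over F) — the count divided by the mean count of its
#' synonymous family.  A family with zero total has RSCU reported as 0
#' for all members and is flagged.  Single-codon families have RSCU 1
#' whenever counted.  Under the `"table8-standard"` partition the UGA/UGG
#' rows are flagged as dialect artifacts (UGA sits in the 3-codon
#' standard stop family whose UAA/UAG counts are excluded, giving it
#' RSCU 3 whenever counted).
#'
#' @param counts named integer vector over the 64 codons (as returned by
#'   [countCodons()]), or any named numeric vector of codon counts —
#'   codons not named are taken as 0.
#' @param code a [GeneticCode-class] carrying the family partition.
#' @param genomeId identifier stored in the result.
#' @return a [CodonUsageTable-class].
#' @examples
#' code <- geneticCode(5L, "table8-standard")
#' cnt <- c(TTA = 430, TTG = 116, CTT = 104, CTC = 2, CTA = 55, CTG = 12)
#' round(rscuValues(rscu(cnt, code))[["TTA"]], 2)  # 3.59
#' @export
rscu <- function(counts, code = geneticCode(5L), genomeId = "genome") {
  full <- integer(64L)
  names(full) <- .CODONS
  if (is.null(names(counts))) stop("counts must be a named vector")
  nm <- chartr("Uu", "Tt", toupper(names(counts)))
  unknown <- setdiff(nm, .CODONS)
  if (length(unknown))
    stop("codon absent from partition: ", paste(unknown, collapse = ", "))
  full[nm] <- as.integer(round(counts))
  fam <- code@family
  vals <- numeric(64L)
  names(vals) <- .CODONS
  flags <- character(0)
  for (f in unique(fam)) {
    i <- names(fam)[fam == f]
    k <- length(i)
    tot <- sum(full[i])
    if (tot == 0L) {
      vals[i] <- 0
      if (f != "*") flags <- c(flags, paste0("family ", f,
                                             ": zero total, RSCU undefined (reported 0)"))
    } else {
      vals[i] <- k * full[i] / tot
    }
  }
  if (code@partitionId == "table8-standard")
    flags <- c(flags,
               "dialect: TGA counted within the 3-codon standard stop family (RSCU 3 when counted); TGG a single-codon family (RSCU 1)")
  new("CodonUsageTable", genomeId = genomeId, code = code,
      counts = full, rscu = vals, totalCodons = sum(full),
      nSkipped = as.integer(attr(counts, "n_skipped") %||% 0L),
      excludedStops = as.character(attr(counts, "excluded_stops") %||% character(0)),
      flags = flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Codon usage table for a genome's PCG set
#'
#' Convenience wrapper: extract CDS, count codons, compute RSCU.
#' @param genome an [AnnotatedGenome-class].
#' @param code a [GeneticCode-class].
#' @param excludeStopCounts see [countCodons()].
#' @return a [CodonUsageTable-class].
#' @export
codonUsage <- function(genome, code = geneticCode(5L),
                       excludeStopCounts = TRUE) {
  cds <- extractCDS(genome, code)
  cnt <- countCodons(cds, code, excludeStopCounts)
  rscu(cnt, code, genomeId = genome@id)
}

#' Start/stop codon profile of a genome's PCGs
#'
#' One row per PCG in genome order: name, length (bp), literal first and
#' last codon of the oriented CDS, direction, and whether the start codon
#' is canonical under the code's initiation set.
#'
#' @param genome an [AnnotatedGenome-class] with PCG features.
#' @param code a [GeneticCode-class].
#' @return data.frame with columns name, copy_index, length_bp,
#'   start_codon, stop_codon, direction, canonical_start.
#' @export
startStopTable <- function(genome, code = geneticCode(5L)) {
  cds <- extractCDS(genome, code)
  f <- genome@features[genome@features$class == "PCG", , drop = FALSE]
  data.frame(
    name = cds$name, copy_index = cds$copy_index,
    length_bp = nchar(cds$seq),
    start_codon = substr(cds$seq, 1L, 3L),
    stop_codon = substring(cds$seq, nchar(cds$seq) - 2L),
    direction = f$strand,
    canonical_start = substr(cds$seq, 1L, 3L) %in% code@startCodons,
    stringsAsFactors = FALSE)
}

#' Amino-acid usage totals, ranked
#'
#' Sums codon counts per family label of the code's partition; stop
#' families are dropped.  Descending order, ties broken alphabetically.
#'
#' @param counts named codon counts (see [rscu()]).
#' @param code a [GeneticCode-class].
#' @return named numeric vector of totals, sorted.
#' @export
aaUsageRanking <- function(counts, code = geneticCode(5L)) {
  full <- numeric(64L)
  names(full) <- .CODONS
  nm <- chartr("Uu", "Tt", toupper(names(counts)))
  full[nm] <- as.numeric(counts)
  fam <- code@family
  tot <- tapply(full, fam[names(full)], sum)
  tot <- tot[names(tot) != "*"]
  tot <- tot[order(-tot, names(tot))]
  structure(as.numeric(tot), names = names(tot))
}

#' Third-position degeneracy class of each codon
#'
#' Degeneracy of a codon's third position = number of third-position
#' states (including its own) coding the same amino acid under `code`;
#' substitutions to stop codons are not counted as synonymous states.
#' Stop codons themselves get NA.
#'
#' @param code a [GeneticCode-class].
#' @return named integer vector over the 64 codons with values 1-4 (NA
#'   for stops).
#' @export
degeneracyClasses <- function(code = geneticCode(5L)) {
  aa <- code@codonToAa
  out <- vapply(.CODONS, function(cod) {
    if (aa[[cod]] == "*") return(NA_integer_)
    alt <- paste0(substr(cod, 1, 2), c("T", "C", "A", "G"))
    sum(aa[alt] == aa[[cod]])
  }, integer(1))
  out
}

#' Base composition at third codon positions stratified by degeneracy
#'
#' Counts A/C/G/T at the third position of every counted codon, grouped
#' by the third-position degeneracy class (1-, 2-, 3-, 4-fold) of that
#' codon under `code`, and reports the AT fraction per class.
#'
#' @param cdsList CDS sequences (as for [countCodons()]) OR a named codon
#'   count vector (names = codons); counts let published codon tables be
#'   analysed directly.
#' @param code a [GeneticCode-class].
#' @return data.frame with columns degeneracy, A, C, G, T, n_codons,
#'   at_fraction.
#' @export
degenerateSiteComposition <- function(cdsList, code = geneticCode(5L)) {
  counts <- if (is.numeric(cdsList) && !is.null(names(cdsList))) {
    full <- numeric(64L); names(full) <- .CODONS
    nm <- chartr("Uu", "Tt", toupper(names(cdsList)))
    full[nm] <- as.numeric(cdsList)
    full
  } else {
    as.numeric(countCodons(cdsList, code, excludeStopCounts = TRUE))
  }
  names(counts) <- .CODONS
  deg <- degeneracyClasses(code)
  third <- substring(.CODONS, 3L, 3L)
  rows <- lapply(1:4, function(d) {
    i <- which(!is.na(deg) & deg == d)
    b <- vapply(c("A", "C", "G", "T"),
                function(x) sum(counts[i][third[i] == x]), numeric(1))
    n <- sum(b)
    data.frame(degeneracy = d, A = b[["A"]], C = b[["C"]], G = b[["G"]],
               T = b[["T"]], n_codons = n,
               at_fraction = if (n > 0) (b[["A"]] + b[["T"]]) / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a codon usage table as TSV
#'
#' Columns codon (RNA alphabet), aa (translation label), family
#' (partition label), count, RSCU (2 dp, half-up, the convention of
#' printed codon tables).
#' @param cut a [CodonUsageTable-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCodonUsageTable <- function(cut, path) {
  codons <- .CODONS
  out <- data.frame(
    codon = chartr("T", "U", codons),
    aa = cut@code@codonToAa[codons],
    family = cut@code@family[codons],
    count = cut@counts[codons],
    RSCU = roundHalfUp(cut@rscu[codons], 2L),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Round half away from zero
#'
#' Printed codon tables round 2.845 to 2.85 (half-up), unlike R's
#' banker's rounding.
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
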