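#' @import methods
NULL

#' Genetic code with an explicit synonymous-family partition
#'
#' Wraps a standard translation table (NCBI numbering; 1 = standard,
#' 5 = invertebrate mitochondrial) together with the partition of the 64
#' codons into synonymous families used for RSCU.  The partition is kept
#' separate from the translation table because published mitogenome codon
#' tables are frequently computed with standard-code families even when
#' translation uses the mitochondrial table: the `"table8-standard"`
#' partition reproduces that convention, `"table5-mito"` groups codons by
#' their translation under the table actually in use.
#'
#' @slot tableId integer translation table id (1 or 5).
#' @slot codonToAa named character of length 64, codon (DNA alphabet) to
#'   one-letter amino acid; stop is `"*"`.
#' @slot startCodons character vector of initiation codons.
#' @slot partitionId `"table8-standard"` or `"table5-mito"`.
#' @slot family named character of length 64 assigning each codon to a
#'   synonymous family label.
#' @exportClass GeneticCode
setClass("GeneticCode",
  representation(
    tableId = "integer",
    codonToAa = "character",
    startCodons = "character",
    partitionId = "character",
    family = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonToAa) != 64L || is.null(names(object@codonToAa)))
    msg <- c(msg, "codonToAa must be a named vector over all 64 codons")
  if (length(object@family) != 64L)
    msg <- c(msg, "family must assign all 64 codons")
  if (!identical(sort(names(object@codonToAa)), sort(names(object@family))))
    msg <- c(msg, "codonToAa and family must be over the same codons")
  if (any(table(object@family) < 1L))
    msg <- c(msg, "every family must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Annotated (circular) mitochondrial genome
#'
#' Holds one nucleotide sequence over {A,C,G,T,N} plus its typed gene
#' features, 0-based half-open coordinates, sorted by start.  Features that
#' spanned the origin of a circular record are linearized at read time by
#' rotating the sequence; the rotation is recorded in `originOffset`.
#'
#' @slot id accession-like identifier.
#' @slot sequence upper-case nucleotide string.
#' @slot circular logical.
#' @slot features data.frame with columns `name`, `class`
#'   (PCG/tRNA/rRNA/control_region/other), `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `copy_index`.
#' @slot sourceFormat one of "genbank", "fasta", "synthetic".
#' @slot originOffset integer rotation applied at read time (bases).
#' @exportClass AnnotatedGenome
setClass("AnnotatedGenome",
  representation(
    id = "character",
    sequence = "character",
    circular = "logical",
    features = "data.frame",
    sourceFormat = "character",
    originOffset = "integer"
  ),
  prototype(sourceFormat = "synthetic", originOffset = 0L)
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  s <- object@sequence
  if (length(s) != 1L || nchar(s) == 0L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", s))
    msg <- c(msg, "sequence may only contain A, C, G, T, N (upper case)")
  f <- object@features
  need <- c("name", "class", "start", "end", "strand", "copy_index")
  if (!all(need %in% names(f)))
    msg <- c(msg, paste("features must have columns:", paste(need, collapse = ", ")))
  else if (nrow(f)) {
    if (any(f$start < 0L) || any(f$end > nchar(s)))
      msg <- c(msg, "feature interval outside [0, genome length)")
    if (any(f$start >= f$end))
      msg <- c(msg, "feature start must be < end after linearization")
    if (is.unsorted(f$start))
      msg <- c(msg, "features must be sorted by start coordinate")
    if (anyDuplicated(paste(f$name, f$copy_index)))
      msg <- c(msg, "(name, copy_index) must be unique")
    pcg <- f$class == "PCG"
    if (any(pcg) && any((f$end - f$start)[pcg] < 3L))
      msg <- c(msg, "PCG features must be at least 3 bp")
  }
  if (length(msg)) msg else TRUE
})

#' Gene order of a genome
#'
#' Ordered gene labels (with strand) from one linearization of a genome.
#' Strand may be NA for orders read from plain label lists; NA strands
#' match any strand in cluster comparisons.
#'
#' @slot id genome identifier.
#' @slot labels character vector of gene labels (duplicates keep copy
#'   suffixes out of the label; multiplicity is positional).
#' @slot strand character vector, "+"/"-"/NA, same length as labels.
#' @slot circular logical.
#' @exportClass GeneOrder
setClass("GeneOrder",
  representation(
    id = "character",
    labels = "character",
    strand = "character",
    circular = "logical"
  )
)

setValidity("GeneOrder", function(object) {
  msg <- character()
  if (length(object@labels) < 1L)
    msg <- c(msg, "gene order must contain at least one label")
  if (any(!nzchar(object@labels)))
    msg <- c(msg, "labels must be non-empty")
  if (length(object@strand) != length(object@labels))
    msg <- c(msg, "strand and labels must have equal length")
  if (length(msg)) msg else TRUE
})

#' Codon usage table with RSCU
#'
#' Per-codon counts over one genome's protein-coding gene set plus RSCU
#' under the partition carried by the GeneticCode used.
#'
#' @slot genomeId identifier of the source genome / CDS set.
#' @slot code the [GeneticCode-class] used.
#' @slot counts named integer over 64 codons (excluded stop codons held
#'   at zero).
#' @slot rscu named numeric over 64 codons.
#' @slot totalCodons integer, sum of counts.
#' @slot nSkipped codons containing N, skipped.
#' @slot excludedStops stop codons whose counts were removed.
#' @slot flags character notes (zero-total families, partition dialect
#'   artifacts such as a stop-family UGA row).
#' @exportClass CodonUsageTable
setClass("CodonUsageTable",
  representation(
    genomeId = "character",
    code = "GeneticCode",
    counts = "integer",
    rscu = "numeric",
    totalCodons = "integer",
    nSkipped = "integer",
    excludedStops = "character",
    flags = "character"
  )
)

setValidity("CodonUsageTable", function(object) {
  msg <- character()
  if (length(object@counts) != 64L || length(object@rscu) != 64L)
    msg <- c(msg, "counts and rscu must cover all 64 codons")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (!isTRUE(all.equal(sum(object@counts), object@totalCodons)))
    msg <- c(msg, "totalCodons must equal the sum of counts")
  if (length(msg)) msg else TRUE
})

#' Gap-free codon alignment of two coding sequences
#'
#' @slot gene gene name.
#' @slot codons1,codons2 character vectors of aligned codons (no gaps, no N).
#' @slot nCodons number of aligned codon columns.
#' @slot droppedColumns number of protein-alignment columns dropped
#'   (gaps or codons containing N or stops).
#' @slot alignedProteins the two gapped protein rows the alignment came from.
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(
    gene = "character",
    codons1 = "character",
    codons2 = "character",
    nCodons = "integer",
    droppedColumns = "integer",
    alignedProteins = "character"
  )
)

setValidity("CodonAlignment", function(object) {
  msg <- character()
  if (length(object@codons1) != length(object@codons2))
    msg <- c(msg, "both codon rows must have equal length")
  if (length(object@codons1) < 1L)
    msg <- c(msg, "alignment must contain at least one codon column")
  if (any(nchar(c(object@codons1, object@codons2)) != 3L))
    msg <- c(msg, "codons must be 3-mers")
  if (any(grepl("[-N]", c(object@codons1, object@codons2))))
    msg <- c(msg, "codon columns may not contain gaps or N")
  if (length(msg)) msg else TRUE
})

#' Result of a pairwise Ka/Ks estimate for one gene pair
#'
#' @slot method "NG86" or "YN00".
#' @slot gene gene name.
#' @slot pair label of the genome pair.
#' @slot S,N synonymous / nonsynonymous sites.
#' @slot Sd,Nd synonymous / nonsynonymous differences (pathway-averaged).
#' @slot kappa transition/transversion ratio (YN00 only, NA otherwise).
#' @slot ka,ks corrected rates per site; NA when the distance correction
#'   is undefined.
#' @slot ratio Ka/Ks, NA when Ks is 0 or undefined.
#' @slot fisherP two-sided Fisher exact p for the site/difference table.
#' @slot nCodons aligned codon columns used.
#' @slot converged logical (YN00 iteration), NA for NG86.
#' @slot notes character vector of warnings (skipped codon pairs etc.).
#' @exportClass KaKsResult
setClass("KaKsResult",
  representation(
    method = "character",
    gene = "character",
    pair = "character",
    S = "numeric", N = "numeric",
    Sd = "numeric", Nd = "numeric",
    kappa = "numeric",
    ka = "numeric", ks = "numeric",
    ratio = "numeric",
    fisherP = "numeric",
    nCodons = "integer",
    converged = "logical",
    notes = "character"
  ),
  prototype(gene = NA_character_, pair = NA_character_,
            kappa = NA_real_, fisherP = NA_real_,
            converged = NA, notes = character())
)

setValidity("KaKsResult", function(object) {
  msg <- character()
  if (!object@method %in% c("NG86", "YN00"))
    msg <- c(msg, "method must be NG86 or YN00")
  if (isTRUE(abs(object@S + object@N - 3 * object@nCodons) > 1e-6))
    msg <- c(msg, "S + N must equal 3 * nCodons")
  if (isTRUE(object@S < 0) || isTRUE(object@N < 0))
    msg <- c(msg, "sites must be non-negative")
  if (length(msg)) msg else TRUE
})
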