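# Generics and accessors for the central classes.

#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @export
setGeneric("isCircularGenome", function(x) standardGeneric("isCircularGenome"))
#' @export
setGeneric("geneLabels", function(x) standardGeneric("geneLabels"))
#' @export
setGeneric("geneStrands", function(x) standardGeneric("geneStrands"))
#' @export
setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))
#' @export
setGeneric("rscuValues", function(x) standardGeneric("rscuValues"))
#' @export
setGeneric("kaksRatio", function(x) standardGeneric("kaksRatio"))

#' @describeIn AnnotatedGenome-class accession-like identifier
#' @param x object
#' @export
setMethod("genomeId", "AnnotatedGenome", function(x) x@id)
#' @describeIn AnnotatedGenome-class nucleotide sequence (character)
#' @export
setMethod("genomeSeq", "AnnotatedGenome", function(x) x@sequence)
#' @describeIn AnnotatedGenome-class feature table (data.frame)
#' @export
setMethod("genomeFeatures", "AnnotatedGenome", function(x) x@features)
#' @describeIn AnnotatedGenome-class circular flag
#' @export
setMethod("isCircularGenome", "AnnotatedGenome", function(x) x@circular)

#' @describeIn GeneOrder-class identifier
#' @export
setMethod("genomeId", "GeneOrder", function(x) x@id)
#' @describeIn GeneOrder-class ordered gene labels
#' @export
setMethod("geneLabels", "GeneOrder", function(x) x@labels)
#' @describeIn GeneOrder-class strand per gene ("+"/"-"/NA)
#' @export
setMethod("geneStrands", "GeneOrder", function(x) x@strand)

#' @describeIn CodonUsageTable-class named per-codon counts
#' @export
setMethod("codonCounts", "CodonUsageTable", function(x) x@counts)
#' @describeIn CodonUsageTable-class named per-codon RSCU values
#' @export
setMethod("rscuValues", "CodonUsageTable", function(x) x@rscu)

#' @describeIn KaKsResult-class the Ka/Ks ratio (NA when undefined)
#' @export
setMethod("kaksRatio", "KaKsResult", function(x) x@ratio)

setMethod("show", "AnnotatedGenome", function(object) {
  cls <- table(object@features$class)
  cat("AnnotatedGenome", object@id, "-", nchar(object@sequence), "bp,",
      if (object@circular) "circular," else "linear,",
      nrow(object@features), "features\n")
  if (length(cls))
    cat("  ", paste(names(cls), as.integer(cls), sep = ":", collapse = "  "), "\n")
})

setMethod("show", "GeneOrder", function(object) {
  cat("GeneOrder", object@id,
      if (object@circular) "(circular):" else "(linear):",
      paste(head(object@labels, 12), collapse = "-"),
      if (length(object@labels) > 12) "..." else "", "\n")
})

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode table", object@tableId,
      "| partition:", object@partitionId,
      "|", length(object@startCodons), "start codons\n")
})

setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable", object@genomeId, "-", object@totalCodons,
      "codons counted (", object@nSkipped, "skipped,",
      "stops excluded:", paste(object@excludedStops, collapse = ","), ")\n")
})

setMethod("show", "KaKsResult", function(object) {
  cat(sprintf("KaKsResult [%s] %s: Ka=%.4g Ks=%.4g Ka/Ks=%.4g (S=%.1f N=%.1f, p=%.3g)\n",
              object@method,
              ifelse(is.na(object@gene), "", object@gene),
              object@ka, object@ks, object@ratio,
              object@S, object@N, object@fisherP))
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment", object@gene, "-", object@nCodons,
      "codon columns (", object@droppedColumns, "dropped )\n")
})
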