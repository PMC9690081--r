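# Base composition, GC/AT content, strand skews and per-feature-class
# genome proportions.

#' Base composition and strand skew of a nucleotide sequence
#'
#' Percentages are computed over counted A/C/G/T; N is excluded from the
#' denominator and reported separately.  AT skew = (A - T)/(A + T),
#' GC skew = (G - C)/(G + C); an undefined skew (empty denominator) is
#' reported as 0 with the corresponding flag set.
#'
#' @param seq non-empty nucleotide string (A,C,G,T,N).
#' @return data.frame with one row: counts `A`,`C`,`G`,`T`,`N_count`,
#'   percentages `A_pct` ... `T_pct`, `GC_pct`, `AT_pct`, `at_skew`,
#'   `gc_skew`, `size_bp`, and flags `at_skew_undefined`,
#'   `gc_skew_undefined`.
#' @examples
#' baseComposition("ACGT")  # 25% each, both skews 0
#' @export
baseComposition <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("sequence must be a single non-empty string")
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  cnt <- vapply(c("A", "C", "G", "T", "N"), function(b) sum(ch == b), 0L)
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence contains no A/C/G/T bases")
  pct <- 100 * cnt[c("A", "C", "G", "T")] / denom
  atU <- (cnt[["A"]] + cnt[["T"]]) == 0L
  gcU <- (cnt[["G"]] + cnt[["C"]]) == 0L
  data.frame(
    A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
    N_count = cnt[["N"]],
    A_pct = pct[["A"]], C_pct = pct[["C"]], G_pct = pct[["G"]],
    T_pct = pct[["T"]],
    GC_pct = pct[["G"]] + pct[["C"]],
    AT_pct = pct[["A"]] + pct[["T"]],
    at_skew = if (atU) 0 else (cnt[["A"]] - cnt[["T"]]) / (cnt[["A"]] + cnt[["T"]]),
    gc_skew = if (gcU) 0 else (cnt[["G"]] - cnt[["C"]]) / (cnt[["G"]] + cnt[["C"]]),
    size_bp = nchar(seq),
    at_skew_undefined = atU, gc_skew_undefined = gcU,
    stringsAsFactors = FALSE)
}

#' Per-feature-class composition summary of an annotated genome
#'
#' One row per class in {whole_genome, PCG, tRNA, rRNA, control_region}.
#' The per-class sequence is the concatenation of that class's feature
#' slices in strand orientation (minus-strand slices reverse-complemented).
#' Overlapping features are counted per class independently, so class
#' proportions can sum above 100 across classes when genes are duplicated
#' or overlap.  Absent classes are omitted with a message.
#'
#' @param genome an [AnnotatedGenome-class].
#' @return data.frame: column `class` plus all [baseComposition()] columns
#'   plus `proportion_pct` (class bp / genome bp * 100).
#' @export
featureClassSummary <- function(genome) {
  L <- nchar(genome@sequence)
  classes <- c("PCG", "tRNA", "rRNA", "control_region")
  rows <- list(cbind(data.frame(class = "whole_genome",
                                stringsAsFactors = FALSE),
                     baseComposition(genome@sequence),
                     proportion_pct = 100))
  f <- genome@features
  for (cl in classes) {
    fi <- f[f$class == cl, , drop = FALSE]
    if (!nrow(fi)) {
      message("feature class absent, row omitted: ", cl)
      next
    }
    slices <- vapply(seq_len(nrow(fi)), function(i) {
      s <- substr(genome@sequence, fi$start[i] + 1L, fi$end[i])
      if (fi$strand[i] == "-") .revComp(s) else s
    }, character(1))
    seqCl <- paste(slices, collapse = "")
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(class = cl, stringsAsFactors = FALSE),
            baseComposition(seqCl),
            proportion_pct = 100 * nchar(seqCl) / L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature-class composition table as TSV
#'
#' Percentages rounded to 1 decimal, mirroring the usual mitogenome
#' feature table layout (A% C% G% T% GC% size proportion).
#' @param summary output of [featureClassSummary()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCompositionTable <- function(summary, path) {
  out <- data.frame(
    class = summary$class,
    A_pct = round(summary$A_pct, 1), C_pct = round(summary$C_pct, 1),
    G_pct = round(summary$G_pct, 1), T_pct = round(summary$T_pct, 1),
    GC_pct = round(summary$GC_pct, 1),
    size_bp = summary$size_bp,
    proportion_pct = round(summary$proportion_pct, 2),
    at_skew = round(summary$at_skew, 3), gc_skew = round(summary$gc_skew, 3),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
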