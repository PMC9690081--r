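# Reading/writing annotated mitochondrial genomes and extracting the
# pieces downstream stages consume (CDS sets, gene orders).

## ---- gene label normalization ------------------------------------------

# Mixed spellings found in deposited mitogenome records -> canonical labels.
.LABEL_ALIASES <- c(
  "COI" = "COX1", "CO1" = "COX1", "COXI" = "COX1", "cox1" = "COX1",
  "COII" = "COX2", "CO2" = "COX2", "COXII" = "COX2", "cox2" = "COX2",
  "COIII" = "COX3", "CO3" = "COX3", "COXIII" = "COX3", "cox3" = "COX3",
  "CYB" = "CYTB", "COB" = "CYTB", "cytb" = "CYTB", "cob" = "CYTB",
  "NAD1" = "ND1", "NAD2" = "ND2", "NAD3" = "ND3", "NAD4" = "ND4",
  "NAD4L" = "ND4L", "NAD5" = "ND5", "NAD6" = "ND6", "NADH1" = "ND1",
  "NADH2" = "ND2", "NADH3" = "ND3", "NADH4" = "ND4", "NADH4L" = "ND4L",
  "NADH5" = "ND5", "NADH6" = "ND6",
  "ATPASE6" = "ATP6", "ATPASE8" = "ATP8", "ATP_6" = "ATP6", "ATP_8" = "ATP8",
  "L-RRNA" = "rrnL", "S-RRNA" = "rrnS", "16S" = "rrnL", "12S" = "rrnS",
  "RRN16" = "rrnL", "RRN12" = "rrnS", "LRRNA" = "rrnL", "SRRNA" = "rrnS",
  "16S RIBOSOMAL RNA" = "rrnL", "12S RIBOSOMAL RNA" = "rrnS",
  "RRNL" = "rrnL", "RRNS" = "rrnS",
  "CONTROL REGION" = "D-loop", "D-LOOP" = "D-loop", "DLOOP" = "D-loop"
)

#' Normalize a gene label to the canonical scheme
#'
#' Canonical labels: COX1/COX2/COX3, ND1-ND6, ND4L, ATP6/ATP8, CYTB,
#' trnX-ANTICODON, rrnS/rrnL, D-loop.  Unknown labels pass through
#' unchanged.
#' @param label character vector of raw labels.
#' @return character vector of canonical labels.
#' @export
normalizeGeneLabel <- function(label) {
  vapply(label, function(x) {
    key <- toupper(trimws(x))
    if (key %in% names(.LABEL_ALIASES)) return(unname(.LABEL_ALIASES[key]))
    if (grepl("^TRN", key)) {
      # keep tRNA labels in trnX-ANTICODON form, preserving case style
      body <- sub("^TRN", "", key)
      return(paste0("trn", body))
    }
    # already canonical?
    if (key %in% c("COX1", "COX2", "COX3", "CYTB", "ATP6", "ATP8",
                   paste0("ND", 1:6), "ND4L"))
      return(key)
    x
  }, character(1), USE.NAMES = FALSE)
}

.emptyFeatures <- function() {
  data.frame(name = character(), class = character(),
             start = integer(), end = integer(),
             strand = character(), copy_index = integer(),
             stringsAsFactors = FALSE)
}

.finalizeFeatures <- function(f) {
  if (!nrow(f)) return(.emptyFeatures())
  f <- f[order(f$start, f$end), , drop = FALSE]
  f$copy_index <- stats::ave(seq_len(nrow(f)), f$name,
                             FUN = seq_along)
  rownames(f) <- NULL
  f
}

.checkSequence <- function(seq) {
  seq <- toupper(seq)
  bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
  if (length(bad))
    stop("sequence contains unsupported IUPAC ambiguity letters: ",
         paste(bad, collapse = ", "), " (only N is allowed)")
  seq
}

#' Construct an AnnotatedGenome
#'
#' @param id identifier.
#' @param sequence nucleotide string over A,C,G,T,N (case-folded to upper).
#' @param features data.frame with columns name, class, start, end
#'   (0-based half-open), strand, and optionally copy_index (reassigned in
#'   coordinate order).
#' @param circular logical.
#' @param sourceFormat provenance tag.
#' @param originOffset rotation (bases) applied when linearizing.
#' @return an [AnnotatedGenome-class].
#' @export
annotatedGenome <- function(id, sequence, features = .emptyFeatures(),
                            circular = TRUE, sourceFormat = "synthetic",
                            originOffset = 0L) {
  sequence <- .checkSequence(sequence)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  new("AnnotatedGenome", id = id, sequence = sequence,
      circular = circular, features = .finalizeFeatures(features),
      sourceFormat = sourceFormat, originOffset = as.integer(originOffset))
}

## ---- GenBank flat file I/O ---------------------------------------------

.parseGbLocation <- function(loc) {
  loc <- gsub("[<> ]", "", loc)
  comp <- FALSE
  while (grepl("^(complement|join|order)\\(", loc)) {
    if (grepl("^complement\\(", loc)) comp <- !comp
    loc <- sub("^(complement|join|order)\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  iv <- do.call(rbind, lapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else se <- rep(as.integer(p), 2L)
    se
  }))
  list(intervals = iv, complement = comp)
}

.gbFeatureClass <- function(key, note) {
  switch(key,
         "CDS" = "PCG",
         "tRNA" = "tRNA",
         "rRNA" = "rRNA",
         "D-loop" = "control_region",
         if (grepl("control region|D-loop", note, ignore.case = TRUE))
           "control_region" else "other")
}

#' Read a GenBank flat file into an AnnotatedGenome
#'
#' Parses the LOCUS line, feature table and ORIGIN sequence of a single
#' GenBank record.  CDS/tRNA/rRNA/D-loop features are mapped to feature
#' classes; gene labels are normalized via [normalizeGeneLabel()];
#' duplicated names get copy_index 2, 3, ... in coordinate order.
#' Features written as a join across the origin of a circular record are
#' linearized by rotating the sequence; the rotation is recorded in the
#' `originOffset` slot.  Unknown labels are kept with class "other" and a
#' warning.
#'
#' @param path path to a GenBank flat file.
#' @return an [AnnotatedGenome-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) stop("GenBank record has no ORIGIN sequence block: ", path)
  endRec <- grep("^//", lines)
  endRec <- if (length(endRec)) endRec[endRec > oi[1]][1] else length(lines) + 1L
  seqLines <- lines[(oi[1] + 1L):(endRec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nchar(sequence)) stop("GenBank record has an empty sequence: ", path)
  sequence <- .checkSequence(sequence)
  L <- nchar(sequence)

  fi <- grep("^FEATURES", lines)
  feats <- .emptyFeatures()
  wrapStart <- NA_integer_
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    # group physical lines into logical feature/qualifier units
    isKey <- grepl("^ {5}\\S", block)
    keyIdx <- which(isKey)
    recs <- list()
    for (k in seq_along(keyIdx)) {
      from <- keyIdx[k]
      to <- if (k < length(keyIdx)) keyIdx[k + 1] - 1L else length(block)
      recs[[k]] <- block[from:to]
    }
    for (rec in recs) {
      head1 <- rec[1]
      key <- sub("^ {5}(\\S+).*$", "\\1", head1)
      if (key %in% c("source", "gene")) next  # gene rows duplicate CDS/tRNA rows
      rest <- trimws(sub("^ {5}\\S+\\s*", "", head1))
      qlines <- if (length(rec) > 1) trimws(rec[-1]) else character()
      # location may continue over lines until the first qualifier
      qstart <- which(grepl("^/", qlines))
      locCont <- if (length(qstart)) qlines[seq_len(min(qstart) - 1L)] else qlines
      quals <- if (length(qstart)) qlines[min(qstart):length(qlines)] else character()
      loc <- paste0(rest, paste(locCont, collapse = ""))
      getQ <- function(name) {
        hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
      }
      gene <- getQ("gene"); product <- getQ("product"); note <- getQ("note")
      pl <- tryCatch(.parseGbLocation(loc),
                     error = function(e) stop("unparseable location '", loc,
                                              "' in ", path))
      iv <- pl$intervals
      if (any(iv < 1L) || any(iv > L))
        stop("feature location outside sequence [1,", L, "]: ", loc)
      label <- if (!is.na(gene)) gene else if (!is.na(product)) product else key
      label <- normalizeGeneLabel(label)
      cls <- .gbFeatureClass(key, paste(na.omit(c(note, product)), collapse = " "))
      if (cls == "other" && key %in% c("CDS", "tRNA", "rRNA"))
        cls <- .gbFeatureClass(key, "")
      start1 <- iv[1, 1]; end1 <- iv[nrow(iv), 2]
      if (nrow(iv) == 2L && iv[1, 2] == L && iv[2, 1] == 1L) {
        # wrap-around join over the origin; end encodes start + true length
        wrapStart <- iv[1, 1]
        lenWrap <- (L - iv[1, 1] + 1L) + iv[2, 2]
        feats <- rbind(feats, data.frame(
          name = label, class = cls,
          start = iv[1, 1] - 1L, end = iv[1, 1] - 1L + lenWrap,
          strand = if (pl$complement) "-" else "+", copy_index = 1L,
          stringsAsFactors = FALSE))
        next
      }
      if (nrow(iv) > 1L) {
        start1 <- min(iv[, 1]); end1 <- max(iv[, 2])
      }
      if (start1 > end1) stop("feature start after end: ", loc)
      feats <- rbind(feats, data.frame(
        name = label, class = cls,
        start = start1 - 1L, end = end1,
        strand = if (pl$complement) "-" else "+", copy_index = 1L,
        stringsAsFactors = FALSE))
    }
  }

  originOffset <- 0L
  if (!is.na(wrapStart)) {
    if (!circular)
      stop("wrap-around feature in a non-circular record: ", path)
    originOffset <- wrapStart - 1L
    sequence <- paste0(substr(sequence, wrapStart, L),
                       substr(sequence, 1L, wrapStart - 1L))
    len <- feats$end - feats$start
    feats$start <- (feats$start - originOffset) %% L
    feats$end <- feats$start + len
    if (any(feats$end > L))
      stop("more than one feature spans the origin; cannot linearize")
  }

  unknown <- feats$class == "other"
  if (any(unknown))
    warning("features kept with class 'other': ",
            paste(unique(feats$name[unknown]), collapse = ", "))
  annotatedGenome(id = id, sequence = sequence, features = feats,
                  circular = circular, sourceFormat = "genbank",
                  originOffset = originOffset)
}

#' Write an AnnotatedGenome as a GenBank flat file
#'
#' Minimal writer covering the fields [readGenBank()] consumes (LOCUS,
#' feature table with /gene qualifiers, ORIGIN).  Round-trips feature
#' names, classes, coordinates and strands.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenBank <- function(genome, path) {
  L <- nchar(genome@sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNK",
                     genome@id, L,
                     if (genome@circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion.", genome@id), con)
  writeLines(sprintf("ACCESSION   %s", genome@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  keyOf <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
             control_region = "D-loop", other = "misc_feature")
  f <- genome@features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", keyOf[[f$class[i]]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome@sequence)
  pos <- seq(1L, L, by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

## ---- FASTA -------------------------------------------------------------

#' Read a FASTA file
#' @param path FASTA file.
#' @return named character vector of upper-case sequences (names = record ids).
#' @export
readFastaSeqs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA file: ", path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#' @param records named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFastaSeqs <- function(records, path) {
  ss <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## ---- CDS extraction, gene order, feature table -------------------------

.revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract coding sequences from an annotated genome
#'
#' Minus-strand features are reverse-complemented into reading
#' orientation; proteins are translated with `code`, dropping the trailing
#' stop.  A CDS whose length is not divisible by 3 has its trailing 1-2
#' bases dropped for translation (flagged); internal stops are flagged,
#' not fatal.
#'
#' @param genome an [AnnotatedGenome-class] with at least one PCG feature.
#' @param code a [GeneticCode-class].
#' @return data.frame with columns name, copy_index, seq, protein,
#'   internal_stop, len_mod3.
#' @export
extractCDS <- function(genome, code = geneticCode(5L)) {
  f <- genome@features[genome@features$class == "PCG", , drop = FALSE]
  if (!nrow(f)) stop("genome has no PCG features")
  out <- lapply(seq_len(nrow(f)), function(i) {
    s <- substr(genome@sequence, f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") s <- .revComp(s)
    lenMod <- nchar(s) %% 3L
    sTr <- if (lenMod) substr(s, 1L, nchar(s) - lenMod) else s
    prot <- translateCodons(sTr, code)
    trailingStop <- grepl("\\*$", prot)
    if (trailingStop) prot <- sub("\\*$", "", prot)
    internal <- grepl("\\*", prot)
    data.frame(name = f$name[i], copy_index = f$copy_index[i],
               seq = s, protein = prot,
               internal_stop = internal, len_mod3 = lenMod != 0L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(res$internal_stop))
    message("CDS with internal stop codon(s): ",
            paste(res$name[res$internal_stop], collapse = ", "))
  if (any(res$len_mod3))
    message("CDS length not divisible by 3 (trailing bases dropped for translation): ",
            paste(res$name[res$len_mod3], collapse = ", "))
  res
}

#' Gene order of a genome
#'
#' Ordered (label, strand) list of the features in the requested classes,
#' by start coordinate from the genome's recorded linearization origin.
#' Duplicates keep their positional multiplicity.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param classes feature classes to include.
#' @return a [GeneOrder-class].
#' @export
geneOrderOf <- function(genome,
                        classes = c("PCG", "tRNA", "rRNA", "control_region")) {
  f <- genome@features[genome@features$class %in% classes, , drop = FALSE]
  geneOrder(f$name, strand = f$strand, id = genome@id,
            circular = genome@circular)
}

#' Construct a GeneOrder from labels
#'
#' @param labels character vector of gene labels, or a single
#'   dash-separated string ("COX1-trnM-ND2").
#' @param strand optional strand vector ("+"/"-"); NA strands match any
#'   strand in comparisons.
#' @param id identifier.
#' @param circular logical.
#' @return a [GeneOrder-class].
#' @export
geneOrder <- function(labels, strand = NA, id = "order", circular = TRUE) {
  if (length(labels) == 1L && grepl("-", labels) &&
      !grepl("^trn", labels) && labels != "D-loop")
    labels <- strsplit(labels, "-")[[1]]
  strand <- rep_len(as.character(strand), length(labels))
  new("GeneOrder", id = id, labels = as.character(labels),
      strand = strand, circular = circular)
}

#' Read a gene order from a plain-text file
#'
#' One label per line, optionally `label:strand`; or a single
#' dash-separated line.
#' @param path file path.
#' @param id identifier (defaults to the file name).
#' @param circular logical.
#' @return a [GeneOrder-class].
#' @export
readGeneOrder <- function(path, id = tools::file_path_sans_ext(basename(path)),
                          circular = TRUE) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !grepl("^#", ln)]
  if (!length(ln)) stop("empty gene-order file: ", path)
  if (length(ln) == 1L && grepl("-", ln))
    return(geneOrder(ln, id = id, circular = circular))
  parts <- strsplit(ln, ":")
  labels <- vapply(parts, `[`, "", 1L)
  strand <- vapply(parts, function(p) if (length(p) > 1L) p[2] else NA_character_, "")
  geneOrder(labels, strand = strand, id = id, circular = circular)
}

#' Write the feature table of a genome as TSV
#'
#' Columns: name, class, start, end, strand, length (1-based inclusive
#' coordinates at this I/O boundary).
#' @param genome an [AnnotatedGenome-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(genome, path) {
  f <- genome@features
  out <- data.frame(name = f$name, class = f$class,
                    start = f$start + 1L, end = f$end,
                    strand = f$strand, length = f$end - f$start,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
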