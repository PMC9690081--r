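code5 <- geneticCode(5L)

test_that("a minimal GenBank record parses to the stated features", {
  p <- write_minimal_genbank(tempfile(fileext = ".gb"))
  g <- readGenBank(p)
  expect_s4_class(g, "AnnotatedGenome")
  expect_equal(genomeId(g), "TEST01")
  expect_true(isCircularGenome(g))
  expect_equal(nchar(genomeSeq(g)), 60L)
  f <- genomeFeatures(g)
  expect_equal(nrow(f), 2L)
  expect_equal(f$name, c("COX1", "trnM-CAT"))
  expect_equal(f$class, c("PCG", "tRNA"))
  expect_equal(f$start, c(0L, 30L))   # 0-based half-open internally
  expect_equal(f$end, c(30L, 60L))
  expect_equal(f$strand, c("+", "-"))
})

test_that("duplicate gene names get copy_index in coordinate order", {
  seq <- strrep("ATGAAATAAC", 9)  # 90 bp
  lines <- c(
    "LOCUS       DUP01 90 bp    DNA     circular   UNK",
    "FEATURES             Location/Qualifiers",
    "     CDS             31..60",
    "                     /gene=\"COX2\"",
    "     CDS             1..30",
    "                     /gene=\"COX2\"",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(substr(seq, 1, 60))),
    sprintf("%9d %s", 61, tolower(substr(seq, 61, 90))),
    "//")
  p <- tempfile(fileext = ".gb")
  writeLines(lines, p)
  g <- readGenBank(p)
  f <- genomeFeatures(g)
  expect_equal(f$name, c("COX2", "COX2"))
  expect_equal(f$copy_index, c(1L, 2L))
  expect_equal(f$start, c(0L, 30L))  # sorted by coordinate
})

test_that("GenBank write -> read round trip preserves the genome", {
  pair <- makeGenomePair(list(pcgCodons = 40L, nGenes = 6L, nTrna = 4L,
                              t = 0.1), seed = 42)
  g <- pair$genome1
  p <- tempfile(fileext = ".gb")
  writeGenBank(g, p)
  g2 <- readGenBank(p)
  expect_identical(genomeSeq(g2), genomeSeq(g))
  cols <- c("name", "class", "start", "end", "strand", "copy_index")
  expect_identical(genomeFeatures(g2)[cols], genomeFeatures(g)[cols])
  expect_identical(isCircularGenome(g2), isCircularGenome(g))
})

test_that("features spanning the origin are linearized with a recorded offset", {
  seq <- strrep("ACGTGGCCAT", 6)  # 60 bp
  lines <- c(
    "LOCUS       WRAP01 60 bp    DNA     circular   UNK",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(51..60,1..20)",
    "                     /gene=\"ATP8\"",
    "     tRNA            31..50",
    "                     /gene=\"trnM-CAT\"",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(substr(seq, 1, 60))),
    "//")
  p <- tempfile(fileext = ".gb")
  writeLines(lines, p)
  g <- readGenBank(p)
  expect_equal(g@originOffset, 50L)
  f <- genomeFeatures(g)
  atp8 <- f[f$name == "ATP8", ]
  expect_equal(atp8$start, 0L)
  expect_equal(atp8$end, 30L)
  # the rotated slice equals the wrap-around slice of the original
  expect_equal(substr(genomeSeq(g), 1, 30),
               paste0(substr(seq, 51, 60), substr(seq, 1, 20)))
})

test_that("format errors are rejected and unknown labels kept as 'other'", {
  p <- tempfile()
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "//"), p)
  expect_error(readGenBank(p), "ORIGIN")
  lines <- c(
    "LOCUS       U01 30 bp    DNA     circular   UNK",
    "FEATURES             Location/Qualifiers",
    "     misc_feature    1..30",
    "                     /gene=\"mysteryelement\"",
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(strrep("atg", 10))),
    "//")
  writeLines(lines, p)
  expect_warning(g <- readGenBank(p), "other")
  expect_equal(genomeFeatures(g)$class, "other")
  expect_equal(genomeFeatures(g)$name, "mysteryelement")  # passes through
  # feature beyond the sequence is a coordinate error
  lines[3] <- "     CDS             1..45"
  writeLines(lines, p)
  expect_error(readGenBank(p), "outside")
})

test_that("FASTA read/write round-trips seeded random records", {
  set.seed(7)
  recs <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(20:80, 1), replace = TRUE),
          collapse = ""), character(1))
  names(recs) <- paste0("rec", 1:100)
  p <- tempfile(fileext = ".fa")
  writeFastaSeqs(recs, p)
  back <- readFastaSeqs(p)
  expect_identical(back, recs)
  # multi-line wrapped sequences concatenate correctly, case folded
  writeLines(c(">x", "acgt", "ACGTNN", "acg"), p)
  expect_identical(unname(readFastaSeqs(p)), "ACGTACGTNNACG")
  writeLines(character(0), p)
  expect_error(readFastaSeqs(p))
})

test_that("extractCDS translates, orients and flags correctly", {
  feats <- data.frame(name = "ATP8", class = "PCG", start = 0L, end = 9L,
                      strand = "+", copy_index = 1L)
  g <- annotatedGenome("t", "ATGAAATAA", feats, circular = FALSE)
  cds <- extractCDS(g, code5)
  expect_equal(cds$seq, "ATGAAATAA")
  expect_equal(cds$protein, "MK")   # trailing stop dropped
  expect_false(cds$internal_stop)

  # minus strand: extracted sequence is the reverse complement of the slice
  s <- random_cds(40, seed = 3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g2 <- annotatedGenome("t2", paste0("AAAA", rc, "TTTT"),
                        data.frame(name = "ND2", class = "PCG", start = 4L,
                                   end = 4L + nchar(s), strand = "-",
                                   copy_index = 1L),
                        circular = FALSE)
  cds2 <- extractCDS(g2, code5)
  expect_identical(cds2$seq, s)
  expect_identical(cds2$protein,
                   sub("\\*$", "", translateCodons(s, code5)))

  # 120 bp ATP8-sized gene -> 120 nt CDS, 39 aa + stop
  s3 <- random_cds(40, seed = 9)
  expect_equal(nchar(s3), 120L)
  g3 <- annotatedGenome("t3", s3,
                        data.frame(name = "ATP8", class = "PCG", start = 0L,
                                   end = 120L, strand = "+", copy_index = 1L),
                        circular = FALSE)
  cds3 <- extractCDS(g3, code5)
  expect_equal(nchar(cds3$seq), 120L)
  expect_equal(nchar(cds3$protein), 39L)

  # internal stop and non-multiple-of-3 lengths flagged, not fatal
  g4 <- annotatedGenome("t4", "ATGTAAAAATG",
                        data.frame(name = "ND1", class = "PCG", start = 0L,
                                   end = 11L, strand = "+", copy_index = 1L),
                        circular = FALSE)
  expect_message(cds4 <- extractCDS(g4, code5), "internal stop")
  expect_true(cds4$internal_stop)
  expect_true(cds4$len_mod3)
})

test_that("every extracted CDS re-locates to its feature slice exactly", {
  pair <- makeGenomePair(list(pcgCodons = 30L, nGenes = 6L, nTrna = 4L),
                         seed = 11)
  g <- pair$genome1
  cds <- extractCDS(g, code5)
  f <- genomeFeatures(g)
  f <- f[f$class == "PCG", ]
  for (i in seq_len(nrow(f))) {
    slice <- substr(genomeSeq(g), f$start[i] + 1L, f$end[i])
    got <- cds$seq[cds$name == f$name[i] & cds$copy_index == f$copy_index[i]]
    if (f$strand[i] == "-")
      slice <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(slice)))
    expect_identical(got, slice)
  }
})

test_that("translation matches the code tables and an independent oracle", {
  expect_equal(translateCodons("ATA", code5), "M")
  expect_equal(translateCodons("ATA", geneticCode(1L)), "I")
  expect_equal(translateCodons("TGA", code5), "W")
  expect_equal(translateCodons("ATGNNATGA", code5), "MXW")
  s <- random_cds(300, seed = 21)
  aa5 <- oracle_code_table(5L)
  cods <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  expect_identical(translateCodons(s, code5),
                   paste(aa5[cods], collapse = ""))
  # cross-check against Biostrings' own translation
  expect_identical(
    sub("\\*$", "", translateCodons(s, code5)),
    sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(s),
      genetic.code = Biostrings::getGeneticCode("5")))))
})

test_that("gene labels normalize to the canonical scheme", {
  expect_equal(normalizeGeneLabel(c("COI", "cytb", "l-rRNA", "NAD4L")),
               c("COX1", "CYTB", "rrnL", "ND4L"))
  expect_equal(normalizeGeneLabel("TRNM-CAT"), "trnM-CAT")
  expect_equal(normalizeGeneLabel("unknownX"), "unknownX")  # passes through
})

test_that("gene order follows coordinates and rotation is an order rotation", {
  feats <- data.frame(name = c("A", "B", "C"), class = "PCG",
                      start = c(0L, 12L, 24L), end = c(12L, 24L, 36L),
                      strand = "+", copy_index = 1L)
  g <- annotatedGenome("r", strrep("ATGAAATTTCCC", 3), feats)
  expect_equal(geneLabels(geneOrderOf(g)), c("A", "B", "C"))

  # rotation of a circular genome yields a rotation of the order
  sq <- genomeSeq(g)
  rot <- paste0(substr(sq, 13, 36), substr(sq, 1, 12))
  feats2 <- data.frame(name = c("B", "C", "A"), class = "PCG",
                       start = c(0L, 12L, 24L), end = c(12L, 24L, 36L),
                       strand = "+", copy_index = 1L)
  g2 <- annotatedGenome("r2", rot, feats2)
  expect_true(is_rotation_of(geneLabels(geneOrderOf(g2)),
                             geneLabels(geneOrderOf(g))))

  # duplicated genes appear with both copies in coordinate order
  featsD <- data.frame(name = c("trnC-GCA", "ND1", "trnC-GCA"),
                       class = c("tRNA", "PCG", "tRNA"),
                       start = c(0L, 12L, 24L), end = c(12L, 24L, 36L),
                       strand = "+", copy_index = c(1L, 1L, 2L))
  gD <- annotatedGenome("rd", strrep("ATGAAATTTCCC", 3), featsD)
  expect_equal(geneLabels(geneOrderOf(gD)),
               c("trnC-GCA", "ND1", "trnC-GCA"))
})

test_that("ambiguity letters other than N are rejected", {
  expect_error(annotatedGenome("x", "ACGTRY"), "ambiguity")
  expect_silent(annotatedGenome("x", "ACGTN"))
})
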