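code5 <- geneticCode(5L)

make_caln <- function(c1, c2, gene = "g") {
  new("CodonAlignment", gene = gene, codons1 = c1, codons2 = c2,
      nCodons = length(c1), droppedColumns = 0L,
      alignedProteins = c("", ""))
}

test_that("protein alignment is optimal and handles the elementary cases", {
  al <- alignProteins("MKVLH", "MKVLH")
  expect_equal(al$a1, "MKVLH")
  expect_equal(al$a2, "MKVLH")

  al2 <- alignProteins("MKV", "MV")
  expect_equal(nchar(al2$a1), 3L)
  expect_equal(sum(strsplit(al2$a2, "")[[1]] == "-"), 1L)
  expect_error(alignProteins("", "MV"), "empty")
})

test_that("alignment score equals an independent affine-gap DP oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(88)
  for (i in 1:15) {
    p1 <- paste(sample(aas, sample(5:25, 1), TRUE), collapse = "")
    p2 <- paste(sample(aas, sample(5:25, 1), TRUE), collapse = "")
    got <- alignProteins(p1, p2)$score
    want <- oracle_align_score(p1, p2, B62, gapOpen = 10, gapExt = 1)
    expect_equal(got, want)
  }
})

test_that("back-translation maps residue columns to source codons", {
  ca <- backTranslateAlignment(list(a1 = "MK", a2 = "MK"),
                               "ATGAAA", "ATGAAG", code5)
  expect_equal(ca@nCodons, 2L)
  expect_equal(ca@codons1, c("ATG", "AAA"))
  expect_equal(ca@codons2, c("ATG", "AAG"))

  # one gap column -> nCodons = length - 1
  ca2 <- backTranslateAlignment(list(a1 = "MKV", a2 = "M-V"),
                                "ATGAAAGTT", "ATGGTA", code5)
  expect_equal(ca2@nCodons, 2L)
  expect_equal(ca2@droppedColumns, 1L)

  # protein/CDS mismatch is an error naming the offending residue
  expect_error(
    backTranslateAlignment(list(a1 = "MK", a2 = "MM"), "ATGAAA", "ATGAAA", code5),
    "residue 2")
})

test_that("codon alignment round-trips simulated pairs", {
  for (seed in c(3, 14, 27)) {
    p <- evolutionParams(omega = 0.4, kappa = 2, t = 0.4)
    anc <- random_cds(60, seed)
    ev <- evolveCodonPair(anc, p, seed = seed + 5)
    ca <- codonAlign(ev$seq1, ev$seq2, code5)
    # re-translating the codon rows reproduces the aligned proteins
    pr1 <- translateCodons(paste(ca@codons1, collapse = ""), code5)
    pr2 <- translateCodons(paste(ca@codons2, collapse = ""), code5)
    expect_identical(pr1, gsub("-", "", ca@alignedProteins[1]))
    expect_identical(pr2, gsub("-", "", ca@alignedProteins[2]))
  }
})

test_that("NG86 reproduces the worked third-position example", {
  caln <- make_caln(c("TTT", "GGG", "CAT"), c("TTC", "GGG", "CAT"))
  r <- kaksNG86(caln, code5)
  expect_equal(r@S, 5 / 3, tolerance = 1e-12)
  expect_equal(r@N, 22 / 3, tolerance = 1e-12)
  expect_equal(r@Sd, 1)
  expect_equal(r@Nd, 0)
  expect_equal(r@ka, 0)
  expect_equal(r@ks, -0.75 * log(0.2), tolerance = 1e-12)
})

test_that("identical sequences give zero rates and an NA ratio", {
  caln <- make_caln(c("ATG", "AAA", "GTT"), c("ATG", "AAA", "GTT"))
  expect_warning(kaksYN00(caln, code5), "fewer than 10")
  for (r in list(kaksNG86(caln, code5),
                 suppressWarnings(kaksYN00(caln, code5)))) {
    expect_equal(r@Sd, 0)
    expect_equal(r@Nd, 0)
    expect_equal(r@ka, 0)
    expect_equal(r@ks, 0)
    expect_true(is.na(r@ratio))
  }
})

test_that("NG86 difference counts equal recursive pathway enumeration on all codon pairs", {
  aa <- oracle_code_table(5L)
  stops <- names(aa)[aa == "*"]
  sense <- setdiff(ALL_CODONS, stops)
  siteTab <- vapply(sense, oracle_syn_sites, numeric(1), aa = aa, stops = stops)
  for (c1 in sense) {
    for (c2 in sense) {
      if (c1 == c2) next
      want <- oracle_pathway_counts(c1, c2, aa, stops)
      caln <- make_caln(c1, c2)
      r <- kaksNG86(caln, code5)
      if (is.null(want)) {
        expect_equal(r@Sd + r@Nd, 0)
        expect_true(length(r@notes) > 0)
      } else {
        expect_equal(r@Sd, want[["Sd"]], tolerance = 1e-12)
        expect_equal(r@Nd, want[["Nd"]], tolerance = 1e-12)
      }
      # independently recomputed sites
      expect_equal(r@S, (siteTab[[c1]] + siteTab[[c2]]) / 2, tolerance = 1e-12)
    }
  }
})

test_that("S + N = 3 * nCodons and swapping sequences changes nothing", {
  for (seed in c(5, 50, 500)) {
    ca <- random_codon_alignment(80, seed)
    for (fn in list(kaksNG86, kaksYN00)) {
      r <- fn(ca, code5)
      expect_equal(r@S + r@N, 3 * r@nCodons, tolerance = 1e-6)
      swapped <- make_caln(ca@codons2, ca@codons1, ca@gene)
      r2 <- fn(swapped, code5)
      for (sl in c("S", "N", "Sd", "Nd", "ka", "ks")) {
        expect_equal(slot(r, sl), slot(r2, sl), tolerance = 1e-9)
      }
    }
  }
})

test_that("YN00 with kappa forced to 1 and uniform frequencies reduces to NG86", {
  rel <- c()
  for (seed in 1:8) {
    p <- evolutionParams(omega = 0.4, kappa = 1, t = 0.4)
    anc <- random_cds(300, seed = 700 + seed)
    ev <- evolveCodonPair(anc, p, seed = 800 + seed)
    ca <- codonAlign(ev$seq1, ev$seq2, code5)
    ry <- kaksYN00(ca, code5, forceKappa = 1, frequencies = "uniform")
    rn <- kaksNG86(ca, code5)
    rel <- c(rel, abs(ry@ka / rn@ka - 1), abs(ry@ks / rn@ks - 1))
  }
  expect_lt(max(rel), 0.05)
})

test_that("estimated Ka rises with true omega at fixed divergence", {
  means <- vapply(c(0.05, 0.5, 1.5), function(om) {
    kas <- vapply(1:5, function(seed) {
      p <- evolutionParams(omega = om, kappa = 2, t = 0.4)
      anc <- random_cds(300, seed = 900 + seed)
      ev <- evolveCodonPair(anc, p, seed = 950 + seed)
      kaksNG86(codonAlign(ev$seq1, ev$seq2, code5), code5)@ka
    }, numeric(1))
    mean(kas)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("Fisher p matches exhaustive enumeration and the elementary cases", {
  expect_equal(fisherKaKs(10, 30, 0, 0), 1)
  # the worked 2x2 example: (2,8; 1,25)
  expect_equal(fisherKaKs(S = 10, N = 26, Sd = 2, Nd = 1),
               oracle_fisher_p(2, 8, 1, 25), tolerance = 1e-12)
  expect_error(fisherKaKs(S = 1, N = 26, Sd = 2, Nd = 1), "negative")
  set.seed(99)
  for (i in 1:40) {
    m <- sample(1:40, 1); n <- sample(1:40, 1)
    a <- sample(0:m, 1); c2 <- sample(0:n, 1)
    got <- fisherKaKs(S = m, N = n, Sd = a, Nd = c2)
    expect_equal(got, oracle_fisher_p(a, m - a, c2, n - c2), tolerance = 1e-12)
    # cross-check against stats::fisher.test
    ft <- stats::fisher.test(matrix(c(a, m - a, c2, n - c2), 2, byrow = TRUE))
    expect_equal(got, ft$p.value, tolerance = 1e-6)
  }
})

test_that("strong purifying selection is detected by the Fisher validation", {
  hits <- 0L
  nrep <- 25L
  for (seed in seq_len(nrep)) {
    p <- evolutionParams(omega = 0.05, kappa = 2, t = 0.5)
    anc <- random_cds(500, seed = 1200 + seed)
    ev <- evolveCodonPair(anc, p, seed = 1300 + seed)
    r <- kaksYN00(codonAlign(ev$seq1, ev$seq2, code5), code5)
    if (!is.na(r@fisherP) && r@fisherP < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("the pairwise matrix covers genes x references with NA rows for gaps", {
  pair <- makeGenomePair(list(pcgCodons = 40L, nGenes = 8L, nTrna = 4L,
                              t = 0.2), seed = 61)
  g1 <- pair$genome1
  # genome vs itself: all Ka = Ks = 0
  self <- pairwiseKaKsMatrix(g1, g1, method = "NG86")
  expect_true(all(self$Ka == 0 & self$Ks == 0))
  expect_true(all(is.na(self$KaKs)))

  refs <- lapply(c(62, 63, 64), function(s)
    makeGenomePair(list(pcgCodons = 40L, nGenes = 8L, nTrna = 4L, t = 0.2),
                   seed = s)$genome2)
  # shared PCG labels depend on each seed's sampled inventory; row count is
  # genes x references regardless
  tabs <- pairwiseKaKsMatrix(g1, refs, method = "YN00")
  nGenes <- length(unique(extractCDS(g1)$name))
  expect_equal(nrow(tabs), nGenes * 3L)
  expect_true(all(tabs$note[is.na(tabs$Ka)] != ""))
})
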