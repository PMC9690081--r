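code5 <- geneticCode(5L)                      # table8-standard partition
code5m <- geneticCode(5L, "table5-mito")

test_that("codon counting matches a brute-force recount", {
  cnt <- countCodons("ATGAAATAA", geneticCode(1L))
  expect_equal(cnt[["ATG"]], 1L)
  expect_equal(cnt[["AAA"]], 1L)
  expect_equal(sum(cnt), 2L)                  # TAA excluded from totals

  set.seed(55)
  cdsSet <- lapply(1:8, function(i) random_cds(sample(20:60, 1), seed = 100 + i))
  got <- countCodons(cdsSet, code5, excludeStopCounts = FALSE)
  # independent sliding-window recount
  want <- integer(64); names(want) <- ALL_CODONS
  for (s in cdsSet) {
    for (k in seq(1, nchar(s) - 2, by = 3)) {
      cod <- substr(s, k, k + 2)
      want[cod] <- want[cod] + 1L
    }
  }
  expect_equal(as.integer(got), as.integer(want))

  # removing one CDS decreases totals by exactly its codon count
  gotMinus <- countCodons(cdsSet[-1], code5, excludeStopCounts = FALSE)
  expect_equal(sum(got) - sum(gotMinus), nchar(cdsSet[[1]]) %/% 3L)

  # codons containing N are skipped and tallied
  withN <- countCodons("ATGNNATTT", code5)
  expect_equal(attr(withN, "n_skipped"), 1L)
  expect_equal(sum(withN), 2L)
  expect_error(countCodons(character(0), code5), "empty")
})

test_that("RSCU reproduces published leucine and isoleucine values", {
  # six-codon Leu family of the venerid profile
  leu <- c(UUA = 430, UUG = 116, CUU = 104, CUC = 2, CUA = 55, CUG = 12)
  cu <- rscu(leu, code5)
  expect_equal(roundHalfUp(rscuValues(cu)[["TTA"]], 2), 3.59)
  # Ile family with AUA under the standard partition (k = 3)
  ile <- c(AUU = 239, AUC = 29, AUA = 253)
  expect_equal(roundHalfUp(rscuValues(rscu(ile, code5))[["ATT"]], 2), 1.38)
  # uniform family -> RSCU 1 everywhere
  unif <- c(GGT = 7, GGC = 7, GGA = 7, GGG = 7)
  expect_true(all(rscuValues(rscu(unif, code5))[names(unif)] == 1))
  expect_error(rscu(c(ZZZ = 5), code5), "absent")
})

test_that("RSCU family sums equal family sizes on random counts", {
  set.seed(66)
  for (rep in 1:20) {
    cnt <- rpois(64, lambda = 30)
    names(cnt) <- ALL_CODONS
    for (code in list(code5, code5m, geneticCode(1L))) {
      cnt2 <- cnt
      cnt2[names(cnt2) %in% stopCodons(code)] <- 0  # stop-exclusion convention
      cu <- rscu(cnt2, code)
      fam <- code@family
      for (f in unique(fam)) {
        i <- names(fam)[fam == f]
        if (sum(cnt2[i]) == 0) next
        expect_equal(sum(rscuValues(cu)[i]), length(i), tolerance = 1e-9)
      }
    }
  }
})

test_that("RSCU is invariant to scaling all counts in a family", {
  leu <- c(TTA = 40, TTG = 10, CTT = 10, CTC = 2, CTA = 5, CTG = 3)
  r1 <- rscuValues(rscu(leu, code5))[names(leu)]
  r2 <- rscuValues(rscu(leu * 17, code5))[names(leu)]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("single-codon families and zero families behave as documented", {
  cu <- rscu(c(ATG = 12), code5m)   # Met family under the mito partition: ATA+ATG
  expect_equal(rscuValues(cu)[["ATG"]], 2)  # 2-codon family, all mass on one
  cuTrp <- rscu(c(TGG = 5), code5)  # single-codon family under table8-standard
  expect_equal(rscuValues(cuTrp)[["TGG"]], 1)
  cu0 <- rscu(c(AAA = 3), code5)
  expect_true(any(grepl("zero total", cu0@flags)))
  expect_equal(rscuValues(cu0)[["GGG"]], 0)
})

test_that("start/stop profile recovers planted codons", {
  feats <- data.frame(name = "ND3", class = "PCG", start = 0L, end = 9L,
                      strand = "+", copy_index = 1L)
  g <- annotatedGenome("s", "ATGAAATAA", feats, circular = FALSE)
  st <- startStopTable(g, code5)
  expect_equal(st$start_codon, "ATG")
  expect_equal(st$stop_codon, "TAA")
  expect_true(st$canonical_start)

  # generator plants ATG starts and TAA stops in every PCG; at zero
  # divergence both are recovered exactly (at t > 0 starts may mutate,
  # as they do in real mitogenomes, but stop codons are held fixed)
  pair <- makeGenomePair(list(pcgCodons = 25L, nGenes = 8L, nTrna = 4L,
                              t = 0), seed = 31)
  st2 <- startStopTable(pair$genome1, code5)
  expect_true(all(st2$start_codon == "ATG"))
  expect_true(all(st2$stop_codon == "TAA"))
  expect_equal(st2$length_bp, rep(75L, nrow(st2)))
  pairT <- makeGenomePair(list(pcgCodons = 25L, nGenes = 8L, nTrna = 4L),
                          seed = 31)
  expect_true(all(startStopTable(pairT$genome2, code5)$stop_codon == "TAA"))
})

test_that("amino-acid ranking equals a brute-force grouping oracle", {
  onlyLys <- aaUsageRanking(c(AAA = 10), code5)
  expect_equal(names(onlyLys)[1], "K")
  set.seed(77)
  for (rep in 1:10) {
    cnt <- rpois(64, 20)
    names(cnt) <- ALL_CODONS
    got <- aaUsageRanking(cnt, code5)
    fam <- code5@family
    want <- tapply(as.numeric(cnt), fam[ALL_CODONS], sum)
    want <- want[names(want) != "*"]
    want <- want[order(-want, names(want))]
    expect_equal(names(got), names(want))
    expect_equal(unname(got), unname(as.numeric(want)))
  }
})

test_that("third-position degeneracy matches an exhaustive code scan", {
  deg <- degeneracyClasses(code5)
  expect_equal(unname(deg[["GGA"]]), 4L)        # Gly: fourfold
  expect_true(is.na(deg[["TAA"]]))              # stop
  # independent scan over all 64 codons
  aa <- oracle_code_table(5L)
  stops <- names(aa)[aa == "*"]
  for (cod in ALL_CODONS) {
    if (cod %in% stops) next
    alt <- paste0(substr(cod, 1, 2), c("T", "C", "A", "G"))
    expect_equal(unname(deg[[cod]]),
                 sum(aa[alt] == aa[[cod]] & !(alt %in% stops)))
  }
  # number of fourfold codons under table 5, via the same oracle
  n4 <- sum(vapply(setdiff(ALL_CODONS, stops), function(cod) {
    alt <- paste0(substr(cod, 1, 2), c("T", "C", "A", "G"))
    sum(aa[alt] == aa[[cod]]) == 4L
  }, logical(1)))
  expect_equal(sum(deg == 4L, na.rm = TRUE), n4)
})

test_that("degenerate-site composition counts third positions per class", {
  d <- degenerateSiteComposition("GGA", code5)
  expect_equal(d$A[d$degeneracy == 4], 1)
  expect_equal(sum(d$n_codons), 1)
  # published venerid codon counts: 2- and 4-fold classes are AT-biased
  for (sp in c("Rphilippinarum", "Rvariegatus")) {
    dd <- degenerateSiteComposition(veneridCodonProfile(sp), code5)
    expect_gt(dd$at_fraction[dd$degeneracy == 2], 0.5)
    expect_gt(dd$at_fraction[dd$degeneracy == 4], 0.5)
  }
})

test_that("the two RSCU dialects differ exactly where documented", {
  # AUA: Ile family (k=3) under table8-standard, Met family under table5-mito
  ile <- c(ATT = 239, ATC = 29, ATA = 253, ATG = 79)
  r8 <- rscuValues(rscu(ile, code5))
  r5 <- rscuValues(rscu(ile, code5m))
  expect_equal(roundHalfUp(r8[["ATA"]], 2), 1.46)
  expect_equal(roundHalfUp(r5[["ATA"]], 2),
               roundHalfUp(2 * 253 / (253 + 79), 2))
})
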