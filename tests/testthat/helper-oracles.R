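# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: pathway enumeration is recursive instead
# of permutation-table based, alignment scoring is a from-scratch Gotoh
# DP, Fisher probabilities come from choose() instead of dhyper().

ALL_CODONS <- local({
  b <- c("T", "C", "A", "G")
  paste0(rep(b, each = 16L), rep(b, each = 4L, times = 4L), rep(b, times = 16L))
})

oracle_code_table <- function(tableId) {
  gc <- Biostrings::getGeneticCode(as.character(tableId))
  structure(as.character(gc), names = names(gc))
}

# --- brute-force NG86 pathway counting (recursive DFS) -------------------
oracle_pathway_counts <- function(c1, c2, aa, stops) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  acc <- list(syn = numeric(0), non = numeric(0))
  walk <- function(cur, remaining, nsyn, nnon) {
    if (!length(remaining)) {
      acc$syn <<- c(acc$syn, nsyn)
      acc$non <<- c(acc$non, nnon)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) next
      walk(nxt, setdiff(remaining, p),
           nsyn + (aa[[cur]] == aa[[nxt]]),
           nnon + (aa[[cur]] != aa[[nxt]]))
    }
  }
  walk(c1, diffs, 0, 0)
  if (!length(acc$syn)) return(NULL)  # all pathways blocked by stops
  c(Sd = mean(acc$syn), Nd = mean(acc$non))
}

# --- independent NG86 synonymous-site fraction ----------------------------
oracle_syn_sites <- function(codon, aa, stops) {
  bases <- c("T", "C", "A", "G")
  s <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (!(alt %in% stops) && aa[[alt]] == aa[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# --- Gotoh affine-gap global alignment, score only ------------------------
oracle_align_score <- function(p1, p2, subMat, gapOpen, gapExt) {
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gapOpen - gapExt * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gapOpen - gapExt * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- subMat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt,
                     X[i - 1, j] - gapExt,
                     Y[i - 1, j] - gapOpen - gapExt)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt,
                     Y[i, j - 1] - gapExt,
                     X[i, j - 1] - gapOpen - gapExt)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive two-sided Fisher p via choose() ---------------------------
oracle_fisher_p <- function(a, b, c2, d) {
  m <- a + b; n <- c2 + d; k <- a + c2
  if (k == 0 || m == 0 || n == 0) return(1)
  supp <- max(0, k - n):min(k, m)
  probs <- vapply(supp, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  pObs <- probs[supp == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# --- misc -----------------------------------------------------------------
is_rotation_of <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  any(vapply(seq_along(y), function(r)
    identical(y[((seq_along(y) + r - 2L) %% length(y)) + 1L], x), logical(1)))
}

random_cds <- function(nCodons, seed, code = geneticCode(5L)) {
  prof <- stats::setNames(rep(1, 64), ALL_CODONS)
  sampleCdsFromRscu(prof, nCodons, code, seed = seed)
}

random_codon_alignment <- function(nCodons, seed, divergence = 0.3,
                                   omega = 0.5, code = geneticCode(5L)) {
  p <- evolutionParams(omega = omega, kappa = 2, t = divergence)
  anc <- random_cds(nCodons, seed, code)
  ev <- evolveCodonPair(anc, p, seed = seed + 1L)
  codonAlign(ev$seq1, ev$seq2, code)
}

# minimal hand-written GenBank record (60 bp, 2 features) used by IO tests
write_minimal_genbank <- function(path,
                                  seq = paste0(strrep("ATG", 10),
                                               strrep("GGC", 10))) {
  stopifnot(nchar(seq) == 60L)
  lines <- c(
    "LOCUS       TEST01 60 bp    DNA     circular   UNK",
    "DEFINITION  synthetic two-gene test record.",
    "ACCESSION   TEST01",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..30",
    "                     /gene=\"COX1\"",
    "     tRNA            complement(31..60)",
    "                     /gene=\"trnM-CAT\"",
    "ORIGIN",
    sprintf("%9d %s", 1, gsub("(.{10})", "\\1 ", tolower(seq))),
    "//")
  writeLines(lines, path)
  path
}
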